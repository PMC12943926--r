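#' Construct a (labelled) point cloud
#'
#' The universal currency of the pipeline: an `N x 3` matrix of XYZ
#' coordinates in metres, with optional per-point semantic class
#' (`0` = ground, `1` = tree, `-1` = unknown), per-point instance id
#' (`-1` = unassigned, `0` = the ground instance, `>= 1` = tree instances)
#' and optional RGB color in `[0, 1]`.
#'
#' @param coords numeric matrix, N x 3 (x, y, z in metres).
#' @param semantic integer vector of length N or `NULL`.
#' @param instance integer vector of length N or `NULL`.
#' @param color numeric matrix N x 3 in `[0, 1]` or `NULL`.
#' @return an object of class `forest_cloud`.
#' @export
point_cloud <- function(coords, semantic = NULL, instance = NULL, color = NULL) {
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(0), 0L, 3L)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have 3 columns (x, y, z)")
  if (nrow(coords) > 0L && !all(is.finite(coords))) stop("coords must be finite")
  n <- nrow(coords)
  if (is.null(semantic)) semantic <- rep(-1L, n)
  if (is.null(instance)) instance <- rep(-1L, n)
  semantic <- as.integer(semantic)
  instance <- as.integer(instance)
  if (length(semantic) != n) stop("semantic must have length N = ", n)
  if (length(instance) != n) stop("instance must have length N = ", n)
  if (any(instance >= 0L & semantic < 0L))
    stop("every point with an instance id must carry a valid semantic class")
  if (!is.null(color)) {
    color <- as.matrix(color)
    storage.mode(color) <- "double"
    if (nrow(color) != n || ncol(color) != 3L) stop("color must be N x 3")
  }
  structure(
    list(coords = coords, semantic = semantic, instance = instance, color = color),
    class = "forest_cloud"
  )
}

#' @export
print.forest_cloud <- function(x, ...) {
  n <- nrow(x$coords)
  lab <- sum(x$instance >= 0L)
  cat(sprintf("<forest_cloud> %d points, %d labelled, %s color\n",
              n, lab, if (is.null(x$color)) "no" else "with"))
  if (n > 0L) {
    r <- apply(x$coords, 2L, range)
    cat(sprintf("  extent: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] m\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `forest_cloud`.
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$coords)

#' Subset a point cloud by point index
#' @param cloud a `forest_cloud`.
#' @param idx integer or logical index over points.
#' @return the subsetted `forest_cloud`.
#' @export
cloud_subset <- function(cloud, idx) {
  point_cloud(cloud$coords[idx, , drop = FALSE],
              cloud$semantic[idx], cloud$instance[idx],
              if (is.null(cloud$color)) NULL else cloud$color[idx, , drop = FALSE])
}

#' Concatenate point clouds
#' @param ... `forest_cloud` objects.
#' @return a single `forest_cloud`.
#' @export
cloud_bind <- function(...) {
  cl <- list(...)
  if (length(cl) == 1L && is.list(cl[[1]]) && !inherits(cl[[1]], "forest_cloud")) cl <- cl[[1]]
  coords <- do.call(rbind, lapply(cl, `[[`, "coords"))
  col <- NULL
  if (all(vapply(cl, function(c) !is.null(c$color), logical(1))))
    col <- do.call(rbind, lapply(cl, `[[`, "color"))
  point_cloud(coords,
              unlist(lapply(cl, `[[`, "semantic")),
              unlist(lapply(cl, `[[`, "instance")),
              col)
}

# Run expr with a private, restored RNG state seeded at `seed`.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Derive a child seed < 2^31 from a master seed and a stream index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 11) %% 2147483629)
}

col_mins <- function(m) if (nrow(m)) apply(m, 2L, min) else rep(NA_real_, ncol(m))
col_maxs <- function(m) if (nrow(m)) apply(m, 2L, max) else rep(NA_real_, ncol(m))
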