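#' Statistical outlier removal (SOR)
#'
#' Removes points whose mean distance to their `k` nearest neighbours exceeds
#' the global mean plus `std_multiplier` standard deviations of that
#' statistic. Labels are carried through.
#'
#' @param cloud a `forest_cloud` with more than `k_neighbors` points.
#' @param k_neighbors number of nearest neighbours (>= 1).
#' @param std_multiplier threshold multiplier on the standard deviation.
#' @return the filtered `forest_cloud`.
#' @export
sor_filter <- function(cloud, k_neighbors = 8L, std_multiplier = 2) {
  stopifnot(inherits(cloud, "forest_cloud"))
  n <- n_points(cloud)
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  if (n <= k_neighbors) stop("need more than k_neighbors = ", k_neighbors, " points")
  md <- knn_mean_distance(cloud$coords, k_neighbors)
  thr <- mean(md) + std_multiplier * stats::sd(md)
  cloud_subset(cloud, md <= thr)
}

# Mean distance to the k nearest neighbours, brute force in blocks.
knn_mean_distance <- function(coords, k) {
  n <- nrow(coords)
  chunk <- max(1L, floor(2e7 / n))
  out <- numeric(n)
  sq <- rowSums(coords^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(coords[s:e, , drop = FALSE], coords)
    d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf  # exclude self
    d2[d2 < 0] <- 0
    out[s:e] <- apply(d2, 1L, function(r) mean(sqrt(sort.int(r, partial = k)[seq_len(k)])))
  }
  out
}

# Map points to XY grid cells; returns list(cell index per point, grid dims,
# origin, occupied-cell row/col).
.xy_cells <- function(coords, cell_size, origin = NULL) {
  if (is.null(origin)) origin <- c(min(coords[, 1]), min(coords[, 2]))
  cx <- pmax(floor((coords[, 1] - origin[1]) / cell_size), 0)
  cy <- pmax(floor((coords[, 2] - origin[2]) / cell_size), 0)
  nr <- max(cx) + 1L; nc <- max(cy) + 1L
  list(ix = as.integer(cx) + 1L, iy = as.integer(cy) + 1L,
       lin = as.integer(cx) + 1L + as.integer(cy) * nr,
       nr = as.integer(nr), nc = as.integer(nc), origin = origin)
}

# Fill NA cells of a matrix from the nearest non-NA cell (BFS ring growth).
.fill_nearest <- function(m) {
  if (!anyNA(m)) return(m)
  if (all(is.na(m))) stop("cannot fill a grid with no observed cells")
  while (anyNA(m)) {
    nr <- nrow(m); nc <- ncol(m)
    shifted <- list(rbind(m[-1, , drop = FALSE], NA),
                    rbind(NA, m[-nr, , drop = FALSE]),
                    cbind(m[, -1, drop = FALSE], NA),
                    cbind(NA, m[, -nc, drop = FALSE]))
    cand <- Reduce(function(a, b) ifelse(is.na(a), b, a), shifted)
    m[is.na(m)] <- cand[is.na(m)]
  }
  m
}

# 3x3 median smoothing with border replication.
.median3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2L || nc < 2L) return(m)
  padr <- rbind(m[1, ], m, m[nr, ])
  pad <- cbind(padr[, 1], padr, padr[, nc])
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- stats::median(pad[i:(i + 2), j:(j + 2)])
  out
}

#' Classify points into ground and tree
#'
#' A grid-minimum ground classifier: the minimum Z per XY cell is median
#' smoothed over 3x3 cell neighbourhoods, and points within
#' `height_threshold` of that local ground level are classed as ground,
#' everything above as tree. The interface is pluggable, so a full
#' cloth-simulation filter could be swapped in; on the flat, open plantation
#' terrain this pipeline targets, the grid minimum is adequate.
#'
#' @param cloud a `forest_cloud`.
#' @param cell_size XY cell size, metres.
#' @param height_threshold points within this height of the smoothed cell
#'   minimum become ground, metres.
#' @return the cloud with `semantic` filled (0 ground, 1 tree).
#' @export
classify_ground <- function(cloud, cell_size = 0.5, height_threshold = 0.3) {
  stopifnot(inherits(cloud, "forest_cloud"))
  if (cell_size <= 0) stop("cell_size must be positive")
  n <- n_points(cloud)
  if (n == 0L) return(cloud)
  g <- .xy_cells(cloud$coords, cell_size)
  zmin <- matrix(NA_real_, g$nr, g$nc)
  agg <- tapply(cloud$coords[, 3], g$lin, min)
  zmin[as.integer(names(agg))] <- agg
  zmin <- .median3(.fill_nearest(zmin))
  ground_level <- zmin[cbind(g$ix, g$iy)]
  sem <- ifelse(cloud$coords[, 3] - ground_level <= height_threshold, 0L, 1L)
  out <- cloud
  out$semantic <- as.integer(sem)
  out
}

#' Build a digital elevation model from ground points
#'
#' Per-cell minimum Z of the ground-class points; empty cells are filled from
#' the nearest non-empty cell.
#'
#' @param cloud a `forest_cloud`; only points with `semantic == 0` are used.
#'   If no semantic labels are present, all points are used.
#' @param cell_size DEM cell size, metres.
#' @return a `dem_grid`: `heights` matrix (rows = x cells, cols = y cells),
#'   `cell_size`, `origin_xy`.
#' @export
build_dem <- function(cloud, cell_size = 0.5) {
  stopifnot(inherits(cloud, "forest_cloud"))
  use <- if (any(cloud$semantic == 0L)) cloud$semantic == 0L else
    rep(TRUE, n_points(cloud))
  if (!any(use)) stop("no ground points: ground filtering failed upstream")
  coords <- cloud$coords[use, , drop = FALSE]
  g <- .xy_cells(coords, cell_size)
  h <- matrix(NA_real_, g$nr, g$nc)
  agg <- tapply(coords[, 3], g$lin, min)
  h[as.integer(names(agg))] <- agg
  structure(list(heights = .fill_nearest(h), cell_size = cell_size,
                 origin_xy = g$origin), class = "dem_grid")
}

# Bilinear interpolation of the DEM at XY positions (cell centers are the
# sample points; queries are clamped to the grid border).
dem_interpolate <- function(dem, xy) {
  h <- dem$heights; nr <- nrow(h); nc <- ncol(h)
  gx <- (xy[, 1] - dem$origin_xy[1]) / dem$cell_size - 0.5
  gy <- (xy[, 2] - dem$origin_xy[2]) / dem$cell_size - 0.5
  gx <- pmin(pmax(gx, 0), nr - 1); gy <- pmin(pmax(gy, 0), nc - 1)
  x0 <- pmin(floor(gx), nr - 2L); y0 <- pmin(floor(gy), nc - 2L)
  if (nr == 1L) x0 <- rep(0, length(gx))
  if (nc == 1L) y0 <- rep(0, length(gy))
  fx <- gx - x0; fy <- gy - y0
  i0 <- as.integer(x0) + 1L; j0 <- as.integer(y0) + 1L
  i1 <- pmin(i0 + 1L, nr); j1 <- pmin(j0 + 1L, nc)
  h[cbind(i0, j0)] * (1 - fx) * (1 - fy) + h[cbind(i1, j0)] * fx * (1 - fy) +
    h[cbind(i0, j1)] * (1 - fx) * fy + h[cbind(i1, j1)] * fx * fy
}

#' Normalize point heights above the terrain
#'
#' `z' = z - DEM(x, y)` with bilinear interpolation; XY and labels unchanged.
#'
#' @param cloud a `forest_cloud`.
#' @param dem a `dem_grid` from [build_dem()].
#' @return the height-normalized cloud.
#' @export
normalize_height <- function(cloud, dem) {
  stopifnot(inherits(cloud, "forest_cloud"), inherits(dem, "dem_grid"))
  out <- cloud
  out$coords[, 3] <- cloud$coords[, 3] - dem_interpolate(dem, cloud$coords[, 1:2, drop = FALSE])
  out
}

#' Balance ground and tree point counts
#'
#' If the ground/tree ratio exceeds `target_ratio`, ground points are
#' uniformly subsampled (seeded) to exactly the target count; tree points are
#' never removed.
#'
#' @param cloud a `forest_cloud` with semantic labels.
#' @param target_ratio maximum allowed ground/tree point ratio (> 0).
#' @param rng_seed integer seed for the subsample.
#' @return the balanced `forest_cloud`.
#' @export
balance_classes <- function(cloud, target_ratio = 1.0, rng_seed = 1L) {
  stopifnot(inherits(cloud, "forest_cloud"))
  if (target_ratio <= 0) stop("target_ratio must be positive")
  ground <- which(cloud$semantic == 0L)
  n_tree <- sum(cloud$semantic == 1L)
  target <- floor(target_ratio * n_tree)
  if (length(ground) <= target || n_tree == 0L) return(cloud)
  keep_ground <- with_seed(rng_seed, sort(sample(ground, target)))
  keep <- sort(c(setdiff(seq_len(n_points(cloud)), ground), keep_ground))
  cloud_subset(cloud, keep)
}

#' Partition a cloud into sliding-window blocks
#'
#' Square XY windows of side `block_size` at stride `stride`; the last window
#' per axis is clamped to the maximum corner so no point is lost. Points on
#' window borders are duplicated into every window containing them; instance
#' ids are kept as-is within each block.
#'
#' @param cloud a `forest_cloud`.
#' @param block_size window side, metres.
#' @param stride window stride, metres, with `0 < stride <= block_size`.
#' @param min_points windows with fewer points are discarded.
#' @return list of blocks; each block is a list with `cloud`,
#'   `window_origin_xy` and `block_size`.
#' @export
tile_blocks <- function(cloud, block_size = 10, stride = 5, min_points = 100L) {
  stopifnot(inherits(cloud, "forest_cloud"))
  if (!(stride > 0 && stride <= block_size)) stop("need 0 < stride <= block_size")
  if (n_points(cloud) == 0L) return(list())
  lo <- col_mins(cloud$coords)[1:2]
  hi <- col_maxs(cloud$coords)[1:2]
  axis_origins <- function(a, b) {
    ext <- b - a
    if (ext <= block_size) return(a)
    ori <- a + stride * (seq_len(ceiling((ext - block_size) / stride) + 1L) - 1L)
    ori[ori > b - block_size] <- b - block_size
    unique(ori)
  }
  ox <- axis_origins(lo[1], hi[1]); oy <- axis_origins(lo[2], hi[2])
  blocks <- list()
  for (x0 in ox) for (y0 in oy) {
    sel <- cloud$coords[, 1] >= x0 & cloud$coords[, 1] <= x0 + block_size &
      cloud$coords[, 2] >= y0 & cloud$coords[, 2] <= y0 + block_size
    if (sum(sel) < min_points) next
    blocks[[length(blocks) + 1L]] <- list(cloud = cloud_subset(cloud, sel),
                                          window_origin_xy = c(x0, y0),
                                          block_size = block_size)
  }
  blocks
}

#' Split blocks into train / validation / test sets
#'
#' Either a seeded random split by fractions, or a spatially separate test
#' region declared as an XY rectangle (blocks whose window intersects the
#' rectangle become test; the rest are split train/val).
#'
#' @param blocks list of blocks from [tile_blocks()].
#' @param train_frac,val_frac fractions in (0, 1), summing to <= 1; the
#'   remainder is the test set.
#' @param rng_seed seed for the random split.
#' @param test_rect optional `c(xmin, ymin, xmax, ymax)` test rectangle.
#' @return list with elements `train`, `val`, `test` (lists of blocks).
#' @export
split_dataset <- function(blocks, train_frac = 0.8, val_frac = 0.2,
                          rng_seed = 1L, test_rect = NULL) {
  if (train_frac <= 0 || train_frac >= 1 || val_frac <= 0 || val_frac >= 1 ||
      train_frac + val_frac > 1 + 1e-9)
    stop("fractions must lie in (0,1) and sum to <= 1")
  pool <- seq_along(blocks)
  test_idx <- integer(0)
  if (!is.null(test_rect)) {
    test_idx <- which(vapply(blocks, function(b) {
      o <- b$window_origin_xy; s <- b$block_size
      o[1] < test_rect[3] && o[1] + s > test_rect[1] &&
        o[2] < test_rect[4] && o[2] + s > test_rect[2]
    }, logical(1)))
    pool <- setdiff(pool, test_idx)
  }
  n <- length(pool)
  n_train <- round(train_frac / (train_frac + val_frac) * n)
  if (is.null(test_rect)) {
    n_train <- floor(train_frac * length(blocks))
    n_val <- floor(val_frac * length(blocks))
    if (n_train < 1L || n_val < 1L) stop("fewer blocks than requested splits")
    ord <- with_seed(rng_seed, sample(pool))
    return(list(train = blocks[ord[seq_len(n_train)]],
                val = blocks[ord[n_train + seq_len(n_val)]],
                test = blocks[ord[-seq_len(n_train + n_val)]]))
  }
  if (n_train < 1L || n - n_train < 1L) stop("fewer blocks than requested splits")
  ord <- with_seed(rng_seed, sample(pool))
  list(train = blocks[ord[seq_len(n_train)]],
       val = blocks[ord[-seq_len(n_train)]],
       test = blocks[test_idx])
}

#' Run the full preprocessing chain on a raw cloud
#'
#' SOR denoising, ground classification, DEM height normalization, class
#' balancing and sliding-window tiling, in that order.
#'
#' @param cloud a raw `forest_cloud`.
#' @param config a configuration list, see [desk_profile()]; the
#'   `preprocess` sub-list holds all thresholds.
#' @return list of training-ready blocks.
#' @export
preprocess_cloud <- function(cloud, config = desk_profile()) {
  pc <- config$preprocess
  cloud <- sor_filter(cloud, pc$sor_k, pc$sor_multiplier)
  cloud <- classify_ground(cloud, pc$ground_cell, pc$ground_threshold)
  dem <- build_dem(cloud, pc$dem_cell)
  cloud <- normalize_height(cloud, dem)
  cloud <- balance_classes(cloud, pc$target_ratio, pc$seed %||% 1L)
  tile_blocks(cloud, pc$block_size, pc$stride, pc$min_points)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
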