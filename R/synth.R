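#' Parameters of a procedurally generated leaf-off tree
#'
#' A tree is a recursive branching skeleton: a trunk segment, then
#' `branching_factor` children per node at every depth up to `branch_depth`
#' (depth 1 = trunk only), each child rotated away from its parent axis by
#' roughly `branch_angle_deg` with jitter, with segment length and radius
#' tapering geometrically. Points are sampled on the cylinder surfaces only
#' (leaf-off: no foliage points).
#'
#' @param height total tree height, metres.
#' @param trunk_radius trunk radius at the base, metres.
#' @param branch_depth recursion depth (>= 1; 1 = bare trunk).
#' @param branching_factor children per node (>= 1).
#' @param branch_angle_deg mean branching angle off the parent axis, in (0, 90).
#' @param crown_radius nominal crown radius, metres (rescaled per plot by the
#'   crown overlap factor).
#' @param points_per_m2 sampling density on the branch surfaces, points per
#'   square metre of cylinder surface.
#' @return a `tree_params` list.
#' @export
tree_params <- function(height = 12, trunk_radius = 0.12, branch_depth = 4L,
                        branching_factor = 3L, branch_angle_deg = 35,
                        crown_radius = 2.2, points_per_m2 = 600) {
  p <- list(height = height, trunk_radius = trunk_radius,
            branch_depth = as.integer(branch_depth),
            branching_factor = as.integer(branching_factor),
            branch_angle_deg = branch_angle_deg, crown_radius = crown_radius,
            points_per_m2 = points_per_m2)
  if (any(unlist(p) <= 0)) stop("all tree parameters must be positive")
  if (branch_angle_deg <= 0 || branch_angle_deg >= 90)
    stop("branch_angle_deg must be in (0, 90)")
  structure(p, class = "tree_params")
}

#' Parameters of a synthetic plantation plot
#'
#' Emulates a leaf-off plantation block: trees on a jittered planting grid
#' (4 trees on a 10 m block at 5 m spacing), a roughened ground surface
#' sampled at uniform density, Gaussian coordinate noise and uniform dropout.
#' The ground forms its own instance (id 0); trees are instances 1..T.
#'
#' @param extent square plot side, metres.
#' @param grid_spacing planting grid spacing, metres (< extent).
#' @param position_jitter uniform jitter of stem positions, metres.
#' @param crown_overlap_factor effective crown radius as a fraction of half
#'   the grid spacing; adjacent crowns interlace when >= 1.
#' @param ground_roughness amplitude of the smooth ground height field, metres.
#' @param noise_sigma isotropic Gaussian coordinate noise, metres.
#' @param dropout_fraction uniform point dropout probability in \[0, 1).
#' @param ground_density ground sampling density, points per square metre.
#' @param base_elevation mean terrain elevation, metres.
#' @param seed integer RNG seed.
#' @return a `plot_params` list.
#' @export
plot_params <- function(extent = 10, grid_spacing = 5, position_jitter = 0.4,
                        crown_overlap_factor = 1.2, ground_roughness = 0.08,
                        noise_sigma = 0.01, dropout_fraction = 0.05,
                        ground_density = 1339, base_elevation = 0, seed = 1L) {
  if (!(extent > grid_spacing && grid_spacing > 0))
    stop("need extent > grid_spacing > 0")
  if (dropout_fraction < 0 || dropout_fraction >= 1)
    stop("dropout_fraction must be in [0, 1)")
  if (crown_overlap_factor < 0) stop("crown_overlap_factor must be >= 0")
  structure(list(extent = extent, grid_spacing = grid_spacing,
                 position_jitter = position_jitter,
                 crown_overlap_factor = crown_overlap_factor,
                 ground_roughness = ground_roughness, noise_sigma = noise_sigma,
                 dropout_fraction = dropout_fraction,
                 ground_density = ground_density,
                 base_elevation = base_elevation, seed = as.integer(seed)),
            class = "plot_params")
}

# Orthonormal pair perpendicular to a unit vector d.
.perp_frame <- function(d) {
  a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(d[2] * a[3] - d[3] * a[2], d[3] * a[1] - d[1] * a[3], d[1] * a[2] - d[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3], d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

# Build the branching skeleton: data.frame of segments
# (sx, sy, sz, ex, ey, ez, radius, depth), rooted at the origin.
.tree_skeleton <- function(params) {
  segs <- list()
  trunk_len <- 0.4 * params$height
  queue <- list(list(start = c(0, 0, 0), dir = c(0, 0, 1),
                     len = trunk_len, radius = params$trunk_radius, depth = 1L))
  while (length(queue)) {
    nd <- queue[[1]]; queue <- queue[-1]
    end <- nd$start + nd$dir * nd$len
    segs[[length(segs) + 1L]] <- c(nd$start, end, nd$radius, nd$depth)
    if (nd$depth < params$branch_depth) {
      fr <- .perp_frame(nd$dir)
      for (b in seq_len(params$branching_factor)) {
        ang <- (params$branch_angle_deg + stats::rnorm(1, 0, 5)) * pi / 180
        ang <- min(max(ang, 0.05), pi / 2 - 0.05)
        phi <- stats::runif(1, 0, 2 * pi)
        dir <- cos(ang) * nd$dir + sin(ang) * (cos(phi) * fr$u + sin(phi) * fr$v)
        dir <- dir / sqrt(sum(dir^2))
        queue[[length(queue) + 1L]] <- list(start = end, dir = dir,
                                            len = nd$len * 0.65,
                                            radius = nd$radius * 0.6,
                                            depth = nd$depth + 1L)
      }
    }
  }
  m <- do.call(rbind, segs)
  colnames(m) <- c("sx", "sy", "sz", "ex", "ey", "ez", "radius", "depth")
  m
}

#' Generate one labelled leaf-off tree
#'
#' @param params a [tree_params()] object.
#' @param base length-3 base position of the stem, metres.
#' @param seed integer RNG seed; the same seed reproduces the tree exactly.
#' @param instance_id instance label assigned to all points (default 1).
#' @param crown_radius effective crown radius override, metres (`NULL` uses
#'   `params$crown_radius`).
#' @return a `forest_cloud` with `semantic = 1` (tree) everywhere and the
#'   skeleton attached as attribute `"skeleton"`.
#' @export
generate_tree <- function(params, base = c(0, 0, 0), seed = 1L,
                          instance_id = 1L, crown_radius = NULL) {
  stopifnot(inherits(params, "tree_params"))
  if (is.null(crown_radius)) crown_radius <- params$crown_radius
  with_seed(seed, {
    sk <- .tree_skeleton(params)
    # rescale lateral spread to the crown radius, and height to params$height
    pts <- rbind(sk[, 1:3, drop = FALSE], sk[, 4:6, drop = FALSE])
    maxr <- sqrt(max(pts[, 1]^2 + pts[, 2]^2))
    if (maxr > 1e-9) {
      f <- crown_radius / maxr
      sk[, c("sx", "sy", "ex", "ey")] <- sk[, c("sx", "sy", "ex", "ey")] * f
    }
    maxz <- max(sk[, c("sz", "ez")])
    fz <- params$height / maxz
    sk[, c("sz", "ez")] <- sk[, c("sz", "ez")] * fz
    coords <- vector("list", nrow(sk))
    for (i in seq_len(nrow(sk))) {
      s <- sk[i, 1:3]; e <- sk[i, 4:6]
      d <- e - s; len <- sqrt(sum(d^2))
      if (len < 1e-9) next
      d <- d / len
      area <- 2 * pi * sk[i, "radius"] * len
      m <- stats::rpois(1, area * params$points_per_m2)
      if (m == 0L) next
      fr <- .perp_frame(d)
      t <- stats::runif(m, 0, len)
      phi <- stats::runif(m, 0, 2 * pi)
      coords[[i]] <- cbind(s[1] + t * d[1], s[2] + t * d[2], s[3] + t * d[3]) +
        sk[i, "radius"] * (cos(phi) %o% fr$u + sin(phi) %o% fr$v)
    }
    coords <- do.call(rbind, coords)
    if (is.null(coords)) coords <- matrix(numeric(0), 0, 3)
    coords <- sweep(coords, 2L, base, "+")
    out <- point_cloud(coords, semantic = rep(1L, nrow(coords)),
                       instance = rep(as.integer(instance_id), nrow(coords)))
    attr(out, "skeleton") <- sk
    out
  })
}

# Smooth deterministic ground height field: low-frequency sinusoid mixture
# whose phases/frequencies derive from the plot seed.
.ground_field <- function(xy, roughness, base_elevation, seed) {
  ph <- with_seed(derive_seed(seed, 77L), stats::runif(6, 0, 2 * pi))
  fr <- with_seed(derive_seed(seed, 78L), stats::runif(4, 0.08, 0.25))
  base_elevation + roughness * (
    sin(2 * pi * fr[1] * xy[, 1] + ph[1]) * cos(2 * pi * fr[2] * xy[, 2] + ph[2]) +
      0.5 * sin(2 * pi * fr[3] * xy[, 1] + ph[3] + 2 * pi * fr[4] * xy[, 2] + ph[4])) / 1.5
}

#' Generate a labelled synthetic plantation plot
#'
#' Trees are planted on a jittered grid; the ground is a roughened height
#' field sampled uniformly and labelled as its own instance (id 0, semantic
#' class ground). Gaussian coordinate noise and uniform dropout are applied
#' to the composed cloud.
#'
#' @param plot a [plot_params()] object.
#' @param tree a [tree_params()] object.
#' @return a `forest_cloud` with attributes `"tree_seeds"`, `"tree_bases"`
#'   and `"crown_radius"` describing the exact per-tree calls, so a noiseless
#'   plot can be recomposed from [generate_tree()].
#' @export
generate_plot <- function(plot, tree) {
  stopifnot(inherits(plot, "plot_params"), inherits(tree, "tree_params"))
  centers <- seq(plot$grid_spacing / 2, plot$extent - plot$grid_spacing / 2,
                 by = plot$grid_spacing)
  pos <- as.matrix(expand.grid(x = centers, y = centers))
  n_trees <- nrow(pos)
  jit <- with_seed(derive_seed(plot$seed, 1L),
                   matrix(stats::runif(2 * n_trees, -plot$position_jitter,
                                       plot$position_jitter), ncol = 2))
  pos <- pos + jit
  crown_r <- max(plot$crown_overlap_factor * plot$grid_spacing / 2, tree$trunk_radius)
  bases <- cbind(pos, .ground_field(pos, plot$ground_roughness,
                                    plot$base_elevation, plot$seed))
  tree_seeds <- vapply(seq_len(n_trees), function(i) derive_seed(plot$seed, 100L + i),
                       integer(1))
  clouds <- lapply(seq_len(n_trees), function(i)
    generate_tree(tree, base = bases[i, ], seed = tree_seeds[i],
                  instance_id = i, crown_radius = crown_r))
  # ground
  ground <- with_seed(derive_seed(plot$seed, 2L), {
    m <- stats::rpois(1, plot$ground_density * plot$extent^2)
    xy <- cbind(stats::runif(m, 0, plot$extent), stats::runif(m, 0, plot$extent))
    z <- .ground_field(xy, plot$ground_roughness, plot$base_elevation, plot$seed)
    point_cloud(cbind(xy, z), semantic = rep(0L, m), instance = rep(0L, m))
  })
  out <- cloud_bind(c(clouds, list(ground)))
  out <- with_seed(derive_seed(plot$seed, 3L), {
    if (plot$noise_sigma > 0)
      out$coords <- out$coords + stats::rnorm(length(out$coords), 0, plot$noise_sigma)
    if (plot$dropout_fraction > 0) {
      keep <- stats::runif(n_points(out)) >= plot$dropout_fraction
      out <- cloud_subset(out, keep)
    }
    out
  })
  attr(out, "tree_seeds") <- tree_seeds
  attr(out, "tree_bases") <- bases
  attr(out, "crown_radius") <- crown_r
  out
}

#' Generate a dataset of labelled synthetic blocks on disk
#'
#' @param plot a [plot_params()] template (its seed is replaced per block).
#' @param tree a [tree_params()] object.
#' @param n_blocks number of blocks to generate.
#' @param out_dir writable output directory (created if missing).
#' @param seed master seed; per-block seeds derive deterministically from it.
#' @return the manifest (invisibly written to `manifest.json`): block file
#'   names, per-block seeds and point counts.
#' @export
generate_dataset <- function(plot, tree, n_blocks, out_dir, seed = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(n_blocks); seeds <- integer(n_blocks); counts <- integer(n_blocks)
  for (i in seq_len(n_blocks)) {
    seeds[i] <- derive_seed(seed, i)
    p <- plot; p$seed <- seeds[i]
    blk <- generate_plot(p, tree)
    files[i] <- sprintf("block_%03d.ply", i)
    counts[i] <- n_points(blk)
    tryCatch(write_point_cloud(blk, file.path(out_dir, files[i]), "ply"),
             error = function(e) stop("failed writing block ", i, ": ",
                                      conditionMessage(e)))
  }
  manifest <- list(seed = seed, n_blocks = n_blocks, files = files,
                   seeds = seeds, n_points = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
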