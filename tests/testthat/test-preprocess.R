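test_that("SOR keeps a homogeneous lattice and removes an isolated outlier", {
  # at k = 3 every lattice point (corners included) has three unit-distance
  # neighbours, so the kNN statistic is exactly constant
  lat <- lattice_cloud(5)
  clean <- sor_filter(lat, k_neighbors = 3, std_multiplier = 2)
  expect_equal(n_points(clean), 125L)

  spiked <- cloud_bind(lat, point_cloud(matrix(c(100, 100, 100), 1)))
  filt <- sor_filter(spiked, k_neighbors = 3, std_multiplier = 2)
  expect_equal(n_points(filt), 125L)
  expect_lt(max(filt$coords), 6)
  # brute-force oracle: the outlier's mean 3-NN distance is the extreme one
  d <- as.matrix(dist(spiked$coords))
  diag(d) <- Inf
  md <- apply(d, 1, function(r) mean(sort(r)[1:3]))
  expect_equal(unname(which.max(md)), 126L)
  expect_gt(md[126], mean(md) + 2 * sd(md))
  # and the package statistic agrees with the brute-force one
  expect_equal(forestseg:::knn_mean_distance(spiked$coords, 3L), unname(md),
               tolerance = 1e-12)

  # idempotent on the already-clean output
  again <- sor_filter(filt, k_neighbors = 3, std_multiplier = 2)
  expect_equal(n_points(again), n_points(filt))
  expect_error(sor_filter(lattice_cloud(2), k_neighbors = 10), "more than")
})

test_that("ground classification separates a plane from a cylinder", {
  flat <- point_cloud(cbind(runif(300, 0, 5), runif(300, 0, 5), 0))
  expect_true(all(classify_ground(flat)$semantic == 0L))

  sc <- plane_cylinder_cloud()
  out <- classify_ground(sc, cell_size = 0.5, height_threshold = 0.3)
  expect_identical(out$semantic, sc$semantic)
})

test_that("ground classification recovers >= 95% of generator labels", {
  pp <- plot_params(ground_density = 30, noise_sigma = 0, dropout_fraction = 0,
                    seed = 6)
  blk <- generate_plot(pp, desk_tree_params())
  out <- classify_ground(blk)
  expect_gte(mean(out$semantic == blk$semantic), 0.95)
})

test_that("the DEM reproduces flat and tilted planes", {
  flat <- point_cloud(cbind(runif(400, 0, 8), runif(400, 0, 8), 3),
                      semantic = rep(0L, 400), instance = rep(0L, 400))
  dem <- build_dem(flat, 0.5)
  expect_true(all(abs(dem$heights - 3) < 1e-9))

  set.seed(2)
  xy <- cbind(runif(2000, 0, 8), runif(2000, 0, 8))
  tilt <- point_cloud(cbind(xy, 0.1 * xy[, 1] + 0.05 * xy[, 2]),
                      semantic = rep(0L, 2000), instance = rep(0L, 2000))
  dem2 <- build_dem(tilt, 0.5)
  # analytic plane oracle: cell minimum within one cell of slope
  for (i in seq_len(nrow(dem2$heights))) for (j in seq_len(ncol(dem2$heights))) {
    x0 <- dem2$origin_xy[1] + (i - 1) * 0.5
    y0 <- dem2$origin_xy[2] + (j - 1) * 0.5
    expect_lt(abs(dem2$heights[i, j] - (0.1 * x0 + 0.05 * y0)), 0.5 * 0.15 + 0.05)
  }

  single <- point_cloud(matrix(c(1, 1, 4), 1), semantic = 0L, instance = 0L)
  dem3 <- build_dem(single, 0.5)
  expect_true(all(dem3$heights == 4))
  expect_error(build_dem(point_cloud(matrix(numeric(0), 0, 3))), "ground")
})

test_that("height normalization subtracts the interpolated terrain", {
  flat5 <- point_cloud(cbind(runif(200, 0, 5), runif(200, 0, 5), 5),
                       semantic = rep(0L, 200), instance = rep(0L, 200))
  dem <- build_dem(flat5, 1)
  pt <- point_cloud(matrix(c(2.5, 2.5, 12), 1))
  expect_equal(normalize_height(pt, dem)$coords[1, 3], 7)

  zero_dem <- structure(list(heights = matrix(0, 3, 3), cell_size = 5,
                             origin_xy = c(-2, -2)), class = "dem_grid")
  same <- normalize_height(pt, zero_dem)
  expect_equal(same$coords, pt$coords)

  # on a synthetic plot, normalized ground sits within threshold + roughness
  pp <- plot_params(ground_density = 25, noise_sigma = 0, dropout_fraction = 0,
                    seed = 9)
  blk <- generate_plot(pp, desk_tree_params())
  cls <- classify_ground(blk)
  norm <- normalize_height(cls, build_dem(cls, 0.5))
  # generator-truth ground points end up within threshold + roughness of 0
  gz <- norm$coords[blk$semantic == 0L, 3]
  expect_lt(max(abs(gz)), 0.3 + pp$ground_roughness + 0.1)
  # labels and point multiset preserved
  expect_identical(norm$semantic, cls$semantic)
  expect_identical(norm$instance, cls$instance)
  expect_equal(norm$coords[, 1:2], cls$coords[, 1:2])
})

test_that("tree bases sit near zero after the full normalization chain", {
  pp <- plot_params(ground_density = 30, noise_sigma = 0, dropout_fraction = 0,
                    seed = 10)
  blk <- generate_plot(pp, desk_tree_params())
  cls <- classify_ground(blk)
  norm <- normalize_height(cls, build_dem(cls, 0.5))
  for (i in 1:4) {
    z <- norm$coords[blk$instance == i, 3]
    expect_lt(min(z), 0.35)   # base within cell-size-induced error of 0
  }
})

test_that("class balancing subsamples ground exactly and reproducibly", {
  cl <- point_cloud(matrix(runif(3300), 1100),
                    semantic = c(rep(0L, 1000), rep(100L, 0), rep(1L, 100)),
                    instance = c(rep(0L, 1000), rep(1L, 100)))
  bal <- balance_classes(cl, target_ratio = 1, rng_seed = 3)
  expect_equal(sum(bal$semantic == 0L), 100L)
  expect_equal(sum(bal$semantic == 1L), 100L)
  bal2 <- balance_classes(cl, target_ratio = 1, rng_seed = 3)
  expect_identical(bal$coords, bal2$coords)
  # already balanced -> identity
  expect_identical(balance_classes(bal, 1, 4)$coords, bal$coords)
})

test_that("tiling matches the closed-form window enumeration and covers all points", {
  set.seed(5)
  cl <- point_cloud(cbind(runif(4000, 0, 20), runif(4000, 0, 20), runif(4000, 0, 5)))
  one <- tile_blocks(cloud_subset(cl, cl$coords[, 1] <= 10 & cl$coords[, 2] <= 10),
                     block_size = 10, stride = 5, min_points = 1)
  expect_length(one, 1L)

  blocks <- tile_blocks(cl, block_size = 10, stride = 5, min_points = 1)
  # oracle: ceil((20 - 10)/5) + 1 = 3 windows per axis
  origins <- unique(t(vapply(blocks, `[[`, numeric(2), "window_origin_xy")))
  ext <- apply(cl$coords[, 1:2], 2, range)
  ax <- function(a, b) unique(pmin(a + 5 * (0:(ceiling((b - a - 10) / 5))), b - 10))
  expect_setequal(round(origins[, 1], 9), round(c(ax(ext[1, 1], ext[2, 1])), 9))
  covered <- rep(FALSE, n_points(cl))
  for (b in blocks) {
    sel <- cl$coords[, 1] >= b$window_origin_xy[1] &
      cl$coords[, 1] <= b$window_origin_xy[1] + 10 &
      cl$coords[, 2] >= b$window_origin_xy[2] &
      cl$coords[, 2] <= b$window_origin_xy[2] + 10
    expect_equal(n_points(b$cloud), sum(sel))
    covered <- covered | sel
  }
  expect_true(all(covered))
})

test_that("dataset splitting is disjoint, seeded and supports a spatial test region", {
  set.seed(8)
  cl <- point_cloud(cbind(runif(6000, 0, 30), runif(6000, 0, 20), runif(6000, 0, 5)))
  blocks <- tile_blocks(cl, 10, 5, min_points = 1)
  sp <- split_dataset(blocks, 0.8, 0.2, rng_seed = 2)
  n <- length(blocks)
  expect_equal(length(sp$train), floor(0.8 * n))
  expect_equal(length(sp$val), floor(0.2 * n))
  sp2 <- split_dataset(blocks, 0.8, 0.2, rng_seed = 2)
  expect_identical(vapply(sp$train, function(b) b$window_origin_xy[1], numeric(1)),
                   vapply(sp2$train, function(b) b$window_origin_xy[1], numeric(1)))

  rect <- c(20, 0, 30, 20)
  sps <- split_dataset(blocks, 0.8, 0.2, rng_seed = 2, test_rect = rect)
  for (b in sps$train) expect_lte(b$window_origin_xy[1] + b$block_size, 20 + 1e-9)
  for (b in sps$test) expect_gt(b$window_origin_xy[1] + b$block_size, 20)
  expect_error(split_dataset(blocks[1], 0.8, 0.2), "fewer blocks")
})
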