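test_that("a depth-1 tree is a single vertical cylinder of the stated height", {
  tp <- tree_params(height = 10, trunk_radius = 0.15, branch_depth = 1,
                    points_per_m2 = 200)
  tr <- generate_tree(tp, base = c(2, 3, 0), seed = 5)
  r_xy <- sqrt((tr$coords[, 1] - 2)^2 + (tr$coords[, 2] - 3)^2)
  expect_lt(max(abs(r_xy - 0.15)), 1e-9)          # all on the cylinder surface
  expect_gte(min(tr$coords[, 3]), 0)
  expect_lte(max(tr$coords[, 3]), 10)
  expect_true(all(tr$semantic == 1L))
  expect_equal(unique(tr$instance), 1L)
})

test_that("tree generation is bit-identical under a fixed seed", {
  tp <- desk_tree_params()
  a <- generate_tree(tp, seed = 77)
  b <- generate_tree(tp, seed = 77)
  expect_identical(a$coords, b$coords)
  c <- generate_tree(tp, seed = 78)
  expect_false(isTRUE(all.equal(dim(a$coords), dim(c$coords))) &&
                 isTRUE(all.equal(a$coords, c$coords)))
})

test_that("point counts track the analytic surface-area x density product", {
  tp <- tree_params(height = 10, trunk_radius = 0.15, branch_depth = 1,
                    points_per_m2 = 300)
  tr <- generate_tree(tp, seed = 9)
  analytic <- 2 * pi * 0.15 * 10 * 300       # cylinder area x density
  expect_lt(abs(n_points(tr) - analytic) / analytic, 0.2)

  tp2 <- desk_tree_params()
  tr2 <- generate_tree(tp2, seed = 10)
  sk <- attr(tr2, "skeleton")
  lens <- sqrt(rowSums((sk[, 4:6] - sk[, 1:3])^2))
  analytic2 <- sum(2 * pi * sk[, "radius"] * lens) * tp2$points_per_m2
  expect_lt(abs(n_points(tr2) - analytic2) / analytic2, 0.2)
})

test_that("two seeds with identical params have equal expected point counts", {
  tp <- tree_params(points_per_m2 = 30)
  counts <- vapply(1:20, function(s) n_points(generate_tree(tp, seed = 100 + s)),
                   numeric(1))
  half1 <- counts[1:10]; half2 <- counts[11:20]
  se <- sqrt(stats::var(half1) / 10 + stats::var(half2) / 10)
  expect_lt(abs(mean(half1) - mean(half2)), 3 * se + 1e-9)
})

test_that("a 10 m plot at 5 m spacing holds 4 trees plus a ground instance", {
  blk <- generate_plot(desk_plot_params(3), desk_tree_params())
  ids <- sort(unique(blk$instance))
  expect_identical(ids, 0:4)                       # ground + 4 trees
  expect_true(all(blk$semantic[blk$instance == 0L] == 0L))
  expect_true(all(blk$semantic[blk$instance > 0L] == 1L))
})

test_that("instance labels partition the non-ground points", {
  blk <- generate_plot(desk_plot_params(8), desk_tree_params())
  expect_true(all(blk$instance >= 0L))             # every point labelled
  tree_pts <- blk$semantic == 1L
  expect_true(all(blk$instance[tree_pts] >= 1L))
  expect_true(all(blk$instance[!tree_pts] == 0L))
})

test_that("zero crown overlap keeps crown point sets XY-disjoint", {
  pp <- plot_params(ground_density = 10, crown_overlap_factor = 0,
                    position_jitter = 0.2, noise_sigma = 0, seed = 4)
  blk <- generate_plot(pp, desk_tree_params())
  bases <- attr(blk, "tree_bases")
  for (i in 1:3) for (j in (i + 1):4) {
    pi_ <- blk$coords[blk$instance == i, 1:2, drop = FALSE]
    pj_ <- blk$coords[blk$instance == j, 1:2, drop = FALSE]
    # nearest pair between the two trees stays clearly separated
    d <- min(sqrt(outer(rowSums(pi_^2), rowSums(pj_^2), "+") -
                    2 * pi_ %*% t(pj_)))
    expect_gt(d, 0.5)
  }
})

test_that("a noiseless plot is the exact union of its trees plus ground", {
  pp <- plot_params(ground_density = 12, noise_sigma = 0, dropout_fraction = 0,
                    seed = 21)
  tp <- desk_tree_params()
  blk <- generate_plot(pp, tp)
  seeds <- attr(blk, "tree_seeds")
  bases <- attr(blk, "tree_bases")
  cr <- attr(blk, "crown_radius")
  recomposed <- lapply(seq_along(seeds), function(i)
    generate_tree(tp, base = bases[i, ], seed = seeds[i], instance_id = i,
                  crown_radius = cr))
  n_trees <- sum(vapply(recomposed, n_points, integer(1)))
  expect_equal(sum(blk$instance >= 1L), n_trees)
  for (i in seq_along(seeds))
    expect_equal(blk$coords[blk$instance == i, ], recomposed[[i]]$coords,
                 ignore_attr = TRUE)
})

test_that("generate_dataset writes reproducible blocks with unique seeds", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  pp <- desk_plot_params(); tp <- desk_tree_params()
  m1 <- generate_dataset(pp, tp, 4L, dir1, seed = 7)
  m2 <- generate_dataset(pp, tp, 4L, dir2, seed = 7)
  expect_length(list.files(dir1, pattern = "\\.ply$"), 4L)
  expect_identical(m1$seeds, m2$seeds)
  expect_false(any(duplicated(m1$seeds)))
  for (f in m1$files)
    expect_identical(read_point_cloud(file.path(dir1, f))$coords,
                     read_point_cloud(file.path(dir2, f))$coords)
  expect_true(file.exists(file.path(dir1, "manifest.json")))
})

test_that("per-block ground density is close to the requested density", {
  pp <- plot_params(ground_density = 40, dropout_fraction = 0, seed = 13)
  blk <- generate_plot(pp, desk_tree_params())
  n_ground <- sum(blk$semantic == 0L)
  lambda <- 40 * pp$extent^2
  expect_lt(abs(n_ground - lambda) / lambda, 5 / sqrt(lambda))  # Poisson error
})
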