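test_that("the distance penalty is the squared normalized Euclidean distance", {
  p_min <- c(0, 0, 0); p_max <- c(10, 10, 10)
  mid <- matrix(c(5, 5, 5), 1)
  D <- distance_penalty(mid, matrix(0.5, 1, 3), p_min, p_max)
  expect_equal(D[1, 1], 0)
  corner <- matrix(p_max, 1)
  D2 <- distance_penalty(corner, matrix(0, 1, 3), p_min, p_max)
  expect_equal(D2[1, 1], 3.0)   # ||(1,1,1)||^2

  set.seed(1)
  coords <- matrix(runif(60, 0, 10), 20)
  centers <- matrix(runif(9), 3)
  D3 <- distance_penalty(coords, centers, p_min, p_max)
  for (k in 1:3) for (i in 1:20) {  # brute-force pairwise oracle
    pn <- (coords[i, ] - p_min) / (p_max - p_min)
    expect_equal(D3[k, i], sum((pn - centers[k, ])^2), tolerance = 1e-12)
  }
  expect_error(distance_penalty(coords, centers, c(0, 0, 0), c(10, 0, 10)),
               "degenerate")
})

test_that("mask scores combine similarity and penalty as S = QF' - lambda D", {
  set.seed(2)
  Q <- matrix(rnorm(3 * 6), 3); F_feat <- matrix(rnorm(7 * 6), 7)
  D <- matrix(runif(21), 3)
  sf <- mask_scores(Q, F_feat, D, lambda = 0.7)
  for (k in 1:3) for (i in 1:7)   # explicit double-loop oracle
    expect_equal(sf$S[k, i], sum(Q[k, ] * F_feat[i, ]) - 0.7 * D[k, i],
                 tolerance = 1e-12)
  # lambda = 0 collapses to the plain dot-product similarity
  sf0 <- mask_scores(Q, F_feat, D, lambda = 0)
  expect_equal(sf0$S, tcrossprod(Q, F_feat))
  # zero queries with lambda = 1 leave pure negative penalty
  sfD <- mask_scores(matrix(0, 3, 6), F_feat, D, lambda = 1)
  expect_equal(sfD$S, -D)
  expect_error(mask_scores(Q, F_feat[, 1:3], D), "dims differ")
})

test_that("center prediction is a sigmoid-bounded two-layer MLP", {
  head0 <- list(W1 = matrix(0, 8, 8), b1 = matrix(0, 1, 8),
                W2 = matrix(0, 8, 3), b2 = matrix(0, 1, 3))
  C <- predict_centers(matrix(rnorm(40), 5), head0)
  expect_equal(C, matrix(0.5, 5, 3))   # sigmoid(0)
  set.seed(3)
  head_r <- list(W1 = matrix(rnorm(64), 8), b1 = matrix(rnorm(8), 1),
                 W2 = matrix(rnorm(24), 8), b2 = matrix(rnorm(3), 1))
  Q <- matrix(rnorm(40), 5)
  C2 <- predict_centers(Q, head_r)
  expect_true(all(C2 > 0 & C2 < 1))
  # dense oracle
  h <- pmax(Q %*% head_r$W1 + rep(head_r$b1, each = 5), 0)
  o <- 1 / (1 + exp(-(h %*% head_r$W2 + rep(head_r$b2, each = 5))))
  expect_equal(C2, o, tolerance = 1e-12)
})

test_that("masked cross-attention honours the previous mask", {
  set.seed(4)
  dq <- 8L
  w <- forestseg:::init_refine_layer(dq, dq)
  Q <- matrix(rnorm(2 * dq), 2)
  F_feat <- matrix(rnorm(5 * dq), 5)
  # all-foreground mask equals unmasked attention
  out_full <- refine_queries(Q, F_feat, matrix(1, 2, 5), w)
  out_none <- refine_queries(Q, F_feat, matrix(0, 2, 5), w)  # empty -> fallback
  expect_equal(out_full, out_none, tolerance = 1e-6)

  # hand-rolled dense oracle of the whole layer
  ln <- function(x, g, b) {
    mu <- rowMeans(x); sd_ <- sqrt(rowMeans((x - mu)^2) + 1e-5)
    (x - mu) / sd_ * rep(as.vector(g), each = nrow(x)) + rep(as.vector(b), each = nrow(x))
  }
  att <- function(qx, kvx, p, bias = 0) {
    q <- qx %*% p$Wq$W + rep(p$Wq$b, each = nrow(qx))
    k <- kvx %*% p$Wk$W + rep(p$Wk$b, each = nrow(kvx))
    v <- kvx %*% p$Wv$W + rep(p$Wv$b, each = nrow(kvx))
    s <- q %*% t(k) / sqrt(ncol(q)) + bias
    a <- exp(s - apply(s, 1, max)); a <- a / rowSums(a)
    (a %*% v) %*% p$Wo$W + rep(p$Wo$b, each = nrow(qx))
  }
  mask <- rbind(c(1, 1, 0, 0, 1), c(0, 1, 1, 1, 0))
  x <- Q + att(ln(Q, w$ln1$gamma, w$ln1$beta), ln(Q, w$ln1$gamma, w$ln1$beta), w$self)
  bias <- (1 - mask) * -1e9
  x <- x + att(ln(x, w$ln2$gamma, w$ln2$beta), F_feat, w$cross, bias)
  h <- ln(x, w$ln3$gamma, w$ln3$beta)
  x <- x + (pmax(h %*% w$ffn$W1 + rep(w$ffn$b1, each = 2), 0) %*% w$ffn$W2 +
              rep(w$ffn$b2, each = 2))
  expect_equal(refine_queries(Q, F_feat, mask, w), x, tolerance = 1e-6)

  # a single-voxel mask makes the query attend to that voxel only
  one <- rbind(c(0, 0, 1, 0, 0), rep(1, 5))
  qn <- ln(Q + att(ln(Q, w$ln1$gamma, w$ln1$beta), ln(Q, w$ln1$gamma, w$ln1$beta),
                   w$self), w$ln2$gamma, w$ln2$beta)
  qq <- qn %*% w$cross$Wq$W + rep(w$cross$Wq$b, each = 2)
  kk <- F_feat %*% w$cross$Wk$W + rep(w$cross$Wk$b, each = 5)
  s <- qq %*% t(kk) / sqrt(ncol(qq)) + (1 - one) * -1e9
  a <- exp(s - apply(s, 1, max)); a <- a / rowSums(a)
  expect_equal(a[1, ], c(0, 0, 1, 0, 0), tolerance = 1e-9)
})

test_that("decoding produces per-layer score fields of the right shape", {
  set.seed(5)
  blk <- generate_plot(desk_plot_params(2), desk_tree_params())
  cfg <- desk_profile(1)
  m <- init_model(cfg, seed = 8)
  g <- voxelize(blk, cfg$voxel_size)
  layers <- decode_instances(m, g)
  expect_length(layers, cfg$decoder$n_layers)
  V <- nrow(g$voxel_coords)
  for (l in layers) {
    expect_equal(dim(l$score_field$S), c(cfg$decoder$n_queries, V))
    expect_equal(l$score_field$S,
                 l$score_field$semantic_term - cfg$decoder$lambda * l$score_field$penalty_term,
                 tolerance = 1e-9)
    expect_true(all(l$centers >= 0 & l$centers <= 1))
    expect_equal(ncol(l$class_logits), 3L)
  }
  # one layer -> exactly one refinement + one scoring pass
  cfg1 <- desk_profile(1); cfg1$decoder$n_layers <- 1L
  m1 <- init_model(cfg1, seed = 8)
  expect_length(decode_instances(m1, g), 1L)
})

test_that("raising lambda never raises any score where the penalty is positive", {
  set.seed(6)
  blk <- generate_plot(desk_plot_params(4), desk_tree_params())
  cfg <- desk_profile(1)
  g <- voxelize(blk, cfg$voxel_size)
  # first layer: identical queries, centers and penalties across lambda, so
  # the sweep isolates the -lambda * D term (later layers also change their
  # attention masks, so only the scoring step itself is monotone)
  scores <- lapply(c(0, 1, 2), function(lam) {
    cfgl <- cfg; cfgl$decoder$lambda <- lam
    m <- init_model(cfgl, seed = 9)   # identical weights, different lambda
    decode_instances(m, g)[[1]]$score_field
  })
  expect_true(all(scores[[2]]$S <= scores[[1]]$S + 1e-9))
  expect_true(all(scores[[3]]$S <= scores[[2]]$S + 1e-9))
  expect_true(all(scores[[2]]$S[scores[[2]]$penalty_term > 1e-6] <
                    scores[[1]]$S[scores[[1]]$penalty_term > 1e-6]))
})

test_that("the assignment solver equals exhaustive search on small problems", {
  perms <- function(v) if (length(v) == 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(2:5, 1); m_ <- sample(2:n, 1)
    cost <- matrix(runif(n * m_), n)
    a <- solve_assignment(cost)
    got <- sum(cost[cbind(which(!is.na(a)), a[!is.na(a)])])
    best <- Inf
    for (rows in utils::combn(n, m_, simplify = FALSE))
      for (p in perms(seq_len(m_)))
        best <- min(best, sum(cost[cbind(rows, p)]))
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("query-to-instance matching is one-to-one, minimal, and handles edge cases", {
  set.seed(7)
  V <- 40L
  gt <- list(masks = rbind(c(rep(1, 20), rep(0, 20)), c(rep(0, 20), rep(1, 20))),
             class = c(0L, 1L), centers = matrix(c(0.2, 0.8, 0.2, 0.8, 0.5, 0.5), 2))
  # two queries whose masks exactly match the two instances -> identity
  scores <- rbind(ifelse(gt$masks[1, ] == 1, 5, -5), ifelse(gt$masks[2, ] == 1, 5, -5))
  logits <- rbind(c(5, -5, -5), c(-5, 5, -5))
  mr <- hungarian_match(logits, scores, gt$centers, gt)
  expect_equal(mr$pairs$gt[order(mr$pairs$query)], c(1L, 2L))
  expect_length(mr$unmatched, 0L)
  # zero ground truth -> everything no-object
  mr0 <- hungarian_match(logits, scores, gt$centers,
                         list(masks = NULL, class = integer(0), centers = NULL))
  expect_equal(mr0$unmatched, 1:2)
  expect_equal(nrow(mr0$pairs), 0L)
})

test_that("the loss hits its floor on perfect predictions and Dice is maximal when disjoint", {
  V <- 30L
  gt <- list(masks = rbind(c(rep(1, 15), rep(0, 15)), c(rep(0, 15), rep(1, 15))),
             class = c(0L, 1L),
             centers = rbind(c(0.25, 0.5, 0.1), c(0.75, 0.5, 0.1)))
  big <- 50
  layers <- list(list(
    class_logits = rbind(c(big, 0, 0), c(0, big, 0), c(0, 0, big)),
    scores = rbind(ifelse(gt$masks[1, ] == 1, big, -big),
                   ifelse(gt$masks[2, ] == 1, big, -big),
                   rep(-big, V)),
    centers = rbind(gt$centers, c(0.5, 0.5, 0.5))))
  out <- segmentation_loss(layers, gt)
  expect_lt(out$total, 0.05)
  expect_lt(out$components$center, 1e-9)
  expect_lt(out$components$dice, 0.15)  # only the +1 smoothing term remains

  # disjoint mask vs GT: Dice loss = 1 up to smoothing
  ns <- asNamespace("forestseg")
  d <- ns$tg_dice_loss(forestseg:::tg_leaf(matrix(c(rep(50, 10), rep(-50, 10)), 1)),
                       matrix(c(rep(0, 10), rep(1, 10)), 1), smooth = 0)
  expect_equal(forestseg:::nval(d), 1)
})

test_that("deep supervision with one layer equals the single-layer loss", {
  set.seed(8)
  V <- 25L
  gt <- list(masks = matrix(rbinom(2 * V, 1, 0.4), 2), class = c(0L, 1L),
             centers = matrix(runif(6), 2))
  layer <- list(class_logits = matrix(rnorm(9), 3),
                scores = matrix(rnorm(3 * V), 3),
                centers = matrix(runif(9), 3))
  one <- segmentation_loss(list(layer), gt)
  two <- segmentation_loss(list(layer, layer), gt)
  expect_equal(two$total, 2 * one$total, tolerance = 1e-9)
  expect_equal(one$total,
               sum(unlist(one$components)), tolerance = 1e-12)
})

test_that("postprocessing discards empty and duplicate queries and labels all points", {
  set.seed(9)
  cl <- point_cloud(matrix(runif(600, 0, 3), 200))
  g <- voxelize(cl, 0.3)
  V <- nrow(g$voxel_coords)
  S <- rbind(rep(10, V),          # full-scene query
             rep(10, V),          # duplicate -> must lose the tie-break
             rep(-10, V))         # all-negative -> empty, discarded
  logits <- rbind(c(0, 9, 0), c(0, 9, 0), c(0, 9, 0))
  pred <- postprocess_instances(S, logits, g, score_threshold = 0.1, min_points = 5)
  expect_length(pred$masks, 1L)
  expect_true(all(pred$point_semantic %in% c(0L, 1L)))
  expect_true(all(pred$point_instance[pred$masks[[1]]] == pred$point_instance[pred$masks[[1]]][1]))
  # no-object argmax queries are never emitted
  logits_no <- rbind(c(0, 0, 9), c(0, 0, 9), c(0, 0, 9))
  pred2 <- postprocess_instances(S, logits_no, g, 0.1, 5)
  expect_length(pred2$masks, 0L)
  expect_true(all(pred2$point_semantic == 0L))  # unclaimed default ground
})
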