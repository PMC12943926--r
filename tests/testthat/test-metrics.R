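test_that("semantic metrics follow the count formulas", {
  # TP=9, FP=1, FN=1 for class 1
  gt <- c(rep(1L, 10), rep(0L, 10))
  pred <- gt
  pred[10] <- 0L   # one FN
  pred[11] <- 1L   # one FP
  sm <- semantic_metrics(pred, gt, classes = 1L)
  expect_equal(sm$per_class$Prec, 0.9)
  expect_equal(sm$per_class$Rec, 0.9)
  expect_equal(sm$per_class$F1, 0.9)
  expect_equal(sm$per_class$IoU, 9 / 11)

  perfect <- semantic_metrics(gt, gt)
  expect_equal(unlist(perfect$average), c(Prec = 1, Rec = 1, F1 = 1, IoU = 1))

  disjoint <- semantic_metrics(rep(0L, 5), rep(1L, 5), classes = 1L)
  expect_equal(unlist(disjoint$per_class[c("Prec", "Rec", "F1", "IoU")]),
               c(Prec = 0, Rec = 0, F1 = 0, IoU = 0), ignore_attr = TRUE)
  expect_error(semantic_metrics(1:3, 1:4), "equal length")
})

test_that("a single detection at IoU 0.67 yields AP 0.4 and AP50 1.0", {
  gt <- list(sets = list(1:100), class = 0L)
  pred <- list(sets = list(1:67), class = 0L, confidence = 1)
  # IoU = 67/100 >= t for t in {0.50, 0.55, 0.60, 0.65}: 4 of 10 thresholds
  ia <- instance_ap(pred, gt)
  expect_equal(ia$per_class$AP, 0.4)
  expect_equal(ia$per_class$AP50, 1.0)
  expect_equal(ia$per_class$AP25, 1.0)
})

test_that("perfect predictions score 1 everywhere", {
  sc <- random_scene(1)
  ident <- list(sets = sc$gt$sets, class = sc$gt$class,
                confidence = rep(1, length(sc$gt$sets)))
  ia <- instance_ap(ident, sc$gt)
  expect_equal(ia$average$AP, 1)
  pr <- detection_pr(ident, sc$gt)
  expect_equal(c(pr$mPrec, pr$mRec), c(1, 1))
  cov <- coverage_metrics(ident, sc$gt)
  expect_equal(c(cov$mCov, cov$mWCov), c(1, 1))
})

test_that("detection precision/recall count strict IoU > 0.5 matches", {
  gt <- list(sets = list(1:50, 51:100), class = c(1L, 1L))
  pred <- list(sets = list(1:50), class = 1L, confidence = 0.9)
  pr <- detection_pr(pred, gt)
  expect_equal(pr$per_class$Prec, 1)
  expect_equal(pr$per_class$Rec, 0.5)
  # an exactly-0.5 IoU does not count under the strict cut
  half <- list(sets = list(c(1:25, 101:125)), class = 1L, confidence = 0.9)
  expect_equal(detection_pr(half, list(sets = list(1:50), class = 1L))$per_class$Prec, 0)
})

test_that("coverage metrics average best IoU, weighted by size", {
  gt <- list(sets = list(1:300, 301:400), class = c(1L, 1L))
  pred <- list(sets = list(1:240, c(301:360, 401:440)), class = c(1L, 1L),
               confidence = c(1, 1))
  # best IoUs: 240/300 = 0.8, 60/140 ~= 0.4286
  cov <- coverage_metrics(pred, gt)
  b2 <- 60 / 140
  expect_equal(cov$mCov, (0.8 + b2) / 2)
  expect_equal(cov$mWCov, 0.75 * 0.8 + 0.25 * b2)
  expect_error(coverage_metrics(pred, list(sets = list(), class = integer(0))),
               "ground-truth")
})

test_that("all instance metrics match the brute-force oracle on random scenes", {
  scenes <- lapply(1:200, random_scene, max_pts = 500, max_inst = 6)
  for (i in seq(1, 200, by = 10)) {   # per-scene agreement on a subsample
    s <- scenes[[i]]
    ora <- oracle_instance_metrics(list(s))
    ia <- instance_ap(s$pred, s$gt)
    pr <- detection_pr(s$pred, s$gt)
    cov <- coverage_metrics(s$pred, s$gt)
    for (cl in names(ora)) {
      row <- ia$per_class[ia$per_class$class == as.integer(cl), ]
      expect_equal(row$AP, ora[[cl]]$AP, tolerance = 1e-9)
      expect_equal(row$AP50, ora[[cl]]$AP50, tolerance = 1e-9)
      expect_equal(row$AP25, ora[[cl]]$AP25, tolerance = 1e-9)
      prow <- pr$per_class[pr$per_class$class == as.integer(cl), ]
      expect_equal(prow$Prec, ora[[cl]]$Prec, tolerance = 1e-9)
      expect_equal(prow$Rec, ora[[cl]]$Rec, tolerance = 1e-9)
      crow <- cov$per_class[cov$per_class$class == as.integer(cl), ]
      if (nrow(crow)) {
        expect_equal(crow$mCov, ora[[cl]]$mCov, tolerance = 1e-9)
        expect_equal(crow$mWCov, ora[[cl]]$mWCov, tolerance = 1e-9)
      }
    }
  }
  # pooled agreement over a scene group
  grp <- scenes[1:12]
  ora <- oracle_instance_metrics(grp)
  ia <- instance_ap(lapply(grp, `[[`, "pred"), lapply(grp, `[[`, "gt"))
  for (cl in names(ora)) {
    row <- ia$per_class[ia$per_class$class == as.integer(cl), ]
    expect_equal(row$AP, ora[[cl]]$AP, tolerance = 1e-9)
  }
})

test_that("semantic metrics match the loop oracle on random labelings", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(50:300, 1)
    gt <- sample(0:1, n, TRUE)
    pred <- ifelse(runif(n) < 0.2, sample(0:1, n, TRUE), gt)
    ora <- oracle_semantic(pred, gt)
    sm <- semantic_metrics(pred, gt)
    for (cl in names(ora)) {
      row <- sm$per_class[sm$per_class$class == as.integer(cl), ]
      expect_equal(unlist(row[c("Prec", "Rec", "F1", "IoU")]), ora[[cl]],
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("metrics are invariant to instance relabelling and AP is threshold-monotone", {
  for (seed in c(3, 17, 42)) {
    s <- random_scene(seed)
    ia <- instance_ap(s$pred, s$gt)
    # shuffle instance order (relabelling)
    perm <- sample(length(s$gt$sets))
    gt2 <- list(sets = s$gt$sets[perm], class = s$gt$class[perm])
    ia2 <- instance_ap(s$pred, gt2)
    expect_equal(ia$per_class, ia2$per_class, tolerance = 1e-12)
    # AP at a higher threshold never exceeds AP at a lower one
    expect_true(all(diff(vapply(c(0.25, 0.5, 0.75, 0.9), function(t)
      instance_ap(s$pred, s$gt, iou_thresholds = t)$average$AP, numeric(1))) <= 1e-12))
    # adding a correct prediction never decreases mCov
    cov0 <- coverage_metrics(s$pred, s$gt)$mCov
    aug <- s$pred
    aug$sets <- c(aug$sets, s$gt$sets[1])
    aug$class <- c(aug$class, s$gt$class[1])
    aug$confidence <- c(aug$confidence, 1)
    expect_gte(coverage_metrics(aug, s$gt)$mCov + 1e-12, cov0)
  }
})

test_that("evaluate_run pools additively and flags unpaired files", {
  dir_p <- withr::local_tempdir(); dir_g <- withr::local_tempdir()
  blocks <- lapply(1:3, function(i) generate_plot(desk_plot_params(i), desk_tree_params()))
  for (i in 1:3) {
    write_point_cloud(blocks[[i]], file.path(dir_g, sprintf("b%d.ply", i)))
    write_point_cloud(blocks[[i]], file.path(dir_p, sprintf("b%d.ply", i)))
  }
  rep <- evaluate_run(dir_p, dir_g)
  expect_equal(rep$semantic$average$IoU, 1)
  expect_equal(rep$instance_ap$average$AP, 1)
  expect_equal(rep$coverage$mWCov, 1)
  # pooled semantic counts equal the sum of per-block counts
  tp_blocks <- sum(vapply(rep$per_block, function(b)
    sum(b$semantic$per_class$TP), numeric(1)))
  expect_equal(sum(rep$semantic$per_class$TP), tp_blocks)
  file.remove(file.path(dir_p, "b3.ply"))
  expect_error(evaluate_run(dir_p, dir_g), "unpaired")
})
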