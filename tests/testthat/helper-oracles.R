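# Independent brute-force implementations of the evaluation metrics, written
# as plain nested loops so they share no code with the package, plus small
# fixture builders used across the suite.

# ---- naive metric oracles ---------------------------------------------------

oracle_iou_sets <- function(a, b) {
  inter <- 0
  for (x in a) if (any(b == x)) inter <- inter + 1
  uni <- length(a) + length(b) - inter
  if (uni == 0) 0 else inter / uni
}

oracle_semantic <- function(pred, gt, classes = sort(unique(gt))) {
  out <- list()
  for (cl in classes) {
    tp <- fp <- fn <- 0
    for (i in seq_along(gt)) {
      if (pred[i] == cl && gt[i] == cl) tp <- tp + 1
      if (pred[i] == cl && gt[i] != cl) fp <- fp + 1
      if (pred[i] != cl && gt[i] == cl) fn <- fn + 1
    }
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    iou <- if (tp + fp + fn == 0) 0 else tp / (tp + fp + fn)
    out[[as.character(cl)]] <- c(Prec = prec, Rec = rec, F1 = f1, IoU = iou)
  }
  out
}

# Greedy confidence-ordered matching for one class at one threshold over a
# list of scenes; returns TP flags in global descending-confidence order and
# the GT count.
oracle_match <- function(scenes, cl, thr, strict = FALSE) {
  det_conf <- c(); det_tp <- c(); n_gt <- 0
  for (s in scenes) {
    pj <- which(s$pred$class == cl)
    gk <- which(s$gt$class == cl)
    n_gt <- n_gt + length(gk)
    if (length(pj) == 0) next
    ord <- pj[order(-s$pred$confidence[pj], pj)]
    taken <- rep(FALSE, length(gk))
    for (j in ord) {
      best_iou <- -1; best_g <- 0
      for (gi in seq_along(gk)) {
        if (taken[gi]) next
        iou <- oracle_iou_sets(s$pred$sets[[j]], s$gt$sets[[gk[gi]]])
        if (iou > best_iou) { best_iou <- iou; best_g <- gi }
      }
      ok <- if (best_g == 0) FALSE else if (strict) best_iou > thr else best_iou >= thr
      if (ok) taken[best_g] <- TRUE
      det_conf <- c(det_conf, s$pred$confidence[j])
      det_tp <- c(det_tp, ok)
    }
  }
  ord <- order(-det_conf)
  list(tp = det_tp[ord], n_gt = n_gt)
}

oracle_ap_class <- function(scenes, cl, thr) {
  m <- oracle_match(scenes, cl, thr)
  if (m$n_gt == 0) return(NA_real_)
  if (length(m$tp) == 0) return(0)
  ap <- 0; tp_cum <- 0; fp_cum <- 0
  prec_at <- numeric(length(m$tp)); rec_at <- numeric(length(m$tp))
  for (i in seq_along(m$tp)) {
    if (m$tp[i]) tp_cum <- tp_cum + 1 else fp_cum <- fp_cum + 1
    prec_at[i] <- tp_cum / (tp_cum + fp_cum)
    rec_at[i] <- tp_cum / m$n_gt
  }
  for (i in seq_along(prec_at)) prec_at[i] <- max(prec_at[i:length(prec_at)])
  prev_rec <- 0
  for (i in seq_along(prec_at)) {
    ap <- ap + (rec_at[i] - prev_rec) * prec_at[i]
    prev_rec <- rec_at[i]
  }
  ap
}

oracle_instance_metrics <- function(scenes, thresholds = seq(0.5, 0.95, by = 0.05)) {
  classes <- sort(unique(unlist(lapply(scenes, function(s) s$gt$class))))
  res <- list()
  for (cl in classes) {
    aps <- sapply(thresholds, function(t) oracle_ap_class(scenes, cl, t))
    det <- oracle_match(scenes, cl, 0.5, strict = TRUE)
    n_pred <- sum(sapply(scenes, function(s) sum(s$pred$class == cl)))
    best <- c(); sizes <- c()
    for (s in scenes) for (gi in which(s$gt$class == cl)) {
      b <- 0
      for (pj in which(s$pred$class == cl))
        b <- max(b, oracle_iou_sets(s$pred$sets[[pj]], s$gt$sets[[gi]]))
      best <- c(best, b); sizes <- c(sizes, length(s$gt$sets[[gi]]))
    }
    res[[as.character(cl)]] <- list(
      AP = mean(aps), AP50 = oracle_ap_class(scenes, cl, 0.5),
      AP25 = oracle_ap_class(scenes, cl, 0.25),
      Prec = if (n_pred == 0) 0 else sum(det$tp) / n_pred,
      Rec = if (det$n_gt == 0) 0 else sum(det$tp) / det$n_gt,
      mCov = if (length(best)) mean(best) else NA_real_,
      mWCov = if (length(best)) sum(sizes / sum(sizes) * best) else NA_real_)
  }
  res
}

# ---- random scene generator -------------------------------------------------

# A random instance-segmentation scene: <= `max_pts` points partitioned into
# <= `max_inst` ground-truth instances (classes 0/1); predictions perturb the
# ground truth by reassigning a fraction of points, splitting or dropping
# instances, with random confidences.
random_scene <- function(seed, max_pts = 500, max_inst = 6) {
  set.seed(seed)
  n <- sample(50:max_pts, 1)
  g <- sample(2:max_inst, 1)
  gt_lab <- sample(g, n, replace = TRUE)
  cls <- c(0L, sample(0:1, g - 1L, replace = TRUE))
  gt <- list(sets = lapply(1:g, function(i) which(gt_lab == i)), class = cls)
  pred_lab <- gt_lab
  flip <- runif(n) < runif(1, 0, 0.35)
  pred_lab[flip] <- sample(g + 2L, sum(flip), replace = TRUE)  # may create extras
  ids <- sort(unique(pred_lab))
  psets <- lapply(ids, function(i) which(pred_lab == i))
  keep <- lengths(psets) > 0
  psets <- psets[keep]; ids <- ids[keep]
  pcls <- sapply(seq_along(ids), function(i)
    if (ids[i] <= g) cls[ids[i]] else sample(0:1, 1))
  pred <- list(sets = psets, class = as.integer(pcls),
               confidence = round(runif(length(psets)), 3))
  list(pred = pred, gt = gt)
}

# ---- small cloud fixtures ---------------------------------------------------

lattice_cloud <- function(n_side = 5, spacing = 1) {
  g <- expand.grid(x = seq_len(n_side), y = seq_len(n_side), z = seq_len(n_side))
  point_cloud(as.matrix(g) * spacing)
}

# Flat-ground-plus-cylinder scene with known labels.
plane_cylinder_cloud <- function(n_plane = 400, n_cyl = 200, height = 10, seed = 1) {
  set.seed(seed)
  plane <- cbind(runif(n_plane, 0, 10), runif(n_plane, 0, 10), 0)
  theta <- runif(n_cyl, 0, 2 * pi)
  cyl <- cbind(5 + 0.2 * cos(theta), 5 + 0.2 * sin(theta), runif(n_cyl, 0.5, height))
  point_cloud(rbind(plane, cyl),
              semantic = c(rep(0L, n_plane), rep(1L, n_cyl)),
              instance = c(rep(0L, n_plane), rep(1L, n_cyl)))
}

desk_tree_params <- function() tree_params(points_per_m2 = 20)
desk_plot_params <- function(seed = 1) plot_params(ground_density = 15, seed = seed)

# Two interlaced-crown trees over a small ground patch; the fixture behind
# the distance-penalty ablation.
two_tree_scene <- function(seed, spacing = 2.4, extent = 6) {
  tp <- tree_params(height = 8, crown_radius = 2, branch_depth = 3,
                    points_per_m2 = 35)
  b1 <- c(extent / 2 - spacing / 2, extent / 2, 0)
  b2 <- c(extent / 2 + spacing / 2, extent / 2, 0)
  t1 <- generate_tree(tp, b1, seed = derive_seed_t(seed, 1), instance_id = 1L,
                      crown_radius = 1.9)
  t2 <- generate_tree(tp, b2, seed = derive_seed_t(seed, 2), instance_id = 2L,
                      crown_radius = 1.9)
  set.seed(derive_seed_t(seed, 3))
  ng <- rpois(1, 12 * extent^2)
  ground <- point_cloud(cbind(runif(ng, 0, extent), runif(ng, 0, extent),
                              rnorm(ng, 0, 0.02)),
                        semantic = rep(0L, ng), instance = rep(0L, ng))
  cloud_bind(t1, t2, ground)
}

derive_seed_t <- function(seed, i) (seed * 7919 + i * 104729) %% 2147483647
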