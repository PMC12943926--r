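#' Semantic segmentation metrics
#'
#' Per-class one-vs-rest precision, recall, F1 and IoU:
#' `Prec = TP/(TP+FP)`, `Rec = TP/(TP+FN)`, `F1 = 2 Prec Rec/(Prec+Rec)`,
#' `IoU = TP/(TP+FP+FN)`, with the 0/0 -> 0 convention, plus macro averages
#' over the classes present in the ground truth.
#'
#' @param pred_sem integer vector of predicted labels.
#' @param gt_sem integer vector of ground-truth labels, same length.
#' @param classes integer vector of class ids to evaluate (default: classes
#'   present in the ground truth).
#' @return a list with `per_class` (data.frame of TP/FP/FN and the four
#'   metrics) and `average` (macro means over classes with ground truth).
#' @export
semantic_metrics <- function(pred_sem, gt_sem, classes = NULL) {
  if (length(pred_sem) != length(gt_sem))
    stop("pred_sem and gt_sem must have equal length")
  if (is.null(classes)) classes <- sort(unique(gt_sem))
  rows <- lapply(classes, function(cl) {
    tp <- sum(pred_sem == cl & gt_sem == cl)
    fp <- sum(pred_sem == cl & gt_sem != cl)
    fn <- sum(pred_sem != cl & gt_sem == cl)
    sdiv <- function(a, b) if (b == 0) 0 else a / b
    prec <- sdiv(tp, tp + fp); rec <- sdiv(tp, tp + fn)
    data.frame(class = cl, TP = tp, FP = fp, FN = fn,
               Prec = prec, Rec = rec,
               F1 = sdiv(2 * prec * rec, prec + rec),
               IoU = sdiv(tp, tp + fp + fn))
  })
  per_class <- do.call(rbind, rows)
  has_gt <- (per_class$TP + per_class$FN) > 0
  avg <- if (any(has_gt)) colMeans(per_class[has_gt, c("Prec", "Rec", "F1", "IoU")])
         else c(Prec = 0, Rec = 0, F1 = 0, IoU = 0)
  list(per_class = per_class, average = as.list(avg))
}

# Pairwise IoU between prediction masks and GT masks given point-index sets.
.pair_iou <- function(pred_sets, gt_sets) {
  iou <- matrix(0, length(pred_sets), length(gt_sets))
  for (j in seq_along(pred_sets)) for (k in seq_along(gt_sets)) {
    int <- length(intersect(pred_sets[[j]], gt_sets[[k]]))
    uni <- length(pred_sets[[j]]) + length(gt_sets[[k]]) - int
    iou[j, k] <- if (uni == 0) 0 else int / uni
  }
  iou
}

# Normalize a scene to the internal representation:
# pred: list(sets = list of point-index vectors, class, confidence)
# gt:   list(sets, class)
# A scene can be given as a pair of labelled clouds or as these lists.
.as_instance_scene <- function(pred, gt) {
  to_sets <- function(x, with_conf) {
    if (inherits(x, "forest_cloud")) {
      ids <- sort(unique(x$instance[x$instance >= 0L]))
      sets <- lapply(ids, function(i) which(x$instance == i))
      cls <- vapply(seq_along(ids), function(i) {
        s <- x$semantic[sets[[i]]]
        as.integer(names(sort(table(s), decreasing = TRUE))[1])
      }, integer(1))
      out <- list(sets = sets, class = cls)
      if (with_conf) out$confidence <- rep(1, length(ids))
      out
    } else x
  }
  list(pred = to_sets(pred, TRUE), gt = to_sets(gt, FALSE))
}

# Greedy confidence-ordered matching at one IoU threshold for one class.
# Each prediction (descending confidence, ties by index) takes the unmatched
# GT with the highest IoU, provided it clears the threshold; `strict` uses
# IoU > t instead of IoU >= t.
.greedy_tp <- function(iou, conf, thr, strict = FALSE) {
  np <- nrow(iou); ng <- ncol(iou)
  order_p <- order(-conf, seq_len(np))
  tp <- logical(np); taken <- logical(ng)
  for (j in order_p) {
    if (ng == 0L) break
    cand <- which(!taken)
    if (!length(cand)) next
    best <- cand[which.max(iou[j, cand])]
    ok <- if (strict) iou[j, best] > thr else iou[j, best] >= thr
    if (ok) { tp[j] <- TRUE; taken[best] <- TRUE }
  }
  tp[order_p]  # aligned with descending-confidence order
}

# Average precision from TP flags in confidence order: all-point
# interpolation of the precision envelope over the PR curve.
.ap_from_tp <- function(tp, n_gt) {
  if (n_gt == 0L) return(NA_real_)
  if (!length(tp)) return(0)
  cum_tp <- cumsum(tp); cum_fp <- cumsum(!tp)
  prec <- cum_tp / (cum_tp + cum_fp)
  rec <- cum_tp / n_gt
  prec_env <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * prec_env)
}

#' Instance-segmentation average precision
#'
#' Per semantic class: predictions are greedily matched to ground-truth
#' instances in descending confidence order (each ground truth matched at
#' most once; a match requires IoU at or above the threshold), the
#' precision-recall curve is integrated with the monotone precision
#' envelope, and AP is the mean over the threshold grid 0.50:0.05:0.95.
#' AP50 and AP25 are the same quantity at the single thresholds 0.50 and
#' 0.25. Scenes may be pooled: pass lists of scenes to rank detections
#' jointly while matching within their own scene.
#'
#' @param pred predicted instances: a labelled `forest_cloud`, a list with
#'   `sets`/`class`/`confidence`, or a list of such scenes.
#' @param gt ground truth in the same shape (confidences ignored).
#' @param iou_thresholds numeric vector of IoU thresholds.
#' @return list with `per_class` data.frame (class, AP, AP50, AP25, n_gt)
#'   and `average` over classes that have ground truth.
#' @export
instance_ap <- function(pred, gt, iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  scenes <- .instance_scenes(pred, gt)
  classes <- sort(unique(unlist(lapply(scenes, function(s) s$gt$class))))
  grid <- sort(unique(c(iou_thresholds, 0.5, 0.25)))
  per <- lapply(classes, function(cl) {
    ap_at <- vapply(grid, function(t) .class_ap(scenes, cl, t), numeric(1))
    n_gt <- sum(vapply(scenes, function(s) sum(s$gt$class == cl), numeric(1)))
    data.frame(class = cl,
               AP = mean(ap_at[match(iou_thresholds, grid)]),
               AP50 = ap_at[match(0.5, grid)],
               AP25 = ap_at[match(0.25, grid)],
               n_gt = n_gt)
  })
  per_class <- do.call(rbind, per)
  keep <- per_class$n_gt > 0
  avg <- if (any(keep)) colMeans(per_class[keep, c("AP", "AP50", "AP25")])
         else c(AP = NA_real_, AP50 = NA_real_, AP25 = NA_real_)
  list(per_class = per_class, average = as.list(avg))
}

.instance_scenes <- function(pred, gt) {
  is_scene_list <- is.list(pred) && !inherits(pred, "forest_cloud") &&
    is.null(pred$sets)
  if (is_scene_list) {
    if (length(pred) != length(gt)) stop("pred and gt scene lists differ in length")
    lapply(seq_along(pred), function(i) .as_instance_scene(pred[[i]], gt[[i]]))
  } else list(.as_instance_scene(pred, gt))
}

# Pooled AP for one class at one threshold: detections ranked globally,
# matched within their own scene.
.class_ap <- function(scenes, cl, thr, strict = FALSE) {
  confs <- list(); tps <- list(); n_gt <- 0L
  for (s in scenes) {
    pj <- which(s$pred$class == cl); gk <- which(s$gt$class == cl)
    n_gt <- n_gt + length(gk)
    if (!length(pj)) next
    iou <- .pair_iou(s$pred$sets[pj], s$gt$sets[gk])
    conf <- s$pred$confidence[pj]
    tp <- .greedy_tp(iou, conf, thr, strict)
    ord <- order(-conf, seq_along(conf))
    confs[[length(confs) + 1L]] <- conf[ord]
    tps[[length(tps) + 1L]] <- tp
  }
  if (n_gt == 0L) return(NA_real_)
  conf <- unlist(confs); tp <- unlist(tps)
  if (!length(conf)) return(0)
  ord <- order(-conf)
  .ap_from_tp(tp[ord], n_gt)
}

#' Instance detection precision and recall
#'
#' A detection is correct when its IoU with an unmatched ground-truth
#' instance exceeds 0.5 (strict), under greedy confidence-ordered matching.
#' Per-class precision and recall are averaged over classes (mPrec, mRec).
#'
#' @inheritParams instance_ap
#' @param iou_cut the strict IoU cut, default 0.5.
#' @return list with `per_class` data.frame and `mPrec`, `mRec`.
#' @export
detection_pr <- function(pred, gt, iou_cut = 0.5) {
  scenes <- .instance_scenes(pred, gt)
  classes <- sort(unique(unlist(lapply(scenes, function(s) s$gt$class))))
  per <- lapply(classes, function(cl) {
    tp <- 0L; np <- 0L; ng <- 0L
    for (s in scenes) {
      pj <- which(s$pred$class == cl); gk <- which(s$gt$class == cl)
      np <- np + length(pj); ng <- ng + length(gk)
      if (!length(pj) || !length(gk)) next
      iou <- .pair_iou(s$pred$sets[pj], s$gt$sets[gk])
      tp <- tp + sum(.greedy_tp(iou, s$pred$confidence[pj], iou_cut, strict = TRUE))
    }
    data.frame(class = cl,
               Prec = if (np == 0L) 0 else tp / np,
               Rec = if (ng == 0L) 0 else tp / ng,
               n_gt = ng)
  })
  per_class <- do.call(rbind, per)
  keep <- per_class$n_gt > 0
  list(per_class = per_class,
       mPrec = if (any(keep)) mean(per_class$Prec[keep]) else 0,
       mRec = if (any(keep)) mean(per_class$Rec[keep]) else 0)
}

#' Instance coverage metrics (mCov, mWCov)
#'
#' For each ground-truth instance, the best IoU achieved by any prediction;
#' mCov is the unweighted mean, mWCov weights each instance by its share of
#' the class's points.
#'
#' @inheritParams instance_ap
#' @return list with `per_class` data.frame and `mCov`, `mWCov` averaged over
#'   classes.
#' @export
coverage_metrics <- function(pred, gt) {
  scenes <- .instance_scenes(pred, gt)
  classes <- sort(unique(unlist(lapply(scenes, function(s) s$gt$class))))
  if (!length(classes) || all(vapply(scenes, function(s) length(s$gt$sets) == 0L, logical(1))))
    stop("coverage metrics need at least one ground-truth instance")
  per <- lapply(classes, function(cl) {
    best <- numeric(0); sizes <- numeric(0)
    for (s in scenes) {
      gk <- which(s$gt$class == cl)
      if (!length(gk)) next
      pj <- which(s$pred$class == cl)
      iou <- if (length(pj)) .pair_iou(s$pred$sets[pj], s$gt$sets[gk]) else
        matrix(0, 0, length(gk))
      best <- c(best, if (nrow(iou)) apply(iou, 2L, max) else rep(0, length(gk)))
      sizes <- c(sizes, lengths(s$gt$sets[gk]))
    }
    if (!length(best)) return(NULL)
    data.frame(class = cl, mCov = mean(best),
               mWCov = sum(sizes / sum(sizes) * best), n_gt = length(best))
  })
  per_class <- do.call(rbind, per)
  list(per_class = per_class, mCov = mean(per_class$mCov),
       mWCov = mean(per_class$mWCov))
}

#' Evaluate a directory (or list) of predictions against ground truth
#'
#' Computes semantic and instance metrics per block and pooled over blocks;
#' semantic counts pool additively, instance metrics pool detections across
#' blocks (matched within their own block).
#'
#' @param pred directory of predicted labelled clouds, or a list of
#'   `forest_cloud`s.
#' @param gt matching directory or list of ground-truth clouds. When
#'   directories are given, files are paired by name.
#' @param out_json optional path: write the pooled report as JSON.
#' @return an `eval_report`: `semantic`, `instance_ap`, `detection`,
#'   `coverage` (pooled) and `per_block` summaries.
#' @export
evaluate_run <- function(pred, gt, out_json = NULL) {
  if (is.character(pred)) {
    pf <- sort(list.files(pred, pattern = "\\.(ply|las|xyz)$", full.names = TRUE))
    gf <- sort(list.files(gt, pattern = "\\.(ply|las|xyz)$", full.names = TRUE))
    if (!length(pf)) stop("no point-cloud files found in '", pred, "'")
    unpaired <- c(setdiff(basename(pf), basename(gf)), setdiff(basename(gf), basename(pf)))
    if (length(unpaired))
      stop("unpaired prediction/ground-truth files: ", paste(unpaired, collapse = ", "))
    pred <- lapply(pf, read_point_cloud)
    gt <- lapply(gf, read_point_cloud)
  }
  if (length(pred) != length(gt)) stop("pred and gt lists differ in length")
  for (i in seq_along(pred))
    if (n_points(pred[[i]]) != n_points(gt[[i]]))
      stop("block ", i, ": prediction and ground truth differ in point count")
  sem_pool <- semantic_metrics(unlist(lapply(pred, `[[`, "semantic")),
                               unlist(lapply(gt, `[[`, "semantic")))
  ap <- instance_ap(pred, gt)
  pr <- detection_pr(pred, gt)
  cov <- coverage_metrics(pred, gt)
  per_block <- lapply(seq_along(pred), function(i) {
    list(semantic = semantic_metrics(pred[[i]]$semantic, gt[[i]]$semantic),
         instance_ap = instance_ap(pred[[i]], gt[[i]]),
         coverage = coverage_metrics(pred[[i]], gt[[i]]))
  })
  rep <- structure(list(semantic = sem_pool, instance_ap = ap, detection = pr,
                        coverage = cov, per_block = per_block),
                   class = "eval_report")
  if (!is.null(out_json)) {
    flat <- list(semantic = c(as.list(sem_pool$average),
                              list(per_class = sem_pool$per_class)),
                 instance = c(ap$average,
                              list(mPrec = pr$mPrec, mRec = pr$mRec,
                                   mCov = cov$mCov, mWCov = cov$mWCov,
                                   per_class = ap$per_class)))
    jsonlite::write_json(flat, out_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("== Semantic segmentation (pooled) ==\n")
  pc <- x$semantic$per_class
  pc$class <- ifelse(pc$class == 0, "Ground", ifelse(pc$class == 1, "Tree", pc$class))
  print(cbind(pc[, "class", drop = FALSE],
              round(pc[, c("Prec", "Rec", "F1", "IoU")], 4)), row.names = FALSE)
  cat(sprintf("  mIoU = %.4f   mF1 = %.4f\n", x$semantic$average$IoU,
              x$semantic$average$F1))
  cat("== Instance segmentation (pooled) ==\n")
  ic <- x$instance_ap$per_class
  ic$class <- ifelse(ic$class == 0, "Ground", ifelse(ic$class == 1, "Tree", ic$class))
  print(cbind(ic[, "class", drop = FALSE],
              round(ic[, c("AP", "AP50", "AP25")], 4)), row.names = FALSE)
  cat(sprintf("  AP = %.4f  AP50 = %.4f  AP25 = %.4f\n",
              x$instance_ap$average$AP, x$instance_ap$average$AP50,
              x$instance_ap$average$AP25))
  cat(sprintf("  mPrec = %.4f  mRec = %.4f  mCov = %.4f  mWCov = %.4f\n",
              x$detection$mPrec, x$detection$mRec,
              x$coverage$mCov, x$coverage$mWCov))
  invisible(x)
}
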