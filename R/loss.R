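# Deep-supervised set-prediction loss: every decoder layer is matched to the
# ground truth and contributes classification, mask (BCE + Dice) and center
# terms. The no-object class is down-weighted in the cross-entropy.

#' Segmentation training loss
#'
#' `total = sum_layers [ CE(class; no-object weight 0.1) + w_bce * BCE +
#' w_dice * Dice on matched masks + w_ctr * L2 on matched centers ]`, with a
#' fresh Hungarian matching per layer (deep supervision). With one layer the
#' total equals the single-layer loss.
#'
#' @param layers list of per-layer predictions; each needs `class_logits`
#'   (K x 3), `scores` or `score_field` (K x V) and `centers` (K x 3).
#'   [decode_instances()] output has this shape.
#' @param gt ground truth as in [hungarian_match()].
#' @param weights loss weights: `cls`, `bce`, `dice`, `ctr`, `no_object`.
#' @return list with `total` and per-component sums (`class`, `bce`, `dice`,
#'   `center`) plus the per-layer matchings.
#' @export
segmentation_loss <- function(layers, gt,
                              weights = list(cls = 2, bce = 5, dice = 5,
                                             ctr = 1, no_object = 0.1)) {
  comp <- c(class = 0, bce = 0, dice = 0, center = 0)
  matches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    lay <- layers[[l]]
    S <- if (!is.null(lay$score_field)) lay$score_field$S else nval(lay$scores)
    logits <- if (!is.null(lay$class_logits)) lay$class_logits else nval(lay$logits)
    centers <- nval(lay$centers)
    m <- hungarian_match(logits, S, centers, gt,
                         weights = weights[c("cls", "bce", "dice", "ctr")])
    matches[[l]] <- m
    lt <- .layer_loss_values(logits, S, centers, gt, m, weights)
    comp <- comp + lt
  }
  total <- sum(comp["class"] + comp["bce"] + comp["dice"] + comp["center"])
  if (!is.finite(total))
    stop("non-finite loss; components: ",
         paste(names(comp), signif(comp, 4), sep = "=", collapse = ", "))
  list(total = total, components = as.list(comp), matches = matches)
}

.layer_loss_values <- function(logits, S, centers, gt, m, w) {
  K <- nrow(logits)
  targets <- rep(3L, K)                    # no-object
  if (nrow(m$pairs)) targets[m$pairs$query] <- gt$class[m$pairs$gt] + 1L
  cw <- c(1, 1, w$no_object)
  p <- exp(logits - apply(logits, 1L, max)); p <- p / rowSums(p)
  wv <- cw[targets]
  ce <- sum(wv * -log(pmax(p[cbind(seq_len(K), targets)], 1e-12))) / sum(wv)
  bce <- dice <- ctr <- 0
  if (nrow(m$pairs)) {
    Sm <- S[m$pairs$query, , drop = FALSE]
    Tm <- gt$masks[m$pairs$gt, , drop = FALSE]
    sp <- pmax(Sm, 0) + log1p(exp(-abs(Sm)))
    bce <- mean(sp - Sm * Tm)
    pm <- 1 / (1 + exp(-Sm))
    dice <- mean(1 - (2 * rowSums(pm * Tm) + 1) / (rowSums(pm) + rowSums(Tm) + 1))
    cm <- centers[m$pairs$query, , drop = FALSE]
    ctr <- mean((cm - gt$centers[m$pairs$gt, , drop = FALSE])^2)
  }
  c(class = w$cls * ce, bce = w$bce * bce, dice = w$dice * dice,
    center = w$ctr * ctr)
}

# Autograd version: same quantities built on tape nodes so gradients flow.
# `layers` are the node lists from decode_graph; matching is computed on
# values (it is piecewise constant, so this is the exact subgradient).
loss_graph <- function(layers, gt, weights = list(cls = 2, bce = 5, dice = 5,
                                                  ctr = 1, no_object = 0.1)) {
  terms <- list()
  comp <- c(class = 0, bce = 0, dice = 0, center = 0)
  for (l in seq_along(layers)) {
    lay <- layers[[l]]
    S <- lay$scores; logits <- lay$logits; centers <- lay$centers
    m <- hungarian_match(nval(logits), nval(S), nval(centers), gt,
                         weights = weights[c("cls", "bce", "dice", "ctr")])
    K <- nrow(nval(logits))
    targets <- rep(3L, K)
    if (nrow(m$pairs)) targets[m$pairs$query] <- gt$class[m$pairs$gt] + 1L
    ce <- tg_scale(tg_cross_entropy(logits, targets, c(1, 1, weights$no_object)),
                   weights$cls)
    terms[[length(terms) + 1L]] <- ce
    comp["class"] <- comp["class"] + nval(ce)
    if (nrow(m$pairs)) {
      Sm <- tg_rows(S, m$pairs$query)
      Tm <- gt$masks[m$pairs$gt, , drop = FALSE]
      bce <- tg_scale(tg_bce_logits(Sm, Tm), weights$bce)
      dce <- tg_scale(tg_dice_loss(Sm, Tm), weights$dice)
      cm <- tg_rows(centers, m$pairs$query)
      ctr <- tg_scale(tg_mse(cm, gt$centers[m$pairs$gt, , drop = FALSE]),
                      weights$ctr)
      terms <- c(terms, list(bce, dce, ctr))
      comp["bce"] <- comp["bce"] + nval(bce)
      comp["dice"] <- comp["dice"] + nval(dce)
      comp["center"] <- comp["center"] + nval(ctr)
    }
  }
  total <- Reduce(tg_add, terms)
  if (!is.finite(nval(total)))
    stop("non-finite loss; components: ",
         paste(names(comp), signif(comp, 4), sep = "=", collapse = ", "))
  list(total = total, components = comp)
}

# Row-subset op (needed for matched-mask losses).
tg_rows <- function(a, idx) {
  av <- nval(a)
  tg_node(av[idx, , drop = FALSE], function(g) {
    full <- matrix(0, nrow(av), ncol(av))
    full[idx, ] <- full[idx, , drop = FALSE] + g
    tg_acc(a, full)
  })
}

# Voxel-level ground truth for one block: majority instance per voxel.
# Returns masks (G x V), class per instance, normalized centroids (point
# level), and voxel semantic labels.
voxel_ground_truth <- function(cloud, grid) {
  inst <- cloud$instance
  p2v <- grid$point_to_voxel
  V <- nrow(grid$voxel_coords)
  ids <- sort(unique(inst[inst >= 0L]))
  # majority vote per voxel
  tab <- table(factor(p2v, levels = seq_len(V)), factor(inst, levels = ids))
  vox_inst <- ids[max.col(tab, ties.method = "first")]
  vox_inst[rowSums(tab) == 0] <- -1L
  G <- length(ids)
  masks <- matrix(0, G, V)
  for (g in seq_len(G)) masks[g, vox_inst == ids[g]] <- 1
  cls <- vapply(ids, function(i) {
    s <- cloud$semantic[inst == i]
    as.integer(names(sort(table(s), decreasing = TRUE))[1])
  }, integer(1))
  ext <- block_extent(grid)
  centers <- t(vapply(ids, function(i) {
    cm <- colMeans(cloud$coords[inst == i, , drop = FALSE])
    (cm - ext$p_min) / (ext$p_max - ext$p_min)
  }, numeric(3)))
  vox_sem <- rep(-1L, V)
  for (g in seq_len(G)) vox_sem[masks[g, ] == 1] <- cls[g]
  keep <- rowSums(masks) > 0
  list(masks = masks[keep, , drop = FALSE], class = cls[keep],
       centers = pmin(pmax(centers[keep, , drop = FALSE], 0), 1),
       ids = ids[keep], voxel_semantic = vox_sem)
}
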