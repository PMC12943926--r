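# Training loop: AdamW with one-cycle learning rate, one block per step,
# deep-supervised set-prediction loss, gradient-norm clipping.

adamw_init <- function(params) {
  list(m = map_tree(function(p) array(0, dim(p)), params),
       v = map_tree(function(p) array(0, dim(p)), params),
       t = 0L)
}

adamw_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-4) {
  opt$t <- opt$t + 1L
  opt$m <- map_tree(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- map_tree(function(v, g) beta2 * v + (1 - beta2) * g * g, opt$v, grads)
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  params <- map_tree(function(p, m, v)
    p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p),
    params, opt$m, opt$v)
  list(params = params, opt = opt)
}

# One-cycle schedule: linear warmup to lr_max over the first 30% of steps,
# cosine anneal to lr_max/100 afterwards.
one_cycle_lr <- function(step, total, lr_max, warmup_frac = 0.3,
                         div_start = 25, div_end = 100) {
  w <- max(1, round(warmup_frac * total))
  if (step <= w) {
    lr_max / div_start + (lr_max - lr_max / div_start) * (step / w)
  } else {
    p <- (step - w) / max(1, total - w)
    lr_end <- lr_max / div_end
    lr_end + (lr_max - lr_end) * (1 + cos(pi * p)) / 2
  }
}

# Clip the global gradient norm.
clip_grads <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(tree_leaves(grads), function(g) sum(g * g), numeric(1))))
  if (is.finite(total) && total > max_norm)
    grads <- map_tree(function(g) g * (max_norm / total), grads)
  grads
}

# Voxelize a block cloud and cache everything training needs.
prepare_block <- function(cloud, config) {
  grid <- voxelize(cloud, config$voxel_size)
  plan <- build_conv_plan(grid)
  gt <- voxel_ground_truth(cloud, grid)
  list(cloud = cloud, grid = grid, plan = plan, gt = gt)
}

#' Train a segmentation model
#'
#' Seeded, resumable training: one optimizer step per block (cycled in a
#' seeded order), AdamW with a one-cycle learning rate, per-step loss
#' components logged, best-validation checkpoint retained when validation
#' blocks are given. Aborts on divergence (non-finite loss), returning the
#' last finite-state model.
#'
#' @param model an `its_model` from [init_model()].
#' @param blocks list of labelled `forest_cloud`s (training blocks) or of
#'   block lists from [tile_blocks()].
#' @param val_blocks optional validation blocks.
#' @param iters optimizer steps; default from the model config.
#' @param log_every print a progress line every this many steps (0 = quiet).
#' @param checkpoint_path optional path: the best (validation loss, else
#'   final) model is written there.
#' @return the trained `its_model` with a `log` attribute: data.frame of
#'   step, lr, loss and components.
#' @export
train_model <- function(model, blocks, val_blocks = NULL, iters = NULL,
                        log_every = 0L, checkpoint_path = NULL) {
  stopifnot(inherits(model, "its_model"))
  if (!length(blocks)) stop("need at least one training block")
  blocks <- lapply(blocks, function(b) if (inherits(b, "forest_cloud")) b else b$cloud)
  iters <- iters %||% model$config$optim$iters
  cfg <- model$config
  prep <- lapply(blocks, prepare_block, config = cfg)
  prep_val <- if (!is.null(val_blocks))
    lapply(lapply(val_blocks, function(b) if (inherits(b, "forest_cloud")) b else b$cloud),
           prepare_block, config = cfg)
  opt <- adamw_init(model$params)
  bs <- min(length(prep), cfg$optim$batch_size)
  order_seed <- derive_seed(cfg$seed, 555L)
  draws <- ceiling(iters * bs / length(prep)) + 1L
  block_order <- with_seed(order_seed,
                           unlist(lapply(seq_len(draws),
                                         function(i) sample(length(prep)))))
  log <- vector("list", iters)
  best_val <- Inf; best_model <- NULL
  for (step in seq_len(iters)) {
    batch <- block_order[(step - 1L) * bs + seq_len(bs)]
    lr <- one_cycle_lr(step, iters, cfg$optim$lr)
    # one backward per block, gradients accumulated across the minibatch:
    # mathematically identical to a joint backward, but the tape only ever
    # holds one block's graph
    grads <- NULL
    comp <- c(class = 0, bce = 0, dice = 0, center = 0)
    loss_value <- 0
    diverged <- FALSE
    for (bi in seq_len(bs)) {
      b <- prep[[batch[bi]]]
      tg_begin()
      pp <- wrap_params(model$params)
      fw <- forward_graph(model, b$grid, plan = b$plan, training = TRUE, pp = pp)
      ls <- loss_graph(fw$layers, b$gt, weights = cfg$loss)
      if (!is.finite(nval(ls$total))) { tg_clear(); diverged <- TRUE; break }
      tg_backward(ls$total)
      g <- grad_tree(pp)
      tg_clear()
      grads <- if (is.null(grads)) map_tree(function(x) x / bs, g)
               else map_tree(function(a, x) a + x / bs, grads, g)
      comp <- comp + ls$components / bs
      loss_value <- loss_value + nval(ls$total) / bs
    }
    if (diverged) {
      warning("training diverged at step ", step, "; returning last good model")
      break
    }
    grads <- clip_grads(grads, cfg$optim$grad_clip)
    upd <- adamw_step(model$params, grads, opt, lr,
                      beta1 = cfg$optim$betas[1], beta2 = cfg$optim$betas[2],
                      eps = cfg$optim$eps, weight_decay = cfg$optim$weight_decay)
    model$params <- upd$params
    opt <- upd$opt
    log[[step]] <- data.frame(step = step, lr = lr, loss = loss_value, t(comp))
    if (log_every > 0L && step %% log_every == 0L)
      message(sprintf("step %4d  lr %.2e  loss %8.4f", step, lr, loss_value))
    if (!is.null(prep_val) && (step %% 25L == 0L || step == iters)) {
      vl <- mean(vapply(prep_val, function(v) {
        fwv <- forward_graph(model, v$grid, plan = v$plan, training = FALSE)
        out <- segmentation_loss(lapply(fwv$layers, function(l)
          list(class_logits = nval(l$logits), scores = nval(l$scores),
               centers = nval(l$centers))), v$gt, weights = cfg$loss)$total
        tg_clear()
        out
      }, numeric(1)))
      if (vl < best_val) { best_val <- vl; best_model <- model }
    }
  }
  if (!is.null(best_model)) model <- best_model
  attr(model, "log") <- do.call(rbind, log[!vapply(log, is.null, logical(1))])
  if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
  model
}

#' Predict instances for a point cloud
#'
#' Voxelizes, runs the network in eval mode, post-processes the final score
#' field and broadcasts the voxel masks back to points.
#'
#' @param model a trained `its_model` (or checkpoint path).
#' @param cloud a `forest_cloud` (labels, if any, are ignored).
#' @return list with `cloud` (the input with predicted `semantic` and
#'   `instance` filled), `instances` (data.frame: id, class, confidence,
#'   n_points, center) and the raw `prediction`.
#' @export
predict_instances <- function(model, cloud) {
  if (is.character(model)) model <- load_checkpoint(model)
  grid <- voxelize(cloud, model$config$voxel_size)
  fw <- forward_graph(model, grid, training = FALSE)
  final <- fw$layers[[length(fw$layers)]]
  pred <- postprocess_instances(
    structure(list(S = nval(final$scores)), class = "score_field"),
    nval(final$logits), grid,
    score_threshold = model$config$decoder$score_threshold,
    min_points = model$config$decoder$min_points)
  tg_clear()
  out <- cloud
  out$semantic <- pred$point_semantic
  out$instance <- pred$point_instance
  inst <- if (length(pred$masks)) data.frame(
    id = vapply(seq_along(pred$masks), function(j)
      unique(pred$point_instance[pred$masks[[j]]])[1], integer(1)),
    class = pred$class,
    confidence = pred$confidence,
    n_points = lengths(pred$masks),
    t(vapply(pred$masks, function(m) colMeans(cloud$coords[m, , drop = FALSE]),
             numeric(3)))
  ) else data.frame()
  if (nrow(inst)) names(inst)[5:7] <- c("cx", "cy", "cz")
  list(cloud = out, instances = inst, prediction = pred)
}
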