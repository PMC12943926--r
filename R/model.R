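#' Full run configuration
#'
#' Bundles the backbone, decoder, optimizer and preprocessing settings. The
#' reference profile ([reference_profile()]) uses the full-width network (AdamW,
#' initial learning rate 2e-4, one-cycle schedule, 300 epochs, batch 10,
#' voxel size 0.15 m) and is GPU-scale; the desk profile ([desk_profile()])
#' keeps the topology but scales widths and problem sizes to a single CPU.
#'
#' @param width_multiplier channel scale of the backbone.
#' @param n_queries K, the number of instance queries per block.
#' @param n_layers cascaded decoder layers.
#' @param lambda balancing coefficient of the distance penalty.
#' @param query_dim query embedding dimension.
#' @param voxel_size voxel edge, metres.
#' @param lr peak learning rate (one-cycle).
#' @param iters optimizer steps (one block per step).
#' @param epochs nominal epochs (reference profile bookkeeping).
#' @param batch_size reference-profile batch size.
#' @param seed master seed: data order, initialisation, everything.
#' @param use_color see [backbone_config()].
#' @return a `run_config` list with `backbone`, `decoder`, `optim`,
#'   `preprocess` and `synth` sections.
#' @export
run_config <- function(width_multiplier = 1, n_queries = 20L, n_layers = 3L,
                       lambda = 1, query_dim = 128L, voxel_size = 0.15,
                       lr = 2e-4, iters = 300L, epochs = 300L,
                       batch_size = 10L, seed = 1L, use_color = FALSE) {
  bb <- backbone_config(width_multiplier, use_color)
  embed_dim <- bb$decoder_channels[4]
  qd <- max(8L, as.integer(round(query_dim * width_multiplier)))
  structure(list(
    backbone = bb,
    decoder = list(n_queries = as.integer(n_queries),
                   n_layers = as.integer(n_layers), lambda = lambda,
                   query_dim = qd, embed_dim = embed_dim,
                   feature_dim = bb$decoder_channels[4],
                   score_threshold = 0.35, min_points = 30L),
    optim = list(name = "adamw", lr = lr, weight_decay = 1e-4,
                 betas = c(0.9, 0.999), eps = 1e-8, schedule = "one_cycle",
                 iters = as.integer(iters), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), grad_clip = 5),
    voxel_size = voxel_size,
    preprocess = list(sor_k = 8L, sor_multiplier = 2, ground_cell = 0.5,
                      ground_threshold = 0.3, dem_cell = 0.5,
                      target_ratio = 1.0, block_size = 10, stride = 5,
                      min_points = 100L, seed = as.integer(seed)),
    loss = list(cls = 2, bce = 5, dice = 5, ctr = 1, no_object = 0.1),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Reference (full-scale) profile
#' @param seed master seed.
#' @return a `run_config` at full width.
#' @export
reference_profile <- function(seed = 1L) run_config(seed = seed)

#' Desk-scale profile
#'
#' Same topology at a quarter of the width: 16 queries, 2 decoder layers,
#' 200 optimizer steps, and synthetic densities that put roughly 3k points
#' in a 10 m block (about 4 trees plus ground) so the whole pipeline trains
#' in minutes on one CPU.
#'
#' @param seed master seed.
#' @return a `run_config`.
#' @export
desk_profile <- function(seed = 1L) {
  cfg <- run_config(width_multiplier = 0.25, n_queries = 16L, n_layers = 2L,
                    lambda = 1, voxel_size = 0.15, lr = 2e-3, iters = 200L,
                    batch_size = 4L, seed = seed)
  cfg$synth <- list(tree = tree_params(points_per_m2 = 20),
                    plot = plot_params(ground_density = 15, seed = seed))
  cfg
}

#' Initialise a segmentation model
#'
#' All weights are drawn under the configuration seed, so initialisation is
#' reproducible.
#'
#' @param config a [run_config()] (e.g. [desk_profile()]).
#' @param seed optional override of `config$seed`.
#' @return an `its_model`: `params` (nested weight list), `state`
#'   (batch-norm running statistics), `config`.
#' @export
init_model <- function(config = desk_profile(), seed = NULL) {
  seed <- seed %||% config$seed
  params <- with_seed(seed, {
    bb <- init_backbone(config$backbone)
    dc <- config$decoder
    dc$feature_dim <- config$backbone$decoder_channels[4]
    list(backbone = bb, decoder = init_decoder(dc))
  })
  structure(list(params = params,
                 state = list(backbone = init_backbone_state(params$backbone)),
                 config = config,
                 config_hash = config_hash(config)),
            class = "its_model")
}

#' @export
print.its_model <- function(x, ...) {
  np <- sum(vapply(tree_leaves(x$params), length, numeric(1)))
  cat(sprintf("<its_model> width x%.2g, K=%d queries, %d decoder layers, %s parameters\n",
              x$config$backbone$width_multiplier, x$config$decoder$n_queries,
              x$config$decoder$n_layers, format(np, big.mark = ",")))
  invisible(x)
}

# FNV-1a over the serialized config: a dependency-free fingerprint stored in
# checkpoints so prediction can refuse incompatible weights.
config_hash <- function(config) {
  bytes <- serialize(config, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the weights, batch-norm running statistics, the full
#' configuration and its hash.
#'
#' @param model an `its_model`.
#' @param path checkpoint file path (RDS).
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: the
#'   model.
#' @export
save_checkpoint <- function(model, path) {
  state_plain <- rapply(model$state, function(e)
    if (is.environment(e)) list(mean = e$mean, var = e$var) else e,
    how = "replace")
  saveRDS(list(params = model$params, state = state_plain,
               config = model$config, config_hash = model$config_hash), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- structure(list(params = ck$params, state = NULL, config = ck$config,
                          config_hash = ck$config_hash), class = "its_model")
  revive <- function(x) {
    if (is.list(x) && !is.null(names(x)) && all(c("mean", "var") %in% names(x)) &&
        length(x) == 2L) {
      e <- new_bn_state(); e$mean <- x$mean; e$var <- x$var; e
    } else if (is.list(x)) lapply(x, revive) else x
  }
  model$state <- revive(ck$state)
  model
}
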