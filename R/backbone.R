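#' Backbone configuration
#'
#' Sparse 3D U-Net: a 5^3 stem convolution, four stride-2 encoder stages of
#' residual blocks (channels 32/64/128/256, blocks 2/3/4/6), and four
#' transpose-convolution decoder stages with skip connections (channels
#' 256/128/96/96, 2 blocks each). Global-context channel gates recalibrate
#' features after the 128- and 256-channel encoder stages and after the final
#' 96-channel decoder stage. `width_multiplier` scales every channel count so
#' the same topology runs at desk scale on a CPU.
#'
#' @param width_multiplier multiplies every channel count (>= applied with a
#'   floor of one channel).
#' @param use_color append mean voxel color to the input features.
#' @param reduction_ratio bottleneck ratio of the channel gate (C -> C/r -> C).
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(width_multiplier = 1, use_color = FALSE,
                            reduction_ratio = 4) {
  ch <- function(c) max(1L, as.integer(round(c * width_multiplier)))
  structure(list(
    width_multiplier = width_multiplier,
    use_color = use_color,
    reduction_ratio = reduction_ratio,
    in_dim = if (use_color) 6L else 3L,
    stem_channels = ch(32),
    encoder_channels = vapply(c(32, 64, 128, 256), ch, integer(1)),
    encoder_blocks = c(2L, 3L, 4L, 6L),
    decoder_channels = vapply(c(256, 128, 96, 96), ch, integer(1)),
    decoder_blocks = c(2L, 2L, 2L, 2L),
    gate_after = c("encoder3", "encoder4", "decoder4"),
    stem_kernel = 5L, block_kernel = 3L, resample_kernel = 2L
  ), class = "backbone_config")
}

#' Structural summary of the backbone
#'
#' One row per stage with operation, kernel size, stride and output channels;
#' used to verify architecture conformance.
#'
#' @param config a [backbone_config()].
#' @return a data.frame describing the stage sequence.
#' @export
backbone_summary <- function(config) {
  enc <- config$encoder_channels; dec <- config$decoder_channels
  rows <- list(
    c("stem", "conv", 5, 1, config$stem_channels),
    c("down1", "conv", 2, 2, enc[1]), c("encoder1", "resblock", 3, 1, enc[1]),
    c("down2", "conv", 2, 2, enc[2]), c("encoder2", "resblock", 3, 1, enc[2]),
    c("down3", "conv", 2, 2, enc[3]), c("encoder3", "resblock", 3, 1, enc[3]),
    c("gate_encoder3", "channel_gate", NA, 1, enc[3]),
    c("down4", "conv", 2, 2, enc[4]), c("encoder4", "resblock", 3, 1, enc[4]),
    c("gate_encoder4", "channel_gate", NA, 1, enc[4]),
    c("up4", "transpose_conv", 2, 2, dec[1]), c("decoder1", "resblock", 3, 1, dec[1]),
    c("up5", "transpose_conv", 2, 2, dec[2]), c("decoder2", "resblock", 3, 1, dec[2]),
    c("up6", "transpose_conv", 2, 2, dec[3]), c("decoder3", "resblock", 3, 1, dec[3]),
    c("up7", "transpose_conv", 2, 2, dec[4]), c("decoder4", "resblock", 3, 1, dec[4]),
    c("gate_decoder4", "channel_gate", NA, 1, dec[4]))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("stage", "operation", "kernel", "stride", "out_channels")
  df$kernel <- as.numeric(df$kernel)
  df$stride <- as.numeric(df$stride)
  df$out_channels <- as.integer(df$out_channels)
  df
}

#' Global average pooling over occupied voxels
#'
#' Compresses a sparse feature tensor (V x C) into a 1 x C channel
#' descriptor: `z_c = mean_i F[i, c]`, the mean over occupied voxels only.
#'
#' @param features V x C feature matrix, V >= 1.
#' @return 1 x C matrix of channel means.
#' @export
channel_pool <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) stop("cannot pool an empty scene (V = 0)")
  matrix(colMeans(features), 1L, dimnames = list(NULL, colnames(features)))
}

#' Channel recalibration gate
#'
#' `F_out = sigmoid(W2 relu(W1 z)) * F_in` with `z` the pooled channel
#' descriptor: a squeeze-excitation-style gate in (0, 1) per channel,
#' broadcast over voxels. Contractive by construction: |F_out| <= |F_in|.
#'
#' @param features V x C feature matrix.
#' @param W1 C x C/r bottleneck weights.
#' @param W2 C/r x C expansion weights.
#' @return the recalibrated V x C matrix, with the gate as attribute `"gate"`.
#' @export
channel_recalibrate <- function(features, W1, W2) {
  features <- as.matrix(features)
  if (ncol(features) != nrow(W1)) stop("W1 rows must equal feature channels")
  if (ncol(W1) != nrow(W2)) stop("W1 and W2 do not compose")
  if (ncol(W2) != ncol(features)) stop("W2 columns must equal feature channels")
  z <- channel_pool(features)
  h <- pmax(z %*% W1, 0)
  s <- 1 / (1 + exp(-(h %*% W2)))
  out <- features * rep(as.vector(s), each = nrow(features))
  attr(out, "gate") <- as.vector(s)
  out
}

init_res_block <- function(cin, cout, k3 = 27L) {
  p <- list(conv1 = init_mat(k3 * cin, cout), bn1 = init_bn(cout),
            conv2 = init_mat(k3 * cout, cout), bn2 = init_bn(cout))
  if (cin != cout) {
    p$proj <- init_mat(cin, cout, sqrt(1 / cin))
    p$bnp <- init_bn(cout)
  }
  p
}

init_channel_gate <- function(c, r) {
  cr <- max(1L, as.integer(round(c / r)))
  list(W1 = init_mat(c, cr, sqrt(1 / c)), W2 = init_mat(cr, c, sqrt(1 / cr)))
}

init_backbone <- function(config) {
  enc <- config$encoder_channels; dec <- config$decoder_channels
  p <- list(stem = list(W = init_mat(125L * config$in_dim, config$stem_channels),
                        bn = init_bn(config$stem_channels)))
  prev <- config$stem_channels
  for (l in 1:4) {
    p[[paste0("down", l)]] <- list(W = init_mat(8L * prev, enc[l]),
                                   bn = init_bn(enc[l]))
    p[[paste0("enc", l)]] <- lapply(seq_len(config$encoder_blocks[l]),
                                    function(i) init_res_block(enc[l], enc[l]))
    prev <- enc[l]
  }
  p$gate_enc3 <- init_channel_gate(enc[3], config$reduction_ratio)
  p$gate_enc4 <- init_channel_gate(enc[4], config$reduction_ratio)
  skip_ch <- c(config$stem_channels, enc[1], enc[2], enc[3])
  prev <- enc[4]
  for (l in 1:4) {
    p[[paste0("up", l)]] <- list(W = init_mat(8L * prev, dec[l]),
                                 bn = init_bn(dec[l]))
    cin <- dec[l] + skip_ch[5L - l]
    p[[paste0("dec", l)]] <- lapply(seq_len(config$decoder_blocks[l]), function(i)
      init_res_block(if (i == 1L) cin else dec[l], dec[l]))
    prev <- dec[l]
  }
  p$gate_dec <- init_channel_gate(dec[4], config$reduction_ratio)
  p
}

# Parallel tree of batch-norm state environments for the backbone params.
init_backbone_state <- function(p) {
  walk <- function(x, nm) {
    if (!is.list(x)) return(NULL)
    if (!is.null(x$gamma)) return(new_bn_state())
    out <- lapply(x, walk)
    names(out) <- names(x)
    out
  }
  lapply(p, walk)
}

# Autograd forward pass of the U-Net. `pp` is the wrapped (leaf-node)
# parameter tree, `st` the batch-norm state tree, `plan` the kernel maps.
# Returns the feature pyramid as nodes, fine (F0) to coarse (F4).
backbone_graph <- function(pp, st, plan, config, features, training = FALSE) {
  x <- tg_leaf(features)
  x <- conv_bn_relu(x, pp$stem, st$stem$bn, plan$stem, training)
  skips <- list(x)
  for (l in 1:4) {
    dn <- paste0("down", l)
    x <- conv_bn_relu(x, pp[[dn]], st[[dn]]$bn, plan$downs[[l]], training)
    en <- paste0("enc", l)
    for (i in seq_along(pp[[en]]))
      x <- res_block(x, pp[[en]][[i]], st[[en]][[i]], plan$same[[l + 1L]], training)
    if (l == 3L) x <- channel_gate_apply(x, pp$gate_enc3)
    if (l == 4L) x <- channel_gate_apply(x, pp$gate_enc4)
    if (l < 4L) skips[[l + 1L]] <- x
  }
  pyramid <- list(x)  # F4 at the coarsest level
  for (l in 1:4) {
    un <- paste0("up", l)
    x <- conv_bn_relu(x, pp[[un]], st[[un]]$bn, plan$ups[[5L - l]], training)
    x <- tg_cbind2(x, skips[[5L - l]])
    de <- paste0("dec", l)
    for (i in seq_along(pp[[de]]))
      x <- res_block(x, pp[[de]][[i]], st[[de]][[i]], plan$same[[5L - l]], training)
    if (l == 4L) x <- channel_gate_apply(x, pp$gate_dec)
    pyramid[[l + 1L]] <- x
  }
  # pyramid[[1]] = F4 ... pyramid[[5]] = F0; return named fine-to-coarse
  list(F0 = pyramid[[5]], F1 = pyramid[[4]], F2 = pyramid[[3]],
       F3 = pyramid[[2]], F4 = pyramid[[1]])
}

#' Run the backbone on a sparse voxel grid
#'
#' @param model a model from [init_model()] (or a bare backbone from
#'   `init_backbone`, wrapped in a list with `config`).
#' @param grid a `voxel_grid` with at least one voxel.
#' @param training use batch statistics and update running norms.
#' @return list with `features` (F0..F4 plain matrices, fine to coarse) and
#'   `coords` (voxel coordinates per level).
#' @export
backbone_forward <- function(model, grid, training = FALSE) {
  if (nrow(grid$voxel_coords) == 0L) stop("empty voxel grid")
  plan <- build_conv_plan(grid)
  pp <- wrap_params(model$params$backbone)
  py <- backbone_graph(pp, model$state$backbone, plan, model$config$backbone,
                       grid$features, training)
  list(features = lapply(py, nval), coords = plan$coords)
}
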