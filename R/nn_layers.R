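# Sparse-tensor plumbing shared by the backbone and decoder: kernel maps for
# sparse convolutions at each resolution level, weight initialisation, and
# attention built from autograd ops.

.offsets <- function(r) as.matrix(expand.grid(dx = r, dy = r, dz = r))

# Kernel map for a stride-1 convolution on one level: out row n takes input
# from kmap[n, o] for each offset o; unoccupied neighbours point at the
# padding row V + 1.
.kmap_same <- function(coords, radius) {
  off <- .offsets(-radius:radius)
  keys <- voxel_key(coords)
  V <- nrow(coords)
  kmap <- matrix(V + 1L, V, nrow(off))
  for (o in seq_len(nrow(off))) {
    m <- match(voxel_key(sweep(coords, 2L, off[o, ], "+")), keys)
    kmap[, o] <- ifelse(is.na(m), V + 1L, m)
  }
  kmap
}

# Stride-2 downsample: coarse coords are unique floor(fine/2); each coarse
# voxel gathers its up-to-8 fine children.
.kmap_down <- function(fine_coords) {
  coarse_all <- fine_coords %/% 2L
  key_c <- voxel_key(coarse_all)
  uk <- unique(key_c)
  coarse <- coarse_all[match(uk, key_c), , drop = FALSE]
  off <- .offsets(0:1)
  keys_f <- voxel_key(fine_coords)
  Vf <- nrow(fine_coords); Vc <- nrow(coarse)
  kmap <- matrix(Vf + 1L, Vc, 8L)
  for (o in 1:8) {
    m <- match(voxel_key(sweep(coarse * 2L, 2L, off[o, ], "+")), keys_f)
    kmap[, o] <- ifelse(is.na(m), Vf + 1L, m)
  }
  list(coords = coarse, kmap = kmap)
}

# Stride-2 transpose convolution up to a known fine coordinate set: each fine
# voxel receives from its (always present) coarse parent through the kernel
# offset given by its parity.
.kmap_up <- function(fine_coords, coarse_coords) {
  parent <- match(voxel_key(fine_coords %/% 2L), voxel_key(coarse_coords))
  par <- fine_coords - (fine_coords %/% 2L) * 2L
  o <- par[, 1] + par[, 2] * 2L + par[, 3] * 4L + 1L
  Vc <- nrow(coarse_coords)
  kmap <- matrix(Vc + 1L, nrow(fine_coords), 8L)
  kmap[cbind(seq_len(nrow(fine_coords)), o)] <- parent
  kmap
}

# Precompute coordinates and kernel maps for all levels of the U-Net.
# Cached per block: the maps depend only on the voxel coordinates.
build_conv_plan <- function(grid, n_levels = 5L, stem_radius = 2L) {
  coords <- list(grid$voxel_coords)
  downs <- vector("list", n_levels - 1L)
  for (l in seq_len(n_levels - 1L)) {
    d <- .kmap_down(coords[[l]])
    coords[[l + 1L]] <- d$coords
    downs[[l]] <- d$kmap
  }
  same <- lapply(seq_len(n_levels), function(l)
    .kmap_same(coords[[l]], 1L))
  stem <- .kmap_same(coords[[1]], stem_radius)
  ups <- lapply(seq_len(n_levels - 1L), function(l)
    .kmap_up(coords[[l]], coords[[l + 1L]]))
  list(coords = coords, stem = stem, same = same, downs = downs, ups = ups,
       n_voxels = vapply(coords, nrow, integer(1)))
}

# ---- initialisation ---------------------------------------------------------

init_mat <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / nr)
  matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
}

init_linear <- function(din, dout, scale = NULL, bias = TRUE) {
  l <- list(W = init_mat(din, dout, scale %||% sqrt(1 / din)))
  if (bias) l$b <- matrix(0, 1L, dout)
  l
}

init_bn <- function(c) list(gamma = matrix(1, 1L, c), beta = matrix(0, 1L, c))

new_bn_state <- function() {
  e <- new.env(parent = emptyenv())
  e$mean <- NULL; e$var <- NULL
  e
}

# ---- composite layers (autograd) -------------------------------------------

conv_bn_relu <- function(x, p, st, kmap, training) {
  tg_relu(tg_batchnorm(tg_sparse_conv(x, p$W, kmap), p$bn$gamma, p$bn$beta,
                       st, training))
}

res_block <- function(x, p, st, kmap, training) {
  y <- tg_sparse_conv(x, p$conv1, kmap)
  y <- tg_relu(tg_batchnorm(y, p$bn1$gamma, p$bn1$beta, st$bn1, training))
  y <- tg_sparse_conv(y, p$conv2, kmap)
  y <- tg_batchnorm(y, p$bn2$gamma, p$bn2$beta, st$bn2, training)
  sc <- if (!is.null(p$proj))
    tg_batchnorm(tg_mm(x, p$proj), p$bnp$gamma, p$bnp$beta, st$bnp, training)
  else x
  tg_relu(tg_add(y, sc))
}

# Global-context channel gate: mean-pool over occupied voxels, two-layer
# bottleneck gate, sigmoid recalibration (no biases, matching the gate's
# closed form sigma(W2 relu(W1 z))).
channel_gate_apply <- function(x, p) {
  z <- tg_colmeans(x)
  s <- tg_sigmoid(tg_mm(tg_relu(tg_mm(z, p$W1)), p$W2))
  tg_mul_rv(x, s)
}

tg_cbind2 <- function(a, b) {
  av <- nval(a); bv <- nval(b)
  ca <- ncol(av)
  tg_node(cbind(av, bv), function(g) {
    tg_acc(a, g[, seq_len(ca), drop = FALSE])
    tg_acc(b, g[, ca + seq_len(ncol(bv)), drop = FALSE])
  })
}

# Scaled dot-product attention. `bias` is an additive constant matrix on the
# attention logits (0 / -1e9 masking) or NULL.
attention <- function(q_in, kv_in, p, bias = NULL) {
  d <- ncol(nval(p$Wq$W))
  q <- tg_lin(q_in, p$Wq$W, p$Wq$b)
  k <- tg_lin(kv_in, p$Wk$W, p$Wk$b)
  v <- tg_lin(kv_in, p$Wv$W, p$Wv$b)
  s <- tg_scale(tg_mm_tb(q, k), 1 / sqrt(d))
  if (!is.null(bias)) s <- tg_add(s, bias)
  a <- tg_softmax_rows(s)
  tg_lin(tg_mm(a, v), p$Wo$W, p$Wo$b)
}

init_attention <- function(dq, dkv) {
  list(Wq = init_linear(dq, dq), Wk = init_linear(dkv, dq),
       Wv = init_linear(dkv, dq), Wo = init_linear(dq, dq))
}

# Squared distance field between predicted normalized centers (K x 3, a
# graph node) and fixed normalized coordinates (V x 3).
tg_center_penalty <- function(centers, pn) {
  cv <- nval(centers)
  D <- outer(rowSums(cv^2), rep(1, nrow(pn))) +
    outer(rep(1, nrow(cv)), rowSums(pn^2)) - 2 * tcrossprod(cv, pn)
  D[D < 0] <- 0
  tg_node(D, function(g) {
    tg_acc(centers, 2 * (cv * rowSums(g) - g %*% pn))
  })
}
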