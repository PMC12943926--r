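# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Nodes are environments holding a value, an accumulated gradient and a
# backward closure; every op appends its node to a tape, and tg_backward()
# walks the tape in reverse. Only what this network needs is implemented:
# matrix products, broadcasting adds/multiplies, ReLU/sigmoid/softmax,
# batch/layer norm, a fused sparse-convolution op (gather - matmul -
# scatter with a precomputed kernel map) and fused segmentation losses.

.tg <- new.env(parent = emptyenv())
.tg$tape <- list(); .tg$n <- 0L; .tg$active <- FALSE

tg_begin <- function() {
  .tg$tape <- vector("list", 1024L); .tg$n <- 0L; .tg$active <- TRUE
  invisible(NULL)
}

tg_clear <- function() {
  .tg$tape <- list(); .tg$n <- 0L; .tg$active <- FALSE
  invisible(NULL)
}

tg_node <- function(val, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val; nd$grad <- NULL; nd$bw <- bw
  if (.tg$active) {
    n <- .tg$n + 1L
    if (n > length(.tg$tape)) length(.tg$tape) <- 2L * length(.tg$tape)
    .tg$tape[[n]] <- nd; .tg$n <- n
  }
  nd
}

tg_leaf <- function(val) tg_node(val)
is_node <- function(x) is.environment(x)
nval <- function(x) if (is_node(x)) x$val else x

tg_acc <- function(nd, g) {
  if (is_node(nd)) nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

tg_backward <- function(loss) {
  loss$grad <- 1
  n <- .tg$n
  if (n > 0L) for (i in n:1L) {
    nd <- .tg$tape[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

# ---- elementary ops ---------------------------------------------------------

tg_mm <- function(a, b) {                      # a %*% b
  av <- nval(a); bv <- nval(b)
  tg_node(av %*% bv, function(g) {
    tg_acc(a, tcrossprod(g, bv))
    tg_acc(b, crossprod(av, g))
  })
}

tg_mm_tb <- function(a, b) {                   # a %*% t(b)
  av <- nval(a); bv <- nval(b)
  tg_node(tcrossprod(av, bv), function(g) {
    tg_acc(a, g %*% bv)
    tg_acc(b, crossprod(g, av))
  })
}

tg_add <- function(a, b) tg_node(nval(a) + nval(b), function(g) {
  tg_acc(a, g); tg_acc(b, g)
})

tg_sub <- function(a, b) tg_node(nval(a) - nval(b), function(g) {
  tg_acc(a, g); tg_acc(b, -g)
})

tg_scale <- function(a, s) tg_node(nval(a) * s, function(g) tg_acc(a, g * s))

tg_mul <- function(a, b) {                     # elementwise, same shape
  av <- nval(a); bv <- nval(b)
  tg_node(av * bv, function(g) { tg_acc(a, g * bv); tg_acc(b, g * av) })
}

tg_add_rv <- function(a, rv) {                 # broadcast a row vector over rows
  rvv <- as.vector(nval(rv))
  av <- nval(a)
  tg_node(av + rep(rvv, each = nrow(av)), function(g) {
    tg_acc(a, g)
    tg_acc(rv, matrix(colSums(g), 1L))
  })
}

tg_mul_rv <- function(a, rv) {                 # scale columns by a row vector
  rvv <- as.vector(nval(rv))
  av <- nval(a)
  sc <- rep(rvv, each = nrow(av))
  tg_node(av * sc, function(g) {
    tg_acc(a, g * sc)
    tg_acc(rv, matrix(colSums(g * av), 1L))
  })
}

tg_relu <- function(a) {
  av <- nval(a)
  pos <- av > 0
  tg_node(av * pos, function(g) tg_acc(a, g * pos))
}

tg_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-nval(a)))
  tg_node(s, function(g) tg_acc(a, g * s * (1 - s)))
}

tg_softmax_rows <- function(a) {
  av <- nval(a)
  m <- av - apply(av, 1L, max)
  e <- exp(m)
  s <- e / rowSums(e)
  tg_node(s, function(g) tg_acc(a, s * (g - rowSums(g * s))))
}

tg_sum <- function(a) {
  av <- nval(a)
  tg_node(sum(av), function(g) tg_acc(a, array(g, dim(av))))
}

tg_colmeans <- function(a) {                   # N x C -> 1 x C mean
  av <- nval(a)
  n <- nrow(av)
  tg_node(matrix(colMeans(av), 1L), function(g)
    tg_acc(a, matrix(rep(as.vector(g) / n, each = n), n)))
}

tg_lin <- function(x, W, b = NULL) {
  y <- tg_mm(x, W)
  if (is.null(b)) y else tg_add_rv(y, b)
}

# ---- normalization ----------------------------------------------------------

# Normalization over rows (the occupied voxels of the scene), per channel.
# Statistics always come from the scene being processed — scene-level
# normalization, which keeps training and inference consistent for sparse
# scenes whose statistics differ block to block. `state` carries running
# averages (updated only when training) used as a fallback for degenerate
# single-voxel inputs.
tg_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  xv <- nval(x)
  n <- nrow(xv)
  gv <- as.vector(nval(gamma)); bv <- as.vector(nval(beta))
  if (n > 1L) {
    mu <- colMeans(xv)
    xc <- xv - rep(mu, each = n)
    va <- colMeans(xc * xc)
    if (training && !is.null(state)) {
      if (is.null(state$mean)) { state$mean <- mu; state$var <- va }
      else {
        state$mean <- (1 - momentum) * state$mean + momentum * mu
        state$var <- (1 - momentum) * state$var + momentum * va
      }
    }
  } else {
    mu <- if (!is.null(state$mean)) state$mean else colMeans(xv)
    va <- if (!is.null(state$var)) state$var else rep(1, ncol(xv))
    xc <- xv - rep(mu, each = n)
  }
  sd_ <- sqrt(va + eps)
  xhat <- xc / rep(sd_, each = n)
  y <- xhat * rep(gv, each = n) + rep(bv, each = n)
  use_batch <- n > 1L
  tg_node(y, function(g) {
    tg_acc(gamma, matrix(colSums(g * xhat), 1L))
    tg_acc(beta, matrix(colSums(g), 1L))
    h <- g * rep(gv, each = n)
    if (use_batch) {
      dx <- (h - rep(colMeans(h), each = n) -
               xhat * rep(colMeans(h * xhat), each = n)) / rep(sd_, each = n)
    } else {
      dx <- h / rep(sd_, each = n)
    }
    tg_acc(x, dx)
  })
}

# Layer normalization per row.
tg_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- nval(x)
  d <- ncol(xv)
  gv <- as.vector(nval(gamma)); bv <- as.vector(nval(beta))
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  sd_ <- sqrt(va + eps)
  xhat <- xc / sd_
  y <- xhat * rep(gv, each = nrow(xv)) + rep(bv, each = nrow(xv))
  tg_node(y, function(g) {
    tg_acc(gamma, matrix(colSums(g * xhat), 1L))
    tg_acc(beta, matrix(colSums(g), 1L))
    h <- g * rep(gv, each = nrow(xv))
    dx <- (h - rowMeans(h) - xhat * rowMeans(h * xhat)) / sd_
    tg_acc(x, dx)
  })
}

# ---- sparse convolution -----------------------------------------------------

# Fused sparse convolution. `kmap` is an integer matrix (N_out x K): kmap[n,o]
# is the input row feeding output n through kernel offset o, or the padding
# row (n_in + 1) when that neighbour is unoccupied. W is (K*C_in) x C_out with
# rows ordered offset-fastest (row = o + (c_in - 1) * K), which lets the
# gathered (N_out * K) x C_in matrix be reinterpreted as the im2col matrix
# with a plain dim<- and no transpose.
tg_sparse_conv <- function(x, W, kmap) {
  xv <- nval(x); Wv <- nval(W)
  n_in <- nrow(xv); cin <- ncol(xv)
  K <- ncol(kmap); n_out <- nrow(kmap)
  pad <- rbind(xv, 0)
  Xcat <- pad[as.vector(kmap), , drop = FALSE]     # (n_out*K) x cin, n fastest
  dim(Xcat) <- c(n_out, K * cin)                   # column = o + (c-1)*K
  y <- Xcat %*% Wv
  tg_node(y, function(g) {
    tg_acc(W, crossprod(Xcat, g))
    dXcat <- tcrossprod(g, Wv)                     # n_out x (K*cin)
    dim(dXcat) <- c(n_out * K, cin)
    rs <- rowsum(dXcat, group = as.vector(kmap), reorder = TRUE)
    rows <- as.integer(rownames(rs))
    dpad <- matrix(0, n_in + 1L, cin)
    dpad[rows, ] <- rs
    tg_acc(x, dpad[seq_len(n_in), , drop = FALSE])
  })
}

# ---- fused losses -----------------------------------------------------------

# Weighted cross-entropy over rows of logits. targets in 1..C; weights per
# class; loss = sum_k w[t_k] * (-log p[k, t_k]) / sum_k w[t_k].
tg_cross_entropy <- function(logits, targets, class_weights) {
  lv <- nval(logits)
  n <- nrow(lv)
  m <- lv - apply(lv, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  w <- class_weights[targets]
  wsum <- sum(w)
  ll <- -log(pmax(p[cbind(seq_len(n), targets)], 1e-12))
  tg_node(sum(w * ll) / wsum, function(g) {
    oh <- matrix(0, n, ncol(lv))
    oh[cbind(seq_len(n), targets)] <- 1
    tg_acc(logits, g * (p - oh) * (w / wsum))
  })
}

# Binary cross-entropy with logits, mean over all elements.
tg_bce_logits <- function(scores, targets) {
  sv <- nval(scores)
  n <- length(sv)
  sp <- pmax(sv, 0) + log1p(exp(-abs(sv)))       # softplus(s), stable
  loss <- sum(sp - sv * targets) / n
  tg_node(loss, function(g) {
    p <- 1 / (1 + exp(-sv))
    tg_acc(scores, g * (p - targets) / n)
  })
}

# Soft Dice loss on sigmoid(scores), mean over rows (one row per instance).
tg_dice_loss <- function(scores, targets, smooth = 1) {
  sv <- nval(scores)
  p <- 1 / (1 + exp(-sv))
  K <- nrow(sv)
  A <- rowSums(p * targets)
  B <- rowSums(p) + rowSums(targets)
  dice <- (2 * A + smooth) / (B + smooth)
  tg_node(mean(1 - dice), function(g) {
    dLdp <- -(2 * targets * (B + smooth) - (2 * A + smooth)) / (B + smooth)^2
    tg_acc(scores, g * dLdp * p * (1 - p) / K)
  })
}

# Mean squared error against a constant target.
tg_mse <- function(a, target) {
  av <- nval(a)
  n <- length(av)
  tg_node(sum((av - target)^2) / n, function(g)
    tg_acc(a, g * 2 * (av - target) / n))
}

# ---- parameter-tree helpers -------------------------------------------------

# Recursively wrap a nested list of matrices as autograd leaves.
wrap_params <- function(p) {
  if (is.list(p)) lapply(p, wrap_params) else tg_leaf(p)
}

# Extract gradients (zeros where a parameter received none).
grad_tree <- function(w) {
  if (is.list(w)) lapply(w, grad_tree)
  else if (is.null(w$grad)) array(0, dim(w$val)) else w$grad
}

# Elementwise map over parallel nested lists of arrays.
map_tree <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- vector("list", length(trees[[1]]))
    names(out) <- names(trees[[1]])
    for (i in seq_along(out))
      out[[i]] <- do.call(map_tree, c(list(f), lapply(trees, `[[`, i)))
    out
  } else do.call(f, trees)
}

tree_leaves <- function(p) {
  if (!is.list(p)) return(list(p))
  do.call(c, lapply(p, tree_leaves))
}
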