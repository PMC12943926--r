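#' Squared distance penalty to predicted instance centers
#'
#' Coordinates are min-max normalized into the unit cube per block and
#' compared against each query's predicted normalized center:
#' `D[k, i] = || (P_i - P_min) / (P_max - P_min) - C_k ||_2^2`.
#'
#' @param coords V x 3 coordinates in metres.
#' @param centers K x 3 predicted centers in `[0, 1]^3`.
#' @param p_min,p_max length-3 min / max corners of the block (strictly
#'   `p_max > p_min` per axis).
#' @return K x V matrix of squared normalized distances.
#' @export
distance_penalty <- function(coords, centers, p_min, p_max) {
  coords <- as.matrix(coords); centers <- as.matrix(centers)
  if (any(p_max <= p_min)) stop("degenerate block extent: p_max must exceed p_min per axis")
  pn <- sweep(sweep(coords, 2L, p_min), 2L, p_max - p_min, "/")
  outer(rowSums(centers^2), rep(1, nrow(pn))) +
    outer(rep(1, nrow(centers)), rowSums(pn^2)) - 2 * tcrossprod(centers, pn)
}

#' Proximity-weighted mask scores
#'
#' The joint score of query k and voxel i combines semantic similarity with
#' a distance penalty: `S[k, i] = <Q_k, F_i> - lambda * D[k, i]`. With
#' `lambda = 0` this collapses to the plain query-feature dot product.
#'
#' @param Q K x D query (mask-embedding) matrix.
#' @param F_feat V x D voxel feature matrix.
#' @param D K x V distance penalty from [distance_penalty()].
#' @param lambda balancing coefficient (>= 0) of the geometric term.
#' @return a `score_field`: list with `S`, `semantic_term`, `penalty_term`,
#'   `lambda`.
#' @export
mask_scores <- function(Q, F_feat, D, lambda = 1) {
  Q <- as.matrix(Q); F_feat <- as.matrix(F_feat)
  if (ncol(Q) != ncol(F_feat)) stop("query and feature embedding dims differ")
  if (lambda < 0) stop("lambda must be >= 0")
  sem <- tcrossprod(Q, F_feat)
  if (!all(dim(D) == dim(sem))) stop("D must be K x V")
  structure(list(S = sem - lambda * D, semantic_term = sem,
                 penalty_term = D, lambda = lambda), class = "score_field")
}

#' Predict normalized instance centers from queries
#'
#' A two-layer MLP with ReLU hidden activation and sigmoid output, so centers
#' always lie in the unit cube.
#'
#' @param Q K x Dq query matrix.
#' @param head list with `W1`, `b1` (Dq -> hidden) and `W2`, `b2`
#'   (hidden -> 3).
#' @return K x 3 matrix of centers in `[0, 1]^3`.
#' @export
predict_centers <- function(Q, head) {
  h <- pmax(sweep(as.matrix(Q) %*% head$W1, 2L, -as.vector(head$b1)), 0)
  1 / (1 + exp(-sweep(h %*% head$W2, 2L, -as.vector(head$b2))))
}

# Additive attention bias from a binary K x V mask: masked-out voxels get
# -1e9; a query with an empty mask falls back to unmasked attention.
mask_bias <- function(prev_mask) {
  bias <- (!prev_mask) * -1e9
  empty <- rowSums(prev_mask) == 0
  bias[empty, ] <- 0
  bias
}

init_refine_layer <- function(dq, dkv, ffn_mult = 4L) {
  list(self = init_attention(dq, dq),
       cross = init_attention(dq, dkv),
       ln1 = init_bn(dq), ln2 = init_bn(dq), ln3 = init_bn(dq),
       ffn = list(W1 = init_mat(dq, ffn_mult * dq, sqrt(2 / dq)),
                  b1 = matrix(0, 1L, ffn_mult * dq),
                  W2 = init_mat(ffn_mult * dq, dq, sqrt(1 / (ffn_mult * dq))),
                  b2 = matrix(0, 1L, dq)))
}

# Query refinement (autograd): pre-norm self-attention over queries, masked
# cross-attention to voxel features, feed-forward; residual connections
# around each sub-layer.
refine_graph <- function(q, feats, prev_mask, pp) {
  qn <- tg_layernorm(q, pp$ln1$gamma, pp$ln1$beta)
  q <- tg_add(q, attention(qn, qn, pp$self))
  qn <- tg_layernorm(q, pp$ln2$gamma, pp$ln2$beta)
  q <- tg_add(q, attention(qn, feats, pp$cross, bias = mask_bias(prev_mask)))
  qn <- tg_layernorm(q, pp$ln3$gamma, pp$ln3$beta)
  ff <- tg_lin(tg_relu(tg_lin(qn, pp$ffn$W1, pp$ffn$b1)), pp$ffn$W2, pp$ffn$b2)
  tg_add(q, ff)
}

#' One query-refinement layer (matrix interface)
#'
#' Self-attention among the K instance queries, masked cross-attention to
#' the voxel features (attention logits to voxel i are suppressed for query
#' k when `prev_mask[k, i]` is 0, falling back to unmasked attention when a
#' query's mask is empty), then a feed-forward network; residuals and layer
#' normalization around each sub-layer (pre-norm).
#'
#' @param queries K x Dq query matrix.
#' @param features V x Df voxel feature matrix.
#' @param prev_mask K x V binary (logical or 0/1) mask from the previous
#'   layer; all-ones for the first layer.
#' @param weights a layer weight list from the model
#'   (`model$params$decoder$layers[[l]]`) or `init_refine_layer`.
#' @return the updated K x Dq query matrix.
#' @export
refine_queries <- function(queries, features, prev_mask, weights) {
  pp <- wrap_params(weights)
  nval(refine_graph(tg_leaf(as.matrix(queries)), tg_leaf(as.matrix(features)),
                 prev_mask != 0, pp))
}

init_decoder <- function(config) {
  dq <- config$query_dim
  ce <- config$embed_dim
  cf <- config$feature_dim
  list(query_embed = init_mat(config$n_queries, dq, 0.1),
       feat_proj = init_linear(cf, ce),
       layers = lapply(seq_len(config$n_layers), function(l)
         init_refine_layer(dq, cf)),
       class_head = init_linear(dq, 3L, 0.01),
       mask_embed = init_linear(dq, ce, 0.05),
       center_head = list(W1 = init_mat(dq, dq, sqrt(2 / dq)),
                          b1 = matrix(0, 1L, dq),
                          W2 = init_mat(dq, 3L, 0.01),
                          b2 = matrix(0, 1L, 3L)))
}

# Full decoder forward (autograd). `f0` is the fine-level feature node,
# `pn` the min-max-normalized voxel coordinates (V x 3 constant), `lambda`
# the penalty weight. Returns per-layer nodes for deep supervision.
decode_graph <- function(pp, f0, pn, config) {
  K <- config$n_queries
  V <- nrow(pn)
  fp <- tg_lin(f0, pp$feat_proj$W, pp$feat_proj$b)
  q <- pp$query_embed
  prev_mask <- matrix(TRUE, K, V)
  layers <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    q <- refine_graph(q, f0, prev_mask, pp$layers[[l]])
    centers <- tg_sigmoid(tg_lin(tg_relu(tg_lin(q, pp$center_head$W1,
                                                pp$center_head$b1)),
                                 pp$center_head$W2, pp$center_head$b2))
    emb <- tg_lin(q, pp$mask_embed$W, pp$mask_embed$b)
    logits <- tg_lin(q, pp$class_head$W, pp$class_head$b)
    sem <- tg_mm_tb(emb, fp)
    pen <- tg_center_penalty(centers, pn)
    S <- tg_sub(sem, tg_scale(pen, config$lambda))
    prev_mask <- nval(S) > 0
    layers[[l]] <- list(queries = q, centers = centers, logits = logits,
                        scores = S, semantic_term = sem, penalty_term = pen)
  }
  layers
}

#' Decode a feature pyramid into per-layer query sets and score fields
#'
#' Alternates query refinement and proximity-weighted mask scoring over
#' cascaded layers; each layer's binarized masks bias the next layer's
#' cross-attention, and every layer's predictions are retained for deep
#' supervision.
#'
#' @param model a model from [init_model()].
#' @param grid the input `voxel_grid`.
#' @param pyramid optional precomputed [backbone_forward()] output.
#' @param training batch-norm mode flag.
#' @return list of layers; each has `queries` (K x Dq), `centers` (K x 3),
#'   `class_logits` (K x 3), and a `score_field` with `S`, `semantic_term`,
#'   `penalty_term` (all K x V).
#' @export
decode_instances <- function(model, grid, pyramid = NULL, training = FALSE) {
  fw <- forward_graph(model, grid, training = training)
  lapply(fw$layers, function(l)
    list(queries = nval(l$queries), centers = nval(l$centers),
         class_logits = nval(l$logits),
         score_field = structure(list(S = nval(l$scores),
                                      semantic_term = nval(l$semantic_term),
                                      penalty_term = nval(l$penalty_term),
                                      lambda = model$config$decoder$lambda),
                                 class = "score_field")))
}

# Shared forward used by training, prediction and the matrix interfaces:
# voxel grid -> backbone pyramid -> decoder layers. Returns nodes. A
# pre-wrapped parameter tree `pp` may be passed so several blocks in one
# minibatch share leaves (gradients then accumulate across blocks).
forward_graph <- function(model, grid, plan = NULL, training = FALSE, pp = NULL) {
  if (is.null(plan)) plan <- build_conv_plan(grid)
  if (is.null(pp)) pp <- wrap_params(model$params)
  py <- backbone_graph(pp$backbone, model$state$backbone, plan,
                       model$config$backbone, grid$features, training)
  centers_m <- voxel_centers(grid)
  ext <- block_extent(grid)
  pn <- sweep(sweep(centers_m, 2L, ext$p_min), 2L, ext$p_max - ext$p_min, "/")
  dcfg <- model$config$decoder
  dcfg$feature_dim <- ncol(nval(py$F0))
  layers <- decode_graph(pp$decoder, py$F0, pn, dcfg)
  list(pyramid = py, layers = layers, params = pp, plan = plan, pn = pn)
}

# Block extent used for coordinate normalization; guards degenerate axes.
block_extent <- function(grid) {
  cm <- voxel_centers(grid)
  p_min <- col_mins(cm); p_max <- col_maxs(cm)
  deg <- p_max - p_min < 1e-9
  p_max[deg] <- p_min[deg] + 1
  list(p_min = p_min, p_max = p_max)
}

#' Turn the final score field into discrete instances
#'
#' Voxel masks are `sigmoid(S) > 0.5`; confidence is the query's class
#' probability times its mean in-mask probability. Queries whose best class
#' is no-object, instances under `score_threshold` or smaller than
#' `min_points` are discarded; overlapping claims on a point resolve to the
#' highest-confidence instance (ties by higher raw score, then query index).
#' Point semantic labels follow the owning instance and default to ground.
#'
#' @param score_field final-layer `score_field` (or its `S` matrix).
#' @param class_logits K x 3 class logits (ground, tree, no-object).
#' @param grid the input `voxel_grid`.
#' @param score_threshold minimum confidence to keep an instance.
#' @param min_points minimum point count to keep an instance.
#' @return an `instance_prediction`: point-level `masks` (list of point
#'   index vectors), `class`, `confidence`, `point_semantic`,
#'   `point_instance` (-1 where unclaimed, ground otherwise owns id 0).
#' @export
postprocess_instances <- function(score_field, class_logits, grid,
                                  score_threshold = 0.35, min_points = 30L) {
  S <- if (inherits(score_field, "score_field")) score_field$S else score_field
  K <- nrow(S)
  probs <- exp(class_logits - apply(class_logits, 1L, max))
  probs <- probs / rowSums(probs)
  cls <- max.col(probs, ties.method = "first")
  msk_p <- 1 / (1 + exp(-S))
  n <- grid$n_points
  keep <- logical(K); conf <- numeric(K)
  vox_masks <- vector("list", K)
  for (k in seq_len(K)) {
    if (cls[k] == 3L) next  # no-object
    vm <- which(msk_p[k, ] > 0.5)
    if (!length(vm)) next
    conf[k] <- probs[k, cls[k]] * mean(msk_p[k, vm])
    if (conf[k] < score_threshold) next
    vox_masks[[k]] <- vm
    keep[k] <- TRUE
  }
  # overlap resolution at point level: best confidence, then raw score, then index
  pt_owner <- rep(0L, n)
  best_conf <- rep(-Inf, n); best_s <- rep(-Inf, n)
  for (k in which(keep)) {
    pts <- which(grid$point_to_voxel %in% vox_masks[[k]])
    s_pt <- S[k, grid$point_to_voxel[pts]]
    better <- conf[k] > best_conf[pts] |
      (conf[k] == best_conf[pts] & s_pt > best_s[pts])
    pts <- pts[better]; s_pt <- s_pt[better]
    pt_owner[pts] <- k
    best_conf[pts] <- conf[k]; best_s[pts] <- s_pt
  }
  kept <- integer(0)
  masks <- list(); out_class <- integer(0); out_conf <- numeric(0)
  for (k in which(keep)) {
    pts <- which(pt_owner == k)
    if (length(pts) < min_points) { pt_owner[pts] <- 0L; next }
    kept <- c(kept, k)
    masks[[length(masks) + 1L]] <- pts
    out_class <- c(out_class, cls[k] - 1L)  # 0 ground, 1 tree
    out_conf <- c(out_conf, conf[k])
  }
  point_sem <- rep(0L, n)       # unclaimed points default to ground
  point_inst <- rep(-1L, n)
  next_tree <- 1L
  for (j in seq_along(masks)) {
    id <- if (out_class[j] == 0L) 0L else { v <- next_tree; next_tree <- next_tree + 1L; v }
    point_inst[masks[[j]]] <- id
    point_sem[masks[[j]]] <- out_class[j]
  }
  structure(list(masks = masks, class = out_class, confidence = out_conf,
                 point_semantic = point_sem, point_instance = point_inst,
                 query_index = kept),
            class = "instance_prediction")
}
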