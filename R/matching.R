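# Linear sum assignment and the set-prediction matching used in training.

#' Minimal-cost one-to-one assignment (rectangular Hungarian)
#'
#' Jonker-Volgenant-style shortest augmenting path solver with potentials,
#' O(n^3). Rows beyond the number of columns stay unassigned.
#'
#' @param cost numeric cost matrix (n rows >= m columns required here; the
#'   wrapper pads as needed).
#' @return integer vector of length nrow(cost): assigned column per row, or
#'   `NA` for unassigned rows.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (m == 0L) return(rep(NA_integer_, n))
  if (m > n) stop("solve_assignment needs nrow >= ncol")
  # column-wise shortest augmenting paths over rows
  INF <- .Machine$double.xmax / 4
  u <- numeric(m + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)      # p[row] = column assigned to row (0 = none)
  way <- integer(n + 1L)
  for (col in seq_len(m)) {
    p[n + 1L] <- col
    j0 <- n + 1L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- cost[j, i0] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  out <- rep(NA_integer_, n)
  for (j in seq_len(n)) if (p[j] != 0L) out[j] <- p[j]
  out
}

#' Match instance queries to ground-truth instances
#'
#' Set-prediction matching: the minimal-cost one-to-one assignment between
#' the K queries and the G ground-truth instances under
#' `cost = w_cls * (-log p_class) + w_bce * BCE + w_dice * Dice + w_ctr *
#' ||C_k - c_g||^2`, computed on voxel-level masks. Unmatched queries are
#' labelled no-object.
#'
#' @param class_logits K x 3 logits (ground, tree, no-object).
#' @param scores K x V mask score matrix.
#' @param centers K x 3 predicted normalized centers.
#' @param gt ground truth: list with `masks` (G x V binary matrix), `class`
#'   (length G, 0 ground / 1 tree) and `centers` (G x 3 normalized).
#' @param weights named list of cost weights (`cls`, `bce`, `dice`, `ctr`).
#' @return a `match_result`: `pairs` (data.frame query/gt), `unmatched`
#'   (query indices assigned no-object), `cost` (total assignment cost).
#' @export
hungarian_match <- function(class_logits, scores, centers, gt,
                            weights = list(cls = 2, bce = 5, dice = 5, ctr = 1)) {
  K <- nrow(class_logits)
  G <- if (is.null(gt$masks)) 0L else nrow(gt$masks)
  if (G == 0L)
    return(structure(list(pairs = data.frame(query = integer(0), gt = integer(0)),
                          unmatched = seq_len(K), cost = 0),
                     class = "match_result"))
  if (K < G) stop("need at least as many queries as ground-truth instances")
  C <- .match_cost(class_logits, scores, centers, gt, weights)
  assign <- solve_assignment(C)
  pairs <- data.frame(query = which(!is.na(assign)),
                      gt = assign[!is.na(assign)])
  structure(list(pairs = pairs, unmatched = which(is.na(assign)),
                 cost = sum(C[cbind(pairs$query, pairs$gt)])),
            class = "match_result")
}

.match_cost <- function(class_logits, scores, centers, gt, weights) {
  K <- nrow(class_logits); G <- nrow(gt$masks); V <- ncol(scores)
  p <- exp(class_logits - apply(class_logits, 1L, max))
  p <- p / rowSums(p)
  cost_cls <- -log(pmax(p[, gt$class + 1L, drop = FALSE], 1e-9))  # K x G
  Tm <- gt$masks
  sp <- pmax(scores, 0) + log1p(exp(-abs(scores)))
  cost_bce <- (outer(rowSums(sp), rep(1, G)) - scores %*% t(Tm)) / V
  pm <- 1 / (1 + exp(-scores))
  inter <- pm %*% t(Tm)
  cost_dice <- 1 - (2 * inter + 1) /
    (outer(rowSums(pm), rep(1, G)) + outer(rep(1, K), rowSums(Tm)) + 1)
  cost_ctr <- outer(rowSums(centers^2), rep(1, G)) +
    outer(rep(1, K), rowSums(gt$centers^2)) - 2 * tcrossprod(centers, gt$centers)
  weights$cls * cost_cls + weights$bce * cost_bce +
    weights$dice * cost_dice + weights$ctr * cost_ctr
}
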