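# Self-attention and collaborative-attention blocks.
#
# A feature map is a matrix with N spatial positions in rows and C channels
# in columns. Queries/keys are linear projections to d_k dimensions
# (equivalent to 1x1x1 convolutions), values stay C-dimensional. Scores are
# scaled dot products; the attention matrix is the row-softmax of the N x N
# score matrix, so every row sums to 1 and coefficients lie in (0, 1). The
# attended aggregate re-enters through a residual gate:
#   y = x + gamma * (A %*% V),  gamma a learnable scalar (init 0, so the
# block is an exact identity at initialization).

.row_softmax <- function(s) {
  m <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - m)
  e / rowSums(e)
}

#' Weights for an attention block
#'
#' @param channels Input channels C.
#' @param key_dim Query/key projection dimension d_k.
#' @param gamma Initial residual gate.
#' @param init `"random"` (small normal) or `"zero"`.
#' @return List with `wq` (C x d_k), `wk` (C x d_k), `wv` (C x C),
#'   `gamma` (scalar).
#' @export
attention_weights <- function(channels, key_dim = 8L, gamma = 0,
                              init = c("random", "zero")) {
  init <- match.arg(init)
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc) else .init_mat(nr, nc, nr, "small")
  }
  list(
    wq = mk(channels, key_dim),
    wk = mk(channels, key_dim),
    wv = mk(channels, channels),
    gamma = gamma
  )
}

#' Self-attention block
#'
#' Applies query/key/value projections to one phase's feature map, forms
#' the row-stochastic N x N attention matrix from scaled dot-product
#' scores, aggregates the values, and adds the result back through the
#' learnable residual gate `gamma`.
#'
#' @param x Feature map, N x C matrix (rows = flattened D*H*W spatial
#'   positions of the 3D map, columns = channels).
#' @param weights An [attention_weights()] list.
#' @return List with `features` (N x C, `x + gamma * A V`) and
#'   `attention` (N x N matrix; every row sums to 1).
#' @export
self_attention <- function(x, weights) {
  if (!all(is.finite(x))) stop("non-finite values in attention input")
  x <- as.matrix(x)
  dk <- ncol(weights$wq)
  q <- x %*% weights$wq
  k <- x %*% weights$wk
  v <- x %*% weights$wv
  a <- .row_softmax(tcrossprod(q, k) / sqrt(dk))
  list(features = x + weights$gamma * (a %*% v), attention = a)
}

#' Collaborative-attention block
#'
#' Cross-phase attention: queries come from the phase's own feature map,
#' keys and values from each of the other phases' (self-attended) maps;
#' the per-pair attended aggregates are averaged and added back through
#' the residual gate. The reported attention matrix is the mean of the
#' pair matrices, which is again row-stochastic.
#'
#' @param own N x C feature map of the querying phase.
#' @param others List of N x C feature maps from the other phases.
#' @param weights An [attention_weights()] list (the querying phase's
#'   collaborative projections, applied to the partners' maps for keys and
#'   values).
#' @return List with `features` (N x C) and `attention` (N x N mean pair
#'   matrix).
#' @export
collaborative_attention <- function(own, others, weights) {
  stopifnot(length(others) >= 1)
  own <- as.matrix(own)
  for (o in others) {
    if (!all(dim(as.matrix(o)) == dim(own))) {
      stop("phase feature maps must share one shape")
    }
  }
  if (!all(is.finite(own))) stop("non-finite values in attention input")
  dk <- ncol(weights$wq)
  q <- own %*% weights$wq
  h <- 0
  a_mean <- 0
  for (o in others) {
    o <- as.matrix(o)
    k <- o %*% weights$wk
    v <- o %*% weights$wv
    a <- .row_softmax(tcrossprod(q, k) / sqrt(dk))
    h <- h + a %*% v
    a_mean <- a_mean + a
  }
  m <- length(others)
  list(
    features = own + weights$gamma * (h / m),
    attention = a_mean / m
  )
}

# ---- batched forward/backward used inside the network ----
# x: array (N, C, B). The scaled-dot-product core (queries from xq, keys
# and values from xkv) runs in C++ (src/attention.cpp); caches Q, K, V, A
# and the aggregate H for the backward pass.

.attn_pair_forward <- function(xq, xkv, w) {
  d <- dim(xq)
  out <- .attn_fwd_cpp(xq, xkv, d[1], d[2], d[3], w$wq, w$wk, w$wv)
  dim(out$h) <- d
  dim(out$a) <- c(d[1], d[1], d[3])
  out
}

.attn_pair_backward <- function(dh, xq, xkv, w, cache) {
  d <- dim(xq)
  out <- .attn_bwd_cpp(dh, xq, xkv, d[1], d[2], d[3], w$wq, w$wk, w$wv,
    cache$a, cache$q, cache$k, cache$v)
  dim(out$dxq) <- d
  dim(out$dxkv) <- d
  out
}

.self_attn_forward_batch <- function(x, w) {
  cc <- .attn_pair_forward(x, x, w)
  list(y = x + w$gamma * cc$h, attn = cc$a, cache = cc)
}

.self_attn_backward_batch <- function(dy, x, w, fwd) {
  dgamma <- sum(dy * fwd$cache$h)
  g <- .attn_pair_backward(w$gamma * dy, x, x, w, fwd$cache)
  list(
    dx = dy + g$dxq + g$dxkv, # residual path plus attention paths
    grads = list(wq = g$dwq, wk = g$dwk, wv = g$dwv, gamma = dgamma)
  )
}

# xs: list per phase of arrays (N, C, B); ws: list per phase of attention
# weights. Phase i attends with its own projections over every other
# phase's map; pair outputs are averaged.
.coll_attn_forward_batch <- function(xs, ws) {
  np <- length(xs)
  ys <- vector("list", np)
  attn <- vector("list", np)
  caches <- vector("list", np)
  for (i in seq_len(np)) {
    pair <- vector("list", np)
    h <- 0; am <- 0
    for (j in seq_len(np)) {
      if (j == i) next
      cc <- .attn_pair_forward(xs[[i]], xs[[j]], ws[[i]])
      pair[[j]] <- cc
      h <- h + cc$h
      am <- am + cc$a
    }
    m <- np - 1L
    hmean <- h / m
    ys[[i]] <- xs[[i]] + ws[[i]]$gamma * hmean
    attn[[i]] <- am / m
    caches[[i]] <- list(pair = pair, hmean = hmean)
  }
  list(ys = ys, attn = attn, caches = caches)
}

.coll_attn_backward_batch <- function(dys, xs, ws, fwd) {
  np <- length(xs)
  dxs <- dys # residual path contributes dy to the own phase
  grads <- vector("list", np)
  for (i in seq_len(np)) {
    m <- np - 1L
    cc <- fwd$caches[[i]]
    dgamma <- sum(dys[[i]] * cc$hmean)
    dh_each <- (ws[[i]]$gamma / m) * dys[[i]]
    gw <- list(wq = 0, wk = 0, wv = 0, gamma = dgamma)
    for (j in seq_len(np)) {
      if (j == i) next
      g <- .attn_pair_backward(dh_each, xs[[i]], xs[[j]], ws[[i]], cc$pair[[j]])
      dxs[[i]] <- dxs[[i]] + g$dxq
      dxs[[j]] <- dxs[[j]] + g$dxkv
      gw$wq <- gw$wq + g$dwq
      gw$wk <- gw$wk + g$dwk
      gw$wv <- gw$wv + g$dwv
    }
    grads[[i]] <- gw
  }
  list(dxs = dxs, grads = grads)
}
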