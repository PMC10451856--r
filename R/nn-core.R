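# Minimal feed-forward engine for 3D volumes.
#
# Activations are arrays of shape (N, C, B): N flattened spatial positions
# (fastest), C channels, B batch samples. All heavy lifting is done through
# BLAS matrix products; 3D convolution uses im2col with gather/scatter
# index tables precomputed per (input shape, channels, batch size).

# ---- 3D convolution (3x3x3 kernel, stride 1, zero padding 1) ----
# Implemented in C++ (src/conv3d.cpp); these wrappers keep the array
# bookkeeping in R. Backward recomputes the im2col buffer from the cached
# layer input, which is cheaper than retaining it.

.conv3d_forward <- function(x, w, b, shape, relu = FALSE) {
  d <- dim(x)
  out <- .conv3d_fwd_cpp(x, as.integer(shape), d[2], d[3], w, b, relu)
  dim(out$y) <- c(d[1], nrow(w), d[3])
  out
}

# dy: gradient at the (post-ReLU) output; mask from the fused forward.
.conv3d_backward <- function(x, dy, w, shape, mask = NULL, need_dx = TRUE) {
  d <- dim(x)
  out <- .conv3d_bwd_cpp(x, dy, as.integer(shape), d[2], d[3], w, need_dx,
    if (is.null(mask)) logical(0) else mask)
  if (need_dx) dim(out$dx) <- d else out$dx <- NULL
  out
}

# ---- 2x2x2 max pooling (C++; argmax indices kept for backward) ----

.pool_forward <- function(x, shape) {
  d <- dim(x)
  out <- .pool_fwd_cpp(x, as.integer(shape), d[2] * d[3])
  dim(out$y) <- c(prod(shape %/% 2L), d[2], d[3])
  out
}

.pool_backward <- function(dy, arg, shape, c_in, batch) {
  dx <- .pool_bwd_cpp(dy, arg, as.integer(shape), c_in * batch)
  dim(dx) <- c(prod(shape), c_in, batch)
  dx
}

# ---- pointwise / dense ----

.relu_forward <- function(x) {
  out <- .relu_fwd_cpp(x)
  dim(out$y) <- dim(x)
  out
}

.relu_backward <- function(dy, mask) {
  dx <- .relu_bwd_cpp(dy, mask)
  dim(dx) <- dim(dy)
  dx
}

.fc_forward <- function(x, w, b) {
  w %*% x + b
}

.fc_backward <- function(dy, x, w) {
  list(dx = crossprod(w, dy), dw = tcrossprod(dy, x), db = rowSums(dy))
}

.dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) {
    return(list(y = x, mask = NULL))
  }
  mask <- matrix(stats::runif(length(x)) >= rate, nrow = nrow(x)) / (1 - rate)
  list(y = x * mask, mask = mask)
}

.dropout_backward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# ---- softmax / cross-entropy ----

#' Column-wise softmax
#' @param logits Numeric matrix, classes in rows, samples in columns (a
#'   vector is treated as one sample).
#' @return Matrix of probabilities; every column sums to 1.
#' @export
softmax_cols <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, ncol = 1)
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

# Mean cross-entropy of probability columns against 0/1 labels
# (label 1 = second row). Returns loss and gradient wrt logits.
.ce_from_logits <- function(logits, labels) {
  p <- softmax_cols(logits)
  b <- ncol(p)
  idx <- cbind(labels + 1L, seq_len(b))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  onehot <- matrix(0, nrow = nrow(p), ncol = b)
  onehot[idx] <- 1
  list(loss = loss, dlogits = (p - onehot) / b, p = p)
}

# ---- parameter utilities ----

.init_mat <- function(nrow, ncol, fan_in, scheme = c("he", "small")) {
  scheme <- match.arg(scheme)
  sd <- if (scheme == "he") sqrt(2 / fan_in) else 0.02
  matrix(stats::rnorm(nrow * ncol, 0, sd), nrow = nrow, ncol = ncol)
}

# Flat iteration over a nested list of numeric parameters.
.params_walk <- function(params, f, other = NULL) {
  if (is.list(params)) {
    out <- vector("list", length(params))
    names(out) <- names(params)
    for (i in seq_along(params)) {
      out[[i]] <- .params_walk(params[[i]], f, if (is.null(other)) NULL else other[[i]])
    }
    out
  } else {
    if (is.null(other)) f(params) else f(params, other)
  }
}

.params_zero_like <- function(params) .params_walk(params, function(p) p * 0)

.params_count <- function(params) {
  total <- 0
  .params_walk(params, function(p) {
    total <<- total + length(p)
    p
  })
  total
}

# SGD with classical momentum and decoupled-from-nothing L2 weight decay:
# v <- mom * v - lr * (g + wd * p); p <- p + v
.sgd_step <- function(params, grads, velocity, lr, momentum, weight_decay) {
  step_one <- function(p, g, v) {
    v2 <- momentum * v - lr * (g + weight_decay * p)
    list(p = p + v2, v = v2)
  }
  rec <- function(p, g, v) {
    if (is.list(p)) {
      out_p <- vector("list", length(p)); out_v <- vector("list", length(p))
      names(out_p) <- names(p); names(out_v) <- names(p)
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], v[[i]])
        out_p[[i]] <- r$p; out_v[[i]] <- r$v
      }
      list(p = out_p, v = out_v)
    } else {
      step_one(p, g, v)
    }
  }
  rec(params, grads, velocity)
}
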