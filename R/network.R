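#' Network configuration
#'
#' Architecture of the single-phase and multi-phase fusion classifiers: a
#' LeNet5-style 3D backbone per phase (three 3x3x3 convolution stages with
#' 2x2x2 max pooling) whose deepest feature map (4x4x4, so N = 64 flattened
#' positions) passes through a self-attention block and — in fusion models —
#' a cross-phase collaborative-attention block before the final pooling and
#' the per-phase 32-dimensional fully connected feature. Fusion models
#' concatenate the per-phase features (|phases| x 32) into a 2-way softmax
#' head; each phase branch also carries a lightweight auxiliary head used
#' by the weighted multi-phase loss.
#'
#' @param phases Ordered character subset of `c("PreP","AP","PP","HBP")`.
#' @param conv_channels Channels of the three convolution stages.
#' @param key_dim Query/key projection dimension of the attention blocks.
#' @param fc_feature_dim_per_phase Per-phase feature width (default 32).
#' @param dropout_rate Dropout on the per-phase fully connected feature
#'   during training.
#' @param attention_gamma_init Initial value of the residual attention
#'   gates (0 = attention blocks start as exact identities).
#' @return A `network_config` list.
#' @export
network_config <- function(phases = c("PreP", "AP", "PP", "HBP"),
                           conv_channels = c(6L, 16L, 32L),
                           key_dim = 8L,
                           fc_feature_dim_per_phase = 32L,
                           dropout_rate = 0.5,
                           attention_gamma_init = 0) {
  phases <- match.arg(phases, .phase_names, several.ok = TRUE)
  stopifnot(length(phases) >= 1, length(phases) <= 4, !anyDuplicated(phases))
  stopifnot(length(conv_channels) == 3, fc_feature_dim_per_phase >= 1)
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  structure(
    list(
      phases = phases,
      conv_channels = as.integer(conv_channels),
      key_dim = as.integer(key_dim),
      fc_feature_dim_per_phase = as.integer(fc_feature_dim_per_phase),
      dropout_rate = dropout_rate,
      attention_gamma_init = attention_gamma_init,
      cube_side = 16L
    ),
    class = "network_config"
  )
}

# Geometry plans (im2col/pool index tables) cached per batch size.
.plan_cache <- new.env(parent = emptyenv())

.layer_plans <- function(config, batch) {
  key <- paste0("b", batch, "_", paste(config$conv_channels, collapse = "-"))
  if (!is.null(.plan_cache[[key]])) {
    return(.plan_cache[[key]])
  }
  cc <- config$conv_channels
  plans <- list(
    shape1 = c(16L, 16L, 16L), shape2 = c(8L, 8L, 8L), shape3 = c(4L, 4L, 4L),
    batch = batch
  )
  .plan_cache[[key]] <- plans
  plans
}

#' Initialize network parameters
#'
#' He-normal initialization for convolution/dense weights, small-normal
#' for attention projections, residual gates at
#' `config$attention_gamma_init`. The parameter count is identical for
#' every phase branch.
#'
#' @param config A [network_config()].
#' @param seed Integer seed.
#' @return An `mvi_network`: list with `config` and nested `params`.
#' @export
network_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  cc <- config$conv_channels
  fdim <- config$fc_feature_dim_per_phase
  branch <- function() {
    list(
      conv1 = list(w = .init_mat(cc[1], 27L, 27), b = numeric(cc[1])),
      conv2 = list(w = .init_mat(cc[2], 27L * cc[1], 27 * cc[1]), b = numeric(cc[2])),
      conv3 = list(w = .init_mat(cc[3], 27L * cc[2], 27 * cc[2]), b = numeric(cc[3])),
      sa = attention_weights(cc[3], config$key_dim, gamma = config$attention_gamma_init),
      fc1 = list(w = .init_mat(fdim, 8L * cc[3], 8 * cc[3]), b = numeric(fdim)),
      head = list(w = .init_mat(2L, fdim, fdim), b = numeric(2))
    )
  }
  params <- list(branches = lapply(config$phases, function(p) branch()))
  names(params$branches) <- config$phases
  if (length(config$phases) > 1) {
    params$ca <- lapply(config$phases, function(p) {
      attention_weights(cc[3], config$key_dim, gamma = config$attention_gamma_init)
    })
    names(params$ca) <- config$phases
    params$fused_head <- list(
      w = .init_mat(2L, fdim * length(config$phases), fdim * length(config$phases)),
      b = numeric(2)
    )
  }
  structure(list(config = config, params = params), class = "mvi_network")
}

#' Number of trainable parameters
#' @param model An `mvi_network`.
#' @return Integer count.
#' @export
n_params <- function(model) .params_count(model$params)

# Forward pass. xs: named list (one entry per configured phase) of arrays
# (4096, 1, B) — z-scored 16^3 cubes flattened along the first dimension.
# Returns logits, per-phase features and attention matrices; with
# keep_cache = TRUE also everything the backward pass needs.
.network_forward <- function(model, xs, train = FALSE, keep_cache = FALSE) {
  config <- model$config
  phases <- config$phases
  stopifnot(all(phases %in% names(xs)))
  b <- dim(xs[[phases[1]]])[3]
  plans <- .layer_plans(config, b)
  cc <- config$conv_channels
  fusion <- length(phases) > 1

  br_cache <- list()
  sa_out <- list()
  for (ph in phases) {
    p <- model$params$branches[[ph]]
    x <- xs[[ph]]
    if (!all(is.finite(x))) stop("non-finite values in input cube for phase ", ph)
    c1 <- .conv3d_forward(x, p$conv1$w, p$conv1$b, plans$shape1, relu = TRUE)
    p1 <- .pool_forward(c1$y, plans$shape1)
    c2 <- .conv3d_forward(p1$y, p$conv2$w, p$conv2$b, plans$shape2, relu = TRUE)
    p2 <- .pool_forward(c2$y, plans$shape2)
    c3 <- .conv3d_forward(p2$y, p$conv3$w, p$conv3$b, plans$shape3, relu = TRUE)
    sa <- .self_attn_forward_batch(c3$y, p$sa)
    sa_out[[ph]] <- sa$y
    br_cache[[ph]] <- list(
      x = x, r1mask = c1$mask, p1 = p1, r2mask = c2$mask,
      p2 = p2, r3mask = c3$mask, r3y = c3$y, sa = sa
    )
  }

  if (fusion) {
    ca <- .coll_attn_forward_batch(sa_out[phases], model$params$ca[phases])
    z <- ca$ys
    names(z) <- phases
  } else {
    ca <- NULL
    z <- sa_out
  }

  feats <- list(); logits_phase <- list()
  for (ph in phases) {
    p <- model$params$branches[[ph]]
    p3 <- .pool_forward(z[[ph]], plans$shape3)
    flat <- matrix(p3$y, nrow = 8L * cc[3]) # (8 spatial * C) x B
    f1 <- .fc_forward(flat, p$fc1$w, p$fc1$b)
    rf <- .relu_forward(f1)
    dr <- .dropout_forward(rf$y, config$dropout_rate, train)
    feats[[ph]] <- dr$y
    logits_phase[[ph]] <- .fc_forward(dr$y, p$head$w, p$head$b)
    br_cache[[ph]]$p3 <- p3
    br_cache[[ph]]$flat <- flat
    br_cache[[ph]]$rfmask <- rf$mask
    br_cache[[ph]]$drmask <- dr$mask
    br_cache[[ph]]$feat <- dr$y
  }

  if (fusion) {
    concat <- do.call(rbind, feats[phases])
    logits <- .fc_forward(concat, model$params$fused_head$w, model$params$fused_head$b)
  } else {
    concat <- feats[[phases[1]]]
    logits <- logits_phase[[phases[1]]]
  }

  out <- list(
    logits = logits,
    logits_phase = logits_phase,
    features = feats,
    attn_self = lapply(br_cache, function(cc_) cc_$sa$attn),
    attn_coll = if (fusion) stats::setNames(ca$attn, phases) else NULL,
    prob = softmax_cols(logits)
  )
  if (keep_cache) {
    out$cache <- list(branches = br_cache, ca = ca, concat = concat, plans = plans)
  }
  out
}

# Backward pass: takes gradients wrt the fused logits and the per-phase
# auxiliary logits, returns the full parameter gradient tree. saliency_at
# optionally captures d(objective)/d(block output) for Grad-CAM.
.network_backward <- function(model, fwd, dlogits_fused, dlogits_phase = NULL,
                              saliency_at = NULL) {
  config <- model$config
  phases <- config$phases
  fusion <- length(phases) > 1
  cc <- config$conv_channels
  cache <- fwd$cache
  plans <- cache$plans
  b <- ncol(fwd$logits)
  grads <- .params_zero_like(model$params)
  captured <- list()

  # head gradients -> per-phase feature gradients
  dfeats <- stats::setNames(
    lapply(phases, function(ph) matrix(0, config$fc_feature_dim_per_phase, b)),
    phases
  )
  if (fusion) {
    g <- .fc_backward(dlogits_fused, cache$concat, model$params$fused_head$w)
    grads$fused_head$w <- g$dw
    grads$fused_head$b <- g$db
    fdim <- config$fc_feature_dim_per_phase
    for (i in seq_along(phases)) {
      rows <- (i - 1L) * fdim + seq_len(fdim)
      dfeats[[phases[i]]] <- g$dx[rows, , drop = FALSE]
    }
  }
  for (ph in phases) {
    dlp <- if (!is.null(dlogits_phase) && !is.null(dlogits_phase[[ph]])) {
      dlogits_phase[[ph]]
    } else if (!fusion && ph == phases[1]) {
      dlogits_fused
    } else {
      NULL
    }
    if (!is.null(dlp)) {
      bc <- cache$branches[[ph]]
      g <- .fc_backward(dlp, bc$feat, model$params$branches[[ph]]$head$w)
      grads$branches[[ph]]$head$w <- grads$branches[[ph]]$head$w + g$dw
      grads$branches[[ph]]$head$b <- grads$branches[[ph]]$head$b + g$db
      dfeats[[ph]] <- dfeats[[ph]] + g$dx
    }
  }

  # per-phase FC/pool backward down to the attention output
  dz <- list()
  for (ph in phases) {
    bc <- cache$branches[[ph]]
    p <- model$params$branches[[ph]]
    d <- .dropout_backward(dfeats[[ph]], bc$drmask)
    d <- .relu_backward(d, bc$rfmask)
    g <- .fc_backward(d, bc$flat, p$fc1$w)
    grads$branches[[ph]]$fc1$w <- g$dw
    grads$branches[[ph]]$fc1$b <- g$db
    dflat <- array(g$dx, dim = c(8L, cc[3], b))
    dz[[ph]] <- .pool_backward(dflat, bc$p3$arg, plans$shape3, cc[3], b)
  }

  # collaborative attention backward (fusion only)
  if (fusion) {
    if (!is.null(saliency_at) && saliency_at == "collaborative_attention") {
      captured$block_grad <- dz
    }
    sa_out <- stats::setNames(
      lapply(phases, function(ph) cache$branches[[ph]]$sa$y), phases
    )
    cb <- .coll_attn_backward_batch(dz[phases], sa_out[phases],
      model$params$ca[phases], cache$ca)
    for (i in seq_along(phases)) {
      grads$ca[[phases[i]]]$wq <- cb$grads[[i]]$wq
      grads$ca[[phases[i]]]$wk <- cb$grads[[i]]$wk
      grads$ca[[phases[i]]]$wv <- cb$grads[[i]]$wv
      grads$ca[[phases[i]]]$gamma <- cb$grads[[i]]$gamma
    }
    dsa <- stats::setNames(cb$dxs, phases)
  } else {
    dsa <- dz
  }
  if (!is.null(saliency_at) && saliency_at == "self_attention") {
    captured$block_grad <- dsa
  }

  # self-attention and convolution stack backward
  for (ph in phases) {
    bc <- cache$branches[[ph]]
    p <- model$params$branches[[ph]]
    sb <- .self_attn_backward_batch(dsa[[ph]], bc$r3y, p$sa, bc$sa)
    grads$branches[[ph]]$sa$wq <- sb$grads$wq
    grads$branches[[ph]]$sa$wk <- sb$grads$wk
    grads$branches[[ph]]$sa$wv <- sb$grads$wv
    grads$branches[[ph]]$sa$gamma <- sb$grads$gamma
    g3 <- .conv3d_backward(bc$p2$y, sb$dx, p$conv3$w, plans$shape3,
      mask = bc$r3mask)
    grads$branches[[ph]]$conv3$w <- g3$dw
    grads$branches[[ph]]$conv3$b <- g3$db
    d <- .pool_backward(g3$dx, bc$p2$arg, plans$shape2, cc[2], b)
    g2 <- .conv3d_backward(bc$p1$y, d, p$conv2$w, plans$shape2,
      mask = bc$r2mask)
    grads$branches[[ph]]$conv2$w <- g2$dw
    grads$branches[[ph]]$conv2$b <- g2$db
    d <- .pool_backward(g2$dx, bc$p1$arg, plans$shape1, cc[1], b)
    g1 <- .conv3d_backward(bc$x, d, p$conv1$w, plans$shape1,
      mask = bc$r1mask, need_dx = FALSE)
    grads$branches[[ph]]$conv1$w <- g1$dw
    grads$branches[[ph]]$conv1$b <- g1$db
  }
  list(grads = grads, captured = captured)
}

#' Forward pass for a single-phase model
#'
#' @param model An `mvi_network` configured with one phase.
#' @param cube A 16x16x16 (z-scored) intensity array, or a list of such
#'   arrays for a batch.
#' @return Tibble with `prob_mvi_negative`, `prob_mvi_positive` (one row
#'   per input cube); probabilities sum to 1.
#' @export
forward_single_phase <- function(model, cube) {
  stopifnot(length(model$config$phases) == 1)
  cubes <- if (is.list(cube)) cube else list(cube)
  x <- .stack_cubes(cubes)
  xs <- stats::setNames(list(x), model$config$phases)
  fwd <- .network_forward(model, xs, train = FALSE)
  tibble::tibble(
    prob_mvi_negative = fwd$prob[1, ],
    prob_mvi_positive = fwd$prob[2, ]
  )
}

#' Forward pass for a fusion model
#'
#' @param model An `mvi_network` with two or more phases.
#' @param cubes Named list mapping each configured phase to a 16^3 cube
#'   (or to a list of cubes for a batch).
#' @return List with `prob` tibble (probabilities sum to 1) and `features`
#'   (named list of per-phase feature matrices, rows =
#'   `fc_feature_dim_per_phase`).
#' @export
forward_fusion <- function(model, cubes) {
  phases <- model$config$phases
  stopifnot(length(phases) >= 2)
  missing <- setdiff(phases, names(cubes))
  if (length(missing) > 0) {
    stop("missing phase cube(s): ", paste(missing, collapse = ", "))
  }
  xs <- lapply(cubes[phases], function(cb) {
    .stack_cubes(if (is.list(cb)) cb else list(cb))
  })
  fwd <- .network_forward(model, xs, train = FALSE)
  list(
    prob = tibble::tibble(
      prob_mvi_negative = fwd$prob[1, ],
      prob_mvi_positive = fwd$prob[2, ]
    ),
    features = fwd$features,
    attn_self = fwd$attn_self,
    attn_coll = fwd$attn_coll
  )
}

# list of 16^3 arrays -> (4096, 1, B)
.stack_cubes <- function(cubes) {
  b <- length(cubes)
  x <- array(0, dim = c(4096L, 1L, b))
  for (i in seq_len(b)) {
    stopifnot(all(dim(cubes[[i]]) == c(16L, 16L, 16L)))
    x[, 1L, i] <- as.vector(cubes[[i]])
  }
  x
}
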