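test_that("self-attention matches the hand-computed toy matrix and softmax closed form", {
  fx <- fixture_toy_attention(x1 = 1, x2 = -1, gamma = 0.5)
  out <- self_attention(fx$x, fx$weights)
  expect_equal(out$attention, fx$expected_attention, tolerance = 1e-6)
  # direct brute-force recomputation with plain matrix arithmetic
  s <- (fx$x %*% t(fx$x)) / 1
  a_manual <- t(apply(s, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(out$attention, a_manual, tolerance = 1e-12)
  expect_equal(out$features, fx$x + 0.5 * a_manual %*% fx$x, tolerance = 1e-12)

  # symmetric inputs give uniform attention rows
  fx2 <- fixture_toy_attention(x1 = 1, x2 = 1)
  expect_equal(self_attention(fx2$x, fx2$weights)$attention,
    matrix(0.5, 2, 2), tolerance = 1e-12)
})

test_that("attention rows are stochastic and gamma = 0 is an exact identity", {
  for (s in 1:5) {
    n <- sample(4:32, 1)
    c <- sample(2:8, 1)
    x <- withr::with_seed(s, matrix(stats::rnorm(n * c), n, c))
    w <- withr::with_seed(s + 99, attention_weights(c, key_dim = 4, gamma = 0.7))
    out <- self_attention(x, w)
    expect_equal(rowSums(out$attention), rep(1, n), tolerance = 1e-6)
    expect_true(all(out$attention > 0 & out$attention < 1))

    w0 <- w
    w0$gamma <- 0
    expect_identical(self_attention(x, w0)$features, x)
  }
  expect_error(self_attention(matrix(c(1, NA), 1), attention_weights(2)),
    "non-finite")
})

test_that("collaborative attention: identity at gamma 0, collapse to self-attention, oracle", {
  set.seed(31)
  n <- 6; c <- 3
  own <- matrix(stats::rnorm(n * c), n, c)
  others <- list(matrix(stats::rnorm(n * c), n, c), matrix(stats::rnorm(n * c), n, c))
  w <- attention_weights(c, key_dim = 2, gamma = 0)
  expect_identical(collaborative_attention(own, others, w)$features, own)

  # partners identical to own with shared projections -> equals self-attention
  w$gamma <- 0.4
  co <- collaborative_attention(own, list(own, own), w)
  sa <- self_attention(own, w)
  expect_equal(co$features, sa$features, tolerance = 1e-12)
  expect_equal(co$attention, sa$attention, tolerance = 1e-12)

  # two-phase cross-attention against a hand-rolled computation
  cr <- collaborative_attention(own, others[1], w)
  q <- own %*% w$wq; k <- others[[1]] %*% w$wk; v <- others[[1]] %*% w$wv
  s <- q %*% t(k) / sqrt(2)
  a <- t(apply(s, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(cr$attention, a, tolerance = 1e-12)
  expect_equal(cr$features, own + 0.4 * a %*% v, tolerance = 1e-12)

  # mean pair matrix is still row-stochastic
  expect_equal(rowSums(collaborative_attention(own, others, w)$attention),
    rep(1, n), tolerance = 1e-9)

  expect_error(collaborative_attention(own, list(matrix(0, 2, 2)), w), "shape")
})

test_that("single-phase forward produces valid probabilities and symmetric output at init", {
  nc <- network_config("AP", dropout_rate = 0)
  model <- network_init(nc, seed = 5)
  pr <- forward_single_phase(model, random_cube(1))
  expect_equal(pr$prob_mvi_negative + pr$prob_mvi_positive, 1, tolerance = 1e-12)

  # zero cube, zero biases, gamma 0: exact (0.5, 0.5) by symmetry
  pr0 <- forward_single_phase(model, array(0, c(16, 16, 16)))
  expect_equal(pr0$prob_mvi_positive, 0.5)

  expect_error(forward_single_phase(model, array(0, c(8, 8, 8))))
})

test_that("gamma = 0 makes both attention blocks exact no-ops in the full network", {
  phases <- c("AP", "HBP")
  nc <- network_config(phases, dropout_rate = 0, attention_gamma_init = 0)
  model <- network_init(nc, seed = 11)
  cubes <- random_cubes(phases, seed = 2)
  out <- forward_fusion(model, cubes)

  # zeroing every attention projection must not change the output
  stripped <- model
  for (ph in phases) {
    for (nm in c("wq", "wk", "wv")) {
      stripped$params$branches[[ph]]$sa[[nm]][] <- 0
      stripped$params$ca[[ph]][[nm]][] <- 0
    }
  }
  out2 <- forward_fusion(stripped, cubes)
  expect_equal(out$prob, out2$prob, tolerance = 1e-12)
})

test_that("fusion forward: 4-phase features concatenate to 128, attention stays row-stochastic", {
  phases <- c("PreP", "AP", "PP", "HBP")
  nc <- network_config(phases, dropout_rate = 0, attention_gamma_init = 0.2)
  model <- network_init(nc, seed = 3)
  cubes <- random_cubes(phases, seed = 9)
  out <- forward_fusion(model, cubes)

  expect_equal(out$prob$prob_mvi_negative + out$prob$prob_mvi_positive, 1,
    tolerance = 1e-12)
  expect_length(out$features, 4)
  expect_equal(sum(vapply(out$features, nrow, integer(1))), 128)

  for (ph in phases) {
    for (i in seq_len(dim(out$attn_self[[ph]])[3])) {
      expect_equal(rowSums(out$attn_self[[ph]][, , i]), rep(1, 64),
        tolerance = 1e-6)
      expect_equal(rowSums(out$attn_coll[[ph]][, , i]), rep(1, 64),
        tolerance = 1e-6)
    }
  }
  expect_error(forward_fusion(model, cubes[c("AP", "PP", "HBP")]), "missing phase")
})

test_that("permuting the phase order with correspondingly permuted weights preserves the output", {
  cubes <- random_cubes(c("AP", "HBP"), seed = 4)
  nc_a <- network_config(c("AP", "HBP"), dropout_rate = 0, attention_gamma_init = 0.3)
  model_a <- network_init(nc_a, seed = 21)
  nc_b <- network_config(c("HBP", "AP"), dropout_rate = 0, attention_gamma_init = 0.3)
  model_b <- network_init(nc_b, seed = 22)
  # transplant weights: same branch/collaborative weights per phase name,
  # fused-head columns reordered to follow the new concatenation order
  model_b$params$branches <- model_a$params$branches[c("HBP", "AP")]
  model_b$params$ca <- model_a$params$ca[c("HBP", "AP")]
  fdim <- nc_a$fc_feature_dim_per_phase
  w <- model_a$params$fused_head$w
  model_b$params$fused_head$w <- w[, c(fdim + seq_len(fdim), seq_len(fdim))]
  model_b$params$fused_head$b <- model_a$params$fused_head$b

  out_a <- forward_fusion(model_a, cubes)
  out_b <- forward_fusion(model_b, cubes)
  expect_equal(out_a$prob, out_b$prob, tolerance = 1e-12)
  expect_equal(out_a$features$AP, out_b$features$AP, tolerance = 1e-12)
})

test_that("parameter count is phase-symmetric and batch-size independent", {
  nc <- network_config(c("PreP", "AP", "PP", "HBP"))
  model <- network_init(nc, seed = 1)
  counts <- vapply(model$params$branches, mvifusion:::.params_count, numeric(1))
  expect_length(unique(counts), 1L)

  xs1 <- lapply(random_cubes(nc$phases, 1), function(cb) mvifusion:::.stack_cubes(list(cb)))
  xs3 <- lapply(random_cubes(nc$phases, 1), function(cb) {
    mvifusion:::.stack_cubes(list(cb, cb, cb))
  })
  f1 <- mvifusion:::.network_forward(model, xs1)
  f3 <- mvifusion:::.network_forward(model, xs3)
  expect_equal(n_params(model), n_params(model))
  expect_equal(f1$prob[, 1], f3$prob[, 1], tolerance = 1e-12)
  expect_equal(f3$prob[, 1], f3$prob[, 3], tolerance = 1e-12)
})

test_that("analytic gradients match numeric differentiation through the full network", {
  phases <- c("AP", "HBP")
  nc <- network_config(phases, dropout_rate = 0)
  model <- network_init(nc, seed = 7)
  for (ph in phases) model$params$branches[[ph]]$sa$gamma <- 0.3
  for (ph in phases) model$params$ca[[ph]]$gamma <- 0.3
  # probe at a generic point: heads start at zero by design, which would
  # block gradient flow to everything upstream
  model$params$fused_head$w[] <- withr::with_seed(1, stats::rnorm(64, 0, 0.2))
  for (ph in phases) {
    model$params$branches[[ph]]$head$w[] <- withr::with_seed(2, stats::rnorm(64, 0, 0.2))
  }
  xs <- withr::with_seed(42, setNames(lapply(phases, function(p) {
    mvifusion:::.stack_cubes(list(
      array(stats::rnorm(4096), c(16, 16, 16)),
      array(stats::rnorm(4096), c(16, 16, 16))
    ))
  }), phases))
  labels <- c(0L, 1L)
  lw <- c(0.3, 0.7)
  lg <- mvifusion:::.batch_loss_grads(model, xs, labels, lw)
  loss_fn <- function(m) mvifusion:::.batch_loss_grads(m, xs, labels, lw)$loss
  eps <- 1e-5

  probe <- function(get, set, g) {
    p0 <- get(model)
    expect_gt(sum(abs(g)), 0) # the tensor as a whole receives gradient
    ks <- withr::with_seed(length(p0), sample(length(p0), min(2, length(p0))))
    for (k in ks) {
      m2 <- model; p <- p0; p[k] <- p[k] + eps; lp <- loss_fn(set(m2, p))
      m2 <- model; p <- p0; p[k] <- p[k] - eps; lm <- loss_fn(set(m2, p))
      num <- (lp - lm) / (2 * eps)
      expect_equal(g[k], num, tolerance = 1e-3)
    }
  }
  ph <- "AP"
  for (nm in c("conv1", "conv3", "fc1", "head")) {
    probe(function(m) m$params$branches[[ph]][[nm]]$w,
      function(m, v) { m$params$branches[[ph]][[nm]]$w[] <- v; m },
      lg$grads$branches[[ph]][[nm]]$w)
  }
  for (nm in c("wq", "wk", "wv", "gamma")) {
    probe(function(m) m$params$branches[[ph]]$sa[[nm]],
      function(m, v) { m$params$branches[[ph]]$sa[[nm]][] <- v; m },
      lg$grads$branches[[ph]]$sa[[nm]])
    probe(function(m) m$params$ca[[ph]][[nm]],
      function(m, v) { m$params$ca[[ph]][[nm]][] <- v; m },
      lg$grads$ca[[ph]][[nm]])
  }
  probe(function(m) m$params$fused_head$w,
    function(m, v) { m$params$fused_head$w[] <- v; m },
    lg$grads$fused_head$w)
})
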