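test_that("Grad-CAM heatmaps are bounded, finite, and respect the layer contract", {
  nc <- network_config("AP", dropout_rate = 0, attention_gamma_init = 0.2)
  model <- network_init(nc, seed = 13)
  model$params$branches$AP$head$w[] <- withr::with_seed(13, stats::rnorm(64, 0, 0.2))
  sal <- grad_cam(model, random_cube(3), layer = "self_attention")
  expect_equal(dim(sal$heatmap), c(16, 16, 16))
  expect_true(all(is.finite(sal$heatmap)))
  expect_gte(min(sal$heatmap), 0)
  expect_lte(max(sal$heatmap), 1)
  if (any(sal$heatmap > 0)) expect_equal(max(sal$heatmap), 1)
  # the attention matrix rides along and is row-stochastic
  expect_equal(rowSums(sal$attention), rep(1, 64), tolerance = 1e-6)

  expect_error(grad_cam(model, random_cube(3), layer = "collaborative_attention"),
    "single-phase")
})

test_that("a head that ignores the attention layer yields an all-zero CAM", {
  nc <- network_config("AP", dropout_rate = 0)
  model <- network_init(nc, seed = 5)
  model$params$branches$AP$head$w[] <- 0
  model$params$branches$AP$head$b[] <- 0
  sal <- grad_cam(model, random_cube(1), layer = "self_attention")
  expect_true(all(sal$heatmap == 0))
  expect_true(all(sal$raw == 0))
})

test_that("Grad-CAM matches an analytic weighted-channel-sum oracle on a frozen model", {
  nc <- network_config("AP", dropout_rate = 0, attention_gamma_init = 0.1)
  model <- network_init(nc, seed = 23)
  model$params$branches$AP$head$w[] <- withr::with_seed(23, stats::rnorm(64, 0, 0.2))
  cube <- random_cube(17)
  sal <- grad_cam(model, cube, layer = "self_attention", target_class = 1L)

  p <- model$params$branches$AP
  fwd <- mvifusion:::.network_forward(
    model, list(AP = mvifusion:::.stack_cubes(list(cube))), keep_cache = TRUE
  )
  y0 <- fwd$cache$branches$AP$sa$y[, , 1]
  # exact gradient of the target logit wrt the attention output, assembled
  # by hand: max-pool selection at y0, then the two dense layers with the
  # ReLU activity pattern frozen at y0
  argmax_of <- function(y, po, c) {
    i <- (po - 1) %% 2; j <- ((po - 1) %/% 2) %% 2; k <- (po - 1) %/% 4
    arr <- array(y[, c], c(4, 4, 4))
    block <- arr[(2 * i + 1):(2 * i + 2), (2 * j + 1):(2 * j + 2),
      (2 * k + 1):(2 * k + 2)]
    w <- which(block == max(block), arr.ind = TRUE)[1, ]
    (2 * i + w[1]) + (2 * j + w[2] - 1) * 4 + (2 * k + w[3] - 1) * 16
  }
  flat <- numeric(256)
  sel <- matrix(0L, 8, 32)
  for (c in 1:32) for (po in 1:8) {
    sel[po, c] <- argmax_of(y0, po, c)
    flat[po + (c - 1) * 8] <- y0[sel[po, c], c]
  }
  f_pre <- p$fc1$w %*% flat + p$fc1$b
  active <- as.numeric(f_pre > 0)
  g_flat <- crossprod(p$fc1$w, p$head$w[2, ] * active) # target = class 1
  grad_y <- matrix(0, 64, 32)
  for (c in 1:32) for (po in 1:8) {
    grad_y[sel[po, c], c] <- grad_y[sel[po, c], c] + g_flat[po + (c - 1) * 8]
  }
  cam_expected <- pmax(y0 %*% colMeans(grad_y), 0)
  expect_equal(as.vector(sal$raw), as.vector(cam_expected), tolerance = 1e-6)
})

test_that("saliency is invariant to constant shifts of the target logit", {
  nc <- network_config("AP", dropout_rate = 0, attention_gamma_init = 0.2)
  model <- network_init(nc, seed = 29)
  model$params$branches$AP$head$w[] <- withr::with_seed(29, stats::rnorm(64, 0, 0.2))
  cube <- random_cube(2)
  s1 <- grad_cam(model, cube, layer = "self_attention", target_class = 1L)
  shifted <- model
  shifted$params$branches$AP$head$b[2] <- shifted$params$branches$AP$head$b[2] + 5
  s2 <- grad_cam(shifted, cube, layer = "self_attention", target_class = 1L)
  expect_equal(s1$heatmap, s2$heatmap, tolerance = 1e-12)
})

test_that("collaborative-attention Grad-CAM runs on fusion models for each phase", {
  phases <- c("AP", "HBP")
  nc <- network_config(phases, dropout_rate = 0, attention_gamma_init = 0.2)
  model <- network_init(nc, seed = 31)
  model$params$fused_head$w[] <- withr::with_seed(31, stats::rnorm(128, 0, 0.2))
  cubes <- random_cubes(phases, seed = 7)
  for (ph in phases) {
    sal <- grad_cam(model, cubes, layer = "collaborative_attention", phase = ph)
    expect_equal(sal$phase, ph)
    expect_true(all(sal$heatmap >= 0 & sal$heatmap <= 1))
  }
})

test_that("attention mass fraction: whole cube 1, empty region 0, uniform proportionality", {
  h <- array(0.5, c(16, 16, 16))
  all_region <- array(TRUE, c(16, 16, 16))
  none <- array(FALSE, c(16, 16, 16))
  expect_equal(attention_mass_fraction(h, all_region), 1)
  expect_equal(attention_mass_fraction(h, none), 0)

  region <- array(FALSE, c(16, 16, 16))
  region[1:16, 1:16, 1:5] <- TRUE # about 31% of voxels
  expect_equal(attention_mass_fraction(h, region), mean(region), tolerance = 1e-12)

  expect_warning(
    out <- attention_mass_fraction(array(0, c(16, 16, 16)), region),
    "all-zero"
  )
  expect_true(is.na(out))
})

test_that("phase weight grids expose 32 entries per phase and track the fused head", {
  phases <- c("PreP", "AP", "PP", "HBP")
  nc <- network_config(phases)
  model <- network_init(nc, seed = 37)
  model$params$fused_head$w[] <- withr::with_seed(37, stats::rnorm(256, 0, 0.2))
  pw <- phase_weight_heatmap(model)
  expect_equal(nrow(pw), 128)
  expect_equal(unname(table(pw$phase)[phases]), rep(32L, 4), ignore_attr = TRUE)
  expect_true(all(pw$weight >= 0))

  # zeroing one phase's fused-head columns zeroes exactly that grid
  fdim <- nc$fc_feature_dim_per_phase
  model$params$fused_head$w[, fdim + seq_len(fdim)] <- 0 # AP segment
  pw2 <- phase_weight_heatmap(model)
  expect_true(all(pw2$weight[pw2$phase == "AP"] == 0))
  expect_true(all(pw2$weight[pw2$phase == "HBP"] > 0))

  single <- network_init(network_config("AP"), seed = 1)
  expect_error(phase_weight_heatmap(single), "fusion")
})

test_that("margin shell regions straddle the resampled mask boundary", {
  mask16 <- array(0, c(16, 16, 16))
  mask16[6:11, 6:11, 6:11] <- 1
  region <- margin_shell_region(mask16, width = 1)
  expect_true(region[6, 8, 8])   # just inside the boundary
  expect_true(region[5, 8, 8])   # just outside
  expect_false(region[8, 8, 8])  # deep interior
  expect_false(region[1, 1, 1])  # far background
})
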