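# Deterministic micro-fixtures used by the test suite (and exported for
# inspection): regenerating them from their parameters is bit-identical.

#' Augmentation-count fixture
#'
#' A deterministic 32^3 ramp cube together with the sliding-window count
#' law `floor((R - c) / s) + 1` per axis, for checking the local-cube
#' augmentation arithmetic (9 offsets per axis and 729 cubes at the
#' default 32 -> 16 stride-2 geometry).
#'
#' @return List with `cube` (32^3 array), `count_law` (function of
#'   `resample_size, cut_size, stride`), and `expected` (tibble of
#'   geometry scenarios with per-axis and total counts).
#' @export
fixture_augmentation_counts <- function() {
  v <- seq_len(32L)
  cube <- outer(outer(v, v, "+"), v, "+") # smooth integer ramp
  count_law <- function(resample_size, cut_size, stride) {
    floor((resample_size - cut_size) / stride) + 1L
  }
  expected <- tibble::tibble(
    resample_size = c(32L, 32L, 32L),
    cut_size = c(16L, 16L, 32L),
    stride = c(2L, 4L, 1L),
    per_axis = c(9L, 5L, 1L),
    total = c(729L, 125L, 1L)
  )
  list(cube = cube, count_law = count_law, expected = expected)
}

#' Toy attention fixture
#'
#' An N = 2, C = 1 feature map with hand-set unit projections, plus the
#' closed-form attention matrix: with scores `s_ij = x_i * x_j` (d_k = 1)
#' each row of the softmax is `(sigma(g), 1 - sigma(g))` for the row's
#' score gap `g`, where `sigma` is the logistic function.
#'
#' @param x1,x2 The two feature values.
#' @param gamma Residual gate.
#' @return List with `x` (2 x 1 matrix), `weights`
#'   ([attention_weights()] with all projections = 1), and
#'   `expected_attention` (2 x 2 matrix computed from the closed form).
#' @export
fixture_toy_attention <- function(x1 = 1, x2 = -1, gamma = 0.5) {
  x <- matrix(c(x1, x2), ncol = 1)
  w <- list(
    wq = matrix(1, 1, 1), wk = matrix(1, 1, 1), wv = matrix(1, 1, 1),
    gamma = gamma
  )
  sigma <- function(g) 1 / (1 + exp(-g))
  # scores s_ij = x_i * x_j / sqrt(1); row i gap g_i = s_i1 - s_i2
  s <- x %*% t(x)
  expected <- rbind(
    c(sigma(s[1, 1] - s[1, 2]), 1 - sigma(s[1, 1] - s[1, 2])),
    c(sigma(s[2, 1] - s[2, 2]), 1 - sigma(s[2, 1] - s[2, 2]))
  )
  list(x = x, weights = w, expected_attention = expected)
}

#' Fixture registry
#'
#' @return Named list of the fixture generator functions.
#' @export
fixture_registry <- function() {
  list(
    augmentation_counts = fixture_augmentation_counts,
    toy_attention = fixture_toy_attention
  )
}
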