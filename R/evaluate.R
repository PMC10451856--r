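#' Rank-based AUC
#'
#' Area under the ROC curve computed from midranks (the Mann-Whitney
#' statistic divided by `n1 * n0`), which handles ties by the standard
#' 1/2 correction.
#'
#' @param scores Numeric vector of predicted scores (higher = more likely
#'   positive).
#' @param labels 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC staircase: one point per distinct threshold, from (0,0) to (1,1).
.roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  n1 <- sum(l == 1L)
  n0 <- sum(l == 0L)
  tp <- cumsum(l == 1L)
  fp <- cumsum(l == 0L)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tibble::tibble(
    threshold = c(Inf, s[keep]),
    tpr = c(0, tp[keep] / n1),
    fpr = c(0, fp[keep] / n0)
  )
}

#' ROC analysis with bootstrap confidence interval
#'
#' Rank-based AUC, a stratified bootstrap percentile confidence interval,
#' the ROC staircase, and accuracy/sensitivity/specificity at an operating
#' threshold (Youden-optimal on the evaluated set by default, or a fixed
#' cutoff).
#'
#' @param scores Numeric scores (higher = more likely MVI-positive).
#' @param labels 0/1 vector.
#' @param conf_level Confidence level of the bootstrap interval.
#' @param n_boot Bootstrap replicates (resampled within each class).
#' @param threshold `"youden"` or a fixed numeric cutoff; predictions are
#'   positive when `score >= threshold`.
#' @param seed Seed for the bootstrap resampling.
#' @return An `mvi_roc` object: list with `auc`, `ci_low`, `ci_high`,
#'   `points` (tibble `threshold`, `fpr`, `tpr`), `threshold`, `accuracy`,
#'   `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95, n_boot = 2000L,
                    threshold = "youden", seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels[!is.na(labels)])) < 2) {
    stop("both classes must be present")
  }
  auc <- auc_rank(scores, labels)
  pts <- .roc_points(scores, labels)

  idx1 <- which(labels == 1L)
  idx0 <- which(labels == 0L)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  boots <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    i1 <- idx1[sample.int(length(idx1), replace = TRUE)]
    i0 <- idx0[sample.int(length(idx0), replace = TRUE)]
    boots[b] <- auc_rank(c(scores[i1], scores[i0]),
      c(rep(1L, length(i1)), rep(0L, length(i0))))
  }
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))

  if (identical(threshold, "youden")) {
    youden <- pts$tpr - pts$fpr
    thr <- pts$threshold[which.max(youden)]
    if (!is.finite(thr)) thr <- max(scores) + 1
  } else {
    thr <- as.numeric(threshold)
  }
  pred <- as.integer(scores >= thr)
  sens <- sum(pred == 1L & labels == 1L) / sum(labels == 1L)
  spec <- sum(pred == 0L & labels == 0L) / sum(labels == 0L)
  acc <- mean(pred == labels)

  structure(
    list(
      auc = auc, ci_low = min(ci[1], auc), ci_high = max(ci[2], auc),
      conf_level = conf_level, points = pts,
      threshold = thr, accuracy = acc, sensitivity = sens, specificity = spec,
      n_pos = length(idx1), n_neg = length(idx0),
      scores = scores, labels = labels
    ),
    class = "mvi_roc"
  )
}

#' @export
print.mvi_roc <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f (%d%% CI %.3f-%.3f), n = %d pos / %d neg\n",
    x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high, x$n_pos, x$n_neg
  ))
  cat(sprintf(
    "Operating point (threshold %.3f): accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
    x$threshold, x$accuracy, x$sensitivity, x$specificity
  ))
  invisible(x)
}

#' Decision curve analysis
#'
#' Net benefit of treating patients whose score reaches the threshold
#' probability `p_t`:
#' `NB(p_t) = TP/n - (FP/n) * p_t / (1 - p_t)`,
#' compared with the treat-all policy (`NB = pi - (1 - pi) p_t/(1 - p_t)`,
#' `pi` the prevalence) and treat-none (`NB = 0`).
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 vector.
#' @param thresholds Threshold-probability grid in `(0, 1)` (values >= 1
#'   are dropped).
#' @return An `mvi_dca` tibble: `threshold`, `net_benefit_model`,
#'   `net_benefit_all`, `net_benefit_none`, `prevalence`.
#' @export
net_benefit <- function(scores, labels, thresholds = seq(0.01, 0.60, by = 0.01)) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  n <- length(labels)
  prev <- mean(labels == 1L)
  nb <- vapply(thresholds, function(pt) {
    pos <- scores >= pt
    tp <- sum(pos & labels == 1L)
    fp <- sum(pos & labels == 0L)
    tp / n - (fp / n) * pt / (1 - pt)
  }, numeric(1))
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  out <- tibble::tibble(
    threshold = thresholds,
    net_benefit_model = nb,
    net_benefit_all = nb_all,
    net_benefit_none = 0,
    prevalence = prev
  )
  class(out) <- c("mvi_dca", class(out))
  out
}

#' Compare evaluated models in one table
#'
#' @param results Named list of `mvi_roc` objects evaluated on the same
#'   patients.
#' @return Tibble with one row per model: `model`, `auc`, `ci_low`,
#'   `ci_high`, `accuracy`, `sensitivity`, `specificity`.
#' @export
compare_models <- function(results) {
  stopifnot(length(results) >= 1)
  ns <- vapply(results, function(r) r$n_pos + r$n_neg, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("all models must be evaluated on the same set of patients")
  }
  labsets <- lapply(results, function(r) sort(r$labels))
  if (!all(vapply(labsets, identical, logical(1), labsets[[1]]))) {
    stop("all models must be evaluated on the same set of patients")
  }
  nm <- names(results)
  if (is.null(nm)) nm <- paste0("model", seq_along(results))
  dplyr::bind_rows(lapply(seq_along(results), function(i) {
    r <- results[[i]]
    tibble::tibble(
      model = nm[i], auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
      accuracy = r$accuracy, sensitivity = r$sensitivity,
      specificity = r$specificity
    )
  }))
}
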