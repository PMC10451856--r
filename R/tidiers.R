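# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ROC result
#' @param x An `mvi_roc`.
#' @param ... Unused.
#' @return Tibble of ROC staircase points (`threshold`, `fpr`, `tpr`).
#' @export
tidy.mvi_roc <- function(x, ...) x$points

#' One-row summary of an ROC result
#' @param x An `mvi_roc`.
#' @param ... Unused.
#' @return Tibble with `auc`, `ci_low`, `ci_high`, `threshold`,
#'   `accuracy`, `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
glance.mvi_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
    threshold = x$threshold, accuracy = x$accuracy,
    sensitivity = x$sensitivity, specificity = x$specificity,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Tidy a cross-validation result
#' @param x An `mvi_cv`.
#' @param ... Unused.
#' @return Tibble of learning-curve rows across folds (`fold`,
#'   `iteration`, `train_loss`, `val_loss`, `val_auc`).
#' @export
tidy.mvi_cv <- function(x, ...) {
  dplyr::bind_rows(lapply(x$fold_models, function(fm) {
    dplyr::mutate(fm$curve, fold = fm$fold, .before = 1)
  }))
}

#' One-row-per-fold summary of a cross-validation result
#' @param x An `mvi_cv`.
#' @param ... Unused.
#' @return Tibble with `fold`, `iterations`, `best_iter`,
#'   `best_val_loss`, `best_val_auc`.
#' @export
glance.mvi_cv <- function(x, ...) {
  dplyr::bind_rows(lapply(x$fold_models, function(fm) {
    at_best <- fm$curve[fm$curve$iteration == fm$best_iter, ]
    tibble::tibble(
      fold = fm$fold, iterations = fm$stopped_at, best_iter = fm$best_iter,
      best_val_loss = fm$best_val_loss,
      best_val_auc = if (nrow(at_best) > 0) at_best$val_auc[1] else NA_real_
    )
  }))
}
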