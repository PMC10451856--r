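# ggplot2 display methods.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#' @param object An `mvi_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mvi_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.2f (%d%% CI %.2f-%.2f)",
        object$auc, round(100 * object$conf_level),
        object$ci_low, object$ci_high)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a decision curve
#' @param object An `mvi_dca` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mvi_dca <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = dplyr::starts_with("net_benefit_"),
    names_prefix = "net_benefit_", names_to = "policy",
    values_to = "net_benefit"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$net_benefit,
    colour = .data$policy)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(-0.05, max(long$net_benefit) + 0.02)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
      colour = NULL, title = "Decision curve analysis") +
    ggplot2::theme_minimal()
}

#' Plot per-phase fusion-head weight grids
#' @param object An `mvi_phase_weights` tibble.
#' @param ncol_grid Grid columns used to fold the 32 features per phase.
#' @param ... Unused.
#' @return A ggplot (one tile grid per phase).
#' @export
autoplot.mvi_phase_weights <- function(object, ncol_grid = 8L, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
    row = (.data$index - 1L) %/% ncol_grid,
    col = (.data$index - 1L) %% ncol_grid,
    phase = factor(.data$phase, levels = unique(.data$phase))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
    fill = .data$weight)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_wrap(~phase, nrow = 1) +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "|w|",
      title = "Fusion-head tensor weights per phase") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot axial slices of a saliency volume
#' @param object A `saliency_volume`.
#' @param slices Which z-slices of the 16^3 heatmap to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saliency_volume <- function(object, slices = c(4L, 8L, 12L), ...) {
  df <- dplyr::bind_rows(lapply(slices, function(z) {
    h <- object$heatmap[, , z]
    tibble::tibble(
      x = rep(seq_len(nrow(h)), times = ncol(h)),
      y = rep(seq_len(ncol(h)), each = nrow(h)),
      value = as.vector(h),
      slice = paste0("z = ", z)
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice, nrow = 1) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "saliency",
      title = sprintf("Grad-CAM (%s, %s)", object$phase, object$layer)
    ) +
    ggplot2::theme_minimal()
}
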