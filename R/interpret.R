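#' Grad-CAM saliency at an attention layer
#'
#' Gradient-weighted class activation mapping computed on the output
#' feature map of the chosen attention block: channel weights are the
#' spatial means of the target-class logit's gradient with respect to the
#' block output, the CAM is the rectified weighted channel sum, upsampled
#' trilinearly from the block's 4x4x4 grid to the 16^3 cube and min-max
#' normalized to `[0, 1]` (an all-constant map stays all zero).
#'
#' @param model An `mvi_network`.
#' @param cubes For a single-phase model a 16^3 cube; for a fusion model a
#'   named list of per-phase 16^3 cubes. Cubes should be z-scored as at
#'   training time.
#' @param layer `"self_attention"` or `"collaborative_attention"` (the
#'   latter exists only in fusion models).
#' @param phase Which phase branch to explain (default: the model's first
#'   phase).
#' @param target_class 0 or 1 (default 1, MVI-positive).
#' @return A `saliency_volume`: list with `heatmap` (16^3 array in
#'   `[0, 1]`), `raw` (unnormalized rectified CAM on the block grid),
#'   `layer`, `phase`, `target_class`, and `attention` (the block's N x N
#'   coefficient matrix for this input).
#' @export
grad_cam <- function(model, cubes, layer = c("self_attention", "collaborative_attention"),
                     phase = NULL, target_class = 1L) {
  layer <- match.arg(layer)
  config <- model$config
  phases <- config$phases
  fusion <- length(phases) > 1
  if (layer == "collaborative_attention" && !fusion) {
    stop("collaborative_attention layer does not exist in a single-phase model")
  }
  if (is.null(phase)) phase <- phases[1]
  stopifnot(phase %in% phases)
  stopifnot(target_class %in% c(0L, 1L))

  if (!is.list(cubes)) cubes <- stats::setNames(list(cubes), phases[1])
  xs <- lapply(cubes[phases], function(cb) .stack_cubes(list(cb)))
  names(xs) <- phases
  fwd <- .network_forward(model, xs, train = FALSE, keep_cache = TRUE)

  # Gradient of the target-class logit of the final head.
  dlogits <- matrix(0, 2, 1)
  dlogits[target_class + 1L, 1] <- 1
  bwd <- .network_backward(model, fwd, dlogits, saliency_at = layer)
  grad <- bwd$captured$block_grad[[phase]][, , 1] # N x C

  feat <- if (layer == "self_attention") {
    fwd$cache$branches[[phase]]$sa$y[, , 1]
  } else {
    fwd$cache$ca$ys[[match(phase, phases)]][, , 1]
  }
  alpha <- colMeans(grad) # channel weights
  cam <- pmax(as.vector(feat %*% alpha), 0) # rectified weighted sum over N=64
  cam3 <- array(cam, dim = c(4L, 4L, 4L))
  up <- resample_trilinear(cam3, c(16L, 16L, 16L))
  rng <- range(up)
  heat <- if (diff(rng) < 1e-12) array(0, dim = dim(up)) else (up - rng[1]) / diff(rng)

  attn <- if (layer == "self_attention") {
    fwd$attn_self[[phase]][, , 1]
  } else {
    fwd$attn_coll[[phase]][, , 1]
  }
  structure(
    list(
      heatmap = heat, raw = cam3, layer = layer, phase = phase,
      target_class = as.integer(target_class), attention = attn
    ),
    class = "saliency_volume"
  )
}

#' Per-phase tensor-weight grids of the fusion head
#'
#' Summarizes the first fully connected layer after concatenation: for
#' each of the `32 * |phases|` concatenated features, the mean absolute
#' weight over the output units, grouped into one 32-entry grid per phase.
#' Large values mean the phase's features drive the fused prediction.
#'
#' @param model A fusion `mvi_network`.
#' @return An `mvi_phase_weights` tibble: `phase`, `index` (1..32),
#'   `weight` (nonnegative).
#' @export
phase_weight_heatmap <- function(model) {
  config <- model$config
  if (length(config$phases) < 2) {
    stop("phase weight heatmaps require a fusion model")
  }
  w <- model$params$fused_head$w # 2 x (fdim * n_phases)
  fdim <- config$fc_feature_dim_per_phase
  vals <- colMeans(abs(w))
  out <- tibble::tibble(
    phase = rep(config$phases, each = fdim),
    index = rep(seq_len(fdim), times = length(config$phases)),
    weight = vals
  )
  class(out) <- c("mvi_phase_weights", class(out))
  out
}

#' Fraction of saliency mass inside a region
#'
#' `sum(heatmap[region]) / sum(heatmap)`; quantifies how much of the
#' model's attention falls on, e.g., the tumor margin plus peritumoral
#' shell.
#'
#' @param saliency A [grad_cam()] result or a bare heatmap array.
#' @param region Logical/0-1 array of the same shape as the heatmap.
#' @return Proportion in `[0, 1]`, or `NA` (with a warning) if the heatmap
#'   is all zero.
#' @export
attention_mass_fraction <- function(saliency, region) {
  h <- if (inherits(saliency, "saliency_volume")) saliency$heatmap else saliency
  stopifnot(all(dim(h) == dim(region)))
  total <- sum(h)
  if (total <= 0) {
    warning("all-zero heatmap: attention mass fraction undefined")
    return(NA_real_)
  }
  sum(h[region > 0]) / total
}

#' Margin + peritumoral region on the 16^3 cube grid
#'
#' Builds, from the mask resampled to the global-cube grid (see
#' [prepare_cube_cache()]), the tumor-margin band: voxels within `width`
#' voxels of the mask surface on either side. With
#' `include_peritumoral = TRUE` the region additionally covers every voxel
#' outside the mask — in a global cube (tumor bounding box plus a 2-voxel
#' expansion) all such voxels are peritumoral context, so the region is
#' then "margin plus peritumoral area", i.e. everything except the deep
#' tumor interior.
#'
#' @param mask16 Numeric 16^3 array (resampled mask, values in `[0, 1]`).
#' @param width Band half-width in voxels.
#' @param include_peritumoral Also include all voxels outside the mask?
#' @return Logical 16^3 array.
#' @export
margin_shell_region <- function(mask16, width = 2L, include_peritumoral = FALSE) {
  m <- mask16 > 0.5
  ero <- !.dilate3d(!m, as.integer(width))
  if (include_peritumoral) {
    return(!ero)
  }
  dil <- .dilate3d(m, as.integer(width))
  dil & !ero
}
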