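#' Configuration for the multi-phase liver phantom generator
#'
#' Defines the synthetic cohort: how many patients, what fraction carry
#' microvascular invasion (MVI), and the effect sizes of the three planted
#' MVI-correlated image features — margin irregularity (all phases),
#' a peritumoral hyperintense ring in the arterial phase (AP), and a
#' peritumoral hypointense ring in the hepatobiliary phase (HBP).
#' MVI-negative tumors are exact ellipsoids with no ring.
#'
#' Intensities are in arbitrary units on a scale where liver background is
#' of order 100. Background means differ per phase (HBP brightest, as
#' functioning parenchyma takes up gadoxetate late); the tumor is
#' hyperintense in AP (arterial enhancement) and hypointense in HBP.
#'
#' @param n_patients Number of patients in the cohort.
#' @param mvi_fraction Fraction of MVI-positive patients in `[0, 1]`;
#'   `round(mvi_fraction * n_patients)` patients get label 1.
#' @param volume_shape Integer triple, voxels per axis (each >= 48 so a
#'   tumor plus its peritumoral ring fits away from the borders).
#' @param tumor_radius_range Length-2 numeric, ellipsoid semi-axis range in
#'   voxels; each of the three radii is drawn uniformly from it.
#' @param margin_irregularity_amp Amplitude (voxels, >= 0) of the smooth
#'   random radial perturbation of the tumor surface. Applied only when the
#'   study is MVI-positive.
#' @param ap_ring_contrast Intensity added to the AP peritumoral shell for
#'   MVI-positive studies (>= 0).
#' @param hbp_ring_contrast Intensity subtracted from the HBP peritumoral
#'   shell for MVI-positive studies (>= 0).
#' @param ring_thickness Shell width in voxels (Chebyshev dilation of the
#'   tumor mask).
#' @param noise_sd Standard deviation of i.i.d. Gaussian voxel noise added
#'   to every phase.
#' @param seed Integer master seed; per-patient randomness is a
#'   counter-based stream of `(seed, patient_index)` so studies are
#'   reproducible independently of generation order.
#' @return An object of class `phantom_config` (a validated list).
#' @export
#' @examples
#' cfg <- phantom_config(n_patients = 4, noise_sd = 0, seed = 1)
#' st <- generate_study(cfg, patient_index = 0, mvi_label = 1)
#' range(st$volumes$AP)
phantom_config <- function(n_patients = 210,
                           mvi_fraction = 1 / 3,
                           volume_shape = c(64L, 64L, 64L),
                           tumor_radius_range = c(8, 13),
                           margin_irregularity_amp = 1.5,
                           ap_ring_contrast = 30,
                           hbp_ring_contrast = 30,
                           ring_thickness = 2L,
                           noise_sd = 5,
                           seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    mvi_fraction = mvi_fraction,
    volume_shape = as.integer(volume_shape),
    tumor_radius_range = as.numeric(tumor_radius_range),
    margin_irregularity_amp = margin_irregularity_amp,
    ap_ring_contrast = ap_ring_contrast,
    hbp_ring_contrast = hbp_ring_contrast,
    ring_thickness = as.integer(ring_thickness),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_patients >= 0,
    cfg$mvi_fraction >= 0, cfg$mvi_fraction <= 1,
    length(cfg$volume_shape) == 3,
    length(cfg$tumor_radius_range) == 2,
    diff(cfg$tumor_radius_range) >= 0,
    is.finite(cfg$margin_irregularity_amp), cfg$margin_irregularity_amp >= 0,
    is.finite(cfg$ap_ring_contrast), cfg$ap_ring_contrast >= 0,
    is.finite(cfg$hbp_ring_contrast), cfg$hbp_ring_contrast >= 0,
    cfg$ring_thickness >= 1,
    is.finite(cfg$noise_sd), cfg$noise_sd >= 0
  )
  if (cfg$n_patients > 0 && any(cfg$volume_shape < 48)) {
    stop("volume_shape must be >= 48 voxels per axis so a tumor plus ring fits")
  }
  structure(cfg, class = "phantom_config")
}

# Per-phase intensity means. HBP background brightest; tumor arterially
# enhancing in AP, hypointense in HBP.
.phase_names <- c("PreP", "AP", "PP", "HBP")
.phantom_background <- c(PreP = 100, AP = 130, PP = 120, HBP = 160)
.phantom_tumor <- c(PreP = 80, AP = 180, PP = 100, HBP = 70)

# Counter-based per-patient seed stream: reproducible regardless of the
# order in which patients are generated. Kept inside 32-bit range.
.patient_seed <- function(seed, patient_index) {
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(patient_index) * 92717 + 11) %%
    2147483629)
}

# Smooth random scalar field on the unit sphere: a superposition of
# von Mises-Fisher bumps at random directions. Band-limited (kappa sets
# the angular scale), so the perturbed margin is lobulated, not fragmented.
.sphere_field <- function(ux, uy, uz, n_bumps = 8, kappa = 5) {
  dirs <- matrix(stats::rnorm(3 * n_bumps), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  amps <- stats::rnorm(n_bumps)
  f <- 0
  for (m in seq_len(n_bumps)) {
    dot <- ux * dirs[m, 1] + uy * dirs[m, 2] + uz * dirs[m, 3]
    f <- f + amps[m] * exp(kappa * (dot - 1))
  }
  f
}

# Chebyshev dilation of a binary 3D array by `iter` voxels (3x3x3 box
# structuring element applied iteratively via axis shifts).
.dilate3d <- function(mask, iter = 1L) {
  d <- dim(mask)
  out <- mask
  for (i in seq_len(iter)) {
    m <- out
    for (ax in 1:3) {
      n <- d[ax]
      idx_lo <- c(1L, seq_len(n - 1L))
      idx_hi <- c(seq_len(n - 1L) + 1L, n)
      if (ax == 1) {
        m <- m | out[idx_lo, , , drop = FALSE] | out[idx_hi, , , drop = FALSE]
      } else if (ax == 2) {
        m <- m | out[, idx_lo, , drop = FALSE] | out[, idx_hi, , drop = FALSE]
      } else {
        m <- m | out[, , idx_lo, drop = FALSE] | out[, , idx_hi, drop = FALSE]
      }
    }
    out <- m
  }
  out
}

# Single connected component check (6-connectivity) by flood fill
# implemented as repeated dilation restricted to the mask.
.is_connected3d <- function(mask) {
  n_fg <- sum(mask)
  if (n_fg == 0L) return(FALSE)
  seed_idx <- which(mask)[1]
  comp <- array(FALSE, dim(mask))
  comp[seed_idx] <- TRUE
  repeat {
    grown <- .dilate3d(comp, 1L) & mask
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  sum(comp) == n_fg
}

#' Generate one synthetic four-phase study
#'
#' Builds a roughly ellipsoidal tumor in a constant liver-like background,
#' per phase, with the MVI-dependent signal planted when `mvi_label = 1`:
#' the surface radius is perturbed by a smooth random field of amplitude
#' `margin_irregularity_amp`, the arterial phase gains `+ap_ring_contrast`
#' and the hepatobiliary phase `-hbp_ring_contrast` in the
#' `ring_thickness`-voxel shell just outside the mask. Gaussian noise of sd
#' `noise_sd` is then added to every phase. Deterministic for a fixed
#' `(seed, patient_index)` pair.
#'
#' @param config A [phantom_config()].
#' @param patient_index 0-based patient counter, `< n_patients`.
#' @param mvi_label 0 or 1.
#' @return A `multi_phase_study`: list with `patient_id`, `volumes` (named
#'   list PreP/AP/PP/HBP of 3D arrays), `mask` (3D 0/1 integer array,
#'   hepatobiliary-phase tumor segmentation; phases are co-registered so it
#'   applies to all), and `mvi_label`.
#' @export
generate_study <- function(config, patient_index, mvi_label) {
  stopifnot(inherits(config, "phantom_config"))
  stopifnot(patient_index >= 0, patient_index < max(config$n_patients, 1L))
  stopifnot(mvi_label %in% c(0L, 1L))
  shape <- config$volume_shape

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(.patient_seed(config$seed, patient_index))

  radii <- stats::runif(3, config$tumor_radius_range[1], config$tumor_radius_range[2])
  amp <- if (mvi_label == 1) config$margin_irregularity_amp else 0
  # Room needed: perturbed radius (radial multiplier clipped at 1.5) plus
  # ring plus a 2-voxel margin.
  reach <- 1.5 * max(radii) + config$ring_thickness + 2
  if (any(2 * reach + 2 > shape)) {
    stop(sprintf(
      "tumor with radii (%.1f, %.1f, %.1f) plus ring does not fit in volume %s",
      radii[1], radii[2], radii[3], paste(shape, collapse = "x")
    ))
  }
  center <- vapply(1:3, function(ax) {
    stats::runif(1, reach + 1, shape[ax] - reach - 1)
  }, numeric(1))

  # Structural computation happens in the sub-box that can contain the
  # tumor plus its ring; the rest of the volume is pure background.
  blo <- pmax(1L, as.integer(floor(center - reach)))
  bhi <- pmin(shape, as.integer(ceiling(center + reach)))
  bdim <- bhi - blo + 1L
  cx <- seq.int(blo[1], bhi[1]) - center[1]
  cy <- seq.int(blo[2], bhi[2]) - center[2]
  cz <- seq.int(blo[3], bhi[3]) - center[3]
  dx <- array(rep(cx, times = bdim[2] * bdim[3]), dim = bdim)
  dy <- array(rep(rep(cy, each = bdim[1]), times = bdim[3]), dim = bdim)
  dz <- array(rep(cz, each = bdim[1] * bdim[2]), dim = bdim)
  rho <- sqrt((dx / radii[1])^2 + (dy / radii[2])^2 + (dz / radii[3])^2)

  if (amp > 0) {
    r_euc <- sqrt(dx^2 + dy^2 + dz^2)
    r_euc[r_euc == 0] <- 1
    f <- .sphere_field(dx / r_euc, dy / r_euc, dz / r_euc)
    f <- (f - mean(f)) / max(stats::sd(f), 1e-12)
    r_bar <- mean(radii)
    mult <- 1 + pmax(pmin(amp * f / r_bar, 0.5), -0.5)
    mask_sub <- rho <= mult
  } else {
    mask_sub <- rho <= 1
  }
  storage.mode(mask_sub) <- "logical"

  shell_sub <- .dilate3d(mask_sub, config$ring_thickness) & !mask_sub
  sx <- blo[1]:bhi[1]; sy <- blo[2]:bhi[2]; sz <- blo[3]:bhi[3]
  mask <- array(FALSE, dim = shape)
  mask[sx, sy, sz] <- mask_sub

  volumes <- lapply(.phase_names, function(ph) {
    v <- array(.phantom_background[[ph]], dim = shape)
    sub <- v[sx, sy, sz]
    sub[mask_sub] <- .phantom_tumor[[ph]]
    if (mvi_label == 1) {
      if (ph == "AP") sub[shell_sub] <- sub[shell_sub] + config$ap_ring_contrast
      if (ph == "HBP") sub[shell_sub] <- sub[shell_sub] - config$hbp_ring_contrast
    }
    v[sx, sy, sz] <- sub
    v
  })
  names(volumes) <- .phase_names
  if (config$noise_sd > 0) {
    for (ph in .phase_names) {
      volumes[[ph]] <- volumes[[ph]] +
        array(stats::rnorm(prod(shape), 0, config$noise_sd), dim = shape)
    }
  }

  mask_int <- array(0L, dim = shape)
  mask_int[mask] <- 1L
  structure(
    list(
      patient_id = sprintf("P%04d", patient_index + 1L),
      volumes = volumes,
      mask = mask_int,
      mvi_label = as.integer(mvi_label)
    ),
    class = "multi_phase_study"
  )
}

# Save/restore the global RNG state so generators are pure.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Cohort MVI labels
#'
#' Exactly `round(mvi_fraction * n_patients)` positives, assigned to a
#' seeded random permutation of patient indices.
#' @param config A [phantom_config()].
#' @return Integer vector of 0/1 labels, one per patient.
#' @export
cohort_labels <- function(config) {
  n <- config$n_patients
  n_pos <- as.integer(round(config$mvi_fraction * n))
  labels <- integer(n)
  if (n == 0L) return(labels)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(.patient_seed(config$seed, -1L))
  labels[sample.int(n, n_pos)] <- 1L
  labels
}

#' Generate a cohort of phantom studies on disk
#'
#' Writes, for each patient, one NIfTI volume per phase plus the tumor mask
#' (`.nii.gz`, unit isotropic voxels), and a roster CSV with columns
#' `patient_id, mvi_label, prep_path, ap_path, pp_path, hbp_path, mask_path`.
#'
#' @param config A [phantom_config()].
#' @param out_dir Output directory (created if missing).
#' @return The roster as a tibble (also written to `roster.csv` in
#'   `out_dir`).
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- cohort_labels(config)
  rows <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    st <- generate_study(config, patient_index = i - 1L, mvi_label = labels[i])
    paths <- c(
      prep_path = file.path(out_dir, sprintf("%s_PreP.nii.gz", st$patient_id)),
      ap_path = file.path(out_dir, sprintf("%s_AP.nii.gz", st$patient_id)),
      pp_path = file.path(out_dir, sprintf("%s_PP.nii.gz", st$patient_id)),
      hbp_path = file.path(out_dir, sprintf("%s_HBP.nii.gz", st$patient_id)),
      mask_path = file.path(out_dir, sprintf("%s_mask.nii.gz", st$patient_id))
    )
    for (k in seq_along(.phase_names)) {
      RNifti::writeNifti(RNifti::asNifti(st$volumes[[.phase_names[k]]], pixdim = c(1, 1, 1)),
        paths[k])
    }
    RNifti::writeNifti(RNifti::asNifti(st$mask, pixdim = c(1, 1, 1)), paths[5])
    rows[[i]] <- tibble::tibble(
      patient_id = st$patient_id, mvi_label = st$mvi_label,
      prep_path = paths[1], ap_path = paths[2], pp_path = paths[3],
      hbp_path = paths[4], mask_path = paths[5]
    )
  }
  roster <- if (config$n_patients > 0) dplyr::bind_rows(rows) else tibble::tibble(
    patient_id = character(), mvi_label = integer(),
    prep_path = character(), ap_path = character(), pp_path = character(),
    hbp_path = character(), mask_path = character()
  )
  readr::write_csv(roster, file.path(out_dir, "roster.csv"))
  roster
}

#' Generate a cohort in memory
#'
#' Like [generate_cohort()] but returns the studies as a list without
#' touching disk; used for large simulation runs where only the extracted
#' cubes are needed.
#' @param config A [phantom_config()].
#' @return List with `studies` (list of `multi_phase_study`) and `roster`
#'   (tibble of `patient_id`, `mvi_label`).
#' @export
generate_cohort_memory <- function(config) {
  labels <- cohort_labels(config)
  studies <- lapply(seq_len(config$n_patients), function(i) {
    generate_study(config, patient_index = i - 1L, mvi_label = labels[i])
  })
  roster <- tibble::tibble(
    patient_id = vapply(studies, `[[`, character(1), "patient_id"),
    mvi_label = labels
  )
  list(studies = studies, roster = roster)
}

#' Read a study written by [generate_cohort()]
#'
#' @param roster_row One row of the roster tibble (with path columns).
#' @return A `multi_phase_study`.
#' @export
read_study <- function(roster_row) {
  stopifnot(nrow(roster_row) == 1)
  read_vol <- function(path) {
    v <- RNifti::readNifti(path)
    array(as.numeric(v), dim = dim(v))
  }
  vols <- list(
    PreP = read_vol(roster_row$prep_path),
    AP = read_vol(roster_row$ap_path),
    PP = read_vol(roster_row$pp_path),
    HBP = read_vol(roster_row$hbp_path)
  )
  m <- RNifti::readNifti(roster_row$mask_path)
  mask <- array(as.integer(as.array(m) > 0.5), dim = dim(m))
  structure(
    list(
      patient_id = roster_row$patient_id,
      volumes = vols, mask = mask,
      mvi_label = as.integer(roster_row$mvi_label)
    ),
    class = "multi_phase_study"
  )
}

#' Peritumoral shell of a tumor mask
#'
#' Voxels within `thickness` voxels (Chebyshev distance) outside the mask;
#' the site of the planted arterial hyperintense and hepatobiliary
#' hypointense rings.
#' @param mask 3D 0/1 array.
#' @param thickness Shell width in voxels.
#' @return Logical 3D array.
#' @export
peritumoral_shell <- function(mask, thickness = 2L) {
  m <- mask > 0
  .dilate3d(m, as.integer(thickness)) & !m
}
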