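#' Trilinear resampling of a 3D volume
#'
#' Resamples with pixel-center alignment: output index `i` (0-based) maps
#' to input coordinate `(i + 0.5) * n_in / n_out - 0.5`, clamped to the
#' grid, so a same-size resample is the identity and a constant volume
#' stays constant.
#'
#' @param vol 3D numeric array.
#' @param out_shape Integer triple.
#' @return 3D numeric array of shape `out_shape`.
#' @export
resample_trilinear <- function(vol, out_shape) {
  d <- dim(vol)
  stopifnot(length(d) == 3, length(out_shape) == 3, all(out_shape >= 1))
  out_shape <- as.integer(out_shape)
  ax <- lapply(1:3, function(k) {
    # 0-based continuous source coordinate for each output voxel center
    src <- (seq_len(out_shape[k]) - 0.5) * d[k] / out_shape[k] - 0.5
    src <- pmin(pmax(src, 0), d[k] - 1)
    lo <- pmin(floor(src), d[k] - 1)
    hi <- pmin(lo + 1, d[k] - 1)
    w <- src - lo
    list(lo = as.integer(lo) + 1L, hi = as.integer(hi) + 1L, w = w)
  })
  out <- array(0, dim = out_shape)
  # Accumulate the 8 trilinear corners; each corner is a fancy-indexed crop.
  for (cx in 0:1) {
    ix <- if (cx == 0) ax[[1]]$lo else ax[[1]]$hi
    wx <- if (cx == 0) 1 - ax[[1]]$w else ax[[1]]$w
    for (cy in 0:1) {
      iy <- if (cy == 0) ax[[2]]$lo else ax[[2]]$hi
      wy <- if (cy == 0) 1 - ax[[2]]$w else ax[[2]]$w
      for (cz in 0:1) {
        iz <- if (cz == 0) ax[[3]]$lo else ax[[3]]$hi
        wz <- if (cz == 0) 1 - ax[[3]]$w else ax[[3]]$w
        w <- outer(outer(wx, wy), wz)
        if (all(w == 0)) next
        out <- out + vol[ix, iy, iz, drop = FALSE] * w
      }
    }
  }
  out
}

#' Bounding box of a tumor mask with peritumoral expansion
#'
#' Computes the tight box around the mask foreground, expands it by
#' `margin` voxels per side to include peritumoral tissue, clamps it to
#' the volume, and then cube-ifies it: shorter axes are extended
#' symmetrically to the longest axis length (again clamped at volume
#' borders), so the extracted region is as close to cubic as the volume
#' allows. Coordinates are 0-based and half-open: `lo` inclusive, `hi`
#' exclusive.
#'
#' @param mask 3D array, nonzero = tumor.
#' @param margin Expansion in voxels per side (default 2).
#' @param cubify Extend shorter axes to the longest axis length?
#' @return A `bounding_box`: list with integer triples `lo`, `hi` and the
#'   originating `volume_shape`.
#' @export
mask_to_bbox <- function(mask, margin = 2L, cubify = TRUE) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  fg <- which(mask > 0, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("mask has no foreground voxels")
  lo <- apply(fg, 2, min) - 1L # 0-based inclusive
  hi <- apply(fg, 2, max)     # 0-based exclusive = max index (1-based)
  lo <- pmax(lo - as.integer(margin), 0L)
  hi <- pmin(hi + as.integer(margin), d)
  if (cubify) {
    target <- max(hi - lo)
    for (ax in 1:3) {
      extra <- target - (hi[ax] - lo[ax])
      if (extra <= 0) next
      grow_lo <- extra %/% 2L
      grow_hi <- extra - grow_lo
      lo[ax] <- lo[ax] - grow_lo
      hi[ax] <- hi[ax] + grow_hi
      # If clamped on one side, push the remainder to the other.
      if (lo[ax] < 0L) {
        hi[ax] <- min(hi[ax] - lo[ax], d[ax])
        lo[ax] <- 0L
      }
      if (hi[ax] > d[ax]) {
        lo[ax] <- max(lo[ax] - (hi[ax] - d[ax]), 0L)
        hi[ax] <- d[ax]
      }
    }
  }
  structure(
    list(lo = as.integer(lo), hi = as.integer(hi), volume_shape = as.integer(d)),
    class = "bounding_box"
  )
}

.crop_bbox <- function(volume, bbox) {
  stopifnot(inherits(bbox, "bounding_box"))
  d <- dim(volume)
  if (any(bbox$lo < 0) || any(bbox$hi > d) || any(bbox$hi - bbox$lo < 2)) {
    stop("degenerate or out-of-volume bounding box")
  }
  volume[
    (bbox$lo[1] + 1L):bbox$hi[1],
    (bbox$lo[2] + 1L):bbox$hi[2],
    (bbox$lo[3] + 1L):bbox$hi[3],
    drop = FALSE
  ]
}

#' Extract the global cubic region of a tumor
#'
#' Crops the bounding box and resamples it to 16x16x16 — the "global cube"
#' carrying whole-tumor context.
#'
#' @param volume 3D intensity array (one phase).
#' @param bbox A [mask_to_bbox()] result.
#' @param patient_id,phase,label Provenance carried on the result.
#' @return A `cubic_region`: list with `data` (16^3 array), `kind`
#'   ("global"), `offset` `c(0,0,0)` and provenance fields.
#' @export
extract_global_cube <- function(volume, bbox, patient_id = NA_character_,
                                phase = NA_character_, label = NA_integer_) {
  cube <- resample_trilinear(.crop_bbox(volume, bbox), c(16L, 16L, 16L))
  structure(
    list(
      patient_id = patient_id, phase = phase, kind = "global",
      data = cube, offset = c(0L, 0L, 0L), label = as.integer(label)
    ),
    class = "cubic_region"
  )
}

#' Offsets of the sliding-window local-cube augmentation
#'
#' Corner offsets when a cube of side `resample_size` is cut into
#' `cut_size` sub-cubes at stride `stride`:
#' `floor((resample_size - cut_size) / stride) + 1` positions per axis.
#' With the defaults (32, 16, 2) that is 9 offsets `0, 2, ..., 16` per
#' axis and 9^3 = 729 cubes in total.
#'
#' @param resample_size,cut_size,stride Integers.
#' @return Integer vector of 0-based corner offsets along one axis.
#' @export
local_cube_offsets <- function(resample_size = 32L, cut_size = 16L, stride = 2L) {
  stopifnot(resample_size >= cut_size, stride >= 1)
  as.integer(seq(0L, resample_size - cut_size, by = stride))
}

#' Sliding-window local-cube augmentation
#'
#' Resamples the bounding-box crop to 32x32x32 and cuts it into 16x16x16
#' sub-cubes at every corner offset in `{0, 2, ..., 16}^3` — 9 positions
#' per axis, 729 local cubes, each inheriting the patient's MVI label.
#'
#' @inheritParams extract_global_cube
#' @param resample_size,cut_size,stride Augmentation geometry (defaults
#'   32, 16, 2).
#' @return A tibble with one row per local cube: `patient_id`, `phase`,
#'   `kind`, `ox`, `oy`, `oz` (0-based corner offsets), `label`, and a
#'   list-column `data` of 16^3 arrays.
#' @export
augment_local_cubes <- function(volume, bbox, patient_id = NA_character_,
                                phase = NA_character_, label = NA_integer_,
                                resample_size = 32L, cut_size = 16L, stride = 2L) {
  big <- resample_trilinear(.crop_bbox(volume, bbox),
    rep(as.integer(resample_size), 3))
  offs <- local_cube_offsets(resample_size, cut_size, stride)
  grid <- tidyr::expand_grid(oz = offs, oy = offs, ox = offs)
  grid <- grid[, c("ox", "oy", "oz")]
  cubes <- purrr::pmap(grid, function(ox, oy, oz) {
    big[ox + seq_len(cut_size), oy + seq_len(cut_size), oz + seq_len(cut_size)]
  })
  tibble::tibble(
    patient_id = patient_id, phase = phase, kind = "local",
    ox = grid$ox, oy = grid$oy, oz = grid$oz,
    label = as.integer(label), data = cubes
  )
}

#' Per-cube z-score normalization
#'
#' Centers and scales a cube to mean 0, sd 1; cubes with sd below `eps`
#' become all zeros.
#' @param cube Numeric array.
#' @param eps Degeneracy guard.
#' @return Array of the same shape.
#' @export
zscore_cube <- function(cube, eps = 1e-8) {
  s <- stats::sd(cube)
  if (!is.finite(s) || s < eps) {
    return(array(0, dim = dim(cube)))
  }
  (cube - mean(cube)) / s
}

#' Stratified train/test split with stratified cross-validation folds
#'
#' Splits the roster by MVI label into train and test sides at
#' `1 - test_fraction : test_fraction` (default 4:1) and assigns the
#' training patients to `n_folds` stratified cross-validation folds.
#' Deterministic for a fixed seed.
#'
#' @param roster Tibble with `patient_id` and `mvi_label` columns.
#' @param test_fraction Proportion of each class held out for testing.
#' @param n_folds Number of cross-validation folds on the training side.
#' @param seed Integer seed.
#' @return A `split_plan`: list with `train_ids`, `test_ids`, and
#'   `fold_assignment` (tibble `patient_id`, `mvi_label`, `fold` in
#'   `0:(n_folds-1)`).
#' @export
make_split <- function(roster, test_fraction = 0.2, n_folds = 5L, seed = 1L) {
  stopifnot(all(c("patient_id", "mvi_label") %in% names(roster)))
  stopifnot(!anyDuplicated(roster$patient_id))
  stopifnot(all(roster$mvi_label %in% c(0L, 1L)))
  classes <- sort(unique(roster$mvi_label))
  if (length(classes) < 2) stop("both MVI classes must be present in the roster")

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))

  train_rows <- list(); test_rows <- list()
  for (cl in classes) {
    sub <- roster[roster$mvi_label == cl, ]
    n <- nrow(sub)
    n_test <- as.integer(round(n * test_fraction))
    ord <- sample.int(n)
    test_rows[[as.character(cl)]] <- sub[ord[seq_len(n_test)], ]
    tr <- sub[ord[setdiff(seq_len(n), seq_len(n_test))], ]
    if (nrow(tr) < n_folds) {
      stop(sprintf("class %d has fewer than %d training patients", cl, n_folds))
    }
    tr$fold <- rep_len(seq_len(n_folds) - 1L, nrow(tr))
    train_rows[[as.character(cl)]] <- tr
  }
  train <- dplyr::bind_rows(train_rows)
  test <- dplyr::bind_rows(test_rows)
  structure(
    list(
      train_ids = train$patient_id,
      test_ids = test$patient_id,
      fold_assignment = tibble::as_tibble(
        train[, c("patient_id", "mvi_label", "fold")]),
      n_folds = as.integer(n_folds),
      seed = as.integer(seed)
    ),
    class = "split_plan"
  )
}

#' Prepare the cube cache for a cohort
#'
#' For every study, computes the bounding box from the mask and stores, per
#' phase, the 16^3 global cube and the 32^3 resampled region that local
#' cubes are sliced from. Volumes themselves are not retained.
#'
#' @param studies List of `multi_phase_study` objects (or a roster tibble
#'   with file paths, which are then read with [read_study()]).
#' @param phases Character subset of `c("PreP","AP","PP","HBP")`.
#' @param margin Bounding-box expansion (default 2).
#' @return Named list (by patient id) of lists with `label`, `bbox`,
#'   `global` (named list of 16^3 arrays per phase), `local32` (named list
#'   of 32^3 arrays per phase), and `mask16` (mask resampled to the global
#'   cube grid, for saliency localization).
#' @export
prepare_cube_cache <- function(studies, phases = .phase_names, margin = 2L) {
  if (is.data.frame(studies)) {
    roster <- studies
    studies <- lapply(seq_len(nrow(roster)), function(i) read_study(roster[i, ]))
  }
  out <- lapply(studies, function(st) {
    bbox <- mask_to_bbox(st$mask, margin = margin)
    glob <- lapply(st$volumes[phases], function(v) {
      extract_global_cube(v, bbox)$data
    })
    loc <- lapply(st$volumes[phases], function(v) {
      resample_trilinear(.crop_bbox(v, bbox), c(32L, 32L, 32L))
    })
    mask16 <- resample_trilinear(
      array(as.numeric(st$mask), dim = dim(st$mask))[
        (bbox$lo[1] + 1L):bbox$hi[1],
        (bbox$lo[2] + 1L):bbox$hi[2],
        (bbox$lo[3] + 1L):bbox$hi[3],
        drop = FALSE
      ],
      c(16L, 16L, 16L)
    )
    list(
      label = st$mvi_label, bbox = bbox,
      global = glob, local32 = loc, mask16 = mask16
    )
  })
  names(out) <- vapply(studies, `[[`, character(1), "patient_id")
  out
}

#' Build the training dataset manifest
#'
#' One row per sample: training patients contribute 729 local cubes plus
#' one global cube each; test patients contribute only their global cube
#' (test data are never augmented). Cube voxel data are not materialized —
#' rows reference the [prepare_cube_cache()] entries and local cubes are
#' sliced on demand during training.
#'
#' @param split A [make_split()] plan.
#' @param cache A [prepare_cube_cache()] result covering all split ids.
#' @return List with `train` and `test` manifests (tibbles with
#'   `patient_id`, `kind`, `ox`, `oy`, `oz`, `label`, `fold`) and the
#'   per-phase sample counts `n_train_per_phase`, `n_test_per_phase`.
#' @export
build_training_dataset <- function(split, cache) {
  stopifnot(inherits(split, "split_plan"))
  missing_ids <- setdiff(c(split$train_ids, split$test_ids), names(cache))
  if (length(missing_ids) > 0) {
    stop("cube cache missing patients: ", paste(missing_ids, collapse = ", "))
  }
  offs <- local_cube_offsets()
  local_grid <- tidyr::expand_grid(oz = offs, oy = offs, ox = offs)[, c("ox", "oy", "oz")]
  fold_of <- stats::setNames(split$fold_assignment$fold, split$fold_assignment$patient_id)

  train <- dplyr::bind_rows(lapply(split$train_ids, function(pid) {
    lab <- cache[[pid]]$label
    dplyr::bind_rows(
      tibble::tibble(
        patient_id = pid, kind = "global", ox = 0L, oy = 0L, oz = 0L,
        label = lab, fold = fold_of[[pid]]
      ),
      tibble::tibble(
        patient_id = pid, kind = "local",
        ox = local_grid$ox, oy = local_grid$oy, oz = local_grid$oz,
        label = lab, fold = fold_of[[pid]]
      )
    )
  }))
  test <- dplyr::bind_rows(lapply(split$test_ids, function(pid) {
    tibble::tibble(
      patient_id = pid, kind = "global", ox = 0L, oy = 0L, oz = 0L,
      label = cache[[pid]]$label, fold = NA_integer_
    )
  }))
  list(
    train = train, test = test,
    n_train_per_phase = nrow(train),
    n_test_per_phase = nrow(test)
  )
}

# Fetch the z-scored 16^3 cube for one manifest row and one phase.
.fetch_cube <- function(cache, patient_id, kind, ox, oy, oz, phase) {
  entry <- cache[[patient_id]]
  if (kind == "global") {
    cube <- entry$global[[phase]]
  } else {
    big <- entry$local32[[phase]]
    cube <- big[ox + 1:16, oy + 1:16, oz + 1:16]
  }
  zscore_cube(cube)
}
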