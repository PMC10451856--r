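test_that("bounding box arithmetic: point mask, margin expansion, clamping", {
  m <- array(0L, c(64, 64, 64))
  m[11, 11, 11] <- 1L # voxel (10,10,10) in 0-based coordinates
  bb <- mask_to_bbox(m, margin = 2, cubify = FALSE)
  expect_equal(bb$lo, c(8L, 8L, 8L))
  expect_equal(bb$hi, c(13L, 13L, 13L))

  # mask touching the volume corner: clamped at 0, never negative
  m2 <- array(0L, c(64, 64, 64))
  m2[1, 1, 1] <- 1L
  bb2 <- mask_to_bbox(m2, margin = 2)
  expect_equal(bb2$lo, c(0L, 0L, 0L))
  expect_true(all(bb2$hi <= 64))

  expect_error(mask_to_bbox(array(0L, c(8, 8, 8))), "foreground")
})

test_that("bounding boxes contain every foreground voxel and are cubic away from borders", {
  for (s in 1:50) {
    cfg <- tiny_phantom_config(noise_sd = 0, seed = 200 + s,
      margin_irregularity_amp = stats::runif(1, 0, 3))
    st <- generate_study(cfg, 0, s %% 2L)
    bb <- mask_to_bbox(st$mask)
    fg <- which(st$mask > 0, arr.ind = TRUE) - 1L # 0-based
    expect_true(all(fg[, 1] >= bb$lo[1] & fg[, 1] < bb$hi[1]))
    expect_true(all(fg[, 2] >= bb$lo[2] & fg[, 2] < bb$hi[2]))
    expect_true(all(fg[, 3] >= bb$lo[3] & fg[, 3] < bb$hi[3]))
    side <- bb$hi - bb$lo
    if (all(bb$lo > 0) && all(bb$hi < dim(st$mask))) {
      expect_equal(length(unique(side)), 1L)
    }
  }
})

test_that("trilinear resampling preserves constants, identity, and ramp monotonicity", {
  const <- array(3.5, c(7, 9, 12))
  expect_equal(resample_trilinear(const, c(16, 16, 16)),
    array(3.5, c(16, 16, 16)))

  v <- random_cube(5)
  expect_equal(resample_trilinear(v, c(16, 16, 16)), v)

  ramp <- array(rep(seq_len(24), times = 24 * 24), c(24, 24, 24))
  out <- resample_trilinear(ramp, c(16, 16, 16))
  expect_true(all(apply(out, c(2, 3), function(col) all(diff(col) >= 0))))
})

test_that("global cube extraction resamples the expanded box to 16^3", {
  cfg <- tiny_phantom_config(noise_sd = 0)
  st <- generate_study(cfg, 0, 1L)
  bb <- mask_to_bbox(st$mask)
  cube <- extract_global_cube(st$volumes$AP, bb, patient_id = "P1",
    phase = "AP", label = 1L)
  expect_s3_class(cube, "cubic_region")
  expect_equal(dim(cube$data), c(16, 16, 16))
  expect_equal(cube$kind, "global")
  expect_equal(cube$offset, c(0L, 0L, 0L))
  # intensities stay inside the crop's range
  expect_gte(min(cube$data), min(st$volumes$AP))
  expect_lte(max(cube$data), max(st$volumes$AP))

  degenerate <- structure(
    list(lo = c(0L, 0L, 0L), hi = c(1L, 16L, 16L), volume_shape = dim(st$mask)),
    class = "bounding_box"
  )
  expect_error(extract_global_cube(st$volumes$AP, degenerate), "degenerate")
})

test_that("local-cube augmentation emits 9 offsets per axis and 729 labeled cubes", {
  cfg <- tiny_phantom_config(noise_sd = 0)
  st <- generate_study(cfg, 0, 1L)
  bb <- mask_to_bbox(st$mask)
  cubes <- augment_local_cubes(st$volumes$HBP, bb, patient_id = "P1",
    phase = "HBP", label = 1L)
  expect_equal(nrow(cubes), 729)
  for (axis in c("ox", "oy", "oz")) {
    expect_equal(sort(unique(cubes[[axis]])), seq(0L, 16L, by = 2L))
  }
  expect_true(all(cubes$label == 1L))
  expect_true(all(vapply(cubes$data, function(d) all(dim(d) == 16), logical(1))))

  # constant input: every local cube is the same constant
  cubes_const <- augment_local_cubes(array(2, dim(st$mask)), bb)
  expect_true(all(vapply(cubes_const$data, function(d) all(d == 2), logical(1))))
})

test_that("the sliding-window count law matches brute-force offset enumeration", {
  brute_count <- function(R, cs, s) {
    o <- 0L
    count <- 0L
    while (o + cs <= R) {
      count <- count + 1L
      o <- o + s
    }
    count
  }
  fx <- fixture_augmentation_counts()
  for (i in seq_len(nrow(fx$expected))) {
    row <- fx$expected[i, ]
    expect_equal(fx$count_law(row$resample_size, row$cut_size, row$stride),
      row$per_axis)
    expect_equal(brute_count(row$resample_size, row$cut_size, row$stride),
      row$per_axis)
    expect_length(local_cube_offsets(row$resample_size, row$cut_size, row$stride),
      row$per_axis)
  }
  # the count law over a grid of geometries
  for (R in c(24L, 32L)) {
    for (cs in c(8L, 16L)) {
      for (s in 1:4) {
        expect_length(local_cube_offsets(R, cs, s), brute_count(R, cs, s))
      }
    }
  }
})

test_that("stratified split reproduces the 4:1 cohort arithmetic", {
  roster <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:210),
    mvi_label = rep(c(1L, 0L), c(70, 140))
  )
  sp <- make_split(roster, seed = 3)
  expect_length(sp$train_ids, 168)
  expect_length(sp$test_ids, 42)
  test_labels <- roster$mvi_label[match(sp$test_ids, roster$patient_id)]
  expect_equal(sum(test_labels == 1), 14)
  expect_equal(sum(test_labels == 0), 28)
  train_labels <- sp$fold_assignment$mvi_label
  expect_equal(sum(train_labels == 1), 56)
  expect_equal(sum(train_labels == 0), 112)

  # partition: disjoint, covering
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), roster$patient_id)

  # folds partition the training side, stratified
  expect_setequal(sp$fold_assignment$patient_id, sp$train_ids)
  per_fold <- table(sp$fold_assignment$fold, sp$fold_assignment$mvi_label)
  expect_true(all(per_fold[, "1"] %in% c(11, 12)))
  expect_true(all(per_fold[, "0"] %in% c(22, 23)))

  # determinism
  expect_identical(make_split(roster, seed = 3), sp)
  expect_false(identical(make_split(roster, seed = 4)$test_ids, sp$test_ids))

  expect_error(make_split(dplyr::mutate(roster, mvi_label = 0L)), "classes")
})

test_that("training dataset manifests count local and global cubes per the augmentation scheme", {
  cfg <- tiny_phantom_config(n_patients = 10, noise_sd = 1)
  coh <- generate_cohort_memory(cfg)
  sp <- make_split(coh$roster, n_folds = 2, seed = 2)
  cache <- prepare_cube_cache(coh$studies, phases = "AP")
  ds <- build_training_dataset(sp, cache)

  n_train <- length(sp$train_ids)
  expect_equal(ds$n_train_per_phase, n_train * 730) # 729 local + 1 global each
  expect_equal(ds$n_test_per_phase, length(sp$test_ids))
  expect_equal(sum(ds$train$kind == "local"), n_train * 729)
  expect_equal(sum(ds$train$kind == "global"), n_train)

  # test patients contribute no augmented cubes
  expect_true(all(ds$test$kind == "global"))
  expect_length(intersect(ds$test$patient_id, ds$train$patient_id), 0)

  # every cube carries its patient's label
  labels <- setNames(coh$roster$mvi_label, coh$roster$patient_id)
  expect_equal(ds$train$label, unname(labels[ds$train$patient_id]))
  expect_equal(ds$test$label, unname(labels[ds$test$patient_id]))

  # missing patient in the cache is an error naming the patient
  expect_error(build_training_dataset(sp, cache[-1]),
    names(cache)[1], fixed = TRUE)
})

test_that("per-cube z-scoring yields mean 0 / sd 1 and zeroes degenerate cubes", {
  z <- zscore_cube(random_cube(3) * 7 + 2)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore_cube(array(4, c(16, 16, 16))), array(0, c(16, 16, 16)))
})
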