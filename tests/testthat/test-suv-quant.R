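vox <- c(2.67, 2.67, 2.00)

test_that("SUV normalization follows the dose-per-weight identity", {
  m <- scan_meta("P01", "S1", injected_dose_MBq = 350, body_weight_kg = 70)
  img <- compute_suv_map(array(5, c(4, 4, 4)), m, vox)
  expect_equal(img$values[1], 1.0)

  # cohort-mean injected dose, hand evaluation
  m2 <- scan_meta("P01", "S1", injected_dose_MBq = 311, body_weight_kg = 80)
  img2 <- compute_suv_map(array(2, c(2, 2, 2)), m2, vox)
  expect_equal(img2$values[1], 2 * 80 / 311)
  expect_equal(img2$values[1], 0.5145, tolerance = 1e-4)
})

test_that("decay correction doubles activity after one half-life", {
  m <- scan_meta("P01", "S1", injected_dose_MBq = 100, body_weight_kg = 50,
                 injection_to_frame_min = 109.77, decay_corrected = FALSE)
  img <- compute_suv_map(array(1, c(2, 2, 2)), m, vox)
  expect_equal(img$values[1], 2 * 50 / 100)
})

test_that("quantification rejects invalid meta and activities", {
  expect_error(scan_meta("P", "S1", injected_dose_MBq = 0,
                         body_weight_kg = 70), "dose")
  expect_error(scan_meta("P", "S1", injected_dose_MBq = 300,
                         body_weight_kg = -1), "weight")
  expect_error(scan_meta("P", "S1", injected_dose_MBq = 300,
                         body_weight_kg = 70, decay_corrected = FALSE),
               "injection_to_frame_min")
  m <- scan_meta("P", "S1", injected_dose_MBq = 300, body_weight_kg = 70)
  a <- array(1, c(3, 3, 3)); a[1] <- -0.5
  expect_error(compute_suv_map(a, m, vox), "negative")
  a[1] <- -1e-4  # small negative noise is clamped
  expect_gte(min(compute_suv_map(a, m, vox)$values), 0)
})

test_that("SUV statistics are linear in activity", {
  m <- scan_meta("P", "S1", injected_dose_MBq = 300, body_weight_kg = 70)
  set.seed(2)
  a <- array(stats::runif(27, 1, 5), c(3, 3, 3))
  mask <- array(FALSE, c(3, 3, 3)); mask[1:2, 1:2, 1:2] <- TRUE
  s1 <- extract_voi_stats(compute_suv_map(a, m, vox), mask)
  s3 <- extract_voi_stats(compute_suv_map(3 * a, m, vox), mask)
  expect_equal(s3$suv_mean, 3 * s1$suv_mean)
  expect_equal(s3$suv_max, 3 * s1$suv_max)
  expect_equal(s3$volume_cm3, s1$volume_cm3)
})

test_that("smoothing is identity at zero FWHM and conserves mass", {
  set.seed(4)
  a <- array(stats::runif(16 * 16 * 12), c(16, 16, 12))
  expect_identical(smooth_image(a, 0, vox), a)

  spike <- array(0, c(21, 21, 21)); spike[11, 11, 11] <- 7
  sm <- smooth_image(spike, 4, c(2, 2, 2))
  expect_equal(sum(sm), 7, tolerance = 1e-6)

  # peak of a centred delta equals the product of the 1-D kernel centres
  sig <- (4 / (2 * sqrt(2 * log(2)))) / 2
  r <- max(1, ceiling(4 * sig))
  k <- stats::dnorm(seq(-r, r), sd = sig); k <- k / sum(k)
  expect_equal(sm[11, 11, 11], 7 * k[r + 1]^3, tolerance = 1e-10)
})

test_that("VOI statistics match hand values and geometry", {
  img <- fltrt:::new_suv_image(array(2, c(10, 10, 10)), vox)
  mask <- array(FALSE, c(10, 10, 10)); mask[1:10, 1:10, 1:10] <- TRUE
  s <- extract_voi_stats(img, mask)
  expect_equal(s$suv_mean, 2); expect_equal(s$suv_max, 2)
  expect_equal(s$volume_cm3, 1000 * 2.67 * 2.67 * 2.00 / 1000)
  expect_equal(s$volume_cm3, 14.2578, tolerance = 1e-4)

  v <- array(0, c(3, 1, 1)); v[, 1, 1] <- c(1, 2, 3)
  img2 <- fltrt:::new_suv_image(v, c(1, 1, 1))
  s2 <- extract_voi_stats(img2, array(TRUE, c(3, 1, 1)))
  expect_equal(s2$suv_mean, 2); expect_equal(s2$suv_max, 3)

  expect_error(extract_voi_stats(img, array(FALSE, c(10, 10, 10))), "empty")
  expect_error(extract_voi_stats(img, array(TRUE, c(2, 2, 2))), "shape")
})

test_that("suv_max is never below suv_mean on random masks", {
  set.seed(9)
  for (i in 1:10) {
    img <- fltrt:::new_suv_image(array(stats::rexp(125), c(5, 5, 5)), vox)
    mask <- array(stats::runif(125) > 0.5, c(5, 5, 5))
    if (!any(mask)) next
    s <- extract_voi_stats(img, mask)
    expect_gte(s$suv_max, s$suv_mean)
  }
})

test_that("bone-overlap QC counts face-adjacent voxels per margin step", {
  d <- c(8, 8, 8)
  lesion <- array(FALSE, d); lesion[2:4, 2:4, 2:4] <- TRUE
  bone <- array(FALSE, d); bone[6:8, 2:4, 2:4] <- TRUE
  qc <- check_bone_overlap(lesion, bone, margin_voxels = 0)
  expect_equal(qc$n_violations, 0); expect_true(qc$pass)

  bone1 <- array(FALSE, d); bone1[4, 3, 3] <- TRUE  # one shared voxel
  qc1 <- check_bone_overlap(lesion, bone1)
  expect_equal(qc1$n_violations, 1); expect_false(qc1$pass)

  # margin 1: compare against a brute-force 6-neighbourhood scan
  bone2 <- array(FALSE, d); bone2[5:8, 2:4, 2:4] <- TRUE  # adjacent slab
  qc2 <- check_bone_overlap(lesion, bone2, margin_voxels = 1)
  brute <- 0
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    if (!lesion[i, j, k]) next
    if (bone2[i, j, k]) { brute <- brute + 1; next }
    for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                   c(0,0,1), c(0,0,-1))) {
      p <- c(i, j, k) + s
      if (all(p >= 1 & p <= 8) && bone2[p[1], p[2], p[3]]) {
        brute <- brute + 1; break
      }
    }
  }
  expect_equal(qc2$n_violations, brute)
})

test_that("phantom lesions recover their activity after quantification", {
  spec <- phantom_spec(grid_shape = c(32, 32, 24),
                       voxel_size_mm = c(2, 2, 2),
                       lesions = list(list(center_mm = c(32, 32, 24),
                                           semi_axes_mm = c(10, 8, 8),
                                           activity_kBq_ml = 4,
                                           type = "primary")),
                       background_activity = 0.5,
                       smoothing_fwhm_mm = 0, noise_sd = 0)
  ph <- generate_phantom(spec)
  m <- scan_meta("P01", "S1", injected_dose_MBq = 70, body_weight_kg = 70)
  img <- compute_suv_map(ph$activity, m, ph$voxel_size_mm)
  s <- extract_voi_stats(img, ph$lesion_masks[[1]])
  expect_equal(s$suv_mean, 4)   # dose/weight = 1 MBq/kg => SUV = activity
  expect_equal(s$suv_max, 4)
})

test_that("voxelized sphere volume approximates the continuous volume", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32),
                       voxel_size_mm = c(2, 2, 2),
                       lesions = list(list(center_mm = c(32, 32, 32),
                                           semi_axes_mm = c(10, 10, 10),
                                           activity_kBq_ml = 1,
                                           type = "node")),
                       background_activity = 0,
                       smoothing_fwhm_mm = 0, noise_sd = 0)
  ph <- generate_phantom(spec)
  vol_mm3 <- sum(ph$lesion_masks[[1]]) * 8
  true_vol <- 4 / 3 * pi * 1000
  # discrepancy bounded by a one-voxel-thick shell at the surface
  expect_lt(abs(vol_mm3 - true_vol), 4 * pi * 100 * 2)
})

test_that("phantom rejects ambiguous or out-of-grid geometry", {
  les <- function(c0) list(center_mm = c0, semi_axes_mm = c(8, 8, 8),
                           activity_kBq_ml = 1, type = "primary")
  expect_error(phantom_spec(grid_shape = c(16, 16, 16),
                            voxel_size_mm = c(2, 2, 2),
                            lesions = list(les(c(2, 16, 16)))),
               "outside the grid")
  spec <- phantom_spec(grid_shape = c(32, 32, 32), voxel_size_mm = c(2, 2, 2),
                       lesions = list(les(c(30, 30, 30)), les(c(34, 34, 34))),
                       smoothing_fwhm_mm = 0)
  expect_error(generate_phantom(spec), "overlapping")
})

test_that("bone box next to a lesion is flagged by the QC check", {
  spec <- phantom_spec(grid_shape = c(24, 24, 24), voxel_size_mm = c(2, 2, 2),
                       lesions = list(list(center_mm = c(20, 24, 24),
                                           semi_axes_mm = c(8, 8, 8),
                                           activity_kBq_ml = 2,
                                           type = "primary")),
                       bone_box = list(min_mm = c(26, 16, 16),
                                       max_mm = c(40, 32, 32),
                                       activity_kBq_ml = 3),
                       smoothing_fwhm_mm = 0)
  ph <- generate_phantom(spec)
  qc <- check_bone_overlap(ph$lesion_masks[[1]], ph$bone_mask,
                           margin_voxels = 1)
  expect_gt(qc$n_violations, 0)
  expect_false(qc$pass)
})

test_that("NIfTI round trip preserves values and voxel geometry", {
  dir <- withr::local_tempdir()
  arr <- array(stats::rnorm(8 * 8 * 4), c(8, 8, 4))
  p <- file.path(dir, "img.nii.gz")
  write_nifti_image(arr, vox, p)
  back <- read_nifti_image(p)
  expect_equal(back$values, arr, tolerance = 1e-6)
  expect_equal(back$voxel_size_mm, vox, tolerance = 1e-5)

  mp <- file.path(dir, "meta.json")
  meta <- scan_meta("P03", "S2", 311, 82.5, 50, decay_corrected = FALSE)
  write_scan_meta(meta, mp)
  expect_equal(read_scan_meta(mp), meta)
})
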