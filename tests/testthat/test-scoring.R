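test_that("minimum lesion footprint follows the 1 mm^2 criterion", {
  expect_identical(min_area_voxels(c(0.4, 0.4)), 7L)
  expect_identical(min_area_voxels(c(1, 1)), 1L)
  expect_identical(min_area_voxels(c(0.33, 0.33)), 10L)
  expect_error(min_area_voxels(c(0, 0.4)), "positive")
  set.seed(5)
  for (rep in 1:20) {
    sp <- stats::runif(2, 0.2, 1.5)
    n <- min_area_voxels(sp)
    expect_gte(n * sp[1] * sp[2], 1 - 1e-9)
    if (n > 1) expect_lt((n - 1) * sp[1] * sp[2], 1)
  }
})

test_that("lesion detection applies HU, area and connectivity rules", {
  vol <- patch_volume()   # 16 x 16 x 6 at (0.5, 0.5, 3) mm
  expect_length(find_lesions(vol, full_mask(vol))$lesions, 0)
  # one 10-voxel 250 HU blob: 2.5 mm^2, weight 2 -> Ag 5
  vol <- patch_volume(patches = list(
    list(x = c(4, 8), y = c(4, 5), z = c(2, 2), hu = 250)))
  les <- find_lesions(vol, full_mask(vol))
  expect_length(les$lesions, 1)
  expect_identical(nrow(les$components), 1L)
  expect_equal(les$components$area_mm2, 2.5)
  expect_equal(agatston_score(les), 5)
  # 3 voxels at 0.4 mm spacing: 0.48 mm^2 < 1 mm^2 -> excluded
  v <- array(30, dim = c(12, 12, 4))
  v[5:7, 5, 2] <- 300
  small <- image_volume(v, c(0.4, 0.4, 3))
  expect_length(find_lesions(small, full_mask(small))$lesions, 0)
  expect_error(find_lesions(vol, array(TRUE, c(2, 2, 2))), "differ")
})

test_that("density weighting uses the four Agatston tiers", {
  for (cse in list(list(hu = 150, w = 1), list(hu = 250, w = 2),
                   list(hu = 350, w = 3), list(hu = 450, w = 4),
                   list(hu = 200, w = 2), list(hu = 399.9, w = 3),
                   list(hu = 400, w = 4))) {
    vol <- patch_volume(patches = list(
      list(x = c(4, 8), y = c(4, 5), z = c(2, 2), hu = cse$hu)))
    expect_equal(agatston_score(find_lesions(vol, full_mask(vol))),
                 2.5 * cse$w, info = paste("HU", cse$hu))
  }
})

test_that("volume and mass scores follow their definitions", {
  vol <- patch_volume(patches = list(
    list(x = c(4, 8), y = c(4, 5), z = c(2, 2), hu = 300)))
  les <- find_lesions(vol, full_mask(vol))
  expect_equal(volume_score(les), 10 * 0.5 * 0.5 * 3)   # 7.5 mm^3
  m1 <- mass_score(les)
  expect_equal(m1, 0.001 * 300 * 7.5)
  # doubling every lesion HU doubles the mass
  vol2 <- patch_volume(patches = list(
    list(x = c(4, 8), y = c(4, 5), z = c(2, 2), hu = 600)))
  expect_equal(mass_score(find_lesions(vol2, full_mask(vol2))), 2 * m1)
  expect_error(mass_score(les, calibration = 0), "positive")
  empty <- find_lesions(patch_volume(), full_mask(patch_volume()))
  expect_equal(volume_score(empty), 0)
  expect_equal(mass_score(empty), 0)
})

test_that("valid lesion count uses a strict 10 Ag threshold per 3D lesion", {
  # three well separated blobs engineered to Ag {5, 10, 24}
  vol <- patch_volume(dim = c(40, 40, 6), patches = list(
    list(x = c(2, 6), y = c(2, 3), z = c(2, 2), hu = 250),    # 2.5 * 2 = 5
    list(x = c(12, 21), y = c(12, 13), z = c(2, 2), hu = 250),# 5.0 * 2 = 10
    list(x = c(30, 37), y = c(30, 32), z = c(2, 2), hu = 450)))# 6 * 4 = 24
  les <- find_lesions(vol, full_mask(vol))
  ags <- sort(vapply(les$lesions, function(l) l$agatston, numeric(1)))
  expect_equal(ags, c(5, 10, 24))
  expect_identical(count_valid_lesions(les), 1L)   # only 24 > 10 (strict)
  expect_equal(sum(ags), agatston_score(les))      # per-lesion additivity
})

test_that("2D components are 8-connected and lesions 26-connected", {
  # diagonal in-plane contact joins a component
  v <- array(30, dim = c(12, 12, 4))
  v[4, 4, 2] <- 300; v[5, 5, 2] <- 300; v[6, 6, 2] <- 300; v[5, 4, 2] <- 300
  vol <- image_volume(v, c(0.6, 0.6, 3))
  les <- find_lesions(vol, full_mask(vol))
  expect_length(les$lesions, 1)
  # diagonal cross-slice contact joins one 3D lesion
  v <- array(30, dim = c(12, 12, 4))
  v[4:6, 4:6, 2] <- 300
  v[7:9, 7:9, 3] <- 300   # touches only diagonally across slices
  vol <- image_volume(v, c(0.6, 0.6, 3))
  les <- find_lesions(vol, full_mask(vol))
  expect_identical(nrow(les$components), 2L)
  expect_length(les$lesions, 1)
})

test_that("calcium outside the ROI contributes exactly zero", {
  v <- array(30, dim = c(24, 24, 6))
  v[4:8, 4:6, 2] <- 400     # inside ROI
  v[16:20, 16:18, 4] <- 400 # outside ROI
  vol <- image_volume(v, c(0.5, 0.5, 3))
  roi <- array(FALSE, dim = dim(v)); roi[1:12, 1:12, ] <- TRUE
  les <- find_lesions(vol, roi)
  expect_length(les$lesions, 1)
  all_les <- find_lesions(vol, full_mask(vol))
  expect_equal(agatston_score(les) * 2, agatston_score(all_les))
})

test_that("adding a qualifying calcified voxel never decreases any score", {
  set.seed(9)
  for (rep in 1:5) {
    v <- array(30, dim = c(20, 20, 5))
    v[6:10, 6:8, 2] <- stats::runif(1, 200, 800)
    vol <- image_volume(v, c(0.5, 0.5, 3))
    les0 <- find_lesions(vol, full_mask(vol))
    v[11, 6:8, 2] <- stats::runif(1, 130, 900)  # grow the lesion
    vol2 <- image_volume(v, c(0.5, 0.5, 3))
    les1 <- find_lesions(vol2, full_mask(vol2))
    expect_gte(agatston_score(les1), agatston_score(les0))
    expect_gte(volume_score(les1), volume_score(les0))
    expect_gte(mass_score(les1), mass_score(les0))
  }
})

test_that("severity bins and sex-specific flags follow the policy", {
  s <- severity(0, "female")
  expect_identical(s$severity_bin, "0")
  expect_false(s$severe)
  expect_identical(severity(2500, "male")$severity_bin, "2000+")
  expect_true(severity(2500, "male")$severe)
  s_f <- severity(1250, "female"); s_m <- severity(1250, "male")
  expect_identical(s_f$severity_bin, "1200-2000")
  expect_identical(s_m$severity_bin, "1200-2000")
  expect_true(s_f$severe); expect_false(s_m$severe)
  # unlikely-severe thresholds (1600 male / 800 female)
  expect_true(severity(700, "female")$unlikely_severe)
  expect_false(severity(900, "female")$unlikely_severe)
  expect_true(severity(1500, "male")$unlikely_severe)
  # unknown sex: bin reported, flags absent
  u <- severity(1250, "unknown")
  expect_identical(u$severity_bin, "1200-2000")
  expect_true(is.na(u$severe))
  expect_error(severity(-1, "male"), "negative")
  # boundary scores land in the lower bin (strict > for the next bin)
  expect_identical(severity(800, "female")$severity_bin, "1-800")
  expect_identical(severity(2000, "male")$severity_bin, "1200-2000")
  expect_false(severity(2000, "male")$severe)
})

test_that("fast scoring matches the scalar reference implementation exactly", {
  set.seed(13)
  for (rep in 1:6) {
    d <- c(sample(16:28, 2, replace = TRUE), sample(4:8, 1))
    v <- array(stats::rnorm(prod(d), 40, 30), dim = d)
    nb <- sample(1:4, 1)
    for (b in seq_len(nb)) {
      c0 <- sapply(d, function(k) sample(3:(k - 3), 1))
      w <- sample(1:3, 3, replace = TRUE)
      v[(c0[1] - w[1]):(c0[1] + w[1]), (c0[2] - w[2]):(c0[2] + w[2]),
        max(c0[3] - 1, 1):min(c0[3] + 1, d[3])] <- stats::runif(1, 140, 900)
    }
    vol <- image_volume(v, c(stats::runif(2, 0.35, 0.9), stats::runif(1, 2.5, 3)))
    roi <- array(stats::runif(prod(d)) > 0.2, dim = d)
    ref <- score_reference(vol, roi)
    les <- find_lesions(vol, roi)
    expect_equal(agatston_score(les), ref$agatston, tolerance = 1e-12)
    expect_equal(volume_score(les), ref$volume_mm3, tolerance = 1e-12)
    expect_equal(mass_score(les), ref$mass_mg, tolerance = 1e-12)
    expect_identical(length(les$lesions), ref$n_lesions)
    expect_identical(count_valid_lesions(les), as.integer(ref$n_valid_lesions))
  }
})
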