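test_that("PCA frame of a flat axis-aligned disk is the z axis", {
  disk <- flat_disk()
  fr <- fit_local_frame(disk, c(1, 1, 1))
  expect_equal(fr$pc3, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$centroid_mm, colMeans(disk$disk_voxels) - 1, tolerance = 1e-12)
  # anisotropic spacing leaves the normal of a z-slice disk unchanged
  fr2 <- fit_local_frame(disk, c(0.5, 0.5, 3))
  expect_equal(fr2$pc3, c(0, 0, 1), tolerance = 1e-12)
})

test_that("PCA frame recovers an exactly planar tilted disk", {
  td <- tilted_disk(30)
  fr <- fit_local_frame(td$disk, td$spacing)
  expect_equal(fr$pc3, td$normal, tolerance = 1e-6)
})

test_that("fitted frames are orthonormal and degenerate disks error", {
  set.seed(11)
  for (rep in 1:10) {
    td <- tilted_disk(stats::runif(1, 5, 55), extent = sample(6:14, 1))
    fr <- fit_local_frame(td$disk, td$spacing)
    M <- cbind(fr$pc1, fr$pc2, fr$pc3)
    expect_lt(max(abs(crossprod(M) - diag(3))), 1e-8)
    expect_gte(fr$pc3[3], 0)
  }
  line <- disk_annotation(cbind(1:10, 5, 5), c(5, 5, 5))
  expect_error(fit_local_frame(line, c(1, 1, 1)), "degenerate")
  expect_error(fit_local_frame(disk_annotation(cbind(1, 1, 1), c(1, 1, 1)),
                               c(1, 1, 1)), "degenerate")
})

test_that("disk radius is the largest in-plane distance from the centre", {
  single <- disk_annotation(matrix(c(5, 5, 3), 1), c(5, 5, 3))
  # radius needs >= 4 voxels for the frame; fit from a flat disk instead
  fr <- fit_local_frame(flat_disk(), c(1, 1, 1))
  expect_equal(disk_radius(single, fr, c(1, 1, 1)), 0)
  # circular disk of mm radius 10 at 0.5 mm spacing
  disk <- flat_disk(radius_vox = 20, centre = c(25, 25, 5), n = 49)
  fr <- fit_local_frame(disk, c(0.5, 0.5, 3))
  expect_equal(disk_radius(disk, fr, c(0.5, 0.5, 3)), 10, tolerance = 0.25)
  # ellipse with semi-axes 8 and 11 mm
  ij <- expand.grid(i = 1:49, j = 1:49)
  ij <- ij[((ij$i - 25) / 16)^2 + ((ij$j - 25) / 22)^2 <= 1, ]
  ell <- disk_annotation(cbind(ij$i, ij$j, 5), c(25, 25, 5))
  fr <- fit_local_frame(ell, c(0.5, 0.5, 3))
  expect_equal(disk_radius(ell, fr, c(0.5, 0.5, 3)), 11, tolerance = 0.25)
})

test_that("disk-to-cylinder expansion matches the analytic volume", {
  # fractional annotated centre and sub-voxel slice spacing keep the
  # cylinder boundary off the voxel lattice in every direction
  disk <- flat_disk(radius_vox = 8, centre = c(33, 33, 45), n = 65)
  disk$center_voxel <- c(33.42, 33.17, 45)
  sp <- c(1, 1, 0.8)
  grid <- list(dim = c(65, 65, 90), spacing = sp)
  fr <- fit_local_frame(disk, sp)
  r_final <- disk_radius(disk, fr, sp) + 2
  mask <- expand_disk_to_cylinder(disk, fr, expansion_config(), grid)
  expect_equal(sum(mask) * prod(sp), pi * r_final^2 * 40, tolerance = 0.02)
  # strictness of the height rule: tiny height keeps only the centre plane
  cfgish <- expansion_config(delta_r_mm = 0, dA_mm = 0.5, dB_mm = 0.5)
  thin <- expand_disk_to_cylinder(disk, fr, cfgish, grid)
  expect_true(all(which(thin, arr.ind = TRUE)[, 3] == 45))
  expect_error(expansion_config(dA_mm = 0, dB_mm = 0), "positive")
  expect_error(expansion_config(delta_r_mm = -1), ">= 0")
})

test_that("vectorized voxelization matches the scalar oracle voxel for voxel", {
  set.seed(21)
  for (rep in 1:8) {
    g <- list(dim = sample(14:30, 3, replace = TRUE),
              spacing = c(stats::runif(2, 0.4, 1.2), stats::runif(1, 2, 3)))
    n <- rand_axis()
    ref <- g$dim * g$spacing / 2 + stats::rnorm(3)
    r <- stats::runif(1, 3, 9)
    zl <- -stats::runif(1, 2, 10); zh <- stats::runif(1, 2, 10)
    fast <- avcscore:::voxelize_cylinder(n, ref, r, zl, zh, g, warn_clip = FALSE)
    slow <- voxelize_cylinder_reference(n, ref, r, zl, zh, g)
    expect_identical(fast, slow)
  }
})

test_that("reconstruction handles degenerate and non-unit inputs", {
  grid <- list(dim = c(32, 32, 32), spacing = c(1, 1, 1))
  expect_error(cylinder_params(c(0, 0, 1.1), c(16, 16, 16), 5, 10), "unit")
  p <- cylinder_params(c(0, 0, 1 + 5e-4), c(16, 16, 16), 5, 10)
  expect_equal(sqrt(sum(p$normal^2)), 1, tolerance = 1e-12)
  tiny <- cylinder_params(c(0, 0, 1), c(16, 16, 16), 0.3, 10)
  expect_warning(m <- reconstruct_cylinder_mask(tiny, grid), "empty")
  expect_equal(sum(m), 0)
})

test_that("translating the origin along the normal shifts the mask centroid", {
  grid <- list(dim = c(48, 48, 48), spacing = c(1, 1, 1))
  n <- c(0, 0, 1)
  p1 <- cylinder_params(n, c(24, 24, 20), 10, 16)
  p2 <- cylinder_params(n, c(24, 24, 25), 10, 16)
  c1 <- cylinder_origin_from_mask(reconstruct_cylinder_mask(p1, grid), grid)
  c2 <- cylinder_origin_from_mask(reconstruct_cylinder_mask(p2, grid), grid)
  expect_equal(c2 - c1, c(0, 0, 5), tolerance = 0.5)
})

test_that("mask centre of mass is the unweighted mm centroid", {
  grid <- list(dim = c(8, 8, 4) + 4, spacing = c(1, 1, 1))
  m <- array(FALSE, dim = grid$dim)
  m[1, 1, 1] <- TRUE
  m[3, 1, 1] <- TRUE
  expect_equal(cylinder_origin_from_mask(m, grid), c(1, 0, 0))
  expect_error(cylinder_origin_from_mask(array(FALSE, grid$dim), grid), "empty")
})

test_that("parameterize/reconstruct round trip recovers generated cylinders", {
  set.seed(31)
  grid <- list(dim = c(72, 72, 72), spacing = c(1, 1, 1))
  for (rep in 1:6) {
    p <- cylinder_params(rand_axis(30), c(36, 36, 36) + stats::rnorm(3, 0, 2),
                         stats::runif(1, 16, 22), 40)
    mask <- reconstruct_cylinder_mask(p, grid)
    est <- parameterize_mask(mask, grid)
    expect_lt(sqrt(sum((est$origin_mm - p$origin_mm)^2)), sqrt(3) / 2)
    expect_lt(abs(est$radius_mm - p$radius_mm), 1)
    expect_gte(abs(sum(est$normal * p$normal)), 0.999)
    expect_gte(dice_coef(reconstruct_cylinder_mask(est, grid), mask), 0.99)
  }
  # smaller cylinders still round trip with high overlap
  p <- cylinder_params(c(0, 0, 1), c(36, 36, 36), 8, 30)
  mask <- reconstruct_cylinder_mask(p, grid)
  est <- parameterize_mask(mask, grid)
  expect_gte(dice_coef(reconstruct_cylinder_mask(est, grid), mask), 0.99)
})

test_that("physical results are invariant to the sampling grid", {
  # the same physical cylinder rasterized on two grids has matching volume
  p <- cylinder_params(c(0.2, -0.1, sqrt(1 - 0.05)), c(30, 30, 30), 12, 30)
  g1 <- list(dim = c(60, 60, 60), spacing = c(1, 1, 1))
  g2 <- list(dim = c(120, 120, 24), spacing = c(0.5, 0.5, 2.5))
  v1 <- sum(reconstruct_cylinder_mask(p, g1)) * prod(g1$spacing)
  v2 <- sum(reconstruct_cylinder_mask(p, g2)) * prod(g2$spacing)
  expect_equal(v1, v2, tolerance = 0.04)
})

test_that("crop-space mapping is a lossless round trip", {
  crop <- grid_crop(crop_offset = c(10, 20, 5), crop_shape = c(64, 64, 64),
                    orig_shape = c(120, 120, 40),
                    orig_spacing = c(0.5, 0.5, 2.5))
  p <- cylinder_params(c(0, 0, 1), c(30, 28, 40), 18, 40)
  pc <- map_params_between_spaces(p, crop, "to_crop")
  expect_equal(pc$origin_mm, p$origin_mm - c(10, 20, 5))
  expect_equal(pc$radius_mm, p$radius_mm)
  back <- map_params_between_spaces(pc, crop, "to_acquisition")
  expect_equal(back$origin_mm, p$origin_mm, tolerance = 1e-6)
  # identity crop
  id <- grid_crop(c(0, 0, 0), c(64, 64, 64), c(64, 64, 64), c(1, 1, 1))
  expect_equal(map_params_between_spaces(p, id, "to_crop")$origin_mm, p$origin_mm)
  # random round trips
  set.seed(41)
  for (rep in 1:10) {
    cr <- grid_crop(stats::rnorm(3, 0, 20), c(64, 64, 64), c(200, 200, 80),
                    c(stats::runif(2, 0.3, 0.6), stats::runif(1, 2.5, 3)))
    pr <- cylinder_params(rand_axis(), stats::runif(3, 20, 60),
                          stats::runif(1, 16, 22), 40)
    rt <- map_params_between_spaces(
      map_params_between_spaces(pr, cr, "to_crop"), cr, "to_acquisition")
    expect_equal(rt$origin_mm, pr$origin_mm, tolerance = 1e-6)
    expect_equal(rt$normal, pr$normal)
  }
  # a crop that would land the centre outside the field of view errors
  far <- cylinder_params(c(0, 0, 1), c(500, 0, 0), 18, 40, space = "iso_crop")
  expect_error(map_params_between_spaces(far, crop, "to_acquisition"),
               "field of view")
})

test_that("cylinder parameters serialize to JSON and back", {
  p <- cylinder_params(rand_axis(), c(12.5, 8, 30), 19.25, 40,
                       dA_mm = 10, dB_mm = 30)
  tf <- withr::local_tempfile(fileext = ".json")
  params_to_json(p, tf)
  q <- params_from_json(tf)
  expect_equal(q$normal, p$normal, tolerance = 1e-12)
  expect_equal(q$origin_mm, p$origin_mm)
  expect_equal(q$radius_mm, p$radius_mm)
  expect_equal(q$dB_mm, 30)
  expect_equal(q$space, "acquisition")
})
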