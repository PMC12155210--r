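test_that("radius rescaling is the exact affine map and inverse", {
  expect_equal(encode_radius(20), 0)
  expect_equal(encode_radius(40), 1)
  for (v in c(-0.2, 0.1)) expect_equal(encode_radius(decode_radius(v)), v)
  for (r in c(16, 19.3, 22)) expect_equal(decode_radius(encode_radius(r)), r)
  expect_error(encode_radius(0), "\\(0, 40]")
  expect_error(encode_radius(41), "\\(0, 40]")
  expect_error(decode_radius(-1), "\\(0, 40]")
})

test_that("parameter encoding round trips through the crop geometry", {
  shape <- c(64, 64, 64)
  p <- cylinder_params(rand_axis(), c(30.5, 28, 40.25), 18.5, 40,
                       space = "iso_crop")
  v <- encode_cylinder_params(p, shape)
  expect_length(v, 7)
  expect_true(all(abs(v) <= 1))
  q <- decode_cylinder_params(v, shape)
  expect_equal(q$normal, p$normal, tolerance = 1e-9)
  expect_equal(q$origin_mm, p$origin_mm, tolerance = 1e-9)
  expect_equal(q$radius_mm, p$radius_mm, tolerance = 1e-9)
  expect_equal(q$height_mm, 40)
})

test_that("the network exposes the contracted shapes", {
  net <- build_network(c(64, 64, 64), base_channels = 8, seed = 2)
  expect_identical(n_regressed_params(net), 7L)
  expect_identical(nrow(net$par$W3), 32L)          # latent channels = 4C
  expect_identical(ncol(net$par$Wm1), 32L)         # pooled descriptor length
  # the default width gives the 256-channel latent descriptor
  netd <- build_network(c(176, 176, 128), seed = 2)
  expect_identical(ncol(netd$par$Wm1), 256L)
  expect_error(build_network(c(60, 64, 64)), "divisible by 8")
  # forward pass on zeros is finite, 7 outputs in [-1, 1]
  fw <- avcscore:::net_forward(net, numeric(64^3))
  expect_true(all(is.finite(fw$logits)))
  expect_length(fw$pv, 7)
  expect_true(all(abs(fw$pv) <= 1))
  expect_error(avcscore:::net_forward(net, numeric(10)), "incompatible")
})

test_that("soft reconstruction converges to the exact cylinder", {
  grid <- list(dim = c(64, 64, 64), spacing = c(1, 1, 1))
  p <- cylinder_params(rand_axis(25), c(32, 32, 32), 18, 40)
  soft <- soft_reconstruct(p, grid, k = 50)
  hard <- reconstruct_cylinder_mask(p, grid)
  expect_gte(dice_coef(soft >= 0.5, hard), 0.995)
  # on the axis centre the membership tends to 1; far outside to 0
  expect_gt(soft[33, 33, 33], 0.999)
  expect_lt(soft[2, 2, 2], 1e-6)
  expect_error(soft_reconstruct(
    cylinder_params(c(0, 0, 1), c(NaN, 0, 0), 5, 10), grid), "finite")
})

test_that("the reconstruction loss is differentiable in all 7 parameters", {
  shape <- c(32, 32, 32)
  rg <- avcscore:::recon_grid(shape, 2L)
  truth_p <- cylinder_params(c(0.1, -0.2, sqrt(1 - 0.05)), c(16, 16, 16), 8, 20,
                             space = "iso_crop")
  truth <- as.numeric(reconstruct_cylinder_mask(truth_p, rg$grid))
  pv <- c(0.05, 0.1, 0.8, 0.05, -0.03, 0.02, -0.5)  # a misfit cylinder
  rl <- avcscore:::recon_loss_grad(pv, truth, rg$coords, shape,
                                   height_mm = 20)
  expect_true(all(is.finite(rl$dpv)))
  expect_gt(abs(rl$dpv[7]), 0)  # radius gradient nonzero for a misfit
  eps <- 1e-6
  for (j in c(1, 4, 7)) {
    p1 <- pv; p1[j] <- p1[j] + eps
    p2 <- pv; p2[j] <- p2[j] - eps
    fd <- (avcscore:::recon_loss_grad(p1, truth, rg$coords, shape, height_mm = 20)$loss -
           avcscore:::recon_loss_grad(p2, truth, rg$coords, shape, height_mm = 20)$loss) /
      (2 * eps)
    expect_equal(rl$dpv[j], fd, tolerance = 1e-4)
  }
})

test_that("network gradients agree with finite differences", {
  set.seed(8)
  net <- build_network(c(16, 16, 16), base_channels = 2, dropout = 0, seed = 3)
  x <- stats::runif(16^3)
  truth <- as.numeric(stats::runif(16^3) > 0.75)
  pv_true <- c(0.1, -0.2, 0.9, 0, 0.1, -0.1, 0.05)
  rg <- avcscore:::recon_grid(c(16, 16, 16), 2L)
  rtruth <- as.numeric(stats::runif(nrow(rg$coords)) > 0.8)
  w <- loss_weights()
  lossfun <- function(nn) {
    fw <- avcscore:::net_forward(nn, x)
    sg <- avcscore:::seg_dice_loss(fw$logits, truth)
    rl <- avcscore:::recon_loss_grad(fw$pv, rtruth, rg$coords, c(16, 16, 16))
    w[["alpha"]] * sg$loss + w[["beta"]] * mean((fw$pv[4:6] - pv_true[4:6])^2) +
      w[["delta"]] * mean((fw$pv[c(1:3, 7)] - pv_true[c(1:3, 7)])^2) +
      w[["gamma"]] * rl$loss
  }
  fw <- avcscore:::net_forward(net, x)
  sg <- avcscore:::seg_dice_loss(fw$logits, truth)
  rl <- avcscore:::recon_loss_grad(fw$pv, rtruth, rg$coords, c(16, 16, 16))
  dpv <- numeric(7)
  dpv[4:6] <- w[["beta"]] * 2 * (fw$pv[4:6] - pv_true[4:6]) / 3
  dpv[c(1:3, 7)] <- dpv[c(1:3, 7)] +
    w[["delta"]] * 2 * (fw$pv[c(1:3, 7)] - pv_true[c(1:3, 7)]) / 4
  dpv <- dpv + w[["gamma"]] * rl$dpv
  gr <- avcscore:::net_backward(net, fw$cache, w[["alpha"]] * sg$dlogits, dpv)
  eps <- 1e-6
  for (nm in c("W1", "W4", "W6", "Wm2", "ln_g")) {
    p0 <- net$par[[nm]]
    for (i in sample(length(p0), 2)) {
      n2 <- net
      n2$par[[nm]][i] <- p0[i] + eps
      lp <- lossfun(n2)
      n2$par[[nm]][i] <- p0[i] - eps
      lm <- lossfun(n2)
      expect_equal(gr[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-4,
                   info = nm)
    }
  }
})

test_that("combined loss decomposes exactly by its weights", {
  logits <- c(4, -4, 2, -2)
  truth <- c(1, 0, 1, 0)
  pv <- c(0.2, 0, 0.9, 0.1, 0, 0, 0.2)
  pt <- c(0.1, 0, 0.95, 0, 0, 0, 0.15)
  full <- combined_loss(logits, truth, pv, pt)
  expect_equal(full$total, sum(0.25 * full$terms))
  # identical parameters zero the MSE terms
  same <- combined_loss(logits, truth, pv, pv)
  expect_equal(same$terms[["mse_origin"]], 0)
  expect_equal(same$terms[["mse_normal_radius"]], 0)
  # branch-1-only configuration keeps exactly the segmentation term
  seg_only <- combined_loss(logits, truth, pv, pt,
                            weights = loss_weights(1, 0, 0, 0))
  expect_equal(seg_only$total, seg_only$terms[["dice_seg"]])
  # branch 2+3 only drops the segmentation term
  reg_only <- combined_loss(logits, truth, pv, pt,
                            weights = loss_weights(0, 1 / 3, 1 / 3, 1 / 3))
  expect_equal(reg_only$terms[["dice_seg"]], 0)
  expect_error(loss_weights(-0.1), "non-negative")
})

test_that("CoM linkage overrides the regressed origin on ideal masks", {
  shape <- c(32, 32, 32)
  grid <- list(dim = shape, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  p <- cylinder_params(c(0, 0, 1), c(16, 15, 17), 9, 20, space = "iso_crop")
  mask <- reconstruct_cylinder_mask(p, grid)
  # fabricate a forward result: confident exact mask, arbitrary regression
  fw <- list(logits = ifelse(as.vector(mask), 10, -10),
             pv = c(0, 0, 0.9, 0.5, -0.5, 0.5, -0.1))
  pred <- avcscore:::predict_params_crop(fw, shape)
  com <- cylinder_origin_from_mask(mask, grid)
  expect_equal(pred$params$origin_mm, com, tolerance = 1e-9)
  expect_false(pred$fallback)
  expect_lt(sqrt(sum((pred$params$origin_mm - p$origin_mm)^2)), sqrt(3) / 2)
  # empty segmentation falls back to the regressed origin with a flag
  fw0 <- list(logits = rep(-10, prod(shape)), pv = fw$pv)
  pred0 <- avcscore:::predict_params_crop(fw0, shape)
  expect_true(pred0$fallback)
  dec <- decode_cylinder_params(avcscore:::clamp_pv(fw$pv), shape)
  expect_equal(pred0$params$origin_mm, dec$origin_mm)
  # predicted normals are unit length
  expect_equal(sqrt(sum(pred$params$normal^2)), 1, tolerance = 1e-9)
})

test_that("dataset splits are deterministic and complete", {
  cfg <- train_config(batch_size = 2, epochs = 1, seed = 99)
  s1 <- avcscore:::split_dataset(310, cfg)
  s2 <- avcscore:::split_dataset(310, cfg)
  expect_identical(s1, s2)
  expect_identical(sort(c(s1$train, s1$val, s1$test)), 1:310)
  expect_length(s1$train, floor(0.65 * 310))
  expect_length(s1$val, floor(0.15 * 310))
  # explicit counts reproduce the published 200 / 49 / 61 partition
  cfg2 <- train_config(split_counts = c(200, 49, 61), seed = 1)
  s3 <- avcscore:::split_dataset(310, cfg2)
  expect_length(s3$train, 200)
  expect_length(s3$val, 49)
  expect_length(s3$test, 61)
  expect_error(avcscore:::split_dataset(10, train_config(split_counts = c(9, 2, 1))),
               "sum")
})

test_that("training rejects datasets smaller than one batch and is seeded", {
  ph <- quick_phantom(seed = 90, blobs = NULL)
  # a 32 mm crop cannot hold the 40 mm cylinder: clipping is expected here
  ds <- suppressWarnings(phantom_dataset(list(ph, ph, ph),
                                         out_shape = c(32, 32, 32)))
  net <- build_network(c(32, 32, 32), base_channels = 2, seed = 1)
  expect_error(suppressWarnings(split_and_train(ds, net, train_config(batch_size = 8))),
               "smaller than one batch")
  cfg <- train_config(batch_size = 2, epochs = 1, lr = 1e-3, seed = 7,
                      split_counts = c(2, 1, 0))
  r1 <- suppressWarnings(split_and_train(ds, net, cfg))
  r2 <- suppressWarnings(split_and_train(ds, net, cfg))
  expect_identical(r1$net$par, r2$net$par)
  expect_identical(nrow(r1$log), 1L)
})

test_that("cylinder agreement metrics behave on identical and shifted pairs", {
  grid <- list(dim = c(48, 48, 48), spacing = c(1, 1, 1))
  p <- cylinder_params(c(0, 0, 1), c(24, 24, 24), 12, 30)
  m_same <- cyl_metrics(p, p, grid)
  expect_equal(m_same$dice, 1)
  expect_equal(m_same$hausdorff_mm, 0)
  expect_equal(m_same$origin_err_mm, 0)
  expect_equal(m_same$normal_cos, 1)
  q <- cylinder_params(c(0, 0, 1), c(27, 24, 24), 12, 30)
  m_shift <- cyl_metrics(q, p, grid)
  expect_lt(m_shift$dice, 1)
  expect_equal(m_shift$origin_err_mm, 3)
  expect_equal(m_shift$hausdorff_mm, 3, tolerance = 0.8)
})
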