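# Multi-task cylinder model: parameter encoding, the differentiable
# soft-cylinder reconstruction (branch 3), the combined loss, training with
# Adam, and inference with centre-of-mass origin linkage.

#' Loss weights of the three branches
#'
#' `alpha` scales the segmentation Dice loss (branch 1), `beta` the origin
#' MSE and `delta` the normal+radius MSE (branch 2), `gamma` the
#' reconstructed-cylinder Dice loss (branch 3). Defaults are all 1/4;
#' zeroing a weight removes exactly that term, reproducing the ablation
#' configurations (segmentation only: `c(1,0,0,0)`; regression +
#' reconstruction only: `c(0, beta, delta, gamma)`).
#'
#' @param alpha,beta,delta,gamma non-negative weights.
#' @return A named numeric vector of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.25, beta = 0.25, delta = 0.25, gamma = 0.25) {
  w <- c(alpha = alpha, beta = beta, delta = delta, gamma = gamma)
  if (any(w < 0)) stop("loss weights must be non-negative")
  structure(w, class = c("loss_weights", "numeric"))
}

#' Encode / decode the cylinder radius for tanh regression
#'
#' The radius (valve cohort range 16-22 mm) is affinely rescaled to
#' \[-1, 1\] via `r_rescaled = 2 * (r / 40) - 1` so all seven regression
#' targets share the tanh output scale; `decode_radius` is the exact
#' inverse.
#'
#' @param r_mm radius in (0, 40\].
#' @param v rescaled value in \[-1, 1\].
#' @return Rescaled value / radius in mm.
#' @export
encode_radius <- function(r_mm) {
  if (any(r_mm <= 0 | r_mm > 40)) stop("radius must lie in (0, 40] mm")
  2 * (r_mm / 40) - 1
}

#' @rdname encode_radius
#' @export
decode_radius <- function(v) {
  r <- 20 * (v + 1)
  if (any(r <= 0 | r > 40)) stop("encoded radius outside (0, 40] mm")
  r
}

# mm extent of a crop-space grid (coordinates run 0 .. extent)
crop_extent <- function(shape, iso = 1) (shape - 1) * iso

#' Encode cylinder parameters as the 7-vector regression target
#'
#' Normal components are already in \[-1, 1\]; origin coordinates are
#' normalized to \[-1, 1\] over the crop extent; the radius uses
#' [encode_radius()]. Height is not regressed (fixed 40 mm).
#'
#' @param p a [cylinder_params] in `iso_crop` space.
#' @param shape crop grid shape.
#' @param iso isotropic spacing, mm.
#' @return Numeric length-7 vector `(mu_x, mu_y, mu_z, x0, y0, z0, r)`.
#' @export
encode_cylinder_params <- function(p, shape, iso = 1) {
  ext <- crop_extent(shape, iso)
  c(p$normal, 2 * p$origin_mm / ext - 1, encode_radius(p$radius_mm))
}

#' Decode a 7-vector regression output into cylinder parameters
#'
#' @param v numeric length-7 in \[-1, 1\].
#' @param shape,iso crop grid geometry.
#' @param height_mm fixed cylinder height (default 40).
#' @return A [cylinder_params] in `iso_crop` space.
#' @export
decode_cylinder_params <- function(v, shape, iso = 1, height_mm = 40) {
  ext <- crop_extent(shape, iso)
  n <- v[1:3]
  nn <- sqrt(sum(n^2))
  if (nn < 1e-6) stop("degenerate regressed normal")
  cylinder_params(n / nn, (v[4:6] + 1) / 2 * ext, decode_radius(v[7]),
                  height_mm, space = "iso_crop")
}

#' Differentiable soft cylinder mask
#'
#' Smooth membership `sigmoid(k (r - rho)) * sigmoid(k (h/2 - |z'|))`
#' evaluated at voxel centres; thresholding at 0.5 converges to the exact
#' strict-inequality cylinder as the sharpness `k` grows.
#'
#' @param p a [cylinder_params].
#' @param grid grid geometry.
#' @param k edge sharpness in 1/mm (default 50).
#' @return Numeric array in \[0, 1\].
#' @export
soft_reconstruct <- function(p, grid, k = 50) {
  if (!all(is.finite(c(p$normal, p$origin_mm, p$radius_mm, p$height_mm))))
    stop("non-finite cylinder parameters")
  g <- as_grid_geometry(grid)
  co <- grid_coords(g)
  m <- soft_cyl_values(p$normal, p$origin_mm, p$radius_mm, p$height_mm, co, k)
  array(m$m, dim = g$dim)
}

# voxel-centre coordinates of a grid as an N x 3 matrix
grid_coords <- function(g) {
  xs <- g$origin[1] + (seq_len(g$dim[1]) - 1) * g$spacing[1]
  ys <- g$origin[2] + (seq_len(g$dim[2]) - 1) * g$spacing[2]
  zs <- g$origin[3] + (seq_len(g$dim[3]) - 1) * g$spacing[3]
  cbind(coord_field(xs, 0 * ys, 0 * zs),
        coord_field(0 * xs, ys, 0 * zs),
        coord_field(0 * xs, 0 * ys, zs))
}

# soft membership + the per-voxel pieces needed for gradients
soft_cyl_values <- function(n, o, r, h, coords, k) {
  d <- sweep(coords, 2, o)
  zp <- as.vector(d %*% n)
  az <- abs(zp)
  rho <- sqrt(pmax(rowSums(d^2) - zp^2, 1e-12))
  s1 <- sigmoid(k * (r - rho))
  s2 <- sigmoid(k * (h / 2 - az))
  list(m = s1 * s2, d = d, zp = zp, az = az, rho = rho, s1 = s1, s2 = s2)
}

# soft Dice_recon loss and its gradient w.r.t. the raw 7-vector pv
recon_loss_grad <- function(pv, truth, coords, shape, iso = 1, k = 50,
                            height_mm = 40, eps = 1e-6) {
  ext <- crop_extent(shape, iso)
  w <- pv[1:3]
  nw <- sqrt(sum(w^2))
  if (nw < 1e-6) return(list(loss = 1, dpv = numeric(7)))
  n <- w / nw
  o <- (pv[4:6] + 1) / 2 * ext
  r <- 20 * (pv[7] + 1)
  sc <- soft_cyl_values(n, o, r, height_mm, coords, k)
  S <- sum(sc$m) + sum(truth) + eps
  I <- sum(sc$m * truth)
  loss <- 1 - 2 * I / S
  a <- -2 * truth / S + 2 * I / S^2          # dL/dm
  c1 <- a * k * sc$s1 * (1 - sc$s1) * sc$s2  # along (r - rho)
  c2 <- a * k * sc$s2 * (1 - sc$s2) * sc$s1  # along (h/2 - |z'|)
  dr <- sum(c1)
  sgn <- sign(sc$zp)
  do <- colSums((c1 / sc$rho) * sc$d) -
    n * sum(c1 * sc$zp / sc$rho) + n * sum(c2 * sgn)
  dn <- colSums((c1 * sc$zp / sc$rho - c2 * sgn) * sc$d)
  # through the normalization n = w / |w|
  dw <- (dn - n * sum(dn * n)) / nw
  dpv <- c(dw, do * ext / 2, dr * 20)
  list(loss = loss, dpv = dpv)
}

# segmentation soft Dice loss and gradient w.r.t. logits
seg_dice_loss <- function(logits, truth, eps = 1e-6) {
  p <- sigmoid(logits)
  S <- sum(p) + sum(truth) + eps
  I <- sum(p * truth)
  loss <- 1 - 2 * I / S
  dp <- -2 * truth / S + 2 * I / S^2
  list(loss = loss, dlogits = dp * p * (1 - p))
}

#' Combined multi-task loss
#'
#' `alpha * Dice(segmentation) + beta * MSE(origin) + delta * MSE(normal,
#' radius) + gamma * Dice_recon`, with the MSE terms evaluated on the
#' \[-1, 1\]-encoded parameters so all targets share one scale, and the
#' reconstruction term evaluated on a (possibly strided) crop-space grid.
#'
#' @param seg_logits numeric vector of segmentation logits.
#' @param seg_true logical/0-1 vector of the truth mask.
#' @param params_pred,params_true encoded 7-vectors.
#' @param weights a [loss_weights].
#' @param recon list with `coords` (N x 3), `truth` (0/1 length N),
#'   `shape`, and optional `iso`, `k`; NULL skips branch 3 even when
#'   `gamma > 0`.
#' @return List with `total` and the individual `terms`.
#' @export
combined_loss <- function(seg_logits, seg_true, params_pred, params_true,
                          weights = loss_weights(), recon = NULL) {
  terms <- c(dice_seg = 0, mse_origin = 0, mse_normal_radius = 0, dice_recon = 0)
  if (weights[["alpha"]] > 0) {
    terms[["dice_seg"]] <- seg_dice_loss(seg_logits, seg_true)$loss
  }
  terms[["mse_origin"]] <- mean((params_pred[4:6] - params_true[4:6])^2)
  terms[["mse_normal_radius"]] <- mean((params_pred[c(1:3, 7)] - params_true[c(1:3, 7)])^2)
  if (weights[["gamma"]] > 0 && !is.null(recon)) {
    rl <- recon_loss_grad(params_pred, recon$truth, recon$coords, recon$shape,
                          iso = recon$iso %||% 1, k = recon$k %||% 50)
    terms[["dice_recon"]] <- rl$loss
  }
  total <- weights[["alpha"]] * terms[["dice_seg"]] +
    weights[["beta"]] * terms[["mse_origin"]] +
    weights[["delta"]] * terms[["mse_normal_radius"]] +
    weights[["gamma"]] * terms[["dice_recon"]]
  list(total = total, terms = terms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Training configuration
#'
#' @param batch_size cases per optimizer step (default 8).
#' @param epochs training epochs (default 600; the desk preset uses far
#'   fewer).
#' @param split fractions for train / validation / held-out test
#'   (default 65/15/20; per-bucket rounding: floor for train and
#'   validation, remainder to test — override with `split_counts`).
#' @param split_counts optional explicit integer counts overriding `split`.
#' @param augment_sd Gaussian intensity augmentation on the \[0, 1\]
#'   normalized input (default 0.1).
#' @param lr Adam learning rate.
#' @param weights a [loss_weights].
#' @param recon_stride stride of the branch-3 reconstruction grid.
#' @param k_sharp soft-cylinder sharpness.
#' @param seed RNG seed controlling the split, shuffling, dropout and
#'   augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 8, epochs = 600,
                         split = c(0.65, 0.15, 0.20), split_counts = NULL,
                         augment_sd = 0.1, lr = 2e-3,
                         weights = loss_weights(), recon_stride = 2L,
                         k_sharp = 50, seed = 1L) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  structure(list(batch_size = batch_size, epochs = epochs, split = split,
                 split_counts = split_counts, augment_sd = augment_sd,
                 lr = lr, weights = weights, recon_stride = as.integer(recon_stride),
                 k_sharp = k_sharp, seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale preset
#'
#' A scaled-down configuration for CPU experimentation and testing:
#' 64^3 isotropic inputs, an 8-channel encoder, single-case batches and
#' 30 epochs at a conservative learning rate.
#'
#' @param seed RNG seed.
#' @return List with `input_shape`, `base_channels` and a [train_config].
#' @export
desk_preset <- function(seed = 1L) {
  list(input_shape = c(64L, 64L, 64L), base_channels = 8L,
       train = train_config(batch_size = 1, epochs = 30, lr = 1e-3, seed = seed))
}

split_dataset <- function(n, cfg) {
  counts <- cfg$split_counts
  if (is.null(counts)) {
    n_tr <- floor(cfg$split[1] * n)
    n_va <- floor(cfg$split[2] * n)
    counts <- c(n_tr, n_va, n - n_tr - n_va)
  }
  if (sum(counts) != n) stop("split counts must sum to the dataset size")
  ord <- with_seed(cfg$seed, function() sample.int(n))
  list(train = ord[seq_len(counts[1])],
       val = ord[counts[1] + seq_len(counts[2])],
       test = ord[counts[1] + counts[2] + seq_len(counts[3])])
}

#' Build a training dataset from phantoms
#'
#' Preprocesses each phantom exactly as a clinical case: isotropic
#' resampling and heart-window cropping, HU windowing to \[0, 1\], the
#' clean parameterized cylinder label rasterized in crop space, and the
#' encoded 7-parameter target.
#'
#' @param phantoms list of `phantom` objects.
#' @param out_shape crop/model input shape (default the 64^3 desk preset).
#' @return List of cases with `image`, `mask`, `pv`, `params_crop`, `crop`.
#' @export
phantom_dataset <- function(phantoms, out_shape = c(64, 64, 64)) {
  lapply(phantoms, function(ph) {
    rc <- resample_crop(ph$volume, ph$heart_bounds, out_shape = out_shape)
    img <- window_normalize(rc$volume)
    pc <- map_params_between_spaces(ph$params, rc$crop, "to_crop")
    pc <- cylinder_params(pc$normal, pc$origin_mm, pc$radius_mm, pc$height_mm,
                          space = "iso_crop")   # symmetric clean label
    grid <- list(dim = out_shape, spacing = rep(1, 3), origin = c(0, 0, 0))
    mask <- suppressWarnings(reconstruct_cylinder_mask(pc, grid))
    list(image = img$values, mask = mask,
         pv = encode_cylinder_params(pc, out_shape),
         params_crop = pc, crop = rc$crop, phantom_seed = ph$spec$seed)
  })
}

# strided reconstruction grid for branch 3
recon_grid <- function(shape, stride, iso = 1) {
  g <- list(dim = as.integer(ceiling(shape / stride)),
            spacing = rep(iso * stride, 3), origin = c(0, 0, 0))
  list(coords = grid_coords(g), shape = shape, grid = g)
}

#' Train the three-branch model
#'
#' Deterministically splits the dataset, then optimizes the combined loss
#' with Adam, applying on-the-fly Gaussian intensity augmentation to the
#' training images. Per-epoch validation tracks segmentation Dice, the
#' reconstructed-cylinder Dice obtained through the centre-of-mass origin
#' linkage, and the origin error in mm.
#'
#' @param dataset list of cases from [phantom_dataset()].
#' @param net an `avc_network` matching the case shape.
#' @param cfg a [train_config].
#' @param verbose print per-epoch progress.
#' @return List with the trained `net`, the split indices, and a `log`
#'   tibble of per-epoch metrics.
#' @export
split_and_train <- function(dataset, net, cfg = train_config(), verbose = FALSE) {
  n <- length(dataset)
  if (n < cfg$batch_size) stop("dataset smaller than one batch")
  shape <- net$cfg$input_shape
  sp <- split_dataset(n, cfg)
  rg <- recon_grid(shape, cfg$recon_stride)
  # truth masks on the reconstruction grid
  recon_truth <- lapply(dataset, function(cs)
    as.numeric(reconstruct_cylinder_mask(cs$params_crop, rg$grid)))
  state <- adam_init(net$par)
  log <- list()
  w <- cfg$weights
  with_seed(cfg$seed + 17L, function() {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(sp$train)
      ep_loss <- 0; nb <- 0
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
        acc <- NULL
        bl <- 0
        for (i in idx) {
          cs <- dataset[[i]]
          x <- as.vector(cs$image)
          if (cfg$augment_sd > 0)
            x <- x + stats::rnorm(length(x), 0, cfg$augment_sd)
          fw <- net_forward(net, x, train = TRUE)
          sg <- seg_dice_loss(fw$logits, as.numeric(cs$mask))
          rl <- recon_loss_grad(fw$pv, recon_truth[[i]], rg$coords, shape,
                                k = cfg$k_sharp)
          dpv <- numeric(7)
          dpv[4:6] <- w[["beta"]] * 2 * (fw$pv[4:6] - cs$pv[4:6]) / 3
          dpv[c(1:3, 7)] <- dpv[c(1:3, 7)] +
            w[["delta"]] * 2 * (fw$pv[c(1:3, 7)] - cs$pv[c(1:3, 7)]) / 4
          dpv <- dpv + w[["gamma"]] * rl$dpv
          dlogits <- w[["alpha"]] * sg$dlogits
          gr <- net_backward(net, fw$cache, dlogits, dpv)
          acc <- accum_grads(acc, gr)
          bl <- bl + w[["alpha"]] * sg$loss +
            w[["beta"]] * mean((fw$pv[4:6] - cs$pv[4:6])^2) +
            w[["delta"]] * mean((fw$pv[c(1:3, 7)] - cs$pv[c(1:3, 7)])^2) +
            w[["gamma"]] * rl$loss
        }
        acc <- scale_grads(acc, 1 / length(idx))
        st <- adam_step(net$par, acc, state, cfg$lr)
        net$par <<- st$par
        state <<- st$state
        ep_loss <- ep_loss + bl / length(idx); nb <- nb + 1
      }
      val <- evaluate_cases(net, dataset[sp$val], recon_grid = rg)
      log[[ep]] <<- tibble::tibble(epoch = ep, train_loss = ep_loss / max(nb, 1),
                                   val_dice_seg = mean(val$dice_seg),
                                   val_dice_recon = mean(val$dice_recon),
                                   val_origin_err_mm = mean(val$origin_err_mm),
                                   val_radius_err_mm = mean(val$radius_err_mm))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val seg %.3f  recon %.3f  origin %.2f mm",
                        ep, ep_loss / max(nb, 1), mean(val$dice_seg),
                        mean(val$dice_recon), mean(val$origin_err_mm)))
    }
  })
  list(net = net, split = sp, log = do.call(rbind, log))
}

# per-case validation metrics in crop space (CoM origin linkage applied)
evaluate_cases <- function(net, cases, recon_grid = NULL) {
  if (length(cases) == 0)
    return(tibble::tibble(dice_seg = NA_real_, dice_recon = NA_real_,
                          origin_err_mm = NA_real_, radius_err_mm = NA_real_,
                          normal_cos = NA_real_, com_fallback = NA))
  shape <- net$cfg$input_shape
  grid <- list(dim = shape, spacing = rep(1, 3), origin = c(0, 0, 0))
  out <- lapply(cases, function(cs) {
    fw <- net_forward(net, as.vector(cs$image), train = FALSE)
    pred <- predict_params_crop(fw, shape)
    rec <- suppressWarnings(reconstruct_cylinder_mask(pred$params, grid))
    seg <- array(sigmoid(fw$logits) >= 0.5, dim = shape)
    tibble::tibble(
      dice_seg = dice_coef(seg, cs$mask),
      dice_recon = dice_coef(rec, cs$mask),
      origin_err_mm = sqrt(sum((pred$params$origin_mm - cs$params_crop$origin_mm)^2)),
      radius_err_mm = abs(pred$params$radius_mm - cs$params_crop$radius_mm),
      normal_cos = abs(sum(pred$params$normal * cs$params_crop$normal)),
      com_fallback = pred$fallback)
  })
  do.call(rbind, out)
}

# decode a forward pass into crop-space params with CoM linkage
predict_params_crop <- function(fw, shape, threshold = 0.5, height_mm = 40) {
  grid <- list(dim = shape, spacing = rep(1, 3), origin = c(0, 0, 0))
  seg <- array(sigmoid(fw$logits) >= threshold, dim = shape)
  dec <- decode_cylinder_params(clamp_pv(fw$pv), shape, height_mm = height_mm)
  fallback <- !any(seg)
  origin <- if (fallback) dec$origin_mm else cylinder_origin_from_mask(seg, grid)
  list(params = cylinder_params(dec$normal, origin, dec$radius_mm, height_mm,
                                space = "iso_crop"),
       fallback = fallback, seg = seg)
}

clamp_pv <- function(pv) {
  pv[7] <- min(max(pv[7], -0.99), 0.99)
  pv
}

#' Predict the valve cylinder for one case
#'
#' Runs the network on a preprocessed isotropic crop, thresholds the
#' branch-1 segmentation at 0.5 and uses its unweighted centre of mass as
#' the cylinder origin (falling back to the regressed origin, with a flag,
#' if the segmentation is empty); the normal and radius come from the
#' regression head, the height is fixed at 40 mm, and the parameters are
#' mapped back to acquisition space through the recorded crop geometry.
#'
#' @param net a trained `avc_network`.
#' @param iso_vol the cropped isotropic [image_volume] (windowed to
#'   \[0, 1\]).
#' @param crop the [grid_crop] recorded during preprocessing.
#' @return List with `params` (acquisition-space [cylinder_params]),
#'   `params_crop`, `seg` (crop-space mask) and `com_fallback`.
#' @export
predict_cylinder <- function(net, iso_vol, crop) {
  fw <- net_forward(net, as.vector(iso_vol$values), train = FALSE)
  pred <- predict_params_crop(fw, net$cfg$input_shape)
  if (pred$fallback)
    warning("empty segmentation: falling back to the regressed origin")
  list(params = map_params_between_spaces(pred$params, crop, "to_acquisition"),
       params_crop = pred$params, seg = pred$seg,
       com_fallback = pred$fallback)
}

#' Dice coefficient between two masks
#'
#' @param a,b logical arrays of equal shape.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both are empty.
#' @export
dice_coef <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Cylinder agreement metrics
#'
#' The evaluation suite used to compare a predicted cylinder with its
#' truth: mask Dice, Hausdorff distance (mm, between mask surfaces),
#' absolute radius difference, origin Euclidean distance and normal cosine
#' similarity.
#'
#' @param pred,truth [cylinder_params] in the same space.
#' @param grid grid geometry on which masks are rasterized.
#' @return One-row tibble.
#' @export
cyl_metrics <- function(pred, truth, grid) {
  mp <- suppressWarnings(reconstruct_cylinder_mask(pred, grid))
  mt <- reconstruct_cylinder_mask(truth, grid)
  tibble::tibble(
    dice = dice_coef(mp, mt),
    hausdorff_mm = hausdorff_masks(mp, mt, grid),
    radius_err_mm = abs(pred$radius_mm - truth$radius_mm),
    origin_err_mm = sqrt(sum((pred$origin_mm - truth$origin_mm)^2)),
    normal_cos = abs(sum(pred$normal * truth$normal)))
}

# symmetric Hausdorff distance between mask surfaces (subsampled for speed)
hausdorff_masks <- function(a, b, grid, max_points = 3000L) {
  g <- as_grid_geometry(grid)
  pa <- surface_points(a, g, max_points)
  pb <- surface_points(b, g, max_points)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(NA_real_)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

surface_points <- function(mask, g, max_points) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), ncol = 3))
  d <- dim(mask)
  on_surface <- logical(nrow(idx))
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- idx
    nb[, ax] <- nb[, ax] + s
    inside <- nb[, ax] >= 1 & nb[, ax] <= d[ax]
    val <- logical(nrow(idx))
    val[inside] <- mask[nb[inside, , drop = FALSE]]
    on_surface <- on_surface | !val
  }
  pts <- voxel_to_mm(idx[on_surface, , drop = FALSE], g$spacing, g$origin)
  if (nrow(pts) > max_points) {
    keep <- seq(1, nrow(pts), length.out = max_points)
    pts <- pts[unique(round(keep)), , drop = FALSE]
  }
  pts
}
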