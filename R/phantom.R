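# Synthetic CTCS phantoms: soft-tissue background, smooth cardiac blob, an
# oblique valve cylinder with mild intrinsic contrast, calcific blobs with
# partial-volume-like edges, a descending-aorta tube for noise QC, Gaussian
# noise and optional streak artifacts. Every phantom carries exact truth
# masks/parameters and an expected score report derived through the scalar
# reference scorer.

# evaluate fn with a temporary RNG state
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Specification of a synthetic CTCS phantom
#'
#' Describes one phantom: grid geometry, the nominal valve cylinder (radius
#' in the 16-22 mm range of adult aortic valves, height 40 mm), anchor
#' placement, calcific blobs, and noise. In-plane spacing defaults to the
#' 0.33-0.59 mm range of coned-down calcium-score acquisitions with 2.5 or
#' 3 mm slices.
#'
#' @param shape grid shape, default `c(168, 168, 36)` (84 x 84 x 90 mm at
#'   the default spacing, enough to hold the largest tilted cylinder).
#' @param spacing mm voxel spacing, default `c(0.5, 0.5, 2.5)`.
#' @param radius_mm cylinder radius (defaults to a draw from \[16, 22\]).
#' @param tilt_deg axis tilt from the scanner z axis (draw from \[10, 30\]).
#' @param azimuth_deg axis azimuth (draw from \[0, 360\)).
#' @param centre_jitter_mm uniform jitter of the cylinder origin around the
#'   volume centre.
#' @param height_mm cylinder height, fixed 40 mm in the valve model.
#' @param blobs data frame of calcifications (columns `radius_mm`,
#'   `peak_hu`, `inside`, and optionally `u`, `v`, `w` placement fractions);
#'   NULL for none.
#' @param noise_sd Gaussian HU noise (default 12).
#' @param streak_count,streak_amplitude streak artifact controls (default
#'   none).
#' @param seed RNG seed making the phantom fully reproducible.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(168, 168, 36), spacing = c(0.5, 0.5, 2.5),
                         radius_mm = NULL, tilt_deg = NULL, azimuth_deg = NULL,
                         centre_jitter_mm = 5, height_mm = 40, blobs = NULL,
                         noise_sd = 12, streak_count = 0, streak_amplitude = 0,
                         seed = 1L) {
  draws <- with_seed(seed, function() {
    list(radius = if (is.null(radius_mm)) stats::runif(1, 16, 22) else radius_mm,
         tilt = if (is.null(tilt_deg)) stats::runif(1, 10, 30) else tilt_deg,
         azim = if (is.null(azimuth_deg)) stats::runif(1, 0, 360) else azimuth_deg,
         jit = stats::runif(3, -centre_jitter_mm, centre_jitter_mm))
  })
  extent <- (shape - 1) * spacing
  centre <- extent / 2 + draws$jit * c(1, 1, 0.5)
  th <- draws$tilt * pi / 180; az <- draws$azim * pi / 180
  normal <- c(sin(th) * cos(az), sin(th) * sin(az), cos(th))
  structure(list(shape = as.integer(shape), spacing = spacing,
                 radius_mm = draws$radius, height_mm = height_mm,
                 normal = normal, centre_mm = centre,
                 blobs = blobs, noise_sd = noise_sd,
                 streak_count = streak_count,
                 streak_amplitude = streak_amplitude, seed = seed),
            class = "phantom_spec")
}

# default blob set: a few inside calcifications, a couple of coronary-like
# distractors outside the cylinder
default_blobs <- function(n_inside = 3, n_outside = 2) {
  n <- n_inside + n_outside
  data.frame(radius_mm = stats::runif(n, 1.5, 3.5),
             peak_hu = stats::runif(n, 200, 900),
             inside = rep(c(TRUE, FALSE), c(n_inside, n_outside)))
}

#' Generate a phantom volume with exact truth records
#'
#' Renders the phantom described by a [phantom_spec] and returns the HU
#' volume together with the exact cylinder mask and parameters, the disk
#' annotation that reproduces the cylinder through the annotate path, anchor
#' points, calcification truth mask, the descending-aorta mask and heart
#' bounding box used by QC/preprocessing, and the expected score report
#' computed by the scalar reference scorer on the final volume.
#'
#' The truth cylinder is derived from the synthesized disk annotation by the
#' same PCA expansion used for real annotations, so the annotate path
#' reproduces it exactly. Inside blobs are kept >= 4 mm clear of the
#' cylinder boundary; outside blobs are kept clear of the cylinder so
#' distractors never leak into the ROI.
#'
#' @param spec a [phantom_spec].
#' @param expected compute the reference-scorer truth report (default TRUE;
#'   skipping it speeds up iterative construction).
#' @return A `phantom` object (see Details).
#' @export
generate_phantom <- function(spec, expected = TRUE) {
  with_seed(spec$seed + 1L, function() generate_phantom_impl(spec, expected))
}

generate_phantom_impl <- function(spec, expected = TRUE) {
  g <- list(dim = spec$shape, spacing = spec$spacing, origin = c(0, 0, 0))
  extent <- (spec$shape - 1) * spec$spacing
  n <- spec$normal
  r <- spec$radius_mm
  cfg <- expansion_config()  # dr 2, dA 10, dB 30
  # nominal CoM sits (dA - dB)/2 = -10 mm along n from the disk centroid
  disk_centroid <- spec$centre_mm + n * (cfg$dB_mm - cfg$dA_mm) / 2
  B <- plane_basis(n)
  # synthesize the disk annotation: 1 mm in-plane lattice of the disk of
  # radius r - dr, snapped to voxel indices
  uv <- expand.grid(u = seq(-r, r, by = 1), v = seq(-r, r, by = 1))
  uv <- uv[uv$u^2 + uv$v^2 <= (r - cfg$delta_r_mm)^2, ]
  pts <- sweep(outer(uv$u, B$e1) + outer(uv$v, B$e2), 2, disk_centroid, "+")
  disk_vox <- unique(round(sweep(pts, 2, spec$spacing, "/")) + 1)
  disk_vox <- disk_vox[apply(disk_vox, 1, function(x) all(x >= 1 & x <= spec$shape)), ]
  centre_vox <- round(disk_centroid / spec$spacing) + 1
  # anchors roughly 120 degrees apart just outside the valve radius
  base_ang <- c(PALA = 90, LARA = 210, RAPA = 330) * pi / 180 +
    stats::runif(3, -20, 20) * pi / 180
  anchors_mm <- t(vapply(base_ang, function(a)
    disk_centroid + (r + 5) * (cos(a) * B$e1 + sin(a) * B$e2), numeric(3)))
  rownames(anchors_mm) <- names(base_ang)
  anchors_vox <- round(sweep(anchors_mm, 2, spec$spacing, "/")) + 1
  disk <- disk_annotation(disk_vox, centre_vox, anchors_vox)
  dc <- disk_to_cylinder(disk, cfg, g)
  params <- dc$params; cyl_mask <- dc$mask
  # ---- render HU ----
  # A mediastinal scene on lung-density background: the heart is a bright
  # soft-tissue ellipsoid whose long axis follows the valve normal and whose
  # width scales with the valve radius, so the cylinder is predictable from
  # cardiac anatomy (as in real non-contrast CT, where the valve itself is
  # nearly invisible); the valve region adds only mild intrinsic contrast.
  xs <- (seq_len(spec$shape[1]) - 1) * spec$spacing[1]
  ys <- (seq_len(spec$shape[2]) - 1) * spec$spacing[2]
  zs <- (seq_len(spec$shape[3]) - 1) * spec$spacing[3]
  soft_edge <- function(d, width) 1 / (1 + exp(d / width))  # 1 inside (d<0)
  lung_hu <- -700; tissue_hu <- 45
  hu <- array(lung_hu, dim = spec$shape)
  dxs <- xs - spec$centre_mm[1]; dys <- ys - spec$centre_mm[2]; dzs <- zs - spec$centre_mm[3]
  zp <- coord_field(n[1] * dxs, n[2] * dys, n[3] * dzs)
  u1 <- coord_field(B$e1[1] * dxs, B$e1[2] * dys, B$e1[3] * dzs)
  u2 <- coord_field(B$e2[1] * dxs, B$e2[2] * dys, B$e2[3] * dzs)
  sa <- r + 12; sc <- 40                      # heart width tracks valve size
  f_heart <- sqrt((u1 / sa)^2 + (u2 / sa)^2 + (zp / sc)^2)
  dist_heart <- (f_heart - 1) * sa            # approximate signed distance, mm
  hu <- hu + (tissue_hu - lung_hu) * soft_edge(dist_heart, 3)
  # descending aorta: z-aligned soft-tissue tube in the mediastinum
  aorta_ctr <- spec$centre_mm[1:2] + 36 / sqrt(2) * c(-1, 1)
  aorta_ctr <- pmin(pmax(aorta_ctr, 14), extent[1:2] - 14)
  d_aorta <- sqrt(coord_field((xs - aorta_ctr[1])^2, (ys - aorta_ctr[2])^2, zs * 0)) - 9
  hu <- pmax(hu, lung_hu + (tissue_hu - lung_hu) * soft_edge(d_aorta, 1))
  # QC mask: vessel interior only, clear of the partial-volume rim
  aorta_mask <- array(d_aorta < -5, dim = spec$shape)
  # valve cylinder: mild intrinsic contrast with a soft 1.5 mm edge
  rho <- sqrt(pmax(coord_field(dxs^2, dys^2, dzs^2) - zp^2, 0))
  d_cyl <- pmax(rho - r, abs(zp) - spec$height_mm / 2)
  hu <- hu + 18 * soft_edge(d_cyl, 1.5)
  # calcific blobs
  blobs <- spec$blobs
  if (!is.null(blobs) && nrow(blobs) > 0) {
    for (b in seq_len(nrow(blobs))) {
      br <- blobs$radius_mm[b]; peak <- blobs$peak_hu[b]
      for (try in 1:200) {
        if (blobs$inside[b]) {
          # uniform inside the cylinder with a 4 mm clearance to the wall
          rr <- (r - 4 - br) * sqrt(stats::runif(1))
          aa <- stats::runif(1, 0, 2 * pi)
          zz <- stats::runif(1, -params$dB_mm + br + 2, params$dA_mm - br - 2)
          ctr <- params$origin_mm + rr * (cos(aa) * B$e1 + sin(aa) * B$e2) + zz * n
          ok <- TRUE
        } else {
          rr <- r + 6 + br + stats::runif(1, 0, 10)
          aa <- stats::runif(1, 0, 2 * pi)
          zz <- stats::runif(1, -params$dB_mm, params$dA_mm)
          ctr <- params$origin_mm + rr * (cos(aa) * B$e1 + sin(aa) * B$e2) + zz * n
          ok <- TRUE
        }
        if (all(ctr > br + 1) && all(ctr < extent - br - 1)) break
        ok <- FALSE
      }
      if (!ok) stop("could not place calcification blob inside the grid")
      # calcified nodule on a soft-tissue pedestal: the Gaussian bump is
      # shaped so its 130 HU contour sits at radius br, and the pedestal
      # blends into whatever background the blob lands on (lung or heart)
      amp <- peak - tissue_hu
      alpha <- log(amp / max(130 - tissue_hu, 1)) / br^2
      if (alpha <= 0) alpha <- 1 / br^2
      d2 <- coord_field((xs - ctr[1])^2, (ys - ctr[2])^2, (zs - ctr[3])^2)
      nodule <- tissue_hu + amp * exp(-alpha * d2)
      blend <- soft_edge(sqrt(d2) - (br + 4), 1.5)
      hu <- pmax(hu, lung_hu + (nodule - lung_hu) * blend)
    }
  }
  calc_mask <- array(hu >= 130, dim = spec$shape)
  if (spec$noise_sd > 0)
    hu <- hu + stats::rnorm(length(hu), 0, spec$noise_sd)
  vol <- image_volume(array(hu, dim = spec$shape), spec$spacing)
  if (spec$streak_count > 0 && spec$streak_amplitude > 0)
    vol <- add_streaks(vol, spec$streak_count, spec$streak_amplitude,
                       seed = spec$seed + 2L,
                       focus = aorta_ctr, focus_radius = 9)
  heart_idx <- which(array(f_heart < 1, dim = spec$shape), arr.ind = TRUE)
  heart_bounds <- rbind((apply(heart_idx, 2, min) - 1) * spec$spacing,
                        (apply(heart_idx, 2, max) - 1) * spec$spacing)
  exp_report <- if (expected) score_reference(vol, cyl_mask) else NULL
  structure(list(volume = vol, cylinder_mask = cyl_mask, params = params,
                 disk = disk, anchors_mm = anchors_mm,
                 calc_mask = calc_mask, aorta_mask = aorta_mask,
                 heart_bounds = heart_bounds, expected = exp_report,
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  ag <- if (is.null(x$expected)) NA_real_ else x$expected$agatston
  cat(sprintf("<phantom> r = %.1f mm cylinder, expected Ag %.1f, seed %d\n",
              x$params$radius_mm, ag, x$spec$seed))
  invisible(x)
}

#' Add streak artifacts to a volume
#'
#' Emulates photon-starvation streaks: thin in-plane lines of alternating
#' sign added across all slices, concentrated around a focus point so the
#' aorta noise statistic responds. Amplitude 0 leaves the volume unchanged.
#'
#' @param vol an [image_volume].
#' @param count number of streak lines.
#' @param amplitude HU amplitude of the alternating pattern.
#' @param seed RNG seed.
#' @param focus in-plane mm point the lines pass near (default volume
#'   centre).
#' @param focus_radius mm scatter of line anchor points around `focus`.
#' @return The modified [image_volume].
#' @export
add_streaks <- function(vol, count, amplitude, seed = 1L,
                        focus = NULL, focus_radius = 10) {
  if (count <= 0 || amplitude == 0) return(vol)
  d <- dim(vol$values)
  sp <- vol$spacing
  if (is.null(focus)) focus <- (d[1:2] - 1) * sp[1:2] / 2
  vol$values <- with_seed(seed, function() {
    v <- vol$values
    nslice <- d[3]
    for (s in seq_len(count)) {
      ang <- stats::runif(1, 0, pi)
      p0 <- focus + stats::runif(2, -focus_radius, focus_radius)
      dir <- c(cos(ang), sin(ang))
      L <- sqrt(sum((d[1:2] * sp[1:2])^2))
      tt <- seq(-L, L, by = min(sp[1:2]) / 2)
      ij <- cbind(round((p0[1] + tt * dir[1]) / sp[1]) + 1,
                  round((p0[2] + tt * dir[2]) / sp[2]) + 1)
      keep <- ij[, 1] >= 1 & ij[, 1] <= d[1] & ij[, 2] >= 1 & ij[, 2] <= d[2]
      ij <- unique(ij[keep, , drop = FALSE])
      if (nrow(ij) == 0) next
      sgn <- amplitude * (-1)^(seq_len(nrow(ij)))
      flat <- (ij[, 2] - 1) * d[1] + ij[, 1]
      for (k in seq_len(nslice)) {
        off <- (k - 1) * d[1] * d[2]
        v[off + flat] <- v[off + flat] + sgn
      }
    }
    v
  })
  vol
}

#' Generate a cohort of phantoms spanning the severity bins
#'
#' Builds `n` phantoms whose expected Agatston scores are steered into the
#' clinical bins (0, 1-800, 800-1200, 1200-2000, 2000+) in the requested
#' proportions, with sex labels for severity-flag testing. Calcification is
#' added blob by blob until the noiseless score enters the target bin.
#'
#' @param n number of phantoms.
#' @param seed cohort seed; case `i` uses `seed * 1000 + i`.
#' @param bin_probs probabilities over the five severity bins.
#' @param sex_probs probabilities for `c(male, female)`.
#' @param ... forwarded to [phantom_spec()] (e.g. smaller `shape` for quick
#'   experiments).
#' @return List of `phantom` objects; each gains a `sex` and `target_bin`
#'   field.
#' @export
make_cohort <- function(n, seed = 1L,
                        bin_probs = c(0.35, 0.3, 0.12, 0.12, 0.11),
                        sex_probs = c(0.5, 0.5), ...) {
  stopifnot(n >= 1, length(bin_probs) == 5)
  bin_probs <- bin_probs / sum(bin_probs)
  edges <- rbind(c(0, 0), c(1, 800), c(800, 1200), c(1200, 2000), c(2000, 3500))
  labels <- c("0", "1-800", "800-1200", "1200-2000", "2000+")
  assign_bins <- with_seed(seed, function()
    sample(1:5, n, replace = TRUE, prob = bin_probs))
  sexes <- with_seed(seed + 1L, function()
    sample(c("male", "female"), n, replace = TRUE, prob = sex_probs))
  dots <- list(...)
  # per-case acquisition geometry spanning the clinical ranges (0.42-0.59 mm
  # in plane, 2.5 or 3 mm slices) at a fixed ~84 x 84 x 90 mm physical extent
  geom <- with_seed(seed + 2L, function() {
    sxy <- stats::runif(n, 0.42, 0.59)
    sz <- sample(c(2.5, 3), n, replace = TRUE)
    list(sxy = sxy, sz = sz)
  })
  lapply(seq_len(n), function(i) {
    case_seed <- seed * 1000L + i
    bin <- assign_bins[i]
    args <- dots
    if (is.null(args$spacing) && is.null(args$shape)) {
      args$spacing <- c(geom$sxy[i], geom$sxy[i], geom$sz[i])
      args$shape <- round(c(84, 84, 90) / args$spacing)
    }
    ph <- do.call(build_case_in_bin,
                  c(list(case_seed = case_seed, bounds = edges[bin, ]), args))
    ph$sex <- sexes[i]
    ph$target_bin <- labels[bin]
    ph
  })
}

# grow calcification until the noiseless Agatston score lands in [lo, hi)
build_case_in_bin <- function(case_seed, bounds, ...) {
  lo <- bounds[1]; hi <- bounds[2]
  if (lo == 0 && hi == 0) {
    spec <- phantom_spec(blobs = NULL, seed = case_seed, ...)
    return(generate_phantom(spec))
  }
  target <- lo + 0.25 * (hi - lo) + 1
  blobs <- NULL
  ag <- 0
  for (iter in 1:60) {
    if (ag >= target) break
    gap <- hi - ag
    # blob size scaled so a single addition cannot overshoot the bin
    br <- max(1.3, min(3.5, sqrt(gap / 160)))
    nb <- with_seed(case_seed + 100L + iter, function()
      data.frame(radius_mm = br * stats::runif(1, 0.8, 1),
                 peak_hu = stats::runif(1, 250, 900),
                 inside = TRUE))
    cand <- rbind(blobs, nb)
    spec <- phantom_spec(blobs = cand, seed = case_seed, noise_sd = 0, ...)
    ph0 <- generate_phantom(spec, expected = FALSE)
    ag2 <- agatston_score(find_lesions(ph0$volume, ph0$cylinder_mask))
    if (is.finite(hi) && ag2 >= hi) next  # overshoot: retry with another draw
    blobs <- cand
    ag <- ag2
  }
  spec <- phantom_spec(blobs = blobs, seed = case_seed, ...)
  generate_phantom(spec)
}
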