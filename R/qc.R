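#' Noise assessment from a descending-aorta mask
#'
#' The descending aorta is a homogeneous blood pool in non-contrast CT, so
#' the standard deviation of its sub-calcium voxels (HU < 130, excluding any
#' candidate calcification) measures image noise. Cases above
#' `sd_denoise` are flagged for median-filter denoising; cases above
#' `sd_exclude` are too noisy for automated analysis.
#'
#' @param vol an [image_volume].
#' @param aorta_mask logical array (externally supplied segmentation).
#' @param hu_max HU ceiling for the statistic (default 130).
#' @param sd_denoise,sd_exclude HU thresholds (defaults 36 and 45).
#' @return A `noise_report` list: `mean_hu`, `sd_hu`, `n_voxels`, `status`
#'   (`"clean"`, `"denoise"` or `"exclude"`).
#' @export
aorta_noise <- function(vol, aorta_mask, hu_max = 130,
                        sd_denoise = 36, sd_exclude = 45) {
  if (!identical(dim(vol$values), dim(aorta_mask)))
    stop("volume and aorta mask shapes differ")
  if (!any(aorta_mask)) stop("aorta mask is empty")
  v <- vol$values[aorta_mask]
  v <- v[v < hu_max]
  if (length(v) < 2) stop("no sub-calcium aorta voxels; cannot assess noise")
  s <- stats::sd(v)
  status <- if (s > sd_exclude) "exclude" else if (s > sd_denoise) "denoise" else "clean"
  structure(list(mean_hu = mean(v), sd_hu = s, n_voxels = length(v),
                 status = status),
            class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("<noise_report> aorta %.1f +/- %.1f HU (n = %d) -> %s\n",
              x$mean_hu, x$sd_hu, x$n_voxels, x$status))
  invisible(x)
}

#' Slice-wise 3x3 median denoising
#'
#' 2D median filtering per axial slice, well suited to the streak artifacts
#' of photon starvation; shape and spacing are preserved. Applied to flagged
#' noisy cases before calcification detection.
#'
#' @param vol an [image_volume].
#' @return The denoised [image_volume].
#' @export
median_denoise <- function(vol) {
  d <- dim(vol$values)
  vol$values <- array(cpp_median3x3(as.vector(vol$values), d), dim = d)
  vol
}

#' Isotropic resampling and heart-window cropping
#'
#' Resamples the acquisition volume to isotropic voxels (trilinear) and
#' extracts a fixed-shape window centred on the heart bounding box, padding
#' with the global minimum where the window extends past the volume. The
#' crop geometry is recorded for lossless coordinate round trips; scoring is
#' always performed on the acquisition-space volume.
#'
#' @param vol an [image_volume].
#' @param heart_bounds 2 x 3 matrix `rbind(lo, hi)` of the heart bounding
#'   box in mm, or a logical heart mask on the same grid.
#' @param out_shape crop window shape, default `c(176, 176, 128)`.
#' @param iso_spacing_mm isotropic voxel size, default 1.
#' @return List with `volume` (the cropped isotropic [image_volume], origin
#'   zero) and `crop` (a [grid_crop]).
#' @export
resample_crop <- function(vol, heart_bounds, out_shape = c(176, 176, 128),
                          iso_spacing_mm = 1) {
  d <- dim(vol$values)
  if (length(dim(heart_bounds)) == 3L) {
    if (!any(heart_bounds)) stop("heart bounding box is empty")
    idx <- which(heart_bounds, arr.ind = TRUE)
    lo <- voxel_to_mm(apply(idx, 2, min), vol$spacing, vol$origin)
    hi <- voxel_to_mm(apply(idx, 2, max), vol$spacing, vol$origin)
    heart_bounds <- rbind(as.numeric(lo), as.numeric(hi))
  }
  if (any(heart_bounds[2, ] < heart_bounds[1, ])) stop("heart bounding box is empty")
  iso_dims <- pmax(as.integer(floor((d - 1) * vol$spacing / iso_spacing_mm)) + 1L, 1L)
  iso <- array(cpp_resample(as.vector(vol$values), d, vol$spacing,
                            iso_dims, rep(iso_spacing_mm, 3),
                            min(vol$values), TRUE),
               dim = iso_dims)
  centre_mm <- colMeans(heart_bounds) - vol$origin
  centre_vox <- centre_mm / iso_spacing_mm          # 0-based iso index
  offset <- round(centre_vox - (out_shape - 1) / 2)
  pad <- min(vol$values)
  out <- array(pad, dim = out_shape)
  src_lo <- pmax(offset + 1, 1)                     # 1-based source range
  src_hi <- pmin(offset + out_shape, iso_dims)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - offset
    dst_hi <- src_hi - offset
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      iso[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  }
  crop <- grid_crop(crop_offset = offset, crop_shape = out_shape,
                    orig_shape = d, orig_spacing = vol$spacing,
                    orig_origin = vol$origin, iso_spacing_mm = iso_spacing_mm,
                    pad_value = pad)
  list(volume = image_volume(out, rep(iso_spacing_mm, 3), origin = c(0, 0, 0)),
       crop = crop)
}

#' Resample a mask through a recorded crop (nearest neighbour)
#'
#' @param mask logical array on the acquisition grid of `crop`.
#' @param crop a [grid_crop].
#' @return Logical array of shape `crop$crop_shape`.
#' @export
resample_mask_to_crop <- function(mask, crop) {
  d <- crop$orig_shape
  iso_dims <- pmax(as.integer(floor((d - 1) * crop$orig_spacing / crop$iso_spacing_mm)) + 1L, 1L)
  iso <- array(cpp_resample(as.double(mask), d, crop$orig_spacing,
                            iso_dims, rep(crop$iso_spacing_mm, 3), 0, FALSE),
               dim = iso_dims)
  out <- array(0, dim = crop$crop_shape)
  offset <- crop$crop_offset
  src_lo <- pmax(offset + 1, 1)
  src_hi <- pmin(offset + crop$crop_shape, iso_dims)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - offset
    dst_hi <- src_hi - offset
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      iso[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  }
  out > 0.5
}
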