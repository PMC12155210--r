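#' Disk-like valve annotation
#'
#' Expert annotation of the aortic valve in a single reformatted slice: the
#' set of labeled disk voxels, the annotated valve centre, and three auxiliary
#' anchor points placed between the pulmonary artery / left atrium (PALA),
#' left / right atrium (LARA) and right atrium / pulmonary artery (RAPA).
#' Anchors later define the angular sub-ROI sectors.
#'
#' @param disk_voxels integer matrix (n x 3) of 1-based voxel indices.
#' @param center_voxel length-3 voxel index of the annotated valve centre.
#' @param anchors 3 x 3 matrix of voxel indices with rownames
#'   `c("PALA", "LARA", "RAPA")`.
#' @return A `disk_annotation` object.
#' @export
disk_annotation <- function(disk_voxels, center_voxel, anchors = NULL) {
  disk_voxels <- matrix(as.numeric(disk_voxels), ncol = 3)
  if (nrow(disk_voxels) == 0) stop("disk annotation is empty")
  if (!is.null(anchors)) {
    anchors <- as.matrix(anchors)
    if (nrow(anchors) != 3 || is.null(rownames(anchors)) ||
        !setequal(rownames(anchors), c("PALA", "LARA", "RAPA")))
      stop("anchors must be a 3x3 matrix with rownames PALA, LARA, RAPA")
    if (anyDuplicated(anchors)) stop("anchor points must be distinct")
  }
  structure(list(disk_voxels = disk_voxels,
                 center_voxel = as.numeric(center_voxel),
                 anchors = anchors),
            class = "disk_annotation")
}

#' Fit the local PCA frame of a disk annotation
#'
#' Principal component analysis of the millimetre-rescaled disk voxel
#' coordinates. `pc1`/`pc2` span the disk plane (decreasing variance) and
#' `pc3` is the disk normal (least variance). The normal sign is fixed so
#' that `pc3` points toward the scanner superior (+z) axis, which defines
#' "above" the valve plane for the asymmetric height expansion; `pc1` is
#' sign-fixed deterministically and `pc2 = pc3 x pc1` keeps the frame
#' right-handed.
#'
#' @param disk a [disk_annotation].
#' @param spacing mm voxel spacing of the grid the annotation lives in.
#' @return A `local_frame` with unit vectors `pc1`, `pc2`, `pc3` and the
#'   `centroid_mm` of the disk.
#' @export
fit_local_frame <- function(disk, spacing) {
  pts <- voxel_to_mm(disk$disk_voxels, spacing)
  if (nrow(pts) < 4) stop("degenerate disk: need at least 4 voxels to fit a plane")
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  if (ev$values[2] <= max(ev$values[1], 1) * 1e-10)
    stop("degenerate disk: voxels are collinear or coincident")
  pc1 <- ev$vectors[, 1]; pc3 <- ev$vectors[, 3]
  if (abs(pc3[3]) > 1e-9) {
    if (pc3[3] < 0) pc3 <- -pc3
  } else {
    nz <- which(abs(pc3) > 1e-9)[1]
    if (pc3[nz] < 0) pc3 <- -pc3
  }
  nz <- which(abs(pc1) > 1e-9)[1]
  if (pc1[nz] < 0) pc1 <- -pc1
  pc2 <- cross3(pc3, pc1)
  structure(list(pc1 = pc1, pc2 = pc2 / sqrt(sum(pc2^2)), pc3 = pc3,
                 centroid_mm = ctr),
            class = "local_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# local (x', y', z') coordinates of mm points relative to a frame and a
# reference point (defaults to the frame centroid)
to_local <- function(pts_mm, frame, ref = frame$centroid_mm) {
  d <- sweep(matrix(pts_mm, ncol = 3), 2, ref)
  cbind(d %*% frame$pc1, d %*% frame$pc2, d %*% frame$pc3)
}

#' Valve radius from a disk annotation
#'
#' The largest in-plane distance `sqrt(x'^2 + y'^2)` from the annotated valve
#' centre (projected into the disk plane) to any disk voxel.
#'
#' @param disk a [disk_annotation].
#' @param frame the [fit_local_frame()] result for the same disk.
#' @param spacing mm voxel spacing.
#' @return Radius in mm.
#' @export
disk_radius <- function(disk, frame, spacing) {
  pts <- voxel_to_mm(disk$disk_voxels, spacing)
  ctr <- voxel_to_mm(disk$center_voxel, spacing)
  loc <- to_local(pts, frame, ref = as.numeric(ctr))
  max(sqrt(loc[, 1]^2 + loc[, 2]^2))
}

#' Disk-to-cylinder expansion parameters
#'
#' Radial margin and height extents used to grow the annotated disk into the
#' valve ROI cylinder: final radius = valve radius + `delta_r_mm`, and the
#' cylinder spans `dA_mm` above to `dB_mm` below the disk centroid along the
#' disk normal. The defaults (2, 10, 30 mm; total height 40 mm) capture the
#' valve apparatus while excluding proximal coronary calcium.
#'
#' @param delta_r_mm radial margin added to the measured valve radius.
#' @param dA_mm extent above the disk centroid (toward the aortic root).
#' @param dB_mm extent below the disk centroid (toward the cusps).
#' @return An `expansion_config`.
#' @export
expansion_config <- function(delta_r_mm = 2, dA_mm = 10, dB_mm = 30) {
  if (any(c(delta_r_mm, dA_mm, dB_mm) < 0)) stop("expansion distances must be >= 0")
  if (dA_mm + dB_mm <= 0) stop("cylinder height dA + dB must be positive")
  structure(list(delta_r_mm = delta_r_mm, dA_mm = dA_mm, dB_mm = dB_mm),
            class = "expansion_config")
}

#' Parameterized cylinder ROI
#'
#' The 8-parameter valve ROI model: a unit axis direction, an origin at the
#' cylinder centre of mass, a radius and a height, optionally split into the
#' extent above (`dA_mm`) and below (`dB_mm`) a reference plane.
#'
#' @param normal unit length-3 axis direction; normalized if within 1e-3 of
#'   unit length, otherwise an error.
#' @param origin_mm length-3 cylinder origin in mm.
#' @param radius_mm,height_mm cylinder radius and height in mm (> 0).
#' @param dA_mm,dB_mm optional split of the height about `origin_mm`;
#'   must satisfy `dA_mm + dB_mm == height_mm`.
#' @param space coordinate space tag, `"acquisition"` or `"iso_crop"`.
#' @return A `cylinder_params` object.
#' @export
cylinder_params <- function(normal, origin_mm, radius_mm, height_mm,
                            dA_mm = NULL, dB_mm = NULL, space = "acquisition") {
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (abs(nn - 1) > 1e-3) stop("normal is not a unit vector (|norm - 1| > 1e-3)")
  normal <- normal / nn
  if (radius_mm <= 0) stop("radius must be positive")
  if (height_mm <= 0) stop("height must be positive")
  if (xor(is.null(dA_mm), is.null(dB_mm))) stop("supply both dA_mm and dB_mm or neither")
  if (!is.null(dA_mm) && abs(dA_mm + dB_mm - height_mm) > 1e-6)
    stop("dA_mm + dB_mm must equal height_mm")
  structure(list(normal = normal, origin_mm = as.numeric(origin_mm),
                 radius_mm = radius_mm, height_mm = height_mm,
                 dA_mm = dA_mm, dB_mm = dB_mm, space = space),
            class = "cylinder_params")
}

#' @export
print.cylinder_params <- function(x, ...) {
  cat(sprintf(
    "<cylinder_params> r = %.2f mm, h = %.2f mm, origin (%.1f, %.1f, %.1f) mm [%s]\n",
    x$radius_mm, x$height_mm, x$origin_mm[1], x$origin_mm[2], x$origin_mm[3], x$space))
  cat(sprintf("  normal (%.3f, %.3f, %.3f)\n", x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

# Accept an image_volume or a list(dim, spacing, origin) as grid geometry.
as_grid_geometry <- function(grid) {
  if (inherits(grid, "image_volume"))
    return(list(dim = dim(grid$values), spacing = grid$spacing, origin = grid$origin))
  if (is.list(grid) && all(c("dim", "spacing") %in% names(grid))) {
    if (is.null(grid$origin)) grid$origin <- c(0, 0, 0)
    return(grid[c("dim", "spacing", "origin")])
  }
  stop("grid must be an image_volume or list(dim, spacing, origin)")
}

# Vectorized strict-inequality cylinder rasterizer: voxel centre included iff
# rho^2 < radius^2 and z_lo < z' < z_hi, with z' measured along `normal` from
# `ref_mm`. Returns a logical array on the grid.
voxelize_cylinder <- function(normal, ref_mm, radius, z_lo, z_hi, grid, warn_clip = TRUE) {
  g <- as_grid_geometry(grid)
  xs <- g$origin[1] + (seq_len(g$dim[1]) - 1) * g$spacing[1] - ref_mm[1]
  ys <- g$origin[2] + (seq_len(g$dim[2]) - 1) * g$spacing[2] - ref_mm[2]
  zs <- g$origin[3] + (seq_len(g$dim[3]) - 1) * g$spacing[3] - ref_mm[3]
  zp <- coord_field(normal[1] * xs, normal[2] * ys, normal[3] * zs)
  r2 <- coord_field(xs^2, ys^2, zs^2) - zp^2
  inside <- (r2 < radius^2) & (zp > z_lo) & (zp < z_hi)
  if (warn_clip) {
    lo <- g$origin - g$spacing / 2
    hi <- g$origin + (g$dim - 1 + 0.5) * g$spacing
    # tight per-axis extent of the finite cylinder about ref_mm
    rad <- radius * sqrt(pmax(1 - normal^2, 0))
    up <- pmax(z_lo * normal, z_hi * normal) + rad
    dn <- pmin(z_lo * normal, z_hi * normal) - rad
    if (any(ref_mm + dn < lo) || any(ref_mm + up > hi))
      warning("cylinder extends outside the image grid; mask clipped to the field of view")
  }
  array(inside, dim = g$dim)
}

#' Expand a disk annotation into the cylinder ROI mask
#'
#' Grows the annotated valve disk into the full valve ROI: a voxel belongs to
#' the cylinder iff its mm-space centre satisfies the strict radial rule
#' `x'^2 + y'^2 < (valve radius + delta_r)^2` and the strict height rule
#' `-dB < z' < dA`, in the local PCA frame about the disk centroid. The mask
#' is produced on the original anisotropic acquisition grid.
#'
#' @param disk a [disk_annotation].
#' @param frame its [fit_local_frame()].
#' @param cfg an [expansion_config].
#' @param grid grid geometry ([image_volume] or `list(dim, spacing, origin)`).
#' @return Logical 3D mask array.
#' @export
expand_disk_to_cylinder <- function(disk, frame, cfg = expansion_config(), grid) {
  g <- as_grid_geometry(grid)
  r <- disk_radius(disk, frame, g$spacing) + cfg$delta_r_mm
  voxelize_cylinder(frame$pc3, frame$centroid_mm, r, -cfg$dB_mm, cfg$dA_mm, g)
}

#' Cylinder parameters from a disk annotation
#'
#' Convenience wrapper: fits the PCA frame, measures the valve radius,
#' rasterizes the expanded cylinder and returns the 8-parameter model with the
#' origin at the mask centre of mass (as used for model training targets).
#'
#' @inheritParams expand_disk_to_cylinder
#' @return List with elements `params` ([cylinder_params]), `mask` and
#'   `frame`.
#' @export
disk_to_cylinder <- function(disk, cfg = expansion_config(), grid) {
  g <- as_grid_geometry(grid)
  frame <- fit_local_frame(disk, g$spacing)
  mask <- expand_disk_to_cylinder(disk, frame, cfg, g)
  r <- disk_radius(disk, frame, g$spacing) + cfg$delta_r_mm
  origin <- cylinder_origin_from_mask(mask, g)
  # split of the height about the mass centre (ideal CoM sits (dA - dB)/2
  # above the disk centroid)
  shift <- sum((origin - frame$centroid_mm) * frame$pc3)
  params <- cylinder_params(frame$pc3, origin, r, cfg$dA_mm + cfg$dB_mm,
                            dA_mm = cfg$dA_mm - shift, dB_mm = cfg$dB_mm + shift)
  list(params = params, mask = mask, frame = frame)
}

#' Reconstruct a cylinder mask from its parameters
#'
#' Rasterizes the parameterized cylinder with the same strict membership rule
#' as [expand_disk_to_cylinder()]. Height is split symmetrically about the
#' origin unless the parameters carry an explicit `dA`/`dB` split (the centre
#' of mass of an ideal cylinder lies at mid-height).
#'
#' @param p a [cylinder_params].
#' @param grid grid geometry.
#' @return Logical 3D mask array.
#' @export
reconstruct_cylinder_mask <- function(p, grid) {
  g <- as_grid_geometry(grid)
  if (p$radius_mm < min(g$spacing[1:2]) / 2) {
    warning("cylinder radius below half the in-plane spacing; mask is empty")
    return(array(FALSE, dim = g$dim))
  }
  if (is.null(p$dA_mm)) {
    voxelize_cylinder(p$normal, p$origin_mm, p$radius_mm,
                      -p$height_mm / 2, p$height_mm / 2, g)
  } else {
    voxelize_cylinder(p$normal, p$origin_mm, p$radius_mm, -p$dB_mm, p$dA_mm, g)
  }
}

#' Centre of mass of a binary mask in mm
#'
#' Unweighted centroid of the member voxel centres; used to link the
#' segmentation output to the cylinder origin.
#'
#' @param mask logical 3D array.
#' @param grid grid geometry.
#' @return Length-3 mm coordinate.
#' @export
cylinder_origin_from_mask <- function(mask, grid) {
  g <- as_grid_geometry(grid)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask: segmentation produced no voxels")
  colMeans(voxel_to_mm(idx, g$spacing, g$origin))
}

#' Estimate cylinder parameters from a binary mask
#'
#' Inverse of [reconstruct_cylinder_mask()]: the axis is the principal
#' direction whose variance is most separated from the other two (the two
#' radial variances of a cylinder are equal), the origin is the mask centre
#' of mass, and radius/height start from the in-plane/axial extents and are
#' optionally refined by minimizing the voxel-wise disagreement with the
#' rasterized model.
#'
#' @param mask logical 3D array containing one cylinder.
#' @param grid grid geometry.
#' @param refine logical; run the discrete mismatch refinement (default TRUE).
#' @return A [cylinder_params] in the grid's space.
#' @export
parameterize_mask <- function(mask, grid, refine = TRUE) {
  g <- as_grid_geometry(grid)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 8) stop("mask too small to parameterize")
  pts <- voxel_to_mm(idx, g$spacing, g$origin)
  origin <- colMeans(pts)
  cen <- sweep(pts, 2, origin)
  ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  # axis = eigenvalue farthest from the median of the three (odd one out)
  sep <- abs(ev$values - stats::median(ev$values))
  ax <- ev$vectors[, which.max(sep)]
  if (abs(ax[3]) > 1e-9) { if (ax[3] < 0) ax <- -ax } else if (ax[which(abs(ax) > 1e-9)[1]] < 0) ax <- -ax
  zp <- cen %*% ax
  rho <- sqrt(pmax(rowSums(cen^2) - zp^2, 0))
  pitch <- max(abs(ax) * g$spacing)
  h0 <- diff(range(zp)) + pitch
  vol_mm3 <- nrow(idx) * prod(g$spacing)
  r0 <- sqrt(vol_mm3 / (pi * h0))
  if (refine) {
    mism <- function(r, h) {
      rec <- voxelize_cylinder(ax, origin, r, -h / 2, h / 2, g, warn_clip = FALSE)
      sum(xor(rec, mask))
    }
    best <- c(r0, h0); bestm <- mism(r0, h0)
    for (step in c(0.5, 0.25, 0.125)) {
      for (dr in c(-step, 0, step)) for (dh in c(-step, 0, step)) {
        if (dr == 0 && dh == 0) next
        cand <- c(best[1] + dr, best[2] + dh)
        if (cand[1] <= 0 || cand[2] <= 0) next
        m <- mism(cand[1], cand[2])
        if (m < bestm) { bestm <- m; best <- cand }
      }
    }
    r0 <- best[1]; h0 <- best[2]
  }
  cylinder_params(ax, origin, r0, h0, space = if (!is.null(g$space)) g$space else "acquisition")
}

#' Geometry of the isotropic crop window
#'
#' Records how an acquisition volume was resampled to isotropic voxels and
#' cropped, so that cylinder parameters can be mapped losslessly between
#' acquisition space and the cropped model-input space.
#'
#' @param crop_offset integer length-3, 0-based voxel offset of the crop
#'   window in the isotropic volume (may be negative when padding was needed).
#' @param crop_shape integer length-3 crop window shape.
#' @param orig_shape,orig_spacing,orig_origin geometry of the acquisition
#'   volume.
#' @param iso_spacing_mm isotropic voxel size (default 1 mm).
#' @param pad_value HU value used to pad under-filled windows.
#' @return A `grid_crop` object.
#' @export
grid_crop <- function(crop_offset, crop_shape, orig_shape, orig_spacing,
                      orig_origin = c(0, 0, 0), iso_spacing_mm = 1, pad_value = NA) {
  structure(list(crop_offset = as.numeric(crop_offset),
                 crop_shape = as.integer(crop_shape),
                 orig_shape = as.integer(orig_shape),
                 orig_spacing = as.numeric(orig_spacing),
                 orig_origin = as.numeric(orig_origin),
                 iso_spacing_mm = iso_spacing_mm,
                 pad_value = pad_value),
            class = "grid_crop")
}

#' Map cylinder parameters between acquisition and iso-crop spaces
#'
#' Radius and height are physical (mm) and space invariant; only the origin
#' translates. The round trip is the identity to floating-point precision.
#'
#' @param p a [cylinder_params].
#' @param crop a [grid_crop].
#' @param direction `"to_crop"` (acquisition to isotropic crop) or
#'   `"to_acquisition"`.
#' @return A [cylinder_params] in the requested space.
#' @export
map_params_between_spaces <- function(p, crop, direction = c("to_crop", "to_acquisition")) {
  direction <- match.arg(direction)
  shift <- crop$orig_origin + crop$crop_offset * crop$iso_spacing_mm
  if (direction == "to_crop") {
    if (!identical(p$space, "acquisition")) stop("parameters are not in acquisition space")
    origin <- p$origin_mm - shift
  } else {
    if (!identical(p$space, "iso_crop")) stop("parameters are not in iso_crop space")
    origin <- p$origin_mm + shift
    fov_lo <- crop$orig_origin - crop$orig_spacing / 2
    fov_hi <- crop$orig_origin + (crop$orig_shape - 0.5) * crop$orig_spacing
    if (any(origin < fov_lo) || any(origin > fov_hi))
      stop("cylinder centre falls outside the original field of view")
  }
  cylinder_params(p$normal, origin, p$radius_mm, p$height_mm,
                  dA_mm = p$dA_mm, dB_mm = p$dB_mm,
                  space = if (direction == "to_crop") "iso_crop" else "acquisition")
}

#' Serialize cylinder parameters to JSON
#'
#' @param p a [cylinder_params].
#' @param path optional file path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
params_to_json <- function(p, path = NULL) {
  rec <- list(normal = p$normal, origin_mm = p$origin_mm,
              radius_mm = p$radius_mm, height_mm = p$height_mm, space = p$space)
  if (!is.null(p$dA_mm)) { rec$dA_mm <- p$dA_mm; rec$dB_mm <- p$dB_mm }
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read cylinder parameters from JSON
#'
#' @param path file path or JSON string produced by [params_to_json()].
#' @return A [cylinder_params].
#' @export
params_from_json <- function(path) {
  rec <- jsonlite::fromJSON(path)
  cylinder_params(rec$normal, rec$origin_mm, rec$radius_mm, rec$height_mm,
                  dA_mm = rec$dA_mm, dB_mm = rec$dB_mm, space = rec$space)
}
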