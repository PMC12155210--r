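# Deliberately simple scalar reference implementations of the cylinder
# rasterizer and the Agatston scorer. They share no code with the fast
# vectorized/compiled paths and exist so those paths can be validated
# voxel-for-voxel on small grids (and so phantom truth reports are derived
# through an independent route).

#' Scalar reference cylinder rasterizer
#'
#' Per-voxel loop applying the strict membership rule
#' `x'^2 + y'^2 < r^2` and `z_lo < z' < z_hi` at each voxel centre.
#' Slow by construction; intended for validation on small grids.
#'
#' @param normal unit axis direction.
#' @param ref_mm reference point on the axis (z' = 0).
#' @param radius cylinder radius, mm.
#' @param z_lo,z_hi strict axial bounds, mm.
#' @param grid grid geometry.
#' @return Logical mask array.
#' @export
voxelize_cylinder_reference <- function(normal, ref_mm, radius, z_lo, z_hi, grid) {
  g <- as_grid_geometry(grid)
  out <- array(FALSE, dim = g$dim)
  for (k in seq_len(g$dim[3])) {
    for (j in seq_len(g$dim[2])) {
      for (i in seq_len(g$dim[1])) {
        p <- g$origin + (c(i, j, k) - 1) * g$spacing - ref_mm
        zp <- p[1] * normal[1] + p[2] * normal[2] + p[3] * normal[3]
        rho2 <- p[1]^2 + p[2]^2 + p[3]^2 - zp^2
        out[i, j, k] <- (rho2 < radius^2) && (zp > z_lo) && (zp < z_hi)
      }
    }
  }
  out
}

# scalar BFS 8-connected labeling of one logical slice
label_slice_reference <- function(sl) {
  d <- dim(sl)
  lab <- matrix(0L, d[1], d[2])
  nxt <- 0L
  for (j0 in seq_len(d[2])) for (i0 in seq_len(d[1])) {
    if (!sl[i0, j0] || lab[i0, j0] > 0L) next
    nxt <- nxt + 1L
    qi <- i0; qj <- j0; head <- 1L
    lab[i0, j0] <- nxt
    while (head <= length(qi)) {
      ci <- qi[head]; cj <- qj[head]; head <- head + 1L
      for (dj in -1:1) for (di in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- ci + di; jj <- cj + dj
        if (ii < 1 || jj < 1 || ii > d[1] || jj > d[2]) next
        if (sl[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          qi <- c(qi, ii); qj <- c(qj, jj)
        }
      }
    }
  }
  lab
}

#' Scalar reference Agatston / volume / mass scorer
#'
#' Independent end-to-end implementation of the scoring rules using explicit
#' per-slice BFS labeling and list-based 3D grouping. Returns the same four
#' headline metrics as the fast path.
#'
#' @param vol an [image_volume].
#' @param roi_mask logical ROI mask.
#' @param hu_threshold,min_area_mm2 detection criteria.
#' @param calibration mass calibration factor.
#' @param min_lesion_ag per-lesion validity threshold (strict `>`).
#' @return List with `agatston`, `volume_mm3`, `mass_mg`, `n_lesions`,
#'   `n_valid_lesions`.
#' @export
score_reference <- function(vol, roi_mask, hu_threshold = 130, min_area_mm2 = 1,
                            calibration = 0.001, min_lesion_ag = 10) {
  sp <- vol$spacing
  d <- dim(vol$values)
  vox_area <- sp[1] * sp[2]
  comps <- list()   # each: list(slice, cells (n x 2), area, max_hu)
  for (k in seq_len(d[3])) {
    sl <- (vol$values[, , k] >= hu_threshold) & roi_mask[, , k]
    if (!any(sl)) next
    lab <- label_slice_reference(sl)
    for (id in seq_len(max(lab))) {
      cells <- which(lab == id, arr.ind = TRUE)
      area <- nrow(cells) * vox_area
      if (area < min_area_mm2 - 1e-9) next
      hu <- vol$values[, , k][cells]
      comps[[length(comps) + 1]] <- list(slice = k, cells = cells,
                                         area = area, max_hu = max(hu),
                                         hu = hu)
    }
  }
  if (length(comps) == 0)
    return(list(agatston = 0, volume_mm3 = 0, mass_mg = 0,
                n_lesions = 0L, n_valid_lesions = 0L))
  # group components into 3D lesions: adjacent slices, 26-connectivity
  n <- length(comps)
  adj <- function(a, b) {
    if (abs(comps[[a]]$slice - comps[[b]]$slice) != 1) return(FALSE)
    ca <- comps[[a]]$cells; cb <- comps[[b]]$cells
    for (r in seq_len(nrow(ca)))
      if (any(abs(cb[, 1] - ca[r, 1]) <= 1 & abs(cb[, 2] - ca[r, 2]) <= 1))
        return(TRUE)
    FALSE
  }
  lesion <- integer(n)
  nles <- 0L
  for (s in seq_len(n)) {
    if (lesion[s] > 0L) next
    nles <- nles + 1L
    stack <- s
    lesion[s] <- nles
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (o in seq_len(n)) {
        if (lesion[o] == 0L && adj(cur, o)) {
          lesion[o] <- nles
          stack <- c(stack, o)
        }
      }
    }
  }
  weight <- function(m) if (m >= 400) 4 else if (m >= 300) 3 else if (m >= 200) 2 else 1
  ag_comp <- vapply(comps, function(cm) cm$area * weight(cm$max_hu), numeric(1))
  ag_les <- vapply(seq_len(nles), function(l) sum(ag_comp[lesion == l]), numeric(1))
  vol_les <- vapply(seq_len(nles), function(l)
    sum(vapply(comps[lesion == l], function(cm) nrow(cm$cells), numeric(1))) * prod(sp),
    numeric(1))
  mean_hu_les <- vapply(seq_len(nles), function(l)
    mean(unlist(lapply(comps[lesion == l], function(cm) cm$hu))), numeric(1))
  list(agatston = sum(ag_comp),
       volume_mm3 = sum(vol_les),
       mass_mg = calibration * sum(mean_hu_les * vol_les),
       n_lesions = nles,
       n_valid_lesions = sum(ag_les > min_lesion_ag))
}
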