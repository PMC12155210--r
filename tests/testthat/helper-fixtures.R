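# Small builders shared across the test files. Everything is generated in
# code; no stored fixtures.

# flat disk annotation in one z-slice (axis-aligned), 1-based indices
flat_disk <- function(radius_vox = 15, centre = c(21, 21, 5), n = 41,
                      with_anchors = TRUE) {
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  ij <- ij[(ij$i - centre[1])^2 + (ij$j - centre[2])^2 <= radius_vox^2, ]
  anchors <- NULL
  if (with_anchors) {
    anchors <- matrix(c(centre[1], centre[2] + radius_vox + 3, centre[3],
                        centre[1] - radius_vox - 3, centre[2] - 4, centre[3],
                        centre[1] + radius_vox + 3, centre[2] - 4, centre[3]),
                      3, 3, byrow = TRUE,
                      dimnames = list(c("PALA", "LARA", "RAPA"), NULL))
  }
  disk_annotation(cbind(ij$i, ij$j, centre[3]), centre, anchors)
}

# exactly planar tilted disk: voxel indices (i, j, j) with spacing
# (1, 1, tan(theta)) lie on the mm plane with normal (0, -sin, cos)
tilted_disk <- function(theta_deg = 30, extent = 12) {
  ij <- expand.grid(i = -extent:extent, j = -extent:extent)
  ij <- ij[ij$i^2 + ij$j^2 <= extent^2, ]
  vox <- cbind(ij$i + extent + 1, ij$j + extent + 1, ij$j + extent + 1)
  list(disk = disk_annotation(vox, c(extent + 1, extent + 1, extent + 1)),
       spacing = c(1, 1, tan(theta_deg * pi / 180)),
       normal = c(0, -sin(theta_deg * pi / 180), cos(theta_deg * pi / 180)))
}

# random unit vector with the z component positive
rand_axis <- function(max_tilt_deg = 40) {
  th <- stats::runif(1, 0, max_tilt_deg) * pi / 180
  az <- stats::runif(1, 0, 2 * pi)
  c(sin(th) * cos(az), sin(th) * sin(az), cos(th))
}

# small HU volume with given background and a list of cuboid patches
patch_volume <- function(dim = c(16, 16, 6), spacing = c(0.5, 0.5, 3),
                         background = 30, patches = list()) {
  v <- array(background, dim = dim)
  for (p in patches) {
    v[p$x[1]:p$x[2], p$y[1]:p$y[2], p$z[1]:p$z[2]] <- p$hu
  }
  image_volume(v, spacing)
}

full_mask <- function(vol) array(TRUE, dim = dim(vol$values))

# quick small phantom used by several files (kept small for speed)
quick_phantom <- function(seed = 42, blobs = data.frame(
    radius_mm = c(2.5, 2), peak_hu = c(500, 260), inside = c(TRUE, TRUE)),
    ...) {
  generate_phantom(phantom_spec(shape = c(120, 120, 30),
                                spacing = c(0.6, 0.6, 2.5),
                                centre_jitter_mm = 2, blobs = blobs,
                                seed = seed, ...))
}
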