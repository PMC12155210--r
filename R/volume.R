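#' 3D image volume in Hounsfield units
#'
#' Lightweight container for a 3D scalar grid with physical geometry. Values
#' are stored in the native acquisition axis order `values[i, j, k]` with the
#' first index along x; the physical centre of voxel `(i, j, k)` (1-based) is
#' `origin + (c(i, j, k) - 1) * spacing` in millimetres.
#'
#' @param values 3D numeric array of HU values.
#' @param spacing numeric length-3, mm per voxel along each axis; must be
#'   strictly positive.
#' @param origin numeric length-3, mm position of the centre of voxel
#'   `(1, 1, 1)`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (any(dim(values) < c(8L, 8L, 4L))) stop("volume too small: need shape >= (8, 8, 4)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  if (!all(is.finite(values))) stop("HU values must be finite")
  structure(list(values = values, spacing = spacing, origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%.1f, %.1f, %.1f) mm\n",
              min(x$values), max(x$values), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

# mm coordinates of voxel centres along one axis
axis_mm <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$values)[axis]) - 1) * vol$spacing[axis]
}

# mm coordinates for a matrix of 1-based voxel indices (n x 3)
voxel_to_mm <- function(idx, spacing, origin = c(0, 0, 0)) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

# Full coordinate field A[i,j,k] = f1[i] + f2[j] + f3[k], returned as a vector
# in array order. Used by the vectorized cylinder rasterizer.
coord_field <- function(f1, f2, f3) {
  n1 <- length(f1); n2 <- length(f2); n3 <- length(f3)
  rep(f1, times = n2 * n3) + rep(rep(f2, each = n1), times = n3) + rep(f3, each = n1 * n2)
}

#' Read a volume from NIfTI
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume]. Spacing is taken from the NIfTI pixdim; the
#'   origin is set to zero (analysis is translation invariant).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp)
}

#' Write a volume or mask to NIfTI
#'
#' @param vol an [image_volume] or a 3D array (masks are written as uint8).
#' @param path output path.
#' @param spacing mm spacing, required when `vol` is a bare array.
#' @param datatype NIfTI datatype; masks default to `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(vol, path, spacing = NULL, datatype = "auto") {
  if (inherits(vol, "image_volume")) {
    arr <- vol$values
    spacing <- vol$spacing
  } else {
    arr <- vol
    if (is.null(spacing)) stop("spacing required when writing a bare array")
    if (is.logical(arr)) {
      arr <- array(as.integer(arr), dim = dim(arr))
      if (identical(datatype, "auto")) datatype <- "uint8"
    }
  }
  attr(arr, "pixdim") <- spacing
  img <- RNifti::asNifti(arr, datatype = if (identical(datatype, "auto")) "double" else datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Window and normalize a CT volume for model input
#'
#' Clips HU values to a display window and affinely rescales to \[0, 1\].
#' The default window of \[-300, 100\] HU brackets soft tissue so the
#' low-contrast valve region occupies most of the dynamic range.
#'
#' @param vol an [image_volume] (or 3D array).
#' @param window numeric length-2, HU window; default `c(-300, 100)`.
#' @return Same type as input with values in \[0, 1\].
#' @export
window_normalize <- function(vol, window = c(-300, 100)) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  f <- function(v) (pmin(pmax(v, window[1]), window[2]) - window[1]) / diff(window)
  if (inherits(vol, "image_volume")) {
    vol$values <- array(f(vol$values), dim = dim(vol$values))
    vol
  } else {
    array(f(vol), dim = dim(vol))
  }
}
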