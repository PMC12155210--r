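# Minimal DICOM series reader: single-frame uncompressed little-endian CT
# slices (explicit or implicit VR). Covers the tags a calcium-score pipeline
# needs — geometry, rescale slope/intercept and pixel data — and refuses
# anything else loudly. Not a general DICOM implementation.

read_uint <- function(raw, n) sum(as.integer(raw[seq_len(n)]) * 256^(seq_len(n) - 1))

dicom_tags <- list(
  rows = c(0x0028, 0x0010), cols = c(0x0028, 0x0011),
  pixel_spacing = c(0x0028, 0x0030), position = c(0x0020, 0x0032),
  slice_location = c(0x0020, 0x1041),
  intercept = c(0x0028, 0x1052), slope = c(0x0028, 0x1053),
  bits_allocated = c(0x0028, 0x0100), pixel_representation = c(0x0028, 0x0103),
  transfer_syntax = c(0x0002, 0x0010), pixel_data = c(0x7FE0, 0x0010))

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  out <- list()
  explicit <- TRUE          # file meta group is always explicit LE
  main_explicit <- NA
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8 <= length(raw)) {
    group <- read_uint(raw[pos:(pos + 1)], 2)
    elem <- read_uint(raw[(pos + 2):(pos + 3)], 2)
    pos <- pos + 4L
    if (group != 0x0002 && is.na(main_explicit)) {
      # decide the main dataset encoding from the transfer syntax
      ts <- out$transfer_syntax
      if (is.null(ts)) stop("missing transfer syntax UID")
      if (ts == "1.2.840.10008.1.2") main_explicit <- FALSE
      else if (ts == "1.2.840.10008.1.2.1") main_explicit <- TRUE
      else stop("unsupported transfer syntax: ", ts)
      explicit <- main_explicit
    }
    if (explicit) {
      vr <- rawToChar(raw[pos:(pos + 1)])
      if (vr %in% long_vrs) {
        len <- read_uint(raw[(pos + 4):(pos + 7)], 4)
        pos <- pos + 8L
      } else {
        len <- read_uint(raw[(pos + 2):(pos + 3)], 2)
        pos <- pos + 4L
      }
    } else {
      len <- read_uint(raw[pos:(pos + 3)], 4)
      pos <- pos + 4L
    }
    if (len == 0xFFFFFFFF) stop("undefined-length elements are not supported")
    val <- raw[pos:(pos + len - 1)]
    pos <- pos + len
    for (nm in names(dicom_tags)) {
      tg <- dicom_tags[[nm]]
      if (group == tg[1] && elem == tg[2]) {
        out[[nm]] <- if (nm == "pixel_data") val else decode_dicom_value(nm, val)
      }
    }
    if (!is.null(out$pixel_data)) break
  }
  required <- c("rows", "cols", "pixel_spacing", "bits_allocated", "pixel_data")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0)
    stop("DICOM file missing required attributes: ", paste(missing, collapse = ", "))
  if (out$bits_allocated != 16) stop("only 16-bit pixel data is supported")
  signed <- isTRUE(out$pixel_representation == 1)
  px <- readBin(out$pixel_data, "integer", n = out$rows * out$cols,
                size = 2, signed = signed, endian = "little")
  if (!signed) px[px < 0] <- px[px < 0] + 65536
  out$pixels <- px
  out$pixel_data <- NULL
  out
}

decode_dicom_value <- function(nm, val) {
  if (nm %in% c("rows", "cols", "bits_allocated", "pixel_representation"))
    return(read_uint(val, length(val)))
  s <- trimws(rawToChar(val[val != as.raw(0)]))
  if (nm == "transfer_syntax") return(s)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

#' Read a DICOM series directory as an image volume
#'
#' Reads every file in the directory, applies the rescale slope/intercept to
#' obtain HU, sorts slices by z position, and derives the slice spacing from
#' the gaps (which must be uniform). Mixed in-plane geometry or non-uniform
#' slice gaps raise errors.
#'
#' @param dir directory containing one single-frame-per-file series.
#' @return An [image_volume] in HU.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2) stop("need at least two DICOM slices in ", dir)
  slices <- lapply(files, parse_dicom_file)
  rows <- unique(vapply(slices, function(s) s$rows, numeric(1)))
  cols <- unique(vapply(slices, function(s) s$cols, numeric(1)))
  sp <- unique(t(vapply(slices, function(s) s$pixel_spacing, numeric(2))))
  if (length(rows) != 1 || length(cols) != 1 || nrow(sp) != 1)
    stop("mixed slice geometry in series")
  z <- vapply(slices, function(s) {
    if (!is.null(s$position)) s$position[3]
    else if (!is.null(s$slice_location)) s$slice_location
    else stop("slice has neither ImagePositionPatient nor SliceLocation")
  }, numeric(1))
  ord <- order(z)
  gaps <- diff(z[ord])
  if (any(abs(gaps - gaps[1]) > 1e-3))
    stop("non-uniform slice spacing: gaps ", paste(round(gaps, 3), collapse = ", "))
  vals <- vapply(slices[ord], function(s) {
    slope <- if (is.null(s$slope)) 1 else s$slope
    inter <- if (is.null(s$intercept)) 0 else s$intercept
    slope * s$pixels + inter
  }, numeric(rows * cols))
  # PixelData is row-major (rows of y), giving x fastest in our convention
  arr <- array(as.numeric(vals), dim = c(cols, rows, length(slices)))
  # PixelSpacing is (row spacing = y, column spacing = x)
  image_volume(arr, spacing = c(sp[1, 2], sp[1, 1], abs(gaps[1])),
               origin = c(0, 0, min(z)))
}
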