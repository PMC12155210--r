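#' Minimum lesion footprint in voxels
#'
#' Agatston criteria require a 2D connected component of at least 1 mm^2:
#' this is the smallest voxel count whose in-plane area reaches that bound.
#'
#' @param in_plane_spacing mm spacing `c(sx, sy)`.
#' @param min_area_mm2 area criterion, default 1 mm^2.
#' @return Integer voxel count.
#' @export
min_area_voxels <- function(in_plane_spacing, min_area_mm2 = 1) {
  if (any(in_plane_spacing <= 0)) stop("spacing must be positive")
  a <- prod(in_plane_spacing[1:2])
  as.integer(ceiling(min_area_mm2 / a - 1e-9))
}

agatston_weight <- function(max_hu) {
  ifelse(max_hu >= 400, 4L, ifelse(max_hu >= 300, 3L, ifelse(max_hu >= 200, 2L, 1L)))
}

#' Find calcified lesions inside an ROI
#'
#' Applies the Agatston detection criteria inside a region of interest:
#' voxels at or above the HU threshold are grouped into 8-connected 2D
#' components per slice, components below the area criterion are discarded,
#' and surviving components are merged across slices into 3D lesions by
#' 26-connectivity.
#'
#' @param vol an [image_volume] of HU values.
#' @param roi_mask logical array congruent with `vol` restricting the search.
#' @param hu_threshold calcium HU threshold (default 130).
#' @param min_area_mm2 minimum 2D component area (default 1 mm^2).
#' @return A `calc_lesions` list: per-lesion voxel indices and a
#'   slice-component table (`tibble` with slice, voxel count, area, max HU,
#'   density weight and Agatston contribution).
#' @export
find_lesions <- function(vol, roi_mask, hu_threshold = 130, min_area_mm2 = 1) {
  if (!identical(dim(vol$values), dim(roi_mask)))
    stop("volume and ROI mask shapes differ")
  sp <- vol$spacing
  cand <- (vol$values >= hu_threshold) & roi_mask
  dims <- dim(cand)
  lab <- cpp_label_slices8(as.vector(cand), dims)
  nlab <- attr(lab, "n")
  empty <- structure(list(lesions = list(),
                          components = component_table(NULL),
                          spacing = sp),
                     class = "calc_lesions")
  if (nlab == 0) return(empty)
  lab <- array(lab, dim = dims)
  # per-component voxel count and max HU
  comp_ids <- seq_len(nlab)
  sel <- which(lab > 0)
  comp_of <- lab[sel]
  n_vox <- tabulate(comp_of, nbins = nlab)
  keep <- n_vox >= min_area_voxels(sp, min_area_mm2)
  if (!any(keep)) return(empty)
  # zero out rejected components before 3D grouping
  drop_sel <- sel[!keep[comp_of]]
  lab[drop_sel] <- 0L
  group <- cpp_group26(as.vector(lab), dims, nlab)   # comp id -> lesion id
  group[!keep] <- NA_integer_
  # renumber lesions compactly
  lesion_ids <- sort(unique(group[keep]))
  remap <- match(group, lesion_ids)
  sel <- which(lab > 0)
  comp_of <- lab[sel]
  hu <- vol$values[sel]
  max_hu <- vapply(split(hu, comp_of), max, numeric(1))
  comp_present <- as.integer(names(max_hu))
  slice_of <- ((sel - 1) %/% (dims[1] * dims[2])) + 1
  comp_slice <- vapply(split(slice_of, comp_of), function(s) s[1], numeric(1))
  area <- n_vox[comp_present] * sp[1] * sp[2]
  w <- agatston_weight(max_hu)
  comps <- tibble::tibble(
    component = comp_present,
    lesion = remap[comp_present],
    slice = as.integer(comp_slice),
    n_voxels = n_vox[comp_present],
    area_mm2 = area,
    max_hu = as.numeric(max_hu),
    weight = as.integer(w),
    agatston = area * w)
  voxels <- which(lab > 0, arr.ind = TRUE)
  lesion_of_voxel <- remap[lab[lab > 0]]
  lesions <- lapply(seq_along(lesion_ids), function(i) {
    vsel <- lesion_of_voxel == i
    list(voxels = voxels[vsel, , drop = FALSE],
         hu = hu[vsel],
         agatston = sum(comps$agatston[comps$lesion == i]),
         volume_mm3 = sum(vsel) * prod(sp),
         mean_hu = mean(hu[vsel]))
  })
  structure(list(lesions = lesions, components = comps, spacing = sp),
            class = "calc_lesions")
}

component_table <- function(x) {
  if (is.null(x))
    return(tibble::tibble(component = integer(), lesion = integer(),
                          slice = integer(), n_voxels = integer(),
                          area_mm2 = numeric(), max_hu = numeric(),
                          weight = integer(), agatston = numeric()))
  x
}

#' @export
print.calc_lesions <- function(x, ...) {
  cat(sprintf("<calc_lesions> %d lesion(s), %d slice component(s)\n",
              length(x$lesions), nrow(x$components)))
  invisible(x)
}

#' Agatston score
#'
#' Sum over 2D slice components of component area (mm^2) times the density
#' weight 1/2/3/4 for a component maximum HU in \[130, 200) / \[200, 300) /
#' \[300, 400) / >= 400. Computed on native slices without slice-increment
#' rescaling.
#'
#' @param lesions a `calc_lesions` from [find_lesions()].
#' @return Agatston score (Ag).
#' @export
agatston_score <- function(lesions) sum(lesions$components$agatston)

#' Volume score
#'
#' Total volume (mm^3) of voxels belonging to qualifying lesions.
#'
#' @param lesions a `calc_lesions`.
#' @return Volume in mm^3.
#' @export
volume_score <- function(lesions) {
  sum(vapply(lesions$lesions, function(l) l$volume_mm3, numeric(1)))
}

#' Mass score
#'
#' `calibration * sum_lesions(mean HU x lesion volume)`. The scanner-specific
#' hydroxyapatite calibration factor is configurable; the default 0.001 is a
#' placeholder that simply converts HU.mm^3 to milligram-scale units and
#' should be replaced by a phantom-derived factor for absolute mass.
#'
#' @param lesions a `calc_lesions`.
#' @param calibration positive calibration factor (default 0.001).
#' @return Mass in mg (relative units under the default calibration).
#' @export
mass_score <- function(lesions, calibration = 0.001) {
  if (calibration <= 0) stop("calibration factor must be positive")
  calibration * sum(vapply(lesions$lesions, function(l) l$mean_hu * l$volume_mm3,
                           numeric(1)))
}

#' Count valid lesions
#'
#' Number of 3D lesions whose individual Agatston score strictly exceeds the
#' validity threshold (10 Ag by default), guarding the lesion count against
#' noise specks.
#'
#' @param lesions a `calc_lesions`.
#' @param min_agatston validity threshold (strict `>`).
#' @return Integer count.
#' @export
count_valid_lesions <- function(lesions, min_agatston = 10) {
  sum(vapply(lesions$lesions, function(l) l$agatston, numeric(1)) > min_agatston)
}

#' Severity policy for aortic valve Agatston scores
#'
#' Clinical bin edges and sex-specific thresholds: severe aortic stenosis is
#' likely above 2000 Ag in males and 1200 Ag in females, and unlikely below
#' 1600 / 800; a conservative intermediate threshold pair (1500 / 900) is
#' also carried for sensitivity analyses.
#'
#' @param bin_edges increasing interior edges of the positive-score bins.
#' @param severe,unlikely,conservative named numeric pairs
#'   `c(male = , female = )`.
#' @param lesion_validity_ag per-lesion validity threshold.
#' @return A `severity_policy`.
#' @export
severity_policy <- function(bin_edges = c(800, 1200, 2000),
                            severe = c(male = 2000, female = 1200),
                            unlikely = c(male = 1600, female = 800),
                            conservative = c(male = 1500, female = 900),
                            lesion_validity_ag = 10) {
  if (is.unsorted(bin_edges, strictly = TRUE)) stop("bin edges must be strictly increasing")
  structure(list(bin_edges = bin_edges, severe = severe, unlikely = unlikely,
                 conservative = conservative,
                 lesion_validity_ag = lesion_validity_ag),
            class = "severity_policy")
}

severity_bin_labels <- function(edges) {
  lo <- c(1, edges)
  hi <- c(edges, Inf)
  c("0", ifelse(is.finite(hi), paste0(lo, "-", hi), paste0(lo[length(lo)], "+")))
}

#' Severity bin and sex-specific flags for an Agatston score
#'
#' Bins scores as 0, 1-800, 800-1200, 1200-2000 and 2000+ and applies the
#' sex-specific likely-severe and unlikely-severe thresholds. With unknown
#' sex the bin is still reported but the flags are `NA`.
#'
#' @param agatston non-negative Agatston score.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param policy a [severity_policy].
#' @return `tibble` with `severity_bin`, `severe`, `unlikely_severe`,
#'   `severe_conservative`.
#' @export
severity <- function(agatston, sex = "unknown", policy = severity_policy()) {
  if (any(agatston < 0)) stop("Agatston score cannot be negative")
  sex <- match.arg(sex, c("male", "female", "unknown"))
  labs <- severity_bin_labels(policy$bin_edges)
  bin <- ifelse(agatston == 0, labs[1],
                labs[1 + findInterval(agatston, c(policy$bin_edges, Inf),
                                      left.open = TRUE) + 1])
  if (sex == "unknown") {
    sev <- NA; unl <- NA; con <- NA
  } else {
    sev <- agatston > policy$severe[[sex]]
    unl <- agatston < policy$unlikely[[sex]]
    con <- agatston > policy$conservative[[sex]]
  }
  tibble::tibble(severity_bin = bin, severe = sev, unlikely_severe = unl,
                 severe_conservative = con)
}

#' Score a case: all calcification metrics inside an ROI
#'
#' Runs lesion detection and assembles the per-case report: Agatston, volume
#' and mass scores, lesion counts, severity bin and sex-specific flags.
#'
#' @param vol an [image_volume] (HU, acquisition space).
#' @param roi_mask logical cylinder ROI mask on the same grid.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param policy a [severity_policy].
#' @param calibration mass calibration factor.
#' @param hu_threshold,min_area_mm2 Agatston detection criteria.
#' @return One-row `tibble` (`score_report`).
#' @export
score_case <- function(vol, roi_mask, sex = "unknown", policy = severity_policy(),
                       calibration = 0.001, hu_threshold = 130, min_area_mm2 = 1) {
  les <- find_lesions(vol, roi_mask, hu_threshold, min_area_mm2)
  ag <- agatston_score(les)
  sev <- severity(ag, sex, policy)
  tibble::tibble(
    agatston = ag,
    volume_mm3 = volume_score(les),
    mass_mg = mass_score(les, calibration),
    n_lesions = length(les$lesions),
    n_valid_lesions = count_valid_lesions(les, policy$lesion_validity_ag),
    sex = sex,
    severity_bin = sev$severity_bin,
    severe = sev$severe,
    unlikely_severe = sev$unlikely_severe,
    severe_conservative = sev$severe_conservative)
}
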