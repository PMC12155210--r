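#' Pipeline configuration
#'
#' One namespace for every threshold in the pipeline so no constant is
#' hidden: Agatston detection (130 HU, 1 mm^2), lesion validity (10 Ag),
#' noise QC (36 / 45 HU), the HU window, the disk-to-cylinder expansion
#' defaults and the severity policy.
#'
#' @param qc_sd_denoise,qc_sd_exclude aorta noise thresholds, HU.
#' @param hu_threshold calcium threshold, HU.
#' @param min_area_mm2 minimum 2D component area.
#' @param calibration mass calibration factor.
#' @param window HU window for model input normalization.
#' @param expansion an [expansion_config].
#' @param policy a [severity_policy].
#' @param crop_shape isotropic model-input shape.
#' @return An `avc_config` list.
#' @export
avc_config <- function(qc_sd_denoise = 36, qc_sd_exclude = 45,
                       hu_threshold = 130, min_area_mm2 = 1,
                       calibration = 0.001, window = c(-300, 100),
                       expansion = expansion_config(),
                       policy = severity_policy(),
                       crop_shape = c(176, 176, 128)) {
  structure(list(qc_sd_denoise = qc_sd_denoise, qc_sd_exclude = qc_sd_exclude,
                 hu_threshold = hu_threshold, min_area_mm2 = min_area_mm2,
                 calibration = calibration, window = window,
                 expansion = expansion, policy = policy,
                 crop_shape = crop_shape),
            class = "avc_config")
}

#' Read a CT volume from NIfTI or a DICOM series directory
#'
#' @param path a `.nii`/`.nii.gz` file or a directory of single-frame DICOM
#'   files (uncompressed little-endian; rescale slope/intercept applied).
#' @return An [image_volume] in HU.
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (grepl("\\.nii(\\.gz)?$", path)) return(read_nifti_volume(path))
  stop("unsupported volume format: ", path)
}

#' Run the full analysis pipeline on one case
#'
#' Fixed stage order: noise QC (when an aorta mask is supplied), optional
#' median denoising, cylinder ROI definition through either the annotate
#' path (disk annotation, PCA expansion) or the predict path (isotropic
#' crop, network, centre-of-mass linkage, mapping back to acquisition
#' space), Agatston scoring on the acquisition-space volume, severity
#' binning, and optional regional sub-ROI analysis. Cases failing QC are
#' returned as excluded records without scores.
#'
#' @param vol an [image_volume] in HU (acquisition space).
#' @param case_id identifier carried into the record.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param disk optional [disk_annotation] (annotate path).
#' @param net,heart_bounds optional trained `avc_network` plus heart
#'   bounding box (predict path; used when `disk` is NULL).
#' @param aorta_mask optional descending-aorta mask enabling QC.
#' @param anchors_mm optional anchor matrix for 27-region analysis
#'   (defaults to mm-mapped disk anchors on the annotate path).
#' @param regional run sub-ROI analysis (default TRUE).
#' @param config an [avc_config].
#' @return A `case_record` list: `case_id`, `status` (`scored` or
#'   `excluded`), `qc`, `source` (`annotated`/`predicted`), `params`,
#'   `scores`, `regional`, `com_fallback`.
#' @export
run_pipeline <- function(vol, case_id = "case", sex = "unknown", disk = NULL,
                         net = NULL, heart_bounds = NULL, aorta_mask = NULL,
                         anchors_mm = NULL, regional = TRUE,
                         config = avc_config()) {
  qc <- NULL
  if (!is.null(aorta_mask)) {
    qc <- aorta_noise(vol, aorta_mask, sd_denoise = config$qc_sd_denoise,
                      sd_exclude = config$qc_sd_exclude)
    if (qc$status == "exclude") {
      return(structure(list(case_id = case_id, status = "excluded", qc = qc,
                            source = NA_character_, params = NULL,
                            scores = NULL, regional = NULL),
                       class = "case_record"))
    }
    if (qc$status == "denoise") vol <- median_denoise(vol)
  }
  com_fallback <- FALSE
  if (!is.null(disk)) {
    dc <- disk_to_cylinder(disk, config$expansion, vol)
    params <- dc$params
    mask <- dc$mask
    source <- "annotated"
    if (is.null(anchors_mm) && !is.null(disk$anchors))
      anchors_mm <- voxel_to_mm(disk$anchors, vol$spacing, vol$origin) |>
        (\(m) { rownames(m) <- rownames(disk$anchors); m })()
  } else {
    if (is.null(net) || is.null(heart_bounds))
      stop("predict path needs a trained network and heart bounds")
    rc <- resample_crop(vol, heart_bounds, out_shape = net$cfg$input_shape)
    img <- window_normalize(rc$volume, config$window)
    pred <- predict_cylinder(net, img, rc$crop)
    params <- pred$params
    com_fallback <- pred$com_fallback
    mask <- reconstruct_cylinder_mask(params, vol)
    source <- "predicted"
  }
  scores <- score_case(vol, mask, sex = sex, policy = config$policy,
                       calibration = config$calibration,
                       hu_threshold = config$hu_threshold,
                       min_area_mm2 = config$min_area_mm2)
  reg <- NULL
  if (regional) {
    part <- partition_cylinder(mask, params, vol, anchors_mm = anchors_mm)
    reg <- regional_scores(vol, part, hu_threshold = config$hu_threshold,
                           min_area_mm2 = config$min_area_mm2)
  }
  structure(list(case_id = case_id, status = "scored", qc = qc,
                 source = source, params = params, scores = scores,
                 regional = reg, com_fallback = com_fallback),
            class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  if (x$status == "excluded") {
    cat(sprintf("<case_record> %s: excluded (aorta sd %.1f HU)\n",
                x$case_id, x$qc$sd_hu))
  } else {
    cat(sprintf("<case_record> %s: %s cylinder, Ag %.1f, bin %s\n",
                x$case_id, x$source, x$scores$agatston, x$scores$severity_bin))
  }
  invisible(x)
}

#' Summarize a cohort of case records
#'
#' @param records list of `case_record`s.
#' @return List with `cases` (one row per scored case), `bins` (severity-bin
#'   histogram by sex) and counts of excluded cases and severe flags.
#' @export
cohort_summary <- function(records) {
  scored <- Filter(function(r) r$status == "scored", records)
  excluded <- length(records) - length(scored)
  if (length(scored) == 0)
    return(list(cases = tibble::tibble(), bins = tibble::tibble(),
                n_excluded = excluded, n_severe = 0L))
  cases <- do.call(rbind, lapply(scored, function(r)
    tibble::tibble(case_id = r$case_id, source = r$source, r$scores)))
  bins <- as.data.frame(table(bin = cases$severity_bin, sex = cases$sex))
  names(bins)[3] <- "n"
  list(cases = cases, bins = tibble::as_tibble(bins),
       n_excluded = excluded,
       n_severe = sum(cases$severe, na.rm = TRUE))
}

#' Write per-case scores to CSV
#'
#' @param summary result of [cohort_summary()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_csv <- function(summary, path) {
  utils::write.csv(summary$cases, path, row.names = FALSE)
  invisible(path)
}

#' Severity-bin histogram plot
#'
#' @param summary result of [cohort_summary()].
#' @return A ggplot object.
#' @export
plot_severity_bins <- function(summary) {
  ggplot2::ggplot(summary$bins,
                  ggplot2::aes(x = .data$bin, y = .data$n, fill = .data$sex)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "AV Agatston bin", y = "cases",
                  title = "Aortic valve calcification severity")
}
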