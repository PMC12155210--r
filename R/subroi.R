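#' Sub-ROI partition scheme
#'
#' Defines how the cylinder ROI is decomposed: three concentric shells at
#' fractions of the radius (A inner, B middle, C outer), three height slabs
#' (D top toward the aortic root, E middle, F bottom toward the cusps), and
#' three angular sectors bounded by rays through the projected anchor points
#' (G flanked by RAPA and PALA, H by PALA and LARA, I by LARA and RAPA).
#'
#' @param shell_fractions strictly increasing radius fractions ending at 1.
#' @param slab_fractions strictly increasing height fractions ending at 1.
#' @param sector_mode `"through_anchor"` (boundary rays pass through the
#'   anchors) or `"bisector"` (boundaries bisect between consecutive
#'   anchors).
#' @return A `sub_roi_scheme`.
#' @export
sub_roi_scheme <- function(shell_fractions = c(1, 2, 3) / 3,
                           slab_fractions = c(1, 2, 3) / 3,
                           sector_mode = c("through_anchor", "bisector")) {
  for (f in list(shell_fractions, slab_fractions)) {
    if (is.unsorted(f, strictly = TRUE) || abs(f[length(f)] - 1) > 1e-9)
      stop("fractions must be strictly increasing and end at 1")
  }
  structure(list(shell_fractions = shell_fractions,
                 slab_fractions = slab_fractions,
                 sector_mode = match.arg(sector_mode)),
            class = "sub_roi_scheme")
}

# wrap angle into [0, 2*pi)
wrap_angle <- function(a) a %% (2 * pi)

#' Sector boundary rays from the anchor points
#'
#' Projects the three anchors into the disk plane about the cylinder axis and
#' returns the boundary angles plus the three sectors as counterclockwise
#' arcs. Sector G is the arc between the RAPA and PALA rays not containing
#' LARA, H between PALA and LARA, I between LARA and RAPA.
#'
#' @param anchors_mm 3 x 3 matrix of anchor positions in mm with rownames
#'   PALA, LARA, RAPA.
#' @param params a [cylinder_params] giving axis and origin.
#' @param basis optional in-plane reference direction (unit, orthogonal to
#'   the axis); a deterministic one is constructed when NULL.
#' @return List with `angles` (named boundary angles, radians) and `sectors`
#'   (tibble with sector, from, to as ccw arcs).
#' @export
sector_boundaries <- function(anchors_mm, params, basis = NULL) {
  anchors_mm <- as.matrix(anchors_mm)
  if (!setequal(rownames(anchors_mm), c("PALA", "LARA", "RAPA")))
    stop("anchors must have rownames PALA, LARA, RAPA")
  B <- plane_basis(params$normal, basis)
  d <- sweep(anchors_mm, 2, params$origin_mm)
  x <- d %*% B$e1
  y <- d %*% B$e2
  ang <- as.vector(wrap_angle(atan2(y, x)))
  names(ang) <- rownames(anchors_mm)
  sep <- outer(ang, ang, function(a, b) pmin(wrap_angle(a - b), wrap_angle(b - a)))
  if (min(sep[upper.tri(sep)]) < 1e-9 || any(sqrt(x^2 + y^2) < 1e-9))
    stop("two anchors project to the same angle; sectors undefined")
  arc <- function(from, to, avoid) {
    # ccw arc from -> to; flip if it contains the avoided anchor
    if (ccw_dist(ang[[from]], ang[[avoid]]) < ccw_dist(ang[[from]], ang[[to]]))
      c(ang[[to]], ang[[from]]) else c(ang[[from]], ang[[to]])
  }
  g <- arc("RAPA", "PALA", "LARA")
  h <- arc("PALA", "LARA", "RAPA")
  i <- arc("LARA", "RAPA", "PALA")
  sectors <- tibble::tibble(sector = c("G", "H", "I"),
                            from = c(g[1], h[1], i[1]),
                            to = c(g[2], h[2], i[2]))
  list(angles = ang, sectors = sectors, basis = B)
}

ccw_dist <- function(from, to) wrap_angle(to - from)

# deterministic in-plane orthonormal basis for a cylinder axis
plane_basis <- function(normal, e1 = NULL) {
  if (is.null(e1)) {
    seed <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- cross3(seed, normal)
  } else {
    e1 <- e1 - sum(e1 * normal) * normal
  }
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(normal, e1)
  list(e1 = e1, e2 = e2 / sqrt(sum(e2^2)))
}

#' Partition a cylinder ROI into shell x slab (x sector) sub-regions
#'
#' Assigns every ROI voxel exactly one (shell, slab, sector) triple through
#' half-open intervals on radius fraction, height fraction and angle. With
#' anchors this yields 27 crossed regions and 9 marginal groupings (A-I);
#' without anchors sectors are undefined and the 9 shell x slab regions are
#' produced instead.
#'
#' @param mask logical ROI mask.
#' @param params the [cylinder_params] that generated the mask.
#' @param grid grid geometry.
#' @param anchors_mm optional anchor matrix (see [sector_boundaries()]).
#' @param scheme a [sub_roi_scheme].
#' @param basis optional in-plane reference direction forwarded to
#'   [sector_boundaries()].
#' @return A `sub_roi_partition`: integer `region` array (0 outside), and a
#'   `regions` tibble with shell/slab/sector codes and labels like
#'   `"A-D-G"`.
#' @export
partition_cylinder <- function(mask, params, grid, anchors_mm = NULL,
                               scheme = sub_roi_scheme(), basis = NULL) {
  g <- as_grid_geometry(grid)
  idx <- which(mask)
  region <- array(0L, dim = g$dim)
  have_sectors <- !is.null(anchors_mm)
  if (length(idx) > 0) {
    vox <- arrayInd(idx, g$dim)
    pts <- voxel_to_mm(vox, g$spacing, g$origin)
    d <- sweep(pts, 2, params$origin_mm)
    zp <- as.vector(d %*% params$normal)
    rho <- sqrt(pmax(rowSums(d^2) - zp^2, 0))
    # half-open (lo, hi] intervals: a voxel exactly on a fraction boundary is
    # assigned to the lower region
    shell <- 1L + findInterval(rho / params$radius_mm,
                               scheme$shell_fractions[-length(scheme$shell_fractions)],
                               left.open = TRUE)
    # height fraction measured from the top (+dA side); D = top slab
    z_top <- if (!is.null(params$dA_mm)) params$dA_mm else params$height_mm / 2
    tfrac <- (z_top - zp) / params$height_mm
    slab <- 1L + findInterval(tfrac,
                              scheme$slab_fractions[-length(scheme$slab_fractions)],
                              left.open = TRUE)
    slab <- pmin(pmax(slab, 1L), 3L)
    shell <- pmin(shell, 3L)
    if (have_sectors) {
      sb <- sector_boundaries(anchors_mm, params, basis)
      B <- sb$basis
      theta <- wrap_angle(atan2(d %*% B$e2, d %*% B$e1))
      sector <- integer(length(theta))
      if (scheme$sector_mode == "bisector") {
        sec <- bisector_sectors(sb)
      } else {
        sec <- sb$sectors
      }
      for (s in seq_len(3)) {
        span <- ccw_dist(sec$from[s], sec$to[s])
        inside <- ccw_dist(sec$from[s], theta) < span - 1e-12
        on_start <- abs(wrap_angle(theta - sec$from[s])) < 1e-12
        sector[inside | on_start] <- s
      }
      sector[sector == 0L] <- 1L  # numerical guard at the closing boundary
      code <- (shell - 1L) * 9L + (slab - 1L) * 3L + sector
    } else {
      code <- (shell - 1L) * 3L + slab
    }
    region[idx] <- code
  }
  regions <- region_table(have_sectors)
  n <- tabulate(region[region > 0L], nbins = nrow(regions))
  regions$n_voxels <- n
  structure(list(region = region, regions = regions,
                 have_sectors = have_sectors, params = params,
                 scheme = scheme),
            class = "sub_roi_partition")
}

# shift sector boundaries to the bisectors between consecutive anchors
bisector_sectors <- function(sb) {
  sec <- sb$sectors
  mid <- function(from, to) wrap_angle(from + ccw_dist(from, to) / 2)
  b_g <- mid(sec$from[1], sec$to[1])  # inside G: between RAPA and PALA rays
  b_h <- mid(sec$from[2], sec$to[2])
  b_i <- mid(sec$from[3], sec$to[3])
  # sectors now run bisector-to-bisector, each containing one anchor ray;
  # keep labels tied to the flanking anatomy of the original arcs
  tibble::tibble(sector = c("G", "H", "I"),
                 from = c(b_i, b_g, b_h),
                 to = c(b_g, b_h, b_i))
}

region_table <- function(have_sectors) {
  shells <- c("A", "B", "C"); slabs <- c("D", "E", "F"); secs <- c("G", "H", "I")
  if (have_sectors) {
    gdf <- expand.grid(sector = secs, slab = slabs, shell = shells,
                       stringsAsFactors = FALSE)[, c("shell", "slab", "sector")]
    tibble::tibble(region = seq_len(27),
                   shell = gdf$shell, slab = gdf$slab, sector = gdf$sector,
                   label = paste(gdf$shell, gdf$slab, gdf$sector, sep = "-"))
  } else {
    gdf <- expand.grid(slab = slabs, shell = shells, stringsAsFactors = FALSE)
    tibble::tibble(region = seq_len(9),
                   shell = gdf$shell, slab = gdf$slab, sector = NA_character_,
                   label = paste(gdf$shell, gdf$slab, sep = "-"))
  }
}

#' Extract a single sub-region mask
#'
#' @param part a `sub_roi_partition`.
#' @param region region number or label (e.g. `"A-D-G"`).
#' @return Logical mask array.
#' @export
region_mask <- function(part, region) {
  if (is.character(region))
    region <- part$regions$region[match(region, part$regions$label)]
  part$region == region
}

#' Marginal (A-I) mask
#'
#' Union of all crossed regions sharing one shell, slab or sector code.
#'
#' @param part a `sub_roi_partition`.
#' @param code one of `"A"`..`"I"`.
#' @return Logical mask array.
#' @export
marginal_mask <- function(part, code) {
  r <- part$regions
  sel <- r$region[r$shell == code | r$slab == code |
                    (!is.na(r$sector) & r$sector == code)]
  array(part$region %in% sel, dim = dim(part$region))
}

#' Regional calcification scores
#'
#' Re-runs Agatston lesion detection inside every crossed sub-region and
#' every marginal region. Regional volume scores are obtained by
#' intersecting the whole-ROI qualifying lesions with each region, so they
#' are exactly additive across the 27 crossed regions; Agatston scores need
#' not be when a lesion straddles a region boundary (its 2D area and density
#' weighting are re-evaluated per side), which is reported via
#' `agatston_additivity_gap`.
#'
#' @param vol an [image_volume].
#' @param part a `sub_roi_partition`.
#' @param hu_threshold,min_area_mm2 Agatston detection criteria.
#' @return A `regional_report`: tibbles `crossed` and `marginal` with per-
#'   region Agatston and volume scores.
#' @export
regional_scores <- function(vol, part, hu_threshold = 130, min_area_mm2 = 1) {
  roi <- array(part$region > 0L, dim = dim(part$region))
  les_total <- find_lesions(vol, roi, hu_threshold, min_area_mm2)
  # region id of every qualifying calcified voxel (for additive volumes)
  vox_region <- integer(0)
  if (length(les_total$lesions) > 0) {
    vx <- do.call(rbind, lapply(les_total$lesions, function(l) l$voxels))
    vox_region <- part$region[vx]
  }
  voxvol <- prod(vol$spacing)
  reg_volume <- function(sel) sum(vox_region %in% sel) * voxvol
  one_ag <- function(mask) {
    agatston_score(find_lesions(vol, mask, hu_threshold, min_area_mm2))
  }
  crossed <- part$regions
  crossed$agatston <- vapply(crossed$region,
                             function(r) one_ag(region_mask(part, r)), numeric(1))
  crossed$volume_mm3 <- vapply(crossed$region, function(r) reg_volume(r), numeric(1))
  codes <- if (part$have_sectors) LETTERS[1:9] else LETTERS[1:6]
  r <- part$regions
  marg_sel <- lapply(codes, function(cd)
    r$region[r$shell == cd | r$slab == cd | (!is.na(r$sector) & r$sector == cd)])
  marginal <- tibble::tibble(
    code = codes,
    axis = rep(c("shell", "slab", "sector"), each = 3)[seq_along(codes)],
    agatston = vapply(codes, function(cd) one_ag(marginal_mask(part, cd)), numeric(1)),
    volume_mm3 = vapply(marg_sel, reg_volume, numeric(1)))
  structure(list(crossed = crossed, marginal = marginal,
                 total_agatston = agatston_score(les_total),
                 total_volume_mm3 = volume_score(les_total),
                 agatston_additivity_gap = sum(crossed$agatston) -
                   agatston_score(les_total)),
            class = "regional_report")
}

#' @export
print.regional_report <- function(x, ...) {
  cat(sprintf("<regional_report> total Ag %.1f over %d crossed regions\n",
              x$total_agatston, nrow(x$crossed)))
  invisible(x)
}

#' Cohort-average regional heatmap table
#'
#' Averages per-region Agatston scores over a list of regional reports,
#' returning one row per case plus the cohort mean, with columns keyed by
#' region labels (`"A-D-G"` style).
#'
#' @param reports list of `regional_report`s.
#' @return List with `cases` (case x region tibble) and `mean` (named
#'   per-region means).
#' @export
regional_summary <- function(reports) {
  stopifnot(length(reports) > 0)
  labels <- reports[[1]]$crossed$label
  mat <- t(vapply(reports, function(r) r$crossed$agatston, numeric(length(labels))))
  colnames(mat) <- labels
  cases <- tibble::as_tibble(mat)
  list(cases = cases, mean = colMeans(mat))
}

#' Heatmap of mean regional Agatston scores
#'
#' Renders the 27-region (or 9-region) table as slab x sector tiles faceted
#' by shell, mirroring how regional calcification burden is usually
#' displayed.
#'
#' @param report a `regional_report` or the `mean` element of
#'   [regional_summary()] paired with `labels`.
#' @return A ggplot object.
#' @export
plot_regional_heatmap <- function(report) {
  df <- if (inherits(report, "regional_report")) report$crossed else report
  if (all(is.na(df$sector))) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$shell, y = .data$slab,
                                          fill = .data$agatston))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sector, y = .data$slab,
                                          fill = .data$agatston)) +
      ggplot2::facet_wrap(~shell, labeller = ggplot2::label_both)
  }
  p + ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_viridis_c(name = "Agatston") +
    ggplot2::scale_y_discrete(limits = c("F", "E", "D")) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Regional aortic valve calcification")
}
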