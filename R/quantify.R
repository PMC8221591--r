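#' Partition anatomical regions into Pvalb+ and non-Pvalb+ ROIs
#'
#' For every labelled region in `region_mask`, the Pvalb+ ROI class is the
#' set of detected Pvalb cell pixels inside the region and the non-Pvalb+
#' ROI is the region minus all Pvalb cell pixels. The partition is exact:
#' the two classes are disjoint and together cover the region.
#'
#' @param cells a [ComponentSet] of Pvalb cell bodies, or an integer label
#'   matrix of cell pixels.
#' @param region_mask integer label matrix of anatomical regions
#'   (0 = background); names taken from `region_names` or `region_<label>`.
#' @param calibration microns per pixel (taken from `cells` when it is a
#'   [ComponentSet]).
#' @param region_names optional names, one per positive region label.
#' @param region_labels optional integer labels to partition (default: the
#'   positive labels present in the mask); a requested label with no pixels
#'   yields a warning and empty outputs for that region.
#' @return named list, one element per region:
#'   `cellLabels` (integer matrix of Pvalb cell labels inside the region),
#'   `nonPvalb` (logical matrix), `region` (logical matrix),
#'   `region_area_um2`, `pvalb_area_um2`, `non_pvalb_area_um2`, `empty` flag.
#' @export
classifyRois <- function(cells, region_mask, calibration = NULL,
                         region_names = NULL, region_labels = NULL) {
  if (is(cells, "ComponentSet")) {
    if (is.null(calibration)) calibration <- cells@calibration
    cell_labels <- cells@labels
  } else {
    cell_labels <- cells
    storage.mode(cell_labels) <- "integer"
  }
  if (is.null(calibration)) stop("calibration is required")
  if (!identical(dim(cell_labels), dim(region_mask))) {
    stop("cell labels and region mask must share the image shape")
  }
  labs <- if (is.null(region_labels)) {
    sort(unique(as.integer(region_mask[region_mask > 0L])))
  } else {
    as.integer(region_labels)
  }
  if (is.null(region_names)) region_names <- paste0("region_", labs)
  if (length(region_names) != length(labs)) {
    stop("one region name per positive region label is required")
  }
  px_um2 <- calibration^2
  out <- list()
  for (k in seq_along(labs)) {
    reg <- region_mask == labs[k]
    if (!any(reg)) {
      warning(sprintf("region '%s' is empty", region_names[k]))
      out[[region_names[k]]] <- list(
        cellLabels = matrix(0L, nrow(region_mask), ncol(region_mask)),
        nonPvalb = reg, region = reg, region_area_um2 = 0,
        pvalb_area_um2 = 0, non_pvalb_area_um2 = 0, empty = TRUE)
      next
    }
    cl <- cell_labels
    cl[!reg] <- 0L
    nonp <- reg & cell_labels == 0L
    out[[region_names[k]]] <- list(
      cellLabels = cl, nonPvalb = nonp, region = reg,
      region_area_um2 = sum(reg) * px_um2,
      pvalb_area_um2 = sum(cl > 0L) * px_um2,
      non_pvalb_area_um2 = sum(nonp) * px_um2, empty = FALSE)
  }
  out
}

#' Average background intensity of an ROI
#'
#' Mean per-pixel fluorescence over the ROI minus all labelled expression
#' areas (the protocol's "selected background area").
#'
#' @param plane intensity matrix.
#' @param roi logical matrix (the ROI pixels).
#' @param labeled logical or integer matrix of all detected expression
#'   pixels to exclude (default none).
#' @return background mean in a.u. per pixel.
#' @export
estimateBackground <- function(plane, roi, labeled = NULL) {
  stopifnot(identical(dim(plane), dim(roi)))
  bg <- roi & (if (is.null(labeled)) TRUE else !(labeled > 0))
  if (!any(bg)) {
    stop("labelled expression covers the whole ROI: no background support")
  }
  mean(plane[bg])
}

#' Automatic selection of representative dots
#'
#' Stand-in for the protocol's manual choice of representative dots:
#' isolated components (no neighbouring component centroid within two mean
#' component diameters) whose area lies within the central 50% of the
#' component-area distribution. Falls back to all components (with a
#' warning) if the rule leaves none.
#'
#' @param dots a [ComponentSet] of dot-scale components.
#' @return integer vector of selected component labels.
#' @export
selectRepresentativeDots <- function(dots) {
  st <- componentStats(dots)
  if (nrow(st) == 0L) stop("no dot components to select from")
  if (nrow(st) == 1L) return(st$label)
  diam_px <- 2 * sqrt(mean(st$n_px) / pi)
  d <- as.matrix(dist(st[, c("centroid_row", "centroid_col")]))
  diag(d) <- Inf
  isolated <- apply(d, 1L, min) > 2 * diam_px
  qs <- quantile(st$area_um2, c(0.25, 0.75), names = FALSE)
  central <- st$area_um2 >= qs[1L] & st$area_um2 <= qs[2L]
  sel <- st$label[isolated & central]
  if (!length(sel)) sel <- st$label[isolated]
  if (!length(sel)) {
    warning("no isolated, central-area dots; using all components")
    sel <- st$label
  }
  sel
}

#' Calibrate the average intensity of a single fluorescent dot
#'
#' `D = (sum of intensities over the selected dots' pixels -
#' background_mean x their total pixel area) / number of selected dots`
#' (or the median of the per-dot background-corrected sums when
#' `average = "median"`). Selection is either an explicit label vector
#' (the manual path) or the automatic rule of [selectRepresentativeDots()].
#'
#' @param plane intensity matrix the components were detected on.
#' @param dots a [ComponentSet] of dot-scale components.
#' @param background_mean background level (a.u./px).
#' @param ids optional integer labels of manually selected dots.
#' @param average `"mean"` (the protocol's formula) or `"median"`.
#' @return single-dot intensity `D > 0` (a.u./dot).
#' @export
calibrateSingleDot <- function(plane, dots, background_mean, ids = NULL,
                               average = c("mean", "median")) {
  average <- match.arg(average)
  st <- componentStats(dots)
  if (nrow(st) == 0L) stop("at least one selected dot is required")
  if (is.null(ids)) ids <- selectRepresentativeDots(dots)
  if (!all(ids %in% st$label)) stop("unknown dot label in 'ids'")
  sel <- st[st$label %in% ids, , drop = FALSE]
  ## intensities re-read from the supplied plane (which may differ from the
  ## detection plane, e.g. rescaled or denoised)
  labs <- componentLabels(dots)
  pos <- labs > 0L & matrix(labs %in% sel$label, nrow(labs))
  totals <- vapply(split(plane[pos], labs[pos]), sum, numeric(1))
  sel$total_intensity <- unname(totals[as.character(sel$label)])
  per_dot <- sel$total_intensity - background_mean * sel$n_px
  D <- if (average == "mean") {
    (sum(sel$total_intensity) - background_mean * sum(sel$n_px)) / nrow(sel)
  } else {
    median(per_dot)
  }
  if (!is.finite(D) || D <= 0) {
    stop("single-dot calibration invalid: background exceeds dot signal")
  }
  D
}

#' Estimate the total fluorescent dot number in an ROI
#'
#' `N = (sum of ROI intensities - background_mean x ROI pixel area) /
#' single_dot_intensity`. The estimate is a ratio of intensities and so is
#' real-valued; a negative numerator is clamped to 0 with a warning.
#'
#' @param plane intensity matrix.
#' @param roi logical matrix of ROI pixels.
#' @param background_mean background level (a.u./px).
#' @param single_dot_intensity calibrated dot intensity (> 0).
#' @return total dot number (real, >= 0).
#' @export
countDots <- function(plane, roi, background_mean, single_dot_intensity) {
  if (single_dot_intensity <= 0) stop("single_dot_intensity must be > 0")
  stopifnot(identical(dim(plane), dim(roi)))
  numerator <- sum(plane[roi]) - background_mean * sum(roi)
  if (numerator < 0) {
    warning("background exceeds ROI signal; clamping dot number to 0")
    return(0)
  }
  numerator / single_dot_intensity
}

#' Dot density of an ROI
#'
#' @param total_dot_number dot count from [countDots()].
#' @param roi_area_um2 ROI area in um^2 (> 0).
#' @param unit `"mm2"` (default) or `"um2"`.
#' @return dots per mm^2 or per um^2.
#' @export
dotsPerArea <- function(total_dot_number, roi_area_um2, unit = c("mm2", "um2")) {
  unit <- match.arg(unit)
  if (roi_area_um2 <= 0) stop("ROI area must be > 0")
  dens_um2 <- total_dot_number / roi_area_um2
  if (unit == "um2") dens_um2 else dens_um2 * 1e6
}

#' Co-expression overlap between Pvalb cells and IEG signal
#'
#' A Pvalb cell is IEG+ iff the fraction of its pixels overlapped by IEG
#' expression exceeds `min_overlap_fraction` (default 0: any overlapping
#' pixel). Reports the proportion of IEG+ cells by count and the overlapping
#' area as a proportion of total Pvalb+ area.
#'
#' @param cells a [ComponentSet] of Pvalb cell bodies.
#' @param ieg a [ComponentSet] (or logical/label matrix) of IEG expression.
#' @param min_overlap_fraction threshold on the overlapped pixel fraction.
#' @return data.frame row: `n_pvalb_cells`, `n_ieg_pos_pvalb_cells`,
#'   `proportion_by_count`, `overlap_area_um2`, `proportion_by_area`
#'   (proportions `NA` when there are no cells), plus a `per_cell`
#'   attribute with the per-cell overlap fractions.
#' @export
overlapMetrics <- function(cells, ieg, min_overlap_fraction = 0) {
  stopifnot(is(cells, "ComponentSet"))
  if (min_overlap_fraction < 0 || min_overlap_fraction > 1) {
    stop("min_overlap_fraction must be in [0, 1]")
  }
  iegMask <- if (is(ieg, "ComponentSet")) ieg@labels > 0L else ieg > 0
  if (!identical(dim(iegMask), dim(cells@labels))) {
    stop("components must come from the same scene (shape mismatch)")
  }
  st <- componentStats(cells)
  n <- nrow(st)
  if (n == 0L) {
    res <- data.frame(n_pvalb_cells = 0L, n_ieg_pos_pvalb_cells = 0L,
                      proportion_by_count = NA_real_, overlap_area_um2 = 0,
                      proportion_by_area = NA_real_)
    attr(res, "per_cell") <- data.frame(label = integer(), overlap_fraction = numeric())
    return(res)
  }
  px_um2 <- cells@calibration^2
  ov_px <- vapply(st$label, function(l) sum(iegMask[cells@labels == l]), integer(1))
  frac <- ov_px / st$n_px
  pos <- frac > min_overlap_fraction
  res <- data.frame(
    n_pvalb_cells = n, n_ieg_pos_pvalb_cells = sum(pos),
    proportion_by_count = mean(pos),
    overlap_area_um2 = sum(ov_px) * px_um2,
    proportion_by_area = sum(ov_px) / sum(st$n_px))
  attr(res, "per_cell") <- data.frame(label = st$label, overlap_fraction = frac,
                                      ieg_positive = pos)
  res
}

#' Background-corrected per-cell intensity and its ECDF
#'
#' Mean per-pixel fluorescence of each Pvalb+ cell minus the background
#' mean, with the empirical cumulative distribution over cells (the
#' protocol's cumulative frequency presentation). Group comparison of two
#' such distributions goes through [groupTest()].
#'
#' @param plane intensity matrix.
#' @param cells a [ComponentSet] of Pvalb cells (>= 1 cell).
#' @param background_mean background level (a.u./px).
#' @return list: `cells` (data.frame `label`, `mean_intensity`) and `ecdf`
#'   (a [stats::ecdf] over cells).
#' @export
perCellIntensity <- function(plane, cells, background_mean) {
  stopifnot(is(cells, "ComponentSet"))
  st <- componentStats(cells)
  if (nrow(st) == 0L) stop("at least one cell is required")
  vals <- vapply(st$label, function(l) mean(plane[cells@labels == l]),
                 numeric(1)) - background_mean
  list(cells = data.frame(label = st$label, mean_intensity = vals),
       ecdf = ecdf(vals))
}

#' Quantify one ROI of one channel
#'
#' Convenience wrapper chaining [estimateBackground()],
#' [calibrateSingleDot()] and [countDots()] into the per-ROI record the
#' reporting pipeline emits.
#'
#' @param plane intensity matrix.
#' @param roi logical matrix of ROI pixels.
#' @param expression a [ComponentSet] of this channel's detected expression
#'   (used both to exclude labelled pixels from the background and, reduced
#'   to dot-scale components inside the ROI, to calibrate the single dot).
#' @param calibration microns per pixel.
#' @param roi_class,region,channel identifiers carried into the record.
#' @param average passed to [calibrateSingleDot()].
#' @return one-row data.frame: identifiers, `roi_area_um2`,
#'   `background_mean`, `single_dot_intensity`, `total_dot_number`,
#'   `dots_per_mm2`, `dots_per_um2`.
#' @export
quantifyRoi <- function(plane, roi, expression, calibration,
                        roi_class = NA_character_, region = NA_character_,
                        channel = NA_character_, average = "mean") {
  roi_area_um2 <- sum(roi) * calibration^2
  if (roi_area_um2 <= 0) stop("empty ROI")
  bg <- estimateBackground(plane, roi, expression@labels)
  inRoi <- componentStats(expression)
  keep <- inRoi$label[vapply(inRoi$label, function(l)
    any(roi[expression@labels == l]), logical(1))]
  if (!length(keep)) {
    return(data.frame(region = region, roi_class = roi_class, channel = channel,
                      roi_area_um2 = roi_area_um2, background_mean = bg,
                      single_dot_intensity = NA_real_, total_dot_number = 0,
                      dots_per_mm2 = 0, dots_per_um2 = 0))
  }
  sub <- new("ComponentSet", labels = expression@labels * (expression@labels %in% keep),
             stats = inRoi[inRoi$label %in% keep, , drop = FALSE],
             calibration = calibration)
  D <- calibrateSingleDot(plane, sub, bg, average = average)
  N <- countDots(plane, roi, bg, D)
  data.frame(region = region, roi_class = roi_class, channel = channel,
             roi_area_um2 = roi_area_um2, background_mean = bg,
             single_dot_intensity = D, total_dot_number = N,
             dots_per_mm2 = dotsPerArea(N, roi_area_um2, "mm2"),
             dots_per_um2 = dotsPerArea(N, roi_area_um2, "um2"))
}
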