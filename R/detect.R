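#' Detect expression components by adaptive local thresholding
#'
#' Implements the protocol's "areas whose mean pixel intensity is 200% of
#' its surroundings" rule in two stages: (1) a pixel-wise seed threshold
#' keeps pixels brighter than `threshold_ratio` times the local mean over
#' the surround window (the adaptive step); (2) the seeds are joined into
#' 8-connected components, components with area strictly greater than
#' `min_area_um2` are kept, and each candidate must pass the component-wise
#' check: mean component intensity >= `threshold_ratio` times the mean of
#' its surround (a square window of side `surround_window_um` centred on the
#' component centroid, with the component's own pixels excluded).
#'
#' The same operation detects both cell-scale expression areas (the default
#' 30 um^2 minimum) and dot-scale components for single-dot calibration
#' (pass a smaller `min_area_um2`).
#'
#' @param plane 2D numeric intensity matrix.
#' @param calibration microns per pixel.
#' @param threshold_ratio acceptance ratio (> 1; default 2 = "200%").
#' @param min_area_um2 minimum component area, um^2, strict.
#' @param surround_window_um side of the square surround window in microns;
#'   must map to at least 3 px and should exceed the largest expected
#'   component.
#' @param pixelwise if `TRUE` (default) the seed mask is the adaptive
#'   pixel-wise threshold described above; if `FALSE` seeds are pixels above
#'   `threshold_ratio` times the global median (a flat-field variant kept
#'   for comparison). Both paths apply the same component-wise check.
#' @return a [ComponentSet]
#' @export
detectComponents <- function(plane, calibration, threshold_ratio = 2,
                             min_area_um2 = 30, surround_window_um = 40,
                             pixelwise = TRUE) {
  stopifnot(is.matrix(plane))
  if (threshold_ratio <= 1) stop("threshold_ratio must be > 1")
  if (min_area_um2 <= 0) stop("min_area_um2 must be > 0")
  win_px <- round(surround_window_um / calibration)
  if (win_px < 3) stop("surround window is smaller than 3 px at this calibration")
  r <- max(1L, win_px %/% 2L)

  seeds <- if (pixelwise) {
    plane > threshold_ratio * .boxMean(plane, r)
  } else {
    plane > threshold_ratio * median(plane)
  }

  empty <- function() new("ComponentSet",
    labels = matrix(0L, nrow(plane), ncol(plane)),
    stats = data.frame(label = integer(), n_px = integer(),
                       area_um2 = numeric(), total_intensity = numeric(),
                       mean_intensity = numeric(), centroid_row = numeric(),
                       centroid_col = numeric()),
    calibration = calibration)
  if (!any(seeds)) return(empty())

  labs <- EBImage::bwlabel(matrix(as.numeric(seeds), nrow(plane)))
  labs <- matrix(as.integer(labs), nrow(plane))
  px_per_um2 <- calibration^2
  tab <- tabulate(labs[labs > 0L])
  keep_area <- which(tab * px_per_um2 > min_area_um2)
  if (!length(keep_area)) return(empty())

  h <- nrow(plane); w <- ncol(plane)
  rows <- row(plane); cols <- col(plane)
  out_label <- matrix(0L, h, w)
  stats <- vector("list", length(keep_area))
  nxt <- 0L
  for (lab in keep_area) {
    idx <- which(labs == lab)
    cr <- mean(rows[idx]); cc <- mean(cols[idx])
    r1 <- max(1L, round(cr) - r); r2 <- min(h, round(cr) + r)
    c1 <- max(1L, round(cc) - r); c2 <- min(w, round(cc) + r)
    winIdx <- which(rows >= r1 & rows <= r2 & cols >= c1 & cols <= c2)
    surround <- setdiff(winIdx, idx)
    if (!length(surround)) next
    compMean <- mean(plane[idx])
    if (compMean >= threshold_ratio * mean(plane[surround])) {
      nxt <- nxt + 1L
      out_label[idx] <- nxt
      stats[[nxt]] <- data.frame(
        label = nxt, n_px = length(idx),
        area_um2 = length(idx) * px_per_um2,
        total_intensity = sum(plane[idx]),
        mean_intensity = compMean,
        centroid_row = cr - 1, centroid_col = cc - 1)
    }
  }
  if (nxt == 0L) return(empty())
  new("ComponentSet", labels = out_label,
      stats = do.call(rbind, stats[seq_len(nxt)]), calibration = calibration)
}
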