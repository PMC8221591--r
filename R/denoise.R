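## Summed-area-table box filtering; edge-truncated normalization.
.boxSum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  sat <- matrix(0, h + 1L, w + 1L)
  sat[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- as.vector(pmin(pmax(row(m) - r, 1L), h)); r2 <- as.vector(pmin(row(m) + r, h))
  c1 <- as.vector(pmin(pmax(col(m) - r, 1L), w)); c2 <- as.vector(pmin(col(m) + r, w))
  matrix(sat[cbind(r2 + 1L, c2 + 1L)] - sat[cbind(r1, c2 + 1L)] -
           sat[cbind(r2 + 1L, c1)] + sat[cbind(r1, c1)], h, w)
}

.boxMean <- function(m, r) {
  .boxSum(m, r) / .boxSum(matrix(1, nrow(m), ncol(m)), r)
}

.padReplicate <- function(m, r) {
  ri <- pmin(pmax(seq_len(nrow(m) + 2L * r) - r, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m) + 2L * r) - r, 1L), ncol(m))
  m[ri, ci]
}

#' Non-local means denoising
#'
#' Classic non-local means: each pixel is replaced by a weighted average of
#' pixels in a search window, with weights decaying in the mean squared
#' difference between the Gaussian-free patches around the two pixels,
#' `w = exp(-max(d2 - 2*sigma^2, 0) / h^2)`. A constant image is a fixed
#' point; on a noisy flat field the output variance is strictly below the
#' input variance; at (near) zero noise the estimated bandwidth collapses
#' and the filter approaches the identity, so sharp structures such as
#' diffraction-limited dots are preserved.
#'
#' @param plane 2D numeric intensity matrix.
#' @param patch_radius patch half-size in pixels (default 2: 5x5 patches).
#' @param search_radius search window half-size in pixels (default 5: 11x11).
#' @param h filter bandwidth in intensity units; `NULL`/`NA` selects
#'   `0.75 * sigma`.
#' @param sigma pixel noise sigma; `NULL`/`NA` estimates it from
#'   pseudo-residuals of horizontal first differences (MAD-based).
#' @return denoised matrix, same shape, non-negative.
#' @export
denoiseNlm <- function(plane, patch_radius = 2L, search_radius = 5L,
                       h = NULL, sigma = NULL) {
  stopifnot(is.matrix(plane), patch_radius >= 1L, search_radius >= 1L)
  if (is.null(sigma) || is.na(sigma)) {
    d <- diff(t(plane))
    sigma <- mad(d) / sqrt(2)
  }
  if (is.null(h) || is.na(h)) h <- 0.75 * sigma
  h <- max(h, 1e-8)
  pad <- .padReplicate(plane, search_radius)
  nr <- nrow(plane); nc <- ncol(plane)
  wsum <- matrix(1, nr, nc)       # self offset, weight exactly 1
  acc <- plane
  for (dr in -search_radius:search_radius) {
    for (dc in -search_radius:search_radius) {
      if (dr == 0L && dc == 0L) next
      shifted <- pad[(1L + search_radius + dr):(nr + search_radius + dr),
                     (1L + search_radius + dc):(nc + search_radius + dc)]
      d2 <- .boxMean((plane - shifted)^2, patch_radius)
      wt <- exp(-pmax(d2 - 2 * sigma^2, 0) / h^2)
      wsum <- wsum + wt
      acc <- acc + wt * shifted
    }
  }
  pmax(acc / wsum, 0)
}
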