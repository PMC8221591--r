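test_that("non-local means keeps constants fixed, shrinks noise, spares structure", {
  cst <- matrix(7, 40, 40)
  expect_identical(denoiseNlm(cst), cst)

  set.seed(5)
  noisy <- matrix(100 + rnorm(64 * 64, 0, 12), 64)
  expect_lt(var(as.vector(denoiseNlm(noisy))), var(as.vector(noisy)))

  ## zero-noise dot scene: per-dot integrated signal changes < 5%
  p <- sceneParams(width_px = 128, height_px = 128, noise_model = "none",
                   noise_sigma = 0, n_cells = 0,
                   dot_channels = list(Arc = list(n = 15, snr = 4, sigma_um = 0.25,
                                                  intensity_cv = 0.1, frac_in_cells = 0)))
  ss <- simulateScene(p, seed = 2)
  plane <- getChannel(ss$scene, "Arc")
  den <- denoiseNlm(plane)
  for (i in seq_len(nrow(ss$truth@dots))) {
    r <- round(ss$truth@dots$row[i]) + 1
    c <- round(ss$truth@dots$col[i]) + 1
    patch <- (r - 5):(r + 5)
    patchc <- (c - 5):(c + 5)
    before <- sum(plane[patch, patchc] - 100)
    after <- sum(den[patch, patchc] - 100)
    expect_lt(abs(after - before) / before, 0.05)
  }
})

test_that("adaptive threshold enforces the area and surround-ratio rules", {
  calib <- 0.5
  flat <- matrix(100, 120, 120)
  expect_equal(nComponents(detectComponents(flat, calib, 2, 30, 20)), 0)

  ## 40 um^2 disk at 3x background: exactly one component
  expect_equal(nComponents(detectComponents(diskImage(mult = 3, area_px = 160),
                                            calib, 2, 30, 20)), 1)
  ## same disk at 1.5x background: below the 200% rule
  expect_equal(nComponents(detectComponents(diskImage(mult = 1.5, area_px = 160),
                                            calib, 2, 30, 20)), 0)
  ## 20 um^2 disk: rejected at the 30 um^2 floor, kept at 10 um^2
  expect_equal(nComponents(detectComponents(diskImage(mult = 3, area_px = 80),
                                            calib, 2, 30, 20)), 0)
  comp <- detectComponents(diskImage(mult = 3, area_px = 80), calib, 2, 10, 20)
  expect_equal(nComponents(comp), 1)
  expect_gt(componentStats(comp)$area_um2, 10)
  expect_error(detectComponents(flat, calib, 2, 30, surround_window_um = 1),
               "3 px")
  expect_error(detectComponents(flat, calib, 1, 30, 20), "> 1")
})

test_that("ROI partition is exact and empty regions are flagged", {
  region <- matrix(0L, 60, 60)
  region[11:50, 11:50] <- 1L            # 1600 px; at 0.5 um/px -> 400 um^2
  cells <- matrix(0L, 60, 60)
  cells[21:30, 21:30] <- 1L             # 100 px -> 25 um^2

  rois <- classifyRois(cells, region, calibration = 0.5)
  r <- rois$region_1
  expect_equal(r$region_area_um2, 400)
  expect_equal(r$pvalb_area_um2, 25)
  expect_equal(r$non_pvalb_area_um2, 375)
  ## exact partition: disjoint and covering
  expect_equal(r$pvalb_area_um2 + r$non_pvalb_area_um2, r$region_area_um2)
  expect_true(all((r$cellLabels > 0) + r$nonPvalb == r$region))

  ## no cells: non-Pvalb ROI is the whole region
  r0 <- classifyRois(matrix(0L, 60, 60), region, calibration = 0.5)$region_1
  expect_equal(r0$non_pvalb_area_um2, 400)

  expect_warning(out <- classifyRois(cells, region, calibration = 0.5,
                                     region_labels = c(1L, 7L)), "empty")
  expect_true(out$region_7$empty)
})

test_that("a scene's cells are each recovered as one Pvalb+ ROI", {
  p <- sceneParams(width_px = 512, height_px = 512, n_cells = 9,
                   cell_intensity_cv = 0.03,
                   dot_channels = list(Arc = list(n = 40, snr = 4, sigma_um = 0.25,
                                                  intensity_cv = 0.1, frac_in_cells = 0)))
  ss <- simulateScene(p, seed = 21)
  cells <- detectComponents(getChannel(ss$scene, "Pvalb"), calibration(ss$scene),
                            2, 30, 40)
  expect_equal(nComponents(cells), 9)
  rois <- classifyRois(cells, getRegionMask(ss$scene, "CTX"))
  expect_equal(length(unique(rois[[1]]$cellLabels[rois[[1]]$cellLabels > 0])), 9)
})

test_that("background estimation averages the unlabelled ROI and needs support", {
  flat <- matrix(7, 10, 10)
  expect_equal(estimateBackground(flat, flat > 0), 7)

  plane <- matrix(0, 2, 5)
  plane[1:10] <- 1:10
  roi <- matrix(TRUE, 2, 5)
  labeled <- matrix(FALSE, 2, 5)
  labeled[plane >= 9] <- TRUE          # the two brightest pixels
  expect_equal(estimateBackground(plane, roi, labeled), mean(1:8))
  expect_error(estimateBackground(plane, roi, matrix(TRUE, 2, 5)), "background")
})

test_that("single-dot calibration follows the printed formula", {
  ## 10 two-pixel dots, total 120 a.u. over 20 px, background 1/px -> 10/dot
  labels <- matrix(0L, 10, 20)
  plane <- matrix(0, 10, 20)
  for (i in 1:10) {
    labels[i, c(2, 3)] <- i
    plane[i, c(2, 3)] <- 6
  }
  comp <- componentSetFromLabels(labels, plane, calibration = 1)
  expect_equal(calibrateSingleDot(plane, comp, 1.0, ids = 1:10), 10)
  ## zero background, single dot: D equals its intensity
  one <- componentSetFromLabels(matrix(c(0L, 1L, 1L, 0L), 2),
                                matrix(c(0, 8, 4, 0), 2), 1)
  expect_equal(calibrateSingleDot(matrix(c(0, 8, 4, 0), 2), one, 0, ids = 1), 12)
  ## background above the signal invalidates the calibration
  expect_error(calibrateSingleDot(plane, comp, 100, ids = 1:10), "background")
})

test_that("dot counting and densities follow the ratio formulas", {
  plane <- matrix(10, 10, 10)           # 100 px, total 1000 a.u.
  roi <- matrix(TRUE, 10, 10)
  expect_equal(countDots(plane, roi, background_mean = 2, single_dot_intensity = 10),
               (1000 - 200) / 10)
  expect_equal(countDots(plane, roi, background_mean = 10, single_dot_intensity = 5), 0)
  expect_warning(n <- countDots(plane, roi, 11, 5), "clamping")
  expect_equal(n, 0)
  expect_error(countDots(plane, roi, 2, 0), "single_dot_intensity")

  expect_equal(dotsPerArea(80, 2000, "mm2"), 40000)
  expect_equal(dotsPerArea(80, 2000, "um2"), 0.04)
  expect_equal(dotsPerArea(80, 2000, "mm2") / dotsPerArea(80, 2000, "um2"), 1e6)
  expect_error(dotsPerArea(80, 0), "> 0")
})

test_that("dot-number estimates are scale- and translation-invariant", {
  p <- sceneParams(width_px = 384, height_px = 384, noise_model = "none",
                   noise_sigma = 0, n_cells = 0,
                   dot_channels = list(Arc = list(n = 60, snr = 4, sigma_um = 0.25,
                                                  intensity_cv = 0.1, frac_in_cells = 0)))
  ss <- simulateScene(p, seed = 13)
  plane <- getChannel(ss$scene, "Arc")
  roi <- matrix(TRUE, 384, 384)
  chain <- function(pl, use_roi = roi) {
    comp <- detectComponents(pl, 0.25, 2, 0.05, 8)
    bg <- estimateBackground(pl, use_roi, componentLabels(comp))
    countDots(pl, use_roi, bg, calibrateSingleDot(pl, comp, bg))
  }
  N <- chain(plane)
  expect_lt(abs(chain(plane * 3.7) - N) / N, 1e-9)

  ## translation: the same pixels shifted by a fixed offset, quantified over
  ## the matching ROI, give the same count up to border effects
  shifted <- matrix(100, 384, 384)
  shifted[21:384, 16:384] <- plane[1:364, 1:369]
  roi1 <- matrix(FALSE, 384, 384); roi1[1:364, 1:369] <- TRUE
  roi2 <- matrix(FALSE, 384, 384); roi2[21:384, 16:384] <- TRUE
  expect_lt(abs(chain(shifted, roi2) - chain(plane, roi1)) /
              chain(plane, roi1), 0.02)
})

test_that("overlap metrics count co-expressing cells correctly", {
  labels <- matrix(0L, 20, 50)
  for (i in 1:5) labels[3:6, (i * 9 - 6):(i * 9 - 3)] <- i   # 5 cells, 16 px each
  plane <- matrix(0, 20, 50)
  cells <- componentSetFromLabels(labels, plane, 1)
  ieg <- matrix(FALSE, 20, 50)
  ieg[3:4, 3:4] <- TRUE                 # overlaps cell 1 (4 px)
  ieg[5, 21] <- TRUE                    # overlaps cell 3 (1 px)
  ov <- overlapMetrics(cells, ieg)
  expect_equal(ov$n_pvalb_cells, 5)
  expect_equal(ov$n_ieg_pos_pvalb_cells, 2)
  expect_equal(ov$proportion_by_count, 0.4)
  expect_equal(ov$overlap_area_um2, 5)
  expect_equal(ov$proportion_by_area, 5 / 80)

  ## no IEG signal: zero everywhere
  ov0 <- overlapMetrics(cells, matrix(FALSE, 20, 50))
  expect_equal(ov0$proportion_by_count, 0)
  expect_equal(ov0$n_ieg_pos_pvalb_cells, 0)

  ## a stricter overlap fraction discounts the 1-px overlap
  ov2 <- overlapMetrics(cells, ieg, min_overlap_fraction = 0.1)
  expect_equal(ov2$n_ieg_pos_pvalb_cells, 1)

  ## no cells: proportions are flagged missing
  none <- componentSetFromLabels(matrix(0L, 20, 50), plane, 1)
  ovna <- overlapMetrics(none, ieg)
  expect_true(is.na(ovna$proportion_by_count))
})

test_that("designed co-expression is recovered within one cell", {
  p <- sceneParams(width_px = 512, height_px = 512, n_cells = 10,
                   cell_intensity_cv = 0.05, coexpress_fraction = 0.3,
                   dot_channels = list(Arc = list(n = 50, snr = 6, sigma_um = 0.25,
                                                  intensity_cv = 0.1, frac_in_cells = 1)))
  ss <- simulateScene(p, seed = 31)
  calib <- calibration(ss$scene)
  cells <- detectComponents(getChannel(ss$scene, "Pvalb"), calib, 2, 30, 40)
  arc <- detectComponents(getChannel(ss$scene, "Arc"), calib, 2, 0.05, 8)
  ov <- overlapMetrics(cells, arc)
  expect_lte(abs(ov$n_ieg_pos_pvalb_cells - sum(ss$truth@cells$pos_Arc)), 1)
})

test_that("per-cell intensities are background-corrected, linear, and rank-preserving", {
  labels <- matrix(0L, 10, 30)
  labels[2:5, 2:5] <- 1L; labels[2:5, 12:15] <- 2L; labels[2:5, 22:25] <- 3L
  plane <- matrix(10, 10, 30)
  plane[labels == 1L] <- 30; plane[labels == 2L] <- 30; plane[labels == 3L] <- 60
  cells <- componentSetFromLabels(labels, plane, 1)
  pci <- perCellIntensity(plane, cells, background_mean = 10)
  expect_equal(pci$cells$mean_intensity, c(20, 20, 50))
  ## identical cells: the ECDF is a single step
  expect_equal(pci$ecdf(19.9), 0)
  expect_equal(pci$ecdf(20), 2 / 3)
  ## doubling the image doubles every background-corrected mean
  pci2 <- perCellIntensity(plane * 2, cells, background_mean = 20)
  expect_equal(pci2$cells$mean_intensity, 2 * pci$cells$mean_intensity)
  ## two designed populations separate in rank order
  expect_true(all(pci$cells$mean_intensity[3] > pci$cells$mean_intensity[1:2]))
})
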