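---
title: "Methods: in situ dot quantification and TRAP qPCR statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in situ dot quantification and TRAP qPCR statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboquant)
```

# Scope

`riboquant` implements two quantification workflows used when comparing
transcript abundance between sleeping and sleep-deprived animals in specific
neuronal populations, together with the synthetic data needed to test them
end to end:

1. a semi-automated smFISH/RNAScope-style **image quantification** protocol —
   punctate hybridization signal ("dots") is counted by intensity rather than
   by segmenting individual puncta, separately for parvalbumin-positive
   (Pvalb+) cell bodies and the non-Pvalb+ remainder of each anatomical
   region;
2. **TRAP qPCR statistics** — reference-gene stability ranking and
   countervailing-pair selection, delta-delta-CT (ddCT) fold changes with
   first-order error propagation, marker enrichment tests against input mRNA,
   Welch group tests and step-down Sidak multiplicity correction;

plus a **behavioral exclusion screen** for sleep-group animals that were
mostly awake at the end of the recording.

# Image quantification model

## Detection

Components are detected by an adaptive rule with two stages
(`detectComponents()`):

* a pixel-wise seed threshold keeps pixels brighter than `threshold_ratio`
  (default 2, i.e. 200%) times the local mean over a square window of side
  `surround_window_um`;
* seeds are joined into connected components; a component is kept if its
  area strictly exceeds `min_component_area_um2` **and** its mean intensity
  is at least `threshold_ratio` times the mean of its surround (the window
  centred on the component centroid, the component's own pixels excluded).

Two readings of the published "mean pixel intensity 200% of its
surroundings" rule are possible — pixel-wise during thresholding or
component-wise after candidate detection. We implement the component-wise
check as the decisive criterion, with the pixel-wise threshold as the seeding
step; the seeding rule can be switched to a global-median variant
(`pixelwise = FALSE`) for comparison. The area floor is read as 30 um^2 (an
"area" in um is dimensionally inconsistent; the value is configurable).
The same operation serves two scales: cell bodies (default 30 um^2 floor)
and dot-scale components for calibration (default floor 0.05 um^2,
`dot_min_area_um2`).

The surround window defaults to 40 um — about four expected PV soma
diameters — and must exceed the largest expected component; a window that
maps to fewer than 3 px is rejected. Detection is scale-invariant by
construction (both stages compare ratios), which the tests exercise
directly.

## Counting by intensity

Within an ROI, with `B` the mean background intensity (mean over ROI pixels
not covered by any detected expression area, `estimateBackground()`) and `D`
the calibrated intensity of a single dot, the total dot number is

    N = (sum of ROI intensities − B × ROI area in px) / D

(`countDots()`), a ratio of intensities: real-valued, clamped at zero with a
warning if background exceeds the signal. `D` is calibrated from
representative dots (`calibrateSingleDot()`):

    D = (sum of intensities over selected dots' pixels − B × their area) / n_dots.

The published protocol selects representative dots manually. The automated
stand-in (`selectRepresentativeDots()`) takes isolated components (no
neighbouring centroid within two mean diameters) whose area lies in the
central 50% of the component-area distribution; explicit label lists are
accepted for the manual path, and the per-dot average can be switched from
the mean (the printed formula) to a median. Densities are reported as
dots/mm^2 and dots/um^2 (`dotsPerArea()`).

Manual curation steps of the published protocol ("refine labeling, remove
artifacts") are modelled as the optional id lists; the automated path is the
tested default, for reproducibility.

## ROI partition, overlap, per-cell intensity

`classifyRois()` partitions every labelled anatomical region exactly: the
Pvalb+ class is the detected cell pixels inside the region, the non-Pvalb+
class is the region minus all cell pixels (disjoint, covering). A Pvalb
cell counts as co-expressing a transcript if the overlapping pixel fraction
exceeds `overlap_min_fraction` — default 0, i.e. any overlapping pixel,
since the protocol states only "overlapping fluorescence" — and overlap is
reported both by cell count and by area (`overlapMetrics()`). Per-cell
background-corrected mean Pvalb intensity and its empirical cumulative
distribution come from `perCellIntensity()`; group comparisons of any of
these quantities go through the same Welch/Sidak machinery as the qPCR side.

# qPCR statistics

All statistics operate on CT values (a log2 scale). Technical replicates
(three per sample in the emulated design) are averaged per gene x sample
with the replicate SD kept as a QC column.

## Reference-gene stability

Four measures are computed per candidate (`stabilityReport()`):

* **model-based** (`stabilityModelBased()`): per group, each sample is
  centred across the candidate genes (removing loading/RT effects); a
  gene's intergroup difference `d` is the deviation of its group mean from
  its across-group mean, and its intragroup variance is the bias-corrected
  within-group variance of the centred values,
  `sigma2 = (v − sum(v)/(k(k−1))) * k/(k−2)` clamped at zero, which removes
  the variance leaked in by centring k genes. The stability value is the
  across-group mean of `|d| + sqrt(sigma2/n)`; lower is more stable. At
  least 3 candidates are required or the decomposition is unidentifiable.
* **pairwise-M** (`stabilityPairwiseM()`): mean over partners of the SD of
  the pairwise CT difference, with an optional iterative-exclusion ranking.
* **raw CT SD** and the **comparative delta-Ct** measure. The latter shares
  its computational core with non-iterative pairwise-M (mean pairwise SD)
  and produces identical values; both columns are reported so the rank
  aggregation mirrors a four-method consensus.

Ranks are aggregated by geometric mean, ties broken by the model-based rank.
The housekeeping pair is chosen among the `top_k` (default 4) aggregated
candidates as the pair minimizing `|d1 + d2|` — countervailing intergroup
drifts cancel in the pair mean — with ties broken by summed stability. As a
final check the selected pair's own group expression ratio
(`2^-CT` pair means, alternative over reference group) and its signed fold
change are reported; a good pair sits near 1.

Because the model-based measure sees only *relative* drifts (sample-centring
absorbs any drift common to all candidates), a designed countervailing pair
is recoverable only when the candidate drifts are interpretable in relative
terms; the default synthetic panel therefore balances its candidate drifts
to sum to zero (see below).

## Fold changes and tests

`deltaCt()` normalizes each target to the arithmetic mean of the pair;
`ddctFoldChange()` returns `ddCT = mean dCT(alt) − mean dCT(ref)`,
`log2FC = −ddCT`, the ratio `2^−ddCT`, and the signed fold change
(`foldChangeConvert()`: `r` if `r >= 1`, else `−1/r`, reported at two
decimals). Error is propagated to first order as the root sum of squares of
the two group SEMs — the convention behind "mean ± SEM with propagated
error" — with a seeded bootstrap SE available for verification.
Cell-marker enrichment of affinity-purified versus input mRNA is the
per-sample ddCT between fractions, tested against zero with a one-sample t
test (`enrichmentVsInput()`); the degenerate all-equal case is reported as
`t = 0, p = 1` at zero and `p = 0` otherwise, by documented convention.

The published omnibus structure feeding the post hoc comparisons is not
fully specified, and the printed per-gene p values are not consistent with a
plain two-sample test on the printed summaries; we therefore implement and
document per-contrast **Welch t tests on delta-CT values** with
**step-down Sidak** adjustment (`holmSidak()`:
`p_adj(i) = max_{j<=i} 1 − (1 − p_(j))^(m−j+1)` over the ascending sort)
across the genes of a family (region x cell population x duration by
default, configurable), and do not use the printed p values as numeric
references. Type-I error calibration of this combination is verified by
simulation in the test suite.

# Behavioral exclusion screen

Sleep/wake scoring arrives as interval labels at 2- or 5-min bins.
`percentSleep()` uses bins fully inside the requested window;
`finalWindowWakeFraction()` evaluates the trailing window as the maximal
suffix of whole bins totalling at most 45 min — with 2-min bins that is 22
bins (44 min), since 45 min is not a whole number of bins and the published
rule does not address partial bins. A sleep-group animal is excluded iff its
trailing wake fraction strictly exceeds 0.60; sleep-deprived animals are
never excluded by this rule (`applyExclusion()`).

# Synthetic data: what it emulates, and what it does not

`simulateScene()` renders exactly the model the estimator assumes: flat
background, isotropic 2D Gaussian dots (the standard point-spread proxy for
diffraction-limited smFISH puncta; shape is not specified by the protocol),
filled circular Pvalb somata, and additive Gaussian pixel noise (a Poisson
mode is available). Defaults emulate a 40x acquisition at 0.25 um/px
(~190 um field): background 100 a.u., noise sigma 20, dot peak amplitude 4x
background, dot sigma 0.25 um, 25 cells of 5 um radius at 2x background,
30% of cells co-expressing the dot channel. Truth (per-dot integrated
intensities as the exact discrete sums of the rendered profiles, cell masks,
per-region counts) is returned alongside, so zero-noise recovery tests are
exact. Dot density is validated up front against an expected merging
fraction (centres within 4 sigma) of at most 5%. Dots are placed at least
`5 sigma + 1` px from the border so rendered mass is not clipped.

The generator does **not** emulate tissue autofluorescence, uneven
illumination, chromatic shift, 3D structure, or segmentation ambiguity
between touching cells; passing recovery tests therefore demonstrate
correctness of the estimator under its own model, not robustness to those
artefacts.

`simulateCtTable()` draws
`CT = baseline + effect x [alt group] + sample effect + gene-level noise +
replicate noise`. The default panel has six housekeeping candidates — the
designed countervailing pair at +/-0.3 cycles, two mildly co-drifting
candidates (+0.12 each) and two strongly drifting unstable ones (-0.94,
+0.7) chosen so the candidate drifts sum to zero (making the designed
relative structure visible to the sample-centred stability analysis and the
unstable genes unambiguous rejects for every method) — and four targets
with effects matching a typical 3-h sleep-deprivation cortex experiment
(e.g. a −1.26-cycle shift, i.e. log2 fold change +1.26). Default sizes
follow the emulated design: 6 biological samples per group, 3 technical
replicates, replicate sigma 0.1 cycles, between-sample sigma 0.3 cycles.

`simulateSleepSeries()` draws independent Bernoulli bins; real sleep bouts
are autocorrelated, which the exclusion rule does not depend on.

# Numerical choices and problem sizes

* Coordinates are 0-based row-major pixel indices; areas are converted via
  the calibration (um/px), which must be shared by all channels of a scene.
* Masks are integer label images (0 = background), matching freehand-tool
  exports; labels within one layer are disjoint by construction.
* Connected components use the labelling of `EBImage::bwlabel`.
* Non-local means (`denoiseNlm()`) uses 5x5 patches in an 11x11 search
  window; the bandwidth defaults to `0.75 sigma` with sigma estimated from
  the MAD of horizontal first differences. At (near) zero noise the
  bandwidth collapses and the filter approaches the identity, so dots
  survive; a constant image is an exact fixed point.
* Dot counts are real-valued and clamped at zero with a warning; a
  calibration in which background exceeds the dot signal is an error.
* Degenerate test inputs (zero variance everywhere) take exact-equality
  branches rather than producing NaN.
* The test suite runs its recovery checks at deliberately modest sizes —
  768x768 px scenes with 200 dots for count recovery (10 seeds), 100 seeded
  panels for pair selection, 10,000 null simulations for test calibration —
  sizes at which the binomial/normal error of each check is small relative
  to its acceptance band.

# Known limitations

* Counting by intensity assumes dots share a characteristic intensity per
  channel; strongly bimodal dot populations would bias `D` and hence `N`.
* The component-wise surround check uses a square window and excludes only
  the candidate's own pixels; in extremely crowded fields the surround mean
  is inflated by neighbours, raising the effective detection threshold.
* The stability analysis cannot see a drift common to all candidate genes
  (no normalization method can); the countervailing-pair criterion operates
  on relative drifts.
* Amplification-efficiency correction, primer diagnostics and absolute
  quantification are out of scope, as are EEG/EMG-based sleep scoring,
  nuclei segmentation and 3D quantification.
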