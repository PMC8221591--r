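#' Parameters for a simulated hybridization scene
#'
#' The generative model is exactly the model the quantification assumes:
#' a flat background, diffraction-limited dots rendered as isotropic 2D
#' Gaussians of per-channel characteristic integrated intensity, filled
#' circular Pvalb cell bodies, and additive pixel noise. The defaults
#' emulate a 40x acquisition (0.25 um/px, ~190 um field) of a cortical field with sparse
#' punctate IEG signal: dot signal-to-background (peak amplitude over
#' background level) of 4, ~4% of dots within merging distance of another
#' dot, and 30% of cells truly co-expressing the dot channel.
#'
#' @param width_px,height_px image size in pixels.
#' @param microns_per_pixel pixel calibration (um/px).
#' @param background flat background level (a.u.).
#' @param noise_sigma additive Gaussian pixel noise sigma (a.u.).
#' @param noise_model `"gaussian"` (default), `"poisson"` or `"none"`.
#' @param dot_channels named list; each element a list with `n` (dot count),
#'   `snr` (peak amplitude / background), `sigma_um` (Gaussian sigma),
#'   `intensity_cv` (per-dot amplitude CV), `frac_in_cells` (fraction of dots
#'   placed inside co-expressing cells).
#' @param n_cells number of Pvalb cell bodies rendered into the `cell_channel`.
#' @param cell_radius_um,cell_snr,cell_intensity_cv cell body geometry and
#'   fill amplitude (relative to background) with per-cell CV.
#' @param cell_channel name of the channel receiving the filled cell bodies.
#' @param coexpress_fraction fraction of cells designated positive for each
#'   dot channel (receives that channel's in-cell dots).
#' @param region_name name of the single rectangular anatomical region mask.
#' @param max_overlap_fraction acceptance limit on the expected fraction of
#'   dots with a same-channel neighbour within 4 sigma (dot merging).
#' @return a parameter list for [simulateScene()]
#' @export
sceneParams <- function(width_px = 768, height_px = 768,
                        microns_per_pixel = 0.25,
                        background = 100, noise_sigma = 20,
                        noise_model = c("gaussian", "poisson", "none"),
                        dot_channels = list(
                          Arc = list(n = 200, snr = 4, sigma_um = 0.25,
                                     intensity_cv = 0.1, frac_in_cells = 0.15)),
                        n_cells = 25, cell_radius_um = 5, cell_snr = 2,
                        cell_intensity_cv = 0.15, cell_channel = "Pvalb",
                        coexpress_fraction = 0.3,
                        region_name = "CTX",
                        max_overlap_fraction = 0.05) {
  p <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
            microns_per_pixel = microns_per_pixel, background = background,
            noise_sigma = noise_sigma, noise_model = match.arg(noise_model),
            dot_channels = dot_channels, n_cells = as.integer(n_cells),
            cell_radius_um = cell_radius_um, cell_snr = cell_snr,
            cell_intensity_cv = cell_intensity_cv, cell_channel = cell_channel,
            coexpress_fraction = coexpress_fraction, region_name = region_name,
            max_overlap_fraction = max_overlap_fraction)
  .validateSceneParams(p)
  p
}

.validateSceneParams <- function(p) {
  if (p$background < 0 || p$noise_sigma < 0) {
    stop("background and noise_sigma must be non-negative")
  }
  area_px <- p$width_px * p$height_px
  for (nm in names(p$dot_channels)) {
    ch <- p$dot_channels[[nm]]
    if (ch$n < 0) stop("dot count must be non-negative")
    if (ch$n > 0 && p$background > 0 && ch$snr < 1) {
      stop(sprintf("channel '%s': SNR (dot peak amplitude / background) must be >= 1", nm))
    }
    sigma_px <- ch$sigma_um / p$microns_per_pixel
    margin <- ceiling(5 * sigma_px) + 1L
    if (2L * margin >= min(p$width_px, p$height_px)) {
      stop(sprintf("channel '%s': dots of sigma %.3g um do not fit inside the image", nm))
    }
    if (ch$n > 1) {
      r <- 4 * sigma_px
      exp_overlap <- 1 - exp(-(ch$n - 1) * pi * r^2 / area_px)
      if (exp_overlap > p$max_overlap_fraction) {
        stop(sprintf(
          "channel '%s': expected dot-overlap fraction %.3f exceeds the %.3f limit; lower the density",
          nm, exp_overlap, p$max_overlap_fraction))
      }
    }
  }
  invisible(TRUE)
}

#' Simulate a ground-truthed hybridization scene
#'
#' Renders `image = background + Gaussian dots + filled cell disks + noise`
#' for every channel and returns the [Scene] together with the full
#' [SceneTruth]. The recorded per-dot integrated intensity is the exact
#' discrete sum of the rendered profile, so at zero noise the integral of
#' `(image - background)` over the field equals the summed truth intensities
#' to machine precision. Deterministic under a fixed seed.
#'
#' @param params parameter list from [sceneParams()].
#' @param seed integer seed.
#' @return `list(scene = Scene, truth = SceneTruth)`
#' @export
simulateScene <- function(params = sceneParams(), seed = 1L) {
  .validateSceneParams(params)
  set.seed(seed)
  h <- params$height_px; w <- params$width_px
  calib <- params$microns_per_pixel
  cellR_px <- params$cell_radius_um / calib

  ## -- cell bodies (rejection-sampled, non-overlapping) ---------------------
  cellMask <- matrix(0L, h, w)
  cells <- data.frame(label = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), radius_px = numeric(),
                      amplitude = numeric())
  if (params$n_cells > 0) {
    margin <- cellR_px + 2
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < params$n_cells && tries < 4000L) {
      tries <- tries + 1L
      cand <- c(runif(1, margin, h - margin), runif(1, margin, w - margin))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) > 2.5 * cellR_px) {
        centers <- rbind(centers, cand)
      }
    }
    if (nrow(centers) < params$n_cells) {
      stop("could not place the requested number of non-overlapping cells; lower n_cells")
    }
    amp <- params$cell_snr * params$background *
      pmax(1 + params$cell_intensity_cv * rnorm(params$n_cells), 0.2)
    rows <- row(cellMask); cols <- col(cellMask)
    for (i in seq_len(params$n_cells)) {
      d2 <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2
      cellMask[d2 <= cellR_px^2] <- i
    }
    cells <- data.frame(label = seq_len(params$n_cells),
                        centroid_row = centers[, 1] - 1,
                        centroid_col = centers[, 2] - 1,
                        radius_px = cellR_px, amplitude = amp)
  }

  ## -- channels -------------------------------------------------------------
  channels <- list()
  dots_all <- list()
  cellPos <- list()
  for (nm in names(params$dot_channels)) {
    ch <- params$dot_channels[[nm]]
    sigma_px <- ch$sigma_um / calib
    margin <- ceiling(5 * sigma_px) + 1L
    plane <- matrix(params$background, h, w)

    n_in <- 0L
    posCells <- integer()
    if (params$n_cells > 0 && ch$n > 0 && ch$frac_in_cells > 0) {
      nPos <- max(1L, round(params$coexpress_fraction * params$n_cells))
      posCells <- sort(sample(seq_len(params$n_cells), nPos))
      n_in <- round(ch$frac_in_cells * ch$n)
    }
    cellPos[[nm]] <- posCells

    centers <- matrix(numeric(0), 0, 2)
    in_cell <- integer()
    if (n_in > 0) {
      host <- sample(posCells, n_in, replace = TRUE)
      rr <- cellR_px * 0.8 * sqrt(runif(n_in))
      th <- runif(n_in, 0, 2 * pi)
      centers <- rbind(centers, cbind(
        cells$centroid_row[host] + 1 + rr * cos(th),
        cells$centroid_col[host] + 1 + rr * sin(th)))
      in_cell <- c(in_cell, host)
    }
    n_out <- ch$n - n_in
    if (n_out > 0) {
      centers <- rbind(centers, cbind(runif(n_out, margin, h - margin),
                                      runif(n_out, margin, w - margin)))
      in_cell <- c(in_cell, rep(0L, n_out))
    }
    ## clamp in-cell dots that drifted too close to the border
    if (nrow(centers) > 0) {
      centers[, 1] <- pmin(pmax(centers[, 1], margin), h - margin)
      centers[, 2] <- pmin(pmax(centers[, 2], margin), w - margin)
    }

    amp <- ch$snr * params$background *
      pmax(1 + ch$intensity_cv * rnorm(nrow(centers)), 0.05)
    intensity <- numeric(nrow(centers))
    if (nrow(centers) > 0) {
      pr <- ceiling(5 * sigma_px)
      off <- -pr:pr
      for (i in seq_len(nrow(centers))) {
        ri <- round(centers[i, 1]); ci <- round(centers[i, 2])
        dr <- off + (ri - centers[i, 1])
        dc <- off + (ci - centers[i, 2])
        patch <- amp[i] * exp(-outer(dr^2, dc^2, "+") / (2 * sigma_px^2))
        plane[ri + off, ci + off] <- plane[ri + off, ci + off] + patch
        intensity[i] <- sum(patch)
      }
    }
    if (nm == params$cell_channel && params$n_cells > 0) {
      plane <- plane + cells$amplitude[pmax(cellMask, 1L)] * (cellMask > 0)
    }
    channels[[nm]] <- plane
    if (nrow(centers) > 0) {
      dots_all[[nm]] <- data.frame(channel = nm, row = centers[, 1] - 1,
                                   col = centers[, 2] - 1, sigma_px = sigma_px,
                                   intensity = intensity, in_cell = in_cell)
    }
  }
  if (!params$cell_channel %in% names(channels) && params$n_cells > 0) {
    plane <- matrix(params$background, h, w)
    plane <- plane + cells$amplitude[pmax(cellMask, 1L)] * (cellMask > 0)
    channels[[params$cell_channel]] <- plane
  }

  ## -- noise ----------------------------------------------------------------
  channels <- lapply(channels, function(plane) {
    noisy <- switch(params$noise_model,
      gaussian = plane + if (params$noise_sigma > 0)
        matrix(rnorm(h * w, 0, params$noise_sigma), h, w) else 0,
      poisson = matrix(rpois(h * w, pmax(plane, 0)), h, w),
      none = plane)
    pmax(noisy, 0)
  })

  region <- matrix(1L, h, w)
  dots <- if (length(dots_all)) do.call(rbind, dots_all) else
    data.frame(channel = character(), row = numeric(), col = numeric(),
               sigma_px = numeric(), intensity = numeric(), in_cell = integer())
  rownames(dots) <- NULL
  for (nm in names(cellPos)) {
    cells[[paste0("pos_", nm)]] <- cells$label %in% cellPos[[nm]]
  }
  regionCounts <- if (nrow(dots)) {
    cnt <- aggregate(list(n_dots = dots$row), by = list(channel = dots$channel),
                     FUN = length)
    cnt$region <- params$region_name
    cnt[, c("region", "channel", "n_dots")]
  } else {
    data.frame(region = character(), channel = character(), n_dots = integer())
  }

  scene <- Scene(channels, calib,
                 setNames(list(region), params$region_name))
  truth <- new("SceneTruth", dots = dots, cells = cells, cellMask = cellMask,
               background = params$background, noiseSigma = params$noise_sigma,
               regionCounts = regionCounts, params = params)
  list(scene = scene, truth = truth)
}

#' Candidate-gene panel for the CT simulator
#'
#' Defines per-gene baseline CT, the true group effect in cycles (the shift
#' added in the alternative group; for a target gene this is its true
#' delta-delta-CT, so true log2 fold change is its negative), a stability
#' class, and optional per-gene extra sample-level noise. Stable genes have
#' effect 0; a countervailing pair has equal-magnitude, opposite-sign
#' effects. The default panel holds six housekeeping candidates — a designed
#' countervailing pair at +/-0.3 cycles, two mildly co-drifting candidates,
#' and two unstable ones with large drifts that balance the panel (candidate
#' drifts sum to zero, so the relative intergroup differences seen by the
#' sample-centred stability analysis equal the designed ones) — plus four
#' targets with effects matching a typical sleep-deprivation experiment.
#'
#' @param gene,baseline_ct,effect_ct,class,gene_sigma vectors of equal length
#'   (class in `"target"`, `"stable"`, `"countervailing_a"`,
#'   `"countervailing_b"`, `"unstable"`, `"candidate"`).
#' @return data.frame panel
#' @export
ctPanel <- function(gene, baseline_ct, effect_ct, class = "candidate",
                    gene_sigma = 0) {
  df <- data.frame(gene = gene, baseline_ct = baseline_ct,
                   effect_ct = effect_ct, class = class,
                   gene_sigma = gene_sigma, stringsAsFactors = FALSE)
  ca <- df$effect_ct[df$class == "countervailing_a"]
  cb <- df$effect_ct[df$class == "countervailing_b"]
  if (length(ca) != length(cb)) {
    stop("countervailing_a and countervailing_b genes must come in pairs")
  }
  if (length(ca) && any(abs(ca + cb) > 1e-12)) {
    stop("a countervailing pair must have equal-magnitude, opposite-sign effects")
  }
  if (any(df$effect_ct[df$class == "stable"] != 0)) {
    stop("stable genes must have group effect 0")
  }
  df
}

#' @rdname ctPanel
#' @export
defaultCtPanel <- function() {
  ctPanel(
    gene = c("Actg1", "Hprt1", "Gapdh", "Tuba4a", "Pgk1", "Tbp",
             "Arc", "Homer1a", "Narp", "Clock"),
    baseline_ct = c(18, 22, 17, 20, 21, 25, 24, 25, 26, 23),
    effect_ct = c(0.3, -0.3, 0.12, 0.12, -0.94, 0.7,
                  -1.26, -1.06, -0.48, 0),
    class = c("countervailing_a", "countervailing_b", "candidate",
              "candidate", "unstable", "unstable",
              "target", "target", "target", "stable"),
    gene_sigma = c(0, 0, 0, 0, 0, 0, 0.35, 0.35, 0.35, 0.2)
  )
}

#' Simulate a long-format qPCR CT table with known truth
#'
#' Generates `CT = baseline + effect * [alt group] + sample effect +
#' gene-level sample noise + replicate noise` for every gene x sample x
#' technical replicate, mirroring a two-group TRAP qPCR design with three
#' technical replicates per sample. The per-sample effect is shared by all
#' genes of that sample (it cancels under housekeeping normalization and
#' under the sample-centering of the stability analysis).
#'
#' @param panel a [ctPanel()] data.frame (truth).
#' @param n_per_group biological samples per group (>= 2).
#' @param n_replicates technical replicates per sample (default 3).
#' @param groups character(2): reference group then alternative group.
#' @param sigma_rep replicate (well) noise sigma in cycles.
#' @param sigma_sample between-sample (loading/RT) effect sigma in cycles.
#' @param seed integer seed.
#' @return `list(table = CT data.frame, truth = panel)`
#' @export
simulateCtTable <- function(panel = defaultCtPanel(), n_per_group = 6L,
                            n_replicates = 3L, groups = c("sleep", "SD"),
                            sigma_rep = 0.1, sigma_sample = 0.3, seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (sigma_rep < 0 || sigma_sample < 0) stop("noise sigmas must be >= 0")
  set.seed(seed)
  samples <- data.frame(
    sample = sprintf("%s_%02d", rep(groups, each = n_per_group),
                     rep(seq_len(n_per_group), 2L)),
    group = rep(groups, each = n_per_group))
  samples$offset <- rnorm(nrow(samples), 0, sigma_sample)

  rows <- expand.grid(gene = panel$gene, sample = samples$sample,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$group <- samples$group[match(rows$sample, samples$sample)]
  i <- match(rows$gene, panel$gene)
  ## gene-level sample noise: one draw per gene x sample, shared by replicates
  gs <- expand.grid(gene = panel$gene, sample = samples$sample,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gs$dev <- rnorm(nrow(gs)) * panel$gene_sigma[match(gs$gene, panel$gene)]
  rows$ct <- panel$baseline_ct[i] +
    panel$effect_ct[i] * (rows$group == groups[2L]) +
    samples$offset[match(rows$sample, samples$sample)] +
    gs$dev[match(paste(rows$gene, rows$sample), paste(gs$gene, gs$sample))] +
    rnorm(nrow(rows), 0, sigma_rep)
  list(table = validateCtTable(rows, require_group = TRUE), truth = panel)
}

#' Simulate a visually scored sleep/wake series
#'
#' Independent Bernoulli sleep bins at fixed bin length, matching visual
#' scoring at 2- or 5-min intervals.
#'
#' @param duration_min total duration (must be a multiple of `bin_min`).
#' @param bin_min scoring interval in minutes (2 or 5 by convention; any
#'   positive value accepted).
#' @param p_sleep probability a bin is scored as sleep.
#' @param seed integer seed.
#' @return a sleep record data.frame: `start_min`, `length_min`, `state`
#'   (`"sleep"`/`"wake"`).
#' @export
simulateSleepSeries <- function(duration_min, bin_min = 5, p_sleep, seed = 1L) {
  if (bin_min <= 0) stop("bin_min must be positive")
  if (duration_min %% bin_min != 0) {
    stop("duration_min must be a whole number of bins")
  }
  if (p_sleep < 0 || p_sleep > 1) stop("p_sleep must be a probability")
  set.seed(seed)
  n <- duration_min / bin_min
  states <- ifelse(rbinom(n, 1L, p_sleep) == 1L, "sleep", "wake")
  sleepRecord(states, bin_min)
}
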