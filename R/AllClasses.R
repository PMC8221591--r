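#' Calibrated multichannel scene
#'
#' A `Scene` bundles the named single-channel intensity planes of one imaged
#' field with its pixel-size calibration and its named anatomical region
#' masks. All planes and masks share one shape; region labels within a mask
#' layer are non-overlapping by construction (one integer label per pixel,
#' 0 = background).
#'
#' @slot channels named list of numeric matrices (one per fluorescence
#'   channel), identical dimensions.
#' @slot calibration positive numeric scalar, microns per pixel (isotropic,
#'   shared by all channels).
#' @slot regionMasks named list of integer label matrices (0 = background)
#'   with the same dimensions as the channels.
#'
#' @seealso [readScene()], [writeScene()], [simulateScene()]
#' @export
setClass("Scene",
  representation(
    channels = "list",
    calibration = "numeric",
    regionMasks = "list"
  )
)

setValidity("Scene", function(object) {
  msg <- character()
  if (length(object@calibration) != 1L || !is.finite(object@calibration) ||
      object@calibration <= 0) {
    msg <- c(msg, "calibration must be a single positive number (um/px)")
  }
  if (length(object@channels) == 0L) {
    msg <- c(msg, "Scene needs at least one channel")
  }
  if (is.null(names(object@channels)) || anyNA(names(object@channels)) ||
      any(names(object@channels) == "")) {
    msg <- c(msg, "channels must be named")
  }
  dims <- lapply(object@channels, dim)
  if (length(unique(dims)) > 1L) {
    msg <- c(msg, "all channels must share the same dimensions")
  }
  for (nm in names(object@regionMasks)) {
    m <- object@regionMasks[[nm]]
    if (!identical(dim(m), dims[[1L]])) {
      msg <- c(msg, sprintf("region mask '%s' does not match the image shape", nm))
    }
    if (any(m < 0) || any(m != round(m))) {
      msg <- c(msg, sprintf("region mask '%s' must hold non-negative integer labels", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Scene channel names
#' @param x,object a `Scene`
#' @export
setMethod("names", "Scene", function(x) names(x@channels))

#' Accessors for Scene objects
#'
#' @param x a [Scene]
#' @param name channel or mask name
#' @return `getChannel` the numeric intensity matrix; `getRegionMask` the
#'   integer label matrix; `calibration` the pixel size in um/px;
#'   `sceneDim` the image dimensions.
#' @export
getChannel <- function(x, name) {
  stopifnot(is(x, "Scene"))
  if (!name %in% names(x@channels)) {
    stop(sprintf("no channel '%s' in Scene (channels: %s)", name,
                 paste(names(x@channels), collapse = ", ")))
  }
  x@channels[[name]]
}

#' @rdname getChannel
#' @export
getRegionMask <- function(x, name) {
  stopifnot(is(x, "Scene"))
  if (!name %in% names(x@regionMasks)) {
    stop(sprintf("no region mask '%s' in Scene", name))
  }
  x@regionMasks[[name]]
}

#' @rdname getChannel
#' @export
calibration <- function(x) {
  stopifnot(is(x, "Scene"))
  x@calibration
}

#' @rdname getChannel
#' @export
sceneDim <- function(x) {
  stopifnot(is(x, "Scene"))
  dim(x@channels[[1L]])
}

#' @rdname getChannel
#' @export
regionMaskNames <- function(x) {
  stopifnot(is(x, "Scene"))
  names(x@regionMasks)
}

setMethod("show", "Scene", function(object) {
  d <- dim(object@channels[[1L]])
  cat(sprintf("Scene: %d x %d px (%.4g um/px)\n", d[1L], d[2L], object@calibration))
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
  cat("  region masks:", if (length(object@regionMasks))
    paste(names(object@regionMasks), collapse = ", ") else "<none>", "\n")
})

#' Scene constructor
#'
#' @param channels named list of numeric matrices.
#' @param calibration microns per pixel (positive scalar).
#' @param regionMasks named list of integer label matrices (may be empty).
#' @return a validated [Scene]
#' @export
Scene <- function(channels, calibration, regionMasks = list()) {
  channels <- lapply(channels, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  regionMasks <- lapply(regionMasks, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    m
  })
  new("Scene", channels = channels, calibration = as.numeric(calibration),
      regionMasks = regionMasks)
}

#' Connected components detected in one channel
#'
#' Holds the integer label matrix of the retained components together with a
#' per-component statistics table. Produced by [detectComponents()].
#'
#' @slot labels integer matrix, 0 = background, k = pixels of component k.
#' @slot stats data.frame with one row per component: `label`, `n_px`,
#'   `area_um2`, `total_intensity`, `mean_intensity`, `centroid_row`,
#'   `centroid_col` (0-based pixel indices).
#' @slot calibration microns per pixel used for the areas.
#' @export
setClass("ComponentSet",
  representation(labels = "matrix", stats = "data.frame", calibration = "numeric")
)

setValidity("ComponentSet", function(object) {
  msg <- character()
  labs <- sort(unique(as.integer(object@labels[object@labels > 0])))
  if (!identical(labs, sort(as.integer(object@stats$label)))) {
    msg <- c(msg, "labels present in the matrix must match the stats table")
  }
  if (length(object@calibration) != 1L || object@calibration <= 0) {
    msg <- c(msg, "calibration must be a positive scalar")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet: %d components (%.4g um/px)\n",
              nrow(object@stats), object@calibration))
  if (nrow(object@stats)) {
    cat(sprintf("  area (um2): median %.3g, range [%.3g, %.3g]\n",
                median(object@stats$area_um2), min(object@stats$area_um2),
                max(object@stats$area_um2)))
  }
})

#' @rdname componentStats
#' @export
nComponents <- function(x) {
  stopifnot(is(x, "ComponentSet"))
  nrow(x@stats)
}

#' Accessors for ComponentSet objects
#'
#' @param x a [ComponentSet]
#' @return `componentStats` the per-component table, `componentLabels` the
#'   integer label matrix, `nComponents` the number of components.
#' @export
componentStats <- function(x) {
  stopifnot(is(x, "ComponentSet"))
  x@stats
}

#' @rdname componentStats
#' @export
componentLabels <- function(x) {
  stopifnot(is(x, "ComponentSet"))
  x@labels
}

#' Ground truth for a simulated scene
#'
#' @slot dots data.frame of true dots: `channel`, `row`, `col` (pixel
#'   coordinates, 0-based), `sigma_px`, `intensity` (integrated, a.u.),
#'   `in_cell` (0 or the cell label the dot was placed in).
#' @slot cells data.frame of true cells: `label`, `centroid_row`,
#'   `centroid_col`, `radius_px`, `amplitude`, per-channel positivity flags.
#' @slot cellMask integer label matrix of true cell bodies.
#' @slot background numeric, flat background level (a.u.).
#' @slot noiseSigma numeric, pixel noise sigma (a.u.).
#' @slot regionCounts data.frame of true dot counts per channel x region.
#' @slot params the generating parameter list (see [sceneParams()]).
#' @export
setClass("SceneTruth",
  representation(
    dots = "data.frame", cells = "data.frame", cellMask = "matrix",
    background = "numeric", noiseSigma = "numeric",
    regionCounts = "data.frame", params = "list"
  )
)

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth: %d dots, %d cells, background %.3g, noise sigma %.3g\n",
              nrow(object@dots), nrow(object@cells), object@background,
              object@noiseSigma))
})

#' Reference-gene stability report
#'
#' Per-candidate variability measures under four stability methods, their
#' ranks, the aggregated rank, and the selected countervailing housekeeping
#' pair with its final fold-change check.
#'
#' @slot perGene data.frame, one row per candidate gene: model-based
#'   intragroup variance and signed intergroup difference, stability value,
#'   pairwise-M, raw CT SD, comparative delta-Ct measure, per-method ranks,
#'   aggregated rank.
#' @slot selectedPair character(2), the chosen housekeeping pair.
#' @slot pairRatio numeric, group expression ratio of the pair
#'   (alt-group mean of 2^-CT over ref-group mean).
#' @slot pairFoldChange numeric, signed fold change of the ratio.
#' @slot groups character(2), reference and alternative group labels.
#' @export
setClass("StabilityReport",
  representation(
    perGene = "data.frame", selectedPair = "character",
    pairRatio = "numeric", pairFoldChange = "numeric", groups = "character"
  )
)

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf("StabilityReport: %d candidate genes (%s vs %s)\n",
              nrow(object@perGene), object@groups[1L], object@groups[2L]))
  ord <- order(object@perGene$rank_aggregate)
  cat("  top ranks:", paste(head(object@perGene$gene[ord], 4L), collapse = ", "), "\n")
  cat(sprintf("  selected pair: %s/%s (ratio %.3g, fold change %.3g)\n",
              object@selectedPair[1L], object@selectedPair[2L],
              object@pairRatio, object@pairFoldChange))
})

#' Accessors for StabilityReport objects
#'
#' @param x a [StabilityReport]
#' @return `stabilityTable` the per-gene table; `selectedPair` the chosen
#'   housekeeping pair (character of length 2).
#' @export
stabilityTable <- function(x) {
  stopifnot(is(x, "StabilityReport"))
  x@perGene
}

#' @rdname stabilityTable
#' @export
selectedPair <- function(x) {
  stopifnot(is(x, "StabilityReport"))
  x@selectedPair
}
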