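#' Run configuration
#'
#' All tunable parameters of the quantification and screening protocol, with
#' the protocol's defaults: components must have mean intensity at least
#' 200% of their local surroundings (`threshold_ratio = 2`), expression areas
#' must exceed 30 um^2 (`min_component_area_um2 = 30`), and sleep-group
#' animals awake for more than 60% of the final 45 min are excluded
#' (`exclusion_wake_threshold = 0.60`, `exclusion_window_min = 45`).
#'
#' @slot threshold_ratio component mean / surround mean acceptance ratio
#'   (> 1; the "200% of its surroundings" rule at the default 2.0).
#' @slot min_component_area_um2 minimum component area in um^2 for
#'   cell-scale expression areas (strictly greater-than; default 30).
#' @slot dot_min_area_um2 minimum component area for dot-scale detection
#'   used by the single-dot calibration (default 0.05 um^2).
#' @slot surround_window_um side of the square surround window centred on a
#'   candidate component (default 40 um, about four expected cell diameters).
#' @slot nlm_patch_radius,nlm_search_radius,nlm_h non-local means denoising
#'   parameters (pixels; `nlm_h = NA` lets the filter pick a bandwidth from
#'   the estimated noise sigma).
#' @slot overlap_min_fraction minimum overlapping pixel fraction for a cell
#'   to count as co-expressing (default 0 = any overlapping pixel).
#' @slot exclusion_wake_threshold wake fraction above which (strictly) a
#'   sleep-group record is excluded (default 0.60).
#' @slot exclusion_window_min trailing scoring window for the exclusion rule
#'   in minutes (default 45).
#' @slot top_k number of top-ranked stability candidates among which the
#'   housekeeping pair is chosen (default 4).
#' @slot alpha family-wise significance level (default 0.05).
#' @slot dot_average `"mean"` or `"median"` over the selected representative
#'   dots in the single-dot calibration (default `"mean"`, matching the
#'   protocol's formula).
#' @slot seed integer RNG seed for stochastic stages (NA = leave RNG alone).
#' @seealso [loadConfig()]
#' @export
setClass("RunConfig",
  representation(
    threshold_ratio = "numeric",
    min_component_area_um2 = "numeric",
    dot_min_area_um2 = "numeric",
    surround_window_um = "numeric",
    nlm_patch_radius = "numeric",
    nlm_search_radius = "numeric",
    nlm_h = "numeric",
    overlap_min_fraction = "numeric",
    exclusion_wake_threshold = "numeric",
    exclusion_window_min = "numeric",
    top_k = "numeric",
    alpha = "numeric",
    dot_average = "character",
    seed = "numeric"
  ),
  prototype(
    threshold_ratio = 2.0,
    min_component_area_um2 = 30,
    dot_min_area_um2 = 0.05,
    surround_window_um = 40,
    nlm_patch_radius = 2,
    nlm_search_radius = 5,
    nlm_h = NA_real_,
    overlap_min_fraction = 0,
    exclusion_wake_threshold = 0.60,
    exclusion_window_min = 45,
    top_k = 4,
    alpha = 0.05,
    dot_average = "mean",
    seed = NA_real_
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  chk1 <- function(x, nm) {
    if (length(x) != 1L) msg <<- c(msg, sprintf("%s must be a single value", nm))
  }
  for (nm in c("threshold_ratio", "min_component_area_um2", "dot_min_area_um2",
               "surround_window_um", "overlap_min_fraction",
               "exclusion_wake_threshold", "exclusion_window_min",
               "top_k", "alpha")) {
    chk1(slot(object, nm), nm)
  }
  if (object@threshold_ratio <= 1) {
    msg <- c(msg, "threshold_ratio must be > 1 (component brighter than surround)")
  }
  if (object@min_component_area_um2 <= 0 || object@dot_min_area_um2 <= 0) {
    msg <- c(msg, "component area thresholds must be > 0")
  }
  if (object@surround_window_um <= 0) {
    msg <- c(msg, "surround_window_um must be > 0")
  }
  if (object@overlap_min_fraction < 0 || object@overlap_min_fraction > 1) {
    msg <- c(msg, "overlap_min_fraction must be in [0, 1]")
  }
  if (object@exclusion_wake_threshold < 0 || object@exclusion_wake_threshold > 1) {
    msg <- c(msg, "exclusion_wake_threshold must be in [0, 1]")
  }
  if (object@exclusion_window_min <= 0) {
    msg <- c(msg, "exclusion_window_min must be > 0")
  }
  if (!object@dot_average %in% c("mean", "median")) {
    msg <- c(msg, "dot_average must be 'mean' or 'median'")
  }
  if (object@top_k < 2) msg <- c(msg, "top_k must be >= 2")
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:\n")
  for (nm in slotNames(object)) {
    cat(sprintf("  %-26s %s\n", nm, paste(slot(object, nm), collapse = ", ")))
  }
})

#' Build a run configuration
#'
#' `runConfig()` constructs a validated [RunConfig] with any subset of
#' parameters overridden; `loadConfig()` reads overrides from a YAML file
#' (an empty file yields all defaults).
#'
#' @param ... named [RunConfig] parameters to override.
#' @return a validated [RunConfig]
#' @examples
#' runConfig()                       # protocol defaults
#' runConfig(threshold_ratio = 3)
#' @export
runConfig <- function(...) {
  over <- list(...)
  bad <- setdiff(names(over), slotNames("RunConfig"))
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  obj <- new("RunConfig")
  for (nm in names(over)) {
    value <- over[[nm]]
    if (nm != "dot_average") value <- as.numeric(value)
    slot(obj, nm) <- value
  }
  validObject(obj)
  obj
}

#' @rdname runConfig
#' @param path path to a YAML configuration file.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  values <- yaml::read_yaml(path)
  if (is.null(values)) values <- list()
  if (!is.list(values)) stop("config file must contain a YAML mapping")
  do.call(runConfig, values)
}

#' @rdname runConfig
#' @param config a [RunConfig]
#' @export
configAsList <- function(config) {
  stopifnot(is(config, "RunConfig"))
  setNames(lapply(slotNames(config), function(nm) slot(config, nm)),
           slotNames(config))
}
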