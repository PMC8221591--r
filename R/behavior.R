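#' Sleep record construction and validation
#'
#' A sleep record is a data.frame of contiguous, non-overlapping scoring
#' bins: `start_min`, `length_min`, `state` ("sleep"/"wake").
#'
#' @param states character vector of bin states.
#' @param bin_min bin length in minutes (scalar) or per-bin vector.
#' @param start_min start of the first bin.
#' @return validated sleep record data.frame
#' @export
sleepRecord <- function(states, bin_min = 5, start_min = 0) {
  lengths <- rep_len(bin_min, length(states))
  rec <- data.frame(start_min = start_min + cumsum(c(0, lengths[-length(lengths)])),
                    length_min = lengths, state = as.character(states),
                    stringsAsFactors = FALSE)
  validateSleepRecord(rec)
}

#' @rdname sleepRecord
#' @param record candidate record data.frame.
#' @export
validateSleepRecord <- function(record) {
  need <- c("start_min", "length_min", "state")
  if (!all(need %in% names(record))) {
    stop("sleep record needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(record) == 0L) stop("sleep record is empty")
  if (!all(record$state %in% c("sleep", "wake"))) {
    stop("states must be 'sleep' or 'wake'")
  }
  if (any(record$length_min <= 0)) stop("bin lengths must be positive")
  ends <- record$start_min + record$length_min
  if (nrow(record) > 1L &&
      any(abs(record$start_min[-1L] - ends[-nrow(record)]) > 1e-9)) {
    stop("bins must be contiguous and non-overlapping")
  }
  record
}

#' Percent of a window spent asleep
#'
#' Uses scoring bins that lie fully inside the window. With no window the
#' whole record is used; `percentSleep + percentWake = 100` exactly.
#'
#' @param record a sleep record (see [sleepRecord()]).
#' @param window optional `c(start_min, end_min)` interval within the record.
#' @return percentage in `[0, 100]`
#' @export
percentSleep <- function(record, window = NULL) {
  record <- validateSleepRecord(record)
  if (!is.null(window)) {
    if (length(window) != 2L || window[2L] <= window[1L]) {
      stop("window must be c(start, end) with end > start")
    }
    span <- c(record$start_min[1L],
              record$start_min[nrow(record)] + record$length_min[nrow(record)])
    if (window[1L] < span[1L] - 1e-9 || window[2L] > span[2L] + 1e-9) {
      stop("window must lie within the record span")
    }
    keep <- record$start_min >= window[1L] - 1e-9 &
      (record$start_min + record$length_min) <= window[2L] + 1e-9
    record <- record[keep, , drop = FALSE]
    if (nrow(record) == 0L) stop("window contains no whole scoring bin")
  }
  100 * sum(record$length_min[record$state == "sleep"]) / sum(record$length_min)
}

#' @rdname percentSleep
#' @export
percentWake <- function(record, window = NULL) {
  100 - percentSleep(record, window)
}

#' Wake fraction over the trailing scoring window
#'
#' Returns the wake fraction over the maximal suffix of whole bins whose
#' total length does not exceed `window_min` (with 2-min bins and the
#' default 45-min window this is the last 22 bins = 44 min, since 45 min is
#' not a whole number of bins).
#'
#' @param record a sleep record.
#' @param window_min trailing window length in minutes (default 45).
#' @return wake fraction in `[0, 1]`
#' @export
finalWindowWakeFraction <- function(record, window_min = 45) {
  record <- validateSleepRecord(record)
  total <- sum(record$length_min)
  if (total < window_min - 1e-9) {
    stop("record is shorter than the requested trailing window")
  }
  lens <- rev(record$length_min)
  k <- max(which(cumsum(lens) <= window_min + 1e-9))
  tail_rec <- record[(nrow(record) - k + 1L):nrow(record), , drop = FALSE]
  sum(tail_rec$length_min[tail_rec$state == "wake"]) / sum(tail_rec$length_min)
}

#' Apply the sleep-group exclusion rule
#'
#' Sleep-group animals whose wake fraction over the trailing window exceeds
#' the threshold (strictly) are excluded; sleep-deprivation-group records are
#' never excluded by this rule.
#'
#' @param records named list of sleep records, one per animal.
#' @param groups character vector (per animal): `"sleep"` or `"SD"`.
#' @param threshold wake-fraction threshold (default 0.60, strict `>`).
#' @param window_min trailing window (default 45 min).
#' @return list with `kept` and `excluded` animal names and a per-animal
#'   `table` (`animal`, `group`, `wake_fraction`, `excluded`).
#' @export
applyExclusion <- function(records, groups, threshold = 0.60, window_min = 45) {
  if (is.null(names(records))) names(records) <- paste0("animal", seq_along(records))
  if (length(groups) != length(records)) {
    stop("one group label per record is required")
  }
  wf <- vapply(records, finalWindowWakeFraction, numeric(1), window_min = window_min)
  excluded <- groups == "sleep" & wf > threshold
  data <- data.frame(animal = names(records), group = groups,
                     wake_fraction = wf, excluded = excluded,
                     row.names = NULL, stringsAsFactors = FALSE)
  list(kept = data$animal[!excluded], excluded = data$animal[excluded],
       table = data)
}
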