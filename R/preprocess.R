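#' Clip a series to the analysis window
#'
#' Retains only minutes within the equilibrated analysis window (default
#' 12:30-15:00, both boundaries inclusive). The first half hour of a logging
#' session is equilibration time and is excluded by the default window.
#'
#' @param series A [paired_series].
#' @param start,end Window boundaries as `"HH:MM"` strings or minutes since
#'   midnight. `start` must precede `end`.
#' @return The clipped [paired_series]; if nothing survives, an empty series
#'   with a warning (never an error).
#' @export
clip_to_window <- function(series, start = "12:30", end = "15:00") {
  stopifnot(inherits(series, "paired_series"))
  start <- if (is.character(start)) parse_clock_time(start) else as.numeric(start)
  end <- if (is.character(end)) parse_clock_time(end) else as.numeric(end)
  if (is.na(start) || is.na(end) || start >= end) {
    stop("invalid analysis window: start must precede end", call. = FALSE)
  }
  keep <- series$time_min >= start & series$time_min <= end
  out <- ps_rebuild(series, series[keep, ])
  if (nrow(out) == 0L) {
    warning("no minutes inside the analysis window for plant ",
      attr(series, "plant_id"), call. = FALSE)
  }
  out
}

#' Trim minutes recorded while evaporative coolers were active
#'
#' Removes minute-pairs whose air temperature is at or below the treatment's
#' trim threshold (strictly-greater-than retention), the signature of active
#' evaporative-cooler cycles in a thermostated glasshouse. Both channels of a
#' pair are removed together so the series stays aligned. Defaults: 16 deg C
#' for the benign treatment, 31 deg C for the high-temperature treatment.
#'
#' @param series A [paired_series].
#' @param treatment Treatment determining the threshold; defaults to the
#'   series' own treatment attribute.
#' @param thresholds Named numeric vector of trim thresholds (deg C).
#' @return A list with `series` (the trimmed [paired_series]) and `report`, a
#'   one-row tibble with `n_input`, `n_retained`, `fraction_trimmed`.
#' @export
trim_by_air_threshold <- function(series, treatment = attr(series, "treatment"),
                                  thresholds = c(benign = 16, high = 31)) {
  stopifnot(inherits(series, "paired_series"))
  treatment <- match.arg(treatment, .treatments)
  thr <- thresholds[[treatment]]
  keep <- series$t_air > thr
  out <- ps_rebuild(series, series[keep, ])
  n_in <- nrow(series)
  report <- tibble::tibble(
    plant_id = attr(series, "plant_id"),
    treatment = treatment,
    threshold_c = thr,
    n_input = n_in,
    n_retained = nrow(out),
    fraction_trimmed = if (n_in > 0L) 1 - nrow(out) / n_in else 0
  )
  if (nrow(out) == 0L && n_in > 0L) {
    warning("all minutes at or below the ", thr, " degC trim threshold for plant ",
      attr(series, "plant_id"), call. = FALSE)
  }
  list(series = out, report = report)
}

#' Preprocess a series: window clipping then threshold trimming
#'
#' Applies [clip_to_window()] followed by [trim_by_air_threshold()] (the two
#' row filters commute) and assembles the full trim report.
#'
#' @inheritParams clip_to_window
#' @inheritParams trim_by_air_threshold
#' @return A list with `series` and `report`; the report records the row count
#'   after each stage and the fraction removed by the temperature threshold.
#' @export
preprocess_series <- function(series, start = "12:30", end = "15:00",
                              thresholds = c(benign = 16, high = 31)) {
  clipped <- suppressWarnings(clip_to_window(series, start, end))
  trimmed <- suppressWarnings(
    trim_by_air_threshold(clipped, thresholds = thresholds)
  )
  n_window <- nrow(clipped)
  report <- tibble::tibble(
    plant_id = attr(series, "plant_id"),
    treatment = attr(series, "treatment"),
    n_input = nrow(series),
    n_after_window = n_window,
    n_after_threshold = nrow(trimmed$series),
    fraction_trimmed_by_threshold =
      if (n_window > 0L) 1 - nrow(trimmed$series) / n_window else 0
  )
  if (nrow(trimmed$series) == 0L) {
    warning("preprocessing left no minutes for plant ",
      attr(series, "plant_id"), call. = FALSE)
  }
  list(series = trimmed$series, report = report)
}
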