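#' Thermal offset of a paired series
#'
#' The thermal offset is the leaf-minus-air temperature difference,
#' \eqn{\Delta T = T_{leaf} - T_{air}}, computed per retained minute; negative
#' values mean the leaf is cooler than the surrounding air (transpirational
#' cooling), positive values a leaf warmer than air.
#'
#' @param series A non-empty, preprocessed [paired_series].
#' @return A list with `delta_t` (per-minute offsets, deg C) and `mean`
#'   (their mean over all retained minutes).
#' @export
thermal_offset <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  if (nrow(series) == 0L) {
    stop("cannot compute a thermal offset from an empty series (plant ",
      attr(series, "plant_id"), ")", call. = FALSE)
  }
  dt <- series$t_leaf - series$t_air
  list(delta_t = dt, mean = mean(dt))
}

#' Windowed leaf-air coupling slopes
#'
#' Partitions the series into non-overlapping windows (default 30 min,
#' left-anchored at the analysis-window start) and fits, per window, the
#' ordinary-least-squares slope of `t_leaf` on `t_air`. Windows with too few
#' minutes or a near-constant air temperature (a degenerate regressor in a
#' thermostated room) are skipped and reported, never imputed.
#'
#' @param series A preprocessed [paired_series].
#' @param window_minutes Window width in minutes.
#' @param min_points Minimum retained minutes for a window to be fitted.
#' @param min_air_range Minimum air-temperature range (deg C) within a window.
#' @param anchor Clock time the window grid is anchored at (`"HH:MM"` or
#'   minutes since midnight); defaults to the analysis-window start.
#' @return A tibble with one row per window: `window_start` (minutes since
#'   midnight), `slope`, `n_points`, `r_squared`, `retained`, `skip_reason`.
#'   At least one window must be retained, otherwise an error names the plant.
#' @export
coupling_slopes <- function(series, window_minutes = 30, min_points = 10,
                            min_air_range = 0.2, anchor = "12:30") {
  stopifnot(inherits(series, "paired_series"))
  anchor <- if (is.character(anchor)) parse_clock_time(anchor) else as.numeric(anchor)
  if (nrow(series) == 0L) {
    stop("no data to fit coupling slopes for plant ",
      attr(series, "plant_id"), call. = FALSE)
  }
  idx <- floor((series$time_min - anchor) / window_minutes)
  rows <- lapply(sort(unique(idx)), function(w) {
    sel <- idx == w
    ta <- series$t_air[sel]
    tl <- series$t_leaf[sel]
    n <- length(ta)
    start <- anchor + w * window_minutes
    if (n < min_points) {
      return(tibble::tibble(window_start = start, slope = NA_real_,
        n_points = n, r_squared = NA_real_, retained = FALSE,
        skip_reason = "too_few_points"))
    }
    if (diff(range(ta)) < min_air_range) {
      return(tibble::tibble(window_start = start, slope = NA_real_,
        n_points = n, r_squared = NA_real_, retained = FALSE,
        skip_reason = "air_range_too_small"))
    }
    slope <- cov(ta, tl) / var(ta)
    r2 <- cor(ta, tl)^2
    tibble::tibble(window_start = start, slope = slope, n_points = n,
      r_squared = r2, retained = TRUE, skip_reason = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  if (!any(out$retained)) {
    stop("no valid coupling windows for plant ", attr(series, "plant_id"),
      " (", nrow(out), " window(s), all skipped)", call. = FALSE)
  }
  out
}

#' Aggregate window slopes into the thermal coupling strength
#'
#' The per-plant coupling strength \eqn{\beta} is the unweighted mean of the
#' retained window slopes; \eqn{\beta \approx 1} means the leaf tracks air
#' temperature isometrically. An n-weighted mean is available as an
#' alternative aggregation (identical when all windows have equal n).
#'
#' @param slopes Output of [coupling_slopes()], or a numeric vector of slopes.
#' @param method `"mean"` (unweighted, default) or `"n_weighted"`.
#' @return The scalar coupling strength.
#' @export
beta_from_slopes <- function(slopes, method = c("mean", "n_weighted")) {
  method <- match.arg(method)
  if (is.numeric(slopes)) {
    slopes <- tibble::tibble(slope = slopes,
      n_points = rep(1L, length(slopes)), retained = !is.na(slopes))
  }
  kept <- slopes[slopes$retained, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no retained window slopes", call. = FALSE)
  switch(method,
    mean = mean(kept$slope),
    n_weighted = sum(kept$slope * kept$n_points) / sum(kept$n_points)
  )
}

#' Classify thermoregulatory behaviour from the coupling strength
#'
#' Leaves with \eqn{\beta \approx 1} are poikilothermic (leaf tracks air),
#' \eqn{\beta < 1} limited homeotherms (excursions damped relative to air) and
#' \eqn{\beta > 1} megatherms (excursions amplified). The tolerance `epsilon`
#' sets the half-width of the poikilothermy band around 1.
#'
#' @param beta Numeric vector of coupling strengths; must be finite.
#' @param epsilon Half-width of the \eqn{\beta \approx 1} band.
#' @return Factor with levels `limited_homeotherm`, `poikilotherm`,
#'   `megatherm`.
#' @export
classify_thermoregulation <- function(beta, epsilon = 0.1) {
  if (any(!is.finite(beta))) {
    stop("beta must be finite for classification", call. = FALSE)
  }
  stopifnot(epsilon >= 0)
  # tiny slack so representable band edges (e.g. beta = 1.1) stay inclusive
  epsilon <- epsilon + 1e-12
  cls <- ifelse(abs(beta - 1) <= epsilon, "poikilotherm",
    ifelse(beta < 1 - epsilon, "limited_homeotherm", "megatherm"))
  factor(cls, levels = .thermo_classes)
}

#' Per-plant coupling metrics
#'
#' Runs [thermal_offset()], [coupling_slopes()], [beta_from_slopes()] and
#' [classify_thermoregulation()] on one preprocessed series.
#'
#' @inheritParams coupling_slopes
#' @param epsilon Poikilothermy band half-width passed to
#'   [classify_thermoregulation()].
#' @param beta_method Aggregation passed to [beta_from_slopes()].
#' @return A one-row tibble: `plant_id`, `treatment`, `delta_t_mean`, `beta`,
#'   `n_windows`, `n_minutes`, `thermo_class`.
#' @export
coupling_metrics <- function(series, window_minutes = 30, min_points = 10,
                             min_air_range = 0.2, anchor = "12:30",
                             epsilon = 0.1, beta_method = "mean") {
  off <- thermal_offset(series)
  slopes <- coupling_slopes(series, window_minutes, min_points,
    min_air_range, anchor)
  b <- beta_from_slopes(slopes, beta_method)
  tibble::tibble(
    plant_id = attr(series, "plant_id"),
    treatment = attr(series, "treatment"),
    delta_t_mean = off$mean,
    beta = b,
    n_windows = sum(slopes$retained),
    n_minutes = nrow(series),
    thermo_class = as.character(classify_thermoregulation(b, epsilon))
  )
}
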