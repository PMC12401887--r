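#' Parameters of the leaf thermal time constant model
#'
#' @param phi Ratio of projected to total leaf area (dimensionless, in (0, 1];
#'   default 0.5 for a bifacial flat leaf).
#' @param cp_w Specific heat capacity of water, J kg-1 K-1 (default 4181).
#' @param cp_d Specific heat capacity of dry leaf matter, J kg-1 K-1
#'   (default 2814).
#' @param u Wind speed at the leaf, m s-1 (default 1.0, still glasshouse air).
#' @param a_h Coefficient of the laminar flat-plate heat-transfer correlation
#'   h = a_h * sqrt(u / width), W m-2 K-1 (m s)^0.5 (default 3.87, the
#'   one-coefficient collapse of 0.664 k_air Pr^(1/3) / nu^(1/2) at ~25 degC).
#' @return A list of class `tau_params`.
#' @export
tau_params <- function(phi = 0.5, cp_w = 4181, cp_d = 2814, u = 1.0,
                       a_h = 3.87) {
  vals <- c(phi = phi, cp_w = cp_w, cp_d = cp_d, u = u, a_h = a_h)
  if (any(vals <= 0)) stop("all tau parameters must be strictly positive",
    call. = FALSE)
  if (phi > 1) stop("phi must lie in (0, 1]", call. = FALSE)
  structure(as.list(vals), class = "tau_params")
}

#' Boundary-layer heat transfer coefficient of a leaf
#'
#' Sensible-heat transfer coefficient from the laminar forced-convection
#' flat-plate correlation, `h = a_h * sqrt(u / width)` (W m-2 K-1): wider
#' leaves have thicker boundary layers and exchange heat less efficiently per
#' unit area.
#'
#' @param width_m Leaf width in metres (the boundary-layer length scale).
#' @param params A [tau_params()] object supplying `u` and `a_h`.
#' @return h in W m-2 K-1.
#' @examples
#' heat_transfer_coefficient(0.01, tau_params()) # 38.7
#' @export
heat_transfer_coefficient <- function(width_m, params = tau_params()) {
  stopifnot(inherits(params, "tau_params"))
  if (any(width_m <= 0)) stop("leaf width must be positive", call. = FALSE)
  if (params$u <= 0) stop("wind speed must be positive", call. = FALSE)
  params$a_h * sqrt(params$u / width_m)
}

#' Leaf thermal time constant
#'
#' The characteristic time (s) for leaf temperature to respond to a step
#' change in its environment, in the absence of latent-heat thermoregulation:
#' the leaf's areal heat capacity divided by its sensible heat conductance,
#' \deqn{\tau = \varphi \, LMA \left( \frac{c_{p,w}}{LDMC \cdot h} +
#'   \frac{c_{p,d} - c_{p,w}}{h} \right).}
#' The bracket is the wet-leaf specific heat per unit dry mass over h: a leaf
#' of dry-matter content LDMC carries (1/LDMC - 1) kg of water per kg dry
#' matter, so its specific heat per dry mass is c_p,w/LDMC + c_p,d - c_p,w.
#' Small tau means a leaf that tracks environmental changes rapidly; thick,
#' water-rich leaves (high LMA, low LDMC) respond slowly.
#'
#' @param lma Leaf mass per area, kg m-2.
#' @param ldmc Leaf dry matter content, kg kg-1, in (0, 1].
#' @param width_m Leaf width in metres, used to compute h; ignored when `h`
#'   is supplied directly.
#' @param params A [tau_params()] object.
#' @param h Optional heat transfer coefficient (W m-2 K-1) overriding the
#'   width-based correlation.
#' @return tau in seconds.
#' @examples
#' thermal_time_constant(lma = 0.1, ldmc = 0.4, h = 25) # 18.171 s
#' @export
thermal_time_constant <- function(lma, ldmc, width_m = NULL,
                                  params = tau_params(), h = NULL) {
  stopifnot(inherits(params, "tau_params"))
  if (any(lma <= 0)) stop("LMA must be positive (kg m-2)", call. = FALSE)
  if (any(ldmc <= 0 | ldmc > 1)) {
    stop("LDMC must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(h)) {
    if (is.null(width_m)) {
      stop("supply either width_m or h", call. = FALSE)
    }
    h <- heat_transfer_coefficient(width_m, params)
  }
  c_mass <- params$cp_w / ldmc + params$cp_d - params$cp_w
  params$phi * lma * c_mass / h
}

#' Air vapour pressure deficit (Tetens)
#'
#' Saturation vapour pressure from the Tetens formula,
#' `es = 0.6108 * exp(17.27 T / (T + 237.3))` (kPa), and
#' `VPD = es * (1 - RH/100)`. Used to report simulated glasshouse conditions.
#'
#' @param t_air_c Air temperature, deg C.
#' @param rh_percent Relative humidity, percent, in \[0, 100\].
#' @return VPD in kPa.
#' @examples
#' vpd(26.3, 30.5) # ~2.38 kPa
#' @export
vpd <- function(t_air_c, rh_percent) {
  if (any(rh_percent < 0 | rh_percent > 100)) {
    stop("relative humidity must lie in [0, 100] %", call. = FALSE)
  }
  es <- 0.6108 * exp(17.27 * t_air_c / (t_air_c + 237.3))
  es * (1 - rh_percent / 100)
}
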