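#' Temperature-dependent Q10
#'
#' Linear dependence of the Q10 temperature sensitivity of dark respiration on
#' measurement temperature, \eqn{Q_{10}(T) = 3.09 - 0.0435\,T}.
#'
#' @param temp leaf temperature (degC); vectorized.
#' @param intercept,slope coefficients of the linear relation.
#'
#' @return Q10 values (dimensionless). Warns outside the supported
#'   range (-10..45 degC).
#' @export
#' @examples
#' tdq10(25)   # 2.0025
tdq10 <- function(temp, intercept = 3.09, slope = 0.0435) {
  if (any(temp < -10 | temp > 45, na.rm = TRUE))
    warning("temperature outside supported range (-10..45 degC)")
  intercept - slope * temp
}

# Evaluate a q10_spec at temperature(s).
q10_value <- function(q10, temp) {
  if (is.numeric(q10)) return(rep_len(q10, length(temp)))
  stopifnot(inherits(q10, "q10_spec"))
  if (q10$mode == "fixed") rep_len(q10$q10, length(temp))
  else tdq10(temp, q10$tdq10_intercept, q10$tdq10_slope)
}

#' Standard temperature-only respiration model
#'
#' Respiration at temperature `temp` from the rate at a reference temperature
#' and a Q10 response: \eqn{R_T = R_{T_{ref}} Q_{10}^{(T - T_{ref})/10}}. In
#' temperature-dependent mode the Q10 is evaluated at the instantaneous
#' temperature `temp`.
#'
#' @param r_ref respiration at `t_ref` (umol CO2 m-2 s-1, > 0).
#' @param q10 a [q10_spec()] (or a single number, taken as a fixed Q10).
#' @param temp temperature (degC); vectorized.
#' @param t_ref reference temperature (degC).
#'
#' @return Respiration at `temp` (same units as `r_ref`).
#' @export
#' @examples
#' standard_model(2.5, q10_spec(), temp = 15, t_ref = 25)  # 1.25
standard_model <- function(r_ref, q10 = q10_spec(), temp, t_ref = 25) {
  if (!is.numeric(r_ref) || any(!is.finite(r_ref)) || any(r_ref <= 0))
    stop("'r_ref' must be positive")
  r_ref * q10_value(q10, temp)^((temp - t_ref) / 10)
}

#' Nocturnal decline fraction
#'
#' The universal temperature-independent decline of the basal respiration
#' rate with time since the onset of darkness:
#' \eqn{R_{T_o}/R_{T_o,initial} = \max(0, 1 - a\,h^b)}. With the universal
#' coefficients (a = 0.08, b = 0.54) the basal rate has fallen by about 25%
#' after 8 h of darkness.
#'
#' @param h hours since darkness onset (>= 0); vectorized.
#' @param p a [decline_params()] object.
#'
#' @return Dimensionless ratio in `[0, 1]`; identically 1 when the decline is
#'   disabled.
#' @export
#' @examples
#' decline_fraction(8)   # about 0.754: a 25% decrease
decline_fraction <- function(h, p = decline_params()) {
  if (!is.numeric(h) || any(!is.finite(h)) || any(h < 0))
    stop("'h' must be non-negative hours since darkness onset")
  stopifnot(inherits(p, "decline_params"))
  if (!p$enabled) return(rep_len(1, length(h)))
  pmax(0, 1 - p$a * h^p$b)
}

#' Merged nocturnal respiration formulation
#'
#' Respiration at any time during the night from the rate captured at sunset,
#' combining the Q10 temperature response with the temperature-independent
#' nocturnal decline:
#' \eqn{R_{T,t} = R_{T,sunset}\; Q_{10}^{0.1 (T_t - T_{sunset})}\,(1 - a h^b)}.
#' With the decline disabled this reduces exactly to the standard
#' temperature-only model anchored at sunset.
#'
#' @param r_sunset respiration at sunset (> 0).
#' @param q10 a [q10_spec()]; in temperature-dependent mode the Q10 is
#'   evaluated at the instantaneous temperature `temp`.
#' @param temp instantaneous temperature (degC); vectorized.
#' @param t_sunset temperature at sunset (degC).
#' @param h hours since sunset (>= 0); vectorized with `temp`.
#' @param decline a [decline_params()] object.
#'
#' @return Respiration (same units as `r_sunset`).
#' @export
#' @examples
#' # 8 h into a night cooling at 0.5 degC/h from sunset:
#' new_formulation(2.5, q10_spec(), temp = 16, t_sunset = 20, h = 8)
new_formulation <- function(r_sunset, q10 = q10_spec(), temp, t_sunset, h,
                            decline = decline_params()) {
  if (!is.numeric(r_sunset) || any(!is.finite(r_sunset)) || any(r_sunset <= 0))
    stop("'r_sunset' must be positive")
  r_sunset * q10_value(q10, temp)^(0.1 * (temp - t_sunset)) *
    decline_fraction(h, decline)
}

#' Temperature-limited leaf respiration
#'
#' The land-surface-model leaf respiration response: the standard Q10 model
#' divided by logistic high- and low-temperature limitation factors,
#' \eqn{R_T = R_{T_{ref}} Q_{10}^{(T-T_{ref})/10} /
#' [(1 + e^{0.3(T - T_{upp})})(1 + e^{0.3(T_{low} - T)})]}.
#' Well inside the limits the denominator is ~1 and the standard model is
#' recovered; at either limit the corresponding factor halves the rate.
#'
#' @inheritParams standard_model
#' @param p a [jules_params()] object supplying `t_ref`, `t_upp`, `t_low`.
#'
#' @return Respiration (same units as `r_ref`), never exceeding the standard
#'   model value.
#' @export
jules_leaf_resp <- function(r_ref, q10 = q10_spec(), temp, p = jules_params()) {
  stopifnot(inherits(p, "jules_params"))
  standard_model(r_ref, q10, temp, p$t_ref) /
    ((1 + exp(p$smoothing * (temp - p$t_upp))) *
       (1 + exp(p$smoothing * (p$t_low - temp))))
}

#' Whole-plant maintenance respiration
#'
#' Scales canopy leaf respiration up to whole-plant maintenance respiration
#' through the root/stem/leaf nitrogen ratios and soil water factor:
#' \eqn{R_m = R_{leaf}\,(\beta + (N_r + N_s)/N_l)}. The scaling is linear, so
#' any nocturnal decline applied to leaf respiration propagates unchanged to
#' root and stem respiration.
#'
#' @param r_leaf canopy leaf respiration (flux units).
#' @param p a [jules_params()] object.
#'
#' @return Maintenance respiration (same units as `r_leaf`).
#' @export
maintenance_resp <- function(r_leaf, p = jules_params()) {
  stopifnot(inherits(p, "jules_params"))
  r_leaf * (p$beta_sw + (p$n_r + p$n_s) / p$n_l)
}

#' Growth respiration
#'
#' Growth respiration as a fixed fraction (default 25%) of the excess of
#' gross primary production over maintenance respiration,
#' \eqn{R_g = f \max(GPP - R_m, 0)}. The clamp at zero covers night-time,
#' when GPP is zero and the unclamped difference would be negative.
#'
#' @param gpp gross primary production (flux units).
#' @param r_m maintenance respiration (same units).
#' @param p a [jules_params()] object supplying the growth fraction.
#'
#' @return Growth respiration (same units), >= 0.
#' @export
growth_resp <- function(gpp, r_m, p = jules_params()) {
  stopifnot(inherits(p, "jules_params"))
  p$growth_fraction * pmax(gpp - r_m, 0)
}
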