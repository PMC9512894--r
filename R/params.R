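#' Temperature-sensitivity specification
#'
#' Describes how the Q10 temperature sensitivity of respiration is evaluated:
#' either a fixed value (default 2, the conventional choice in land-surface
#' modelling) or the temperature-dependent form
#' \eqn{Q_{10}(T) = 3.09 - 0.0435\,T}, in which the sensitivity itself
#' declines linearly with leaf temperature.
#'
#' @param mode `"fixed"` or `"temperature_dependent"`.
#' @param q10 fixed Q10 value (dimensionless, > 0); ignored in
#'   temperature-dependent mode.
#' @param tdq10_intercept,tdq10_slope coefficients of the linear
#'   temperature-dependent Q10 (intercept dimensionless, slope per degree C).
#'
#' @return An object of class `q10_spec`.
#' @seealso [tdq10()], [standard_model()]
#' @export
#' @examples
#' q10_spec()                          # fixed Q10 = 2
#' q10_spec("temperature_dependent")   # Q10(T) = 3.09 - 0.0435 T
q10_spec <- function(mode = c("fixed", "temperature_dependent"), q10 = 2,
                     tdq10_intercept = 3.09, tdq10_slope = 0.0435) {
  mode <- match.arg(mode)
  if (!is.numeric(q10) || length(q10) != 1L || !is.finite(q10) || q10 <= 0)
    stop("'q10' must be a single positive number")
  if (mode == "temperature_dependent" &&
      tdq10_intercept - tdq10_slope * 45 <= 0)
    stop("temperature-dependent Q10 is non-positive within -10..45 degC")
  structure(list(mode = mode, q10 = q10,
                 tdq10_intercept = tdq10_intercept,
                 tdq10_slope = tdq10_slope),
            class = "q10_spec")
}

#' @export
print.q10_spec <- function(x, ...) {
  if (x$mode == "fixed") {
    cat("Q10 specification: fixed, Q10 =", x$q10, "\n")
  } else {
    cat(sprintf("Q10 specification: temperature-dependent, Q10(T) = %g - %g T\n",
                x$tdq10_intercept, x$tdq10_slope))
  }
  invisible(x)
}

#' Nocturnal decline parameters
#'
#' Parameters of the universal nocturnal decline of the basal respiration
#' rate, \eqn{R_{T_o}/R_{T_o,initial} = 1 - a\,h^b}, where `h` is hours since
#' the onset of darkness. Defaults are the coefficients of the universal
#' cross-species model (a = 0.08, b = 0.54).
#'
#' @param a dimensionless scale (>= 0).
#' @param b dimensionless exponent (> 0).
#' @param enabled if `FALSE` the decline factor is identically 1.
#'
#' @return An object of class `decline_params`.
#' @seealso [decline_fraction()]
#' @export
decline_params <- function(a = 0.08, b = 0.54, enabled = TRUE) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a < 0)
    stop("'a' must be a single non-negative number")
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("'b' must be a single positive number")
  structure(list(a = a, b = b, enabled = isTRUE(enabled)),
            class = "decline_params")
}

#' @export
print.decline_params <- function(x, ...) {
  cat(sprintf("Nocturnal decline: 1 - %g * h^%g%s\n", x$a, x$b,
              if (x$enabled) "" else " (disabled)"))
  invisible(x)
}

#' Whole-plant respiration parameters
#'
#' Parameters of the land-surface-model respiration scheme: the reference
#' temperature, the high/low temperature limits of the logistic denominator
#' applied to leaf respiration, the root/stem/leaf nitrogen contents and soil
#' water factor that scale leaf respiration up to whole-plant maintenance
#' respiration, and the growth-respiration fraction.
#'
#' Only the nitrogen ratios matter, so the contents are dimensionless here.
#' Defaults (`t_upp = 36`, `t_low = 0`, nitrogen ratio 1, `beta_sw = 1`)
#' describe an unstressed broadleaf canopy whose root-plus-stem respiration
#' matches its leaf respiration.
#'
#' @param t_ref reference temperature (degC) of the Q10 response.
#' @param t_upp,t_low upper and lower temperature limits (degC), `t_low <
#'   t_upp`.
#' @param n_r,n_s,n_l root, stem and leaf nitrogen contents (arbitrary common
#'   unit; `n_l > 0`).
#' @param beta_sw soil-water stress factor in `[0, 1]`.
#' @param growth_fraction fraction of `GPP - R_m` respired as growth, in
#'   `[0, 1]`.
#'
#' @return An object of class `jules_params`.
#' @seealso [jules_leaf_resp()], [maintenance_resp()], [growth_resp()]
#' @export
jules_params <- function(t_ref = 25, t_upp = 36, t_low = 0,
                         n_r = 0.5, n_s = 0.5, n_l = 1,
                         beta_sw = 1, growth_fraction = 0.25) {
  if (!is.numeric(t_low) || !is.numeric(t_upp) || t_low >= t_upp)
    stop("temperature limits invalid: need t_low < t_upp")
  if (!is.numeric(n_l) || n_l <= 0)
    stop("leaf nitrogen content 'n_l' must be positive")
  if (beta_sw < 0 || beta_sw > 1)
    stop("'beta_sw' must lie in [0, 1]")
  if (growth_fraction < 0 || growth_fraction > 1)
    stop("'growth_fraction' must lie in [0, 1]")
  structure(list(t_ref = t_ref, t_upp = t_upp, t_low = t_low,
                 n_r = n_r, n_s = n_s, n_l = n_l,
                 beta_sw = beta_sw, growth_fraction = growth_fraction,
                 smoothing = 0.3),
            class = "jules_params")
}

#' @export
print.jules_params <- function(x, ...) {
  cat("Whole-plant respiration parameters\n")
  cat(sprintf("  T_ref %g degC, limits (%g, %g) degC\n",
              x$t_ref, x$t_low, x$t_upp))
  cat(sprintf("  (N_r + N_s)/N_l = %g, beta_sw = %g, growth fraction = %g\n",
              (x$n_r + x$n_s) / x$n_l, x$beta_sw, x$growth_fraction))
  invisible(x)
}
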