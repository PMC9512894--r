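#' Q10 from a pair of measurements
#'
#' Temperature sensitivity implied by two respiration measurements at
#' different temperatures, \eqn{Q_{10} = (R_2/R_1)^{10/(T_2 - T_1)}}. Applied
#' to a brief (<= 30 min) artificial temperature manipulation this estimates
#' the inherent Q10; applied to measurements hours apart under natural
#' nocturnal cooling it gives the apparent Q10, which confounds the
#' temperature response with the temperature-independent decline of the
#' basal rate.
#'
#' @param r1,r2 respiration at the two measurements (> 0).
#' @param t1,t2 temperatures (degC), `t1 != t2`.
#'
#' @return Q10 (dimensionless).
#' @export
#' @examples
#' q10_from_pair(2, 20, 1, 10)  # halving over 10 degC: Q10 = 2
q10_from_pair <- function(r1, t1, r2, t2) {
  if (any(r1 <= 0) || any(r2 <= 0)) stop("respiration must be positive")
  if (any(t1 == t2))
    stop("temperature sensitivity undefined for equal temperatures")
  (r2 / r1)^(10 / (t2 - t1))
}

#' Decompose a nocturnal respiration decrease into temperature and
#' non-temperature control
#'
#' Splits the observed decrease in respiration between the beginning and end
#' of a night into the part explained by the temperature change acting
#' through the inherent Q10 (`alpha`) and the further, temperature-
#' independent decrease (`beta`), and reports the temperature-control
#' fraction `tc = alpha/(alpha + beta)`.
#'
#' For a warming night or a net respiration increase the construct is not
#' defined; `tc` is returned as `NA` with a warning rather than as a silent
#' negative number.
#'
#' @param r_start,r_end_obs observed respiration at the start and end of the
#'   night (`r_start > 0`).
#' @param t_start,t_end temperatures at the two measurements (degC).
#' @param q10_inh inherent Q10 (> 0).
#'
#' @return An object of class `tc_decomposition`: list with `alpha`, `beta`,
#'   `tc`, `r_temp_only`.
#' @export
#' @examples
#' # 8 h of cooling at 0.5 degC/h with the universal decline:
#' tc_decompose(2.5, 2.5 * 2^-0.4 * decline_fraction(8), 18, 14, 2)
tc_decompose <- function(r_start, r_end_obs, t_start, t_end, q10_inh) {
  if (r_start <= 0) stop("'r_start' must be positive")
  if (q10_inh <= 0) stop("'q10_inh' must be positive")
  r_temp_only <- r_start * q10_inh^((t_end - t_start) / 10)
  alpha <- r_start - r_temp_only
  beta <- r_temp_only - r_end_obs
  tc <- NA_real_
  if (t_end > t_start) {
    warning("warming night: temperature control undefined")
  } else if (alpha + beta <= 0 && !(alpha == 0 && beta == 0)) {
    warning("net respiration increase: temperature control undefined")
  } else if (alpha == 0 && beta == 0) {
    tc <- NA_real_  # no decrease at all: the fraction is undefined
  } else {
    tc <- alpha / (alpha + beta)
  }
  structure(list(alpha = alpha, beta = beta, tc = tc,
                 r_temp_only = r_temp_only),
            class = "tc_decomposition")
}

#' @export
print.tc_decomposition <- function(x, ...) {
  cat(sprintf(
    "Temperature control of nocturnal respiration\n  alpha = %.4g, beta = %.4g, TC = %.3f\n",
    x$alpha, x$beta, x$tc))
  invisible(x)
}

#' Apparent Q10 as a function of cooling rate
#'
#' Closed-form apparent Q10 obtained from endpoint measurements of a night
#' of length `L` cooling linearly at rate `c`, when the basal rate declines
#' by the universal power law:
#' \eqn{Q_{10,app}(c) = Q_{10,inh} (1 - a L^b)^{-10/(cL)}}. The apparent
#' sensitivity diverges as the cooling rate approaches zero and relaxes to
#' the inherent Q10 for fast cooling.
#'
#' @param q10_inh inherent Q10.
#' @param cooling_rate vector of cooling rates (degC/h, > 0; non-positive
#'   entries are flagged `NA`).
#' @param night_length night length `L` (h).
#' @param decline a [decline_params()] object.
#'
#' @return Data frame with `cooling_rate` and `q10_app`.
#' @export
apparent_q10_curve <- function(q10_inh = 2, cooling_rate,
                               night_length = 8,
                               decline = decline_params()) {
  dec <- decline_fraction(night_length, decline)
  q10_app <- ifelse(cooling_rate > 0,
                    q10_inh * dec^(-10 / (cooling_rate * night_length)),
                    NA_real_)
  if (any(cooling_rate <= 0))
    warning("non-positive cooling rates flagged as NA (undefined)")
  data.frame(cooling_rate = cooling_rate, q10_app = q10_app)
}

#' Temperature control as a function of cooling rate
#'
#' Applies [tc_decompose()] to the analytic endpoint states of a linearly
#' cooling night of length `L` at each cooling rate: the observed endpoint is
#' \eqn{Q_{10,inh}^{-cL/10}(1 - a L^b)} of the initial rate. TC tends to 0 as
#' cooling vanishes and to 1 as cooling dominates, increasing monotonically
#' in between.
#'
#' @inheritParams apparent_q10_curve
#' @return Data frame with `cooling_rate` and `tc`.
#' @export
tc_curve <- function(q10_inh = 2, cooling_rate, night_length = 8,
                     decline = decline_params()) {
  dec <- decline_fraction(night_length, decline)
  tc <- vapply(cooling_rate, function(cr) {
    if (cr < 0) return(NA_real_)
    if (cr == 0) {
      # no temperature change: all of the decrease is non-temperature control
      return(if (dec < 1) 0 else NA_real_)
    }
    r_end <- q10_inh^(-cr * night_length / 10) * dec
    tc_decompose(1, r_end, t_start = 0, t_end = -cr * night_length,
                 q10_inh = q10_inh)$tc
  }, numeric(1))
  data.frame(cooling_rate = cooling_rate, tc = tc)
}

#' Cumulative nocturnal overestimation by the constant-basal-rate model
#'
#' Integrates respiration through a night under the same temperature path
#' with and without the nocturnal decline of the basal rate, returning both
#' integrals and their (cumulative) difference -- the amount by which a
#' constant-basal-rate model overestimates accumulated nocturnal CO2 efflux.
#' Integration is trapezoidal on the model timestep. At constant temperature
#' the relative reduction has the closed form
#' \eqn{(a/(b+1)) L^b} for a night of length `L`.
#'
#' @param r_initial initial (sunset) respiration.
#' @param q10_inh inherent Q10 driving the temperature response.
#' @param schedule a [cooling_schedule()] for the night's temperature path.
#' @param night_length night length (h).
#' @param decline a [decline_params()] object.
#' @param timestep integration timestep (min; must divide the night).
#'
#' @return An object of class `overestimation`: list with the stepped
#'   `series` (h, temperature, both respiration paths, cumulative
#'   difference), totals `total_standard` and `total_decline` (flux-hours),
#'   `difference` and `relative` (difference as a fraction of the standard
#'   total).
#' @export
cumulative_overestimation <- function(r_initial = 2.5, q10_inh = 2,
                                      schedule = cooling_schedule("linear"),
                                      night_length = 8,
                                      decline = decline_params(),
                                      timestep = 15) {
  if ((night_length * 60) %% timestep != 0)
    stop("'timestep' must divide the night length")
  h <- seq(0, night_length, by = timestep / 60)
  temp <- schedule_temperature(schedule, h)
  r_std <- r_initial * q10_inh^(0.1 * (temp - schedule$t_start))
  r_dec <- r_std * decline_fraction(h, decline)
  cumdiff <- c(0, cumsum(diff(h) *
                           (utils::head(r_std - r_dec, -1) +
                              utils::tail(r_std - r_dec, -1)) / 2))
  total_std <- trapz(h, r_std)
  total_dec <- trapz(h, r_dec)
  structure(list(series = data.frame(h = h, temperature_C = temp,
                                     r_standard = r_std, r_decline = r_dec,
                                     cumulative_difference = cumdiff),
                 total_standard = total_std, total_decline = total_dec,
                 difference = total_std - total_dec,
                 relative = (total_std - total_dec) / total_std),
            class = "overestimation")
}

#' @export
print.overestimation <- function(x, ...) {
  cat(sprintf(
    "Cumulative nocturnal overestimation: %.4g flux-hours (%.2f%% of the constant-basal-rate total)\n",
    x$difference, 100 * x$relative))
  invisible(x)
}

# trapezoidal rule
trapz <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
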