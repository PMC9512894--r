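#' Sunrise, sunset and night length
#'
#' Standard astronomical approximation: solar declination
#' \eqn{\delta = -23.44 \cos(2\pi (doy + 10)/365)} and hour angle
#' \eqn{\cos H = -\tan\phi \tan\delta}, giving local solar sunrise/sunset
#' times and night length. Polar day and night clamp to 0 h and 24 h.
#'
#' @param latitude latitude (degrees, positive north, |lat| <= 90).
#' @param doy day of year (vectorized).
#'
#' @return Data frame with `doy`, `sunrise`, `sunset` (local solar hours)
#'   and `night_length` (h).
#' @export
#' @examples
#' sun_times(0, 80)    # equinox at the equator: 12 h night
sun_times <- function(latitude, doy) {
  if (abs(latitude) > 90) stop("latitude must be within [-90, 90]")
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  x <- -tan(latitude * pi / 180) * tan(decl)
  x <- pmin(pmax(x, -1), 1)
  day_len <- 2 * acos(x) * 180 / pi / 15
  data.frame(doy = doy, sunrise = 12 - day_len / 2,
             sunset = 12 + day_len / 2, night_length = 24 - day_len)
}

#' Site simulation configuration
#'
#' Bundles everything [run_site()] needs: the respiration formulation, the
#' whole-plant respiration parameters, the leaf basal respiration at the
#' reference temperature, the site latitude, the timestep and the
#' net-primary-production reporting threshold below which percentage effects
#' are masked.
#'
#' @param form a [formulation()].
#' @param resp a [jules_params()].
#' @param r_ref leaf respiration at the reference temperature
#'   (umol CO2 m-2 s-1).
#' @param latitude site latitude (degrees).
#' @param timestep timestep (min; must divide 24 h).
#' @param npp_threshold annual NPP (g C m-2 yr-1) below which percentage
#'   effects are not reported.
#'
#' @return An object of class `site_config`.
#' @export
site_config <- function(form = formulation("new"), resp = jules_params(),
                        r_ref = 1, latitude = 0, timestep = 15,
                        npp_threshold = 50) {
  stopifnot(inherits(form, "resp_formulation"),
            inherits(resp, "jules_params"))
  if (1440 %% timestep != 0) stop("'timestep' must divide 24 h")
  if (npp_threshold < 0) stop("'npp_threshold' must be >= 0")
  if (r_ref <= 0) stop("'r_ref' must be positive")
  structure(list(form = form, resp = resp, r_ref = r_ref,
                 latitude = latitude, timestep = timestep,
                 npp_threshold = npp_threshold),
            class = "site_config")
}

# umol CO2 m-2 s-1 sustained for one year, as g C m-2 yr-1
FLUX_TO_GC_YR <- 12.011e-6 * 86400 * 365

#' Step a single site through its forcing
#'
#' Desk-scale analogue of a land-surface-model respiration experiment. At
#' every timestep leaf respiration follows the temperature-limited response
#' ([jules_leaf_resp()]) with the formulation's Q10; through the night
#' (between the sunset and sunrise of [sun_times()]) formulations with the
#' nocturnal decline multiply it by [decline_fraction()] of the hours since
#' the timestep at or immediately preceding sunset. Maintenance respiration
#' scales leaf respiration by the nitrogen ratios and soil water factor at
#' every step, growth respiration takes its fixed fraction of `GPP - R_m`
#' (clamped at zero, which is the night-time value), and
#' `NPP = GPP - R_p` with `R_p = R_m + R_g`.
#'
#' @param forcing a `resp_forcing` data frame from [gen_forcing()] (or read
#'   with [read_forcing()]): regular sub-daily `hour` grid covering whole
#'   days, `t_air`, `gpp`.
#' @param cfg a [site_config()].
#'
#' @return An object of class `site_output`: list with `steps` (stepped
#'   series of leaf R, R_m, R_g, R_p, GPP, NPP, night flag and hours since
#'   sunset), `config`, and scalar aggregates `mean_rp`, `mean_npp`,
#'   `annual_npp_gC` (g C m-2 yr-1).
#' @export
run_site <- function(forcing, cfg = site_config()) {
  stopifnot(is.data.frame(forcing),
            all(c("doy", "hour", "t_air", "gpp") %in% names(forcing)),
            inherits(cfg, "site_config"))
  step_h <- cfg$timestep / 60
  dh <- diff(forcing$hour)
  if (!all(abs(dh[dh > 0] - step_h) < 1e-9))
    stop("forcing timestep does not match the configuration (gap in forcing?)")
  if (nrow(forcing) %% (24 / step_h) != 0)
    stop("forcing must cover whole days")

  form <- cfg$form
  p <- cfg$resp
  n <- nrow(forcing)
  st_by_doy <- sun_times(cfg$latitude, forcing$doy)
  sunrise <- st_by_doy$sunrise
  sunset <- st_by_doy$sunset
  hour <- forcing$hour

  night <- hour >= sunset | hour < sunrise
  # hours since the timestep at or immediately preceding sunset; h resets at
  # sunrise. Evening: measure from the last step boundary <= sunset of the
  # same day; pre-dawn: from the previous day's sunset (periodic for day 1).
  sunset_step <- floor(sunset / step_h) * step_h
  prev_sunset_step <- c(sunset_step[1], utils::head(sunset_step, -1))
  # previous calendar day's sunset for rows before sunrise
  day_index <- cumsum(c(1, diff(forcing$doy) != 0 | diff(hour) < 0))
  prev_day_sunset <- sunset_step
  for (d in unique(day_index)) {
    rows <- day_index == d
    prev_rows <- day_index == d - 1
    prev_day_sunset[rows] <- if (any(prev_rows))
      sunset_step[which(prev_rows)[1]] else sunset_step[which(rows)[1]]
  }
  h_night <- rep(NA_real_, n)
  evening <- night & hour >= sunset
  predawn <- night & hour < sunrise
  h_night[evening] <- hour[evening] - sunset_step[evening]
  h_night[predawn] <- hour[predawn] + 24 - prev_day_sunset[predawn]
  h_night[!night] <- 0

  leaf_r <- jules_leaf_resp(cfg$r_ref, form$q10, forcing$t_air, p)
  if (form$decline$enabled) {
    dec <- rep(1, n)
    dec[night] <- decline_fraction(h_night[night], form$decline)
    leaf_r <- leaf_r * dec
  }
  r_m <- maintenance_resp(leaf_r, p)
  r_g <- growth_resp(forcing$gpp, r_m, p)
  r_p <- r_m + r_g
  npp <- forcing$gpp - r_p

  steps <- data.frame(day = forcing$day %||% day_index, doy = forcing$doy,
                      hour = hour, t_air = forcing$t_air, night = night,
                      h_night = h_night, leaf_r = leaf_r, r_m = r_m,
                      r_g = r_g, r_p = r_p, gpp = forcing$gpp, npp = npp)
  structure(list(steps = steps, config = cfg,
                 mean_rp = mean(r_p), mean_npp = mean(npp),
                 annual_npp_gC = mean(npp) * FLUX_TO_GC_YR),
            class = "site_output")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nightly leaf-respiration integrals of a site run
#'
#' Trapezoidal integral of leaf respiration over each night of a run, on the
#' model timestep. The integral is closed at sunrise: the final partial step
#' is completed with the sunrise-step leaf respiration, carrying the decline
#' factor at the full night length for formulations with the nocturnal
#' decline (the stepped series itself resets at sunrise).
#'
#' @param output a `site_output` from [run_site()].
#' @return Data frame with one row per night block: `night`, `night_length`
#'   (h) and `integral` (flux-hours).
#' @export
nightly_leaf_integral <- function(output) {
  stopifnot(inherits(output, "site_output"))
  s <- output$steps
  step_h <- output$config$timestep / 60
  form <- output$config$form
  r <- rle(s$night)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- which(r$values)
  out <- lapply(seq_along(blocks), function(k) {
    i0 <- starts[blocks[k]]; i1 <- ends[blocks[k]]
    x <- s$h_night[i0:i1]
    y <- s$leaf_r[i0:i1]
    if (i1 < nrow(s)) {
      xe <- x[length(x)] + step_h
      ye <- s$leaf_r[i1 + 1L]
      if (form$decline$enabled)
        ye <- ye * decline_fraction(xe, form$decline)
      x <- c(x, xe); y <- c(y, ye)
    }
    data.frame(night = k, night_length = max(x) - x[1],
               integral = trapz(x, y))
  })
  do.call(rbind, out)
}

#' @export
print.site_output <- function(x, ...) {
  cat(sprintf(
    "Site run ('%s', lat %g, %d steps)\n  mean R_p %.4g, mean NPP %.4g umol CO2 m-2 s-1 (annual NPP %.0f g C m-2 yr-1)\n",
    x$config$form$name, x$config$latitude, nrow(x$steps),
    x$mean_rp, x$mean_npp, x$annual_npp_gC))
  invisible(x)
}

#' Compare two site runs
#'
#' Differences between a baseline run (typically without the nocturnal
#' decline) and a variant (with it) over identical forcing: absolute and
#' percentage changes in mean whole-plant respiration and NPP. Because
#' `NPP = GPP - R_p` with shared GPP, the reduction in R_p is identical to
#' the increase in NPP in absolute terms, step for step. Sites whose
#' baseline annual NPP is at or below the reporting threshold are flagged
#' and their percentage effects masked (`NA`).
#'
#' @param base,variant `site_output` objects from the same forcing and
#'   timestep.
#' @param threshold annual NPP reporting threshold (g C m-2 yr-1; default
#'   from the baseline configuration).
#'
#' @return An object of class `run_comparison`: list with `delta_rp`,
#'   `delta_npp` (mean flux differences, variant minus base), `pct_rp`,
#'   `pct_npp` (percent of the baseline means; `NA` when masked),
#'   `excluded`, `annual_npp_base_gC`, and the stepwise difference series.
#' @export
compare_runs <- function(base, variant,
                         threshold = base$config$npp_threshold) {
  stopifnot(inherits(base, "site_output"), inherits(variant, "site_output"))
  if (nrow(base$steps) != nrow(variant$steps) ||
      base$config$timestep != variant$config$timestep ||
      any(abs(base$steps$t_air - variant$steps$t_air) > 1e-12) ||
      any(abs(base$steps$gpp - variant$steps$gpp) > 1e-12))
    stop("runs are not on identical forcing and timestep")
  d_rp_steps <- variant$steps$r_p - base$steps$r_p
  d_npp_steps <- variant$steps$npp - base$steps$npp
  delta_rp <- mean(d_rp_steps)
  delta_npp <- mean(d_npp_steps)
  excluded <- base$annual_npp_gC <= threshold
  structure(list(delta_rp = delta_rp, delta_npp = delta_npp,
                 pct_rp = if (excluded) NA_real_ else
                   100 * delta_rp / base$mean_rp,
                 pct_npp = if (excluded) NA_real_ else
                   100 * delta_npp / base$mean_npp,
                 excluded = excluded,
                 annual_npp_base_gC = base$annual_npp_gC,
                 steps = data.frame(hour = base$steps$hour,
                                    delta_rp = d_rp_steps,
                                    delta_npp = d_npp_steps)),
            class = "run_comparison")
}

#' @export
print.run_comparison <- function(x, ...) {
  cat("Paired site-run comparison (variant - base)\n")
  cat(sprintf("  mean delta R_p  %.4g (%s%%)\n", x$delta_rp,
              if (is.na(x$pct_rp)) "masked" else sprintf("%.2f", x$pct_rp)))
  cat(sprintf("  mean delta NPP  %.4g (%s%%)\n", x$delta_npp,
              if (is.na(x$pct_npp)) "masked" else sprintf("%.2f", x$pct_npp)))
  if (x$excluded)
    cat(sprintf("  [baseline annual NPP %.1f g C m-2 yr-1 below threshold: percentages masked]\n",
                x$annual_npp_base_gC))
  invisible(x)
}
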