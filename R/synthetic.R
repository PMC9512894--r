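#' Species profile for synthetic traces
#'
#' Ground-truth parameters of one simulated species: its nocturnal decline
#' coefficients, typical initial respiration, replicate-to-replicate spread
#' and inherent Q10.
#'
#' @param name species label.
#' @param a,b true decline coefficients (defaults: the universal model).
#' @param r_initial_mean mean initial respiration (umol CO2 m-2 s-1, > 0).
#' @param replicate_cv coefficient of variation of the initial rate between
#'   replicates (>= 0).
#' @param q10_inh true inherent Q10.
#' @param growth_form `"tree"` or `"herbaceous"`.
#' @param biome `"temperate"` or `"tropical"`.
#'
#' @return An object of class `species_profile`.
#' @export
species_profile <- function(name = "species", a = 0.08, b = 0.54,
                            r_initial_mean = 2.5, replicate_cv = 0.15,
                            q10_inh = 2,
                            growth_form = c("tree", "herbaceous"),
                            biome = c("temperate", "tropical")) {
  if (r_initial_mean <= 0) stop("'r_initial_mean' must be positive")
  if (replicate_cv < 0) stop("'replicate_cv' must be non-negative")
  structure(list(name = name, a = a, b = b,
                 r_initial_mean = r_initial_mean,
                 replicate_cv = replicate_cv, q10_inh = q10_inh,
                 growth_form = match.arg(growth_form),
                 biome = match.arg(biome)),
            class = "species_profile")
}

#' Nocturnal cooling schedule
#'
#' Temperature path through the night: constant, linear cooling at a fixed
#' rate (degC per hour, as in the 0.5 degC/h worked examples), or exponential
#' relaxation toward a floor temperature with a given time constant.
#'
#' @param kind `"constant"`, `"linear"` or `"relaxation"`.
#' @param t_start temperature at sunset (degC).
#' @param rate cooling rate (degC/h) for the linear schedule.
#' @param tau relaxation time constant (h) for the relaxation schedule.
#' @param t_min floor temperature (degC).
#'
#' @return An object of class `cooling_schedule`.
#' @export
cooling_schedule <- function(kind = c("constant", "linear", "relaxation"),
                             t_start = 20, rate = 0.5, tau = 4, t_min = -Inf) {
  kind <- match.arg(kind)
  if (kind == "constant") rate <- 0
  if (kind == "linear" && rate < 0) stop("'rate' must be non-negative")
  if (kind == "relaxation") {
    if (tau <= 0) stop("'tau' must be positive")
    if (!is.finite(t_min)) stop("relaxation schedule needs a finite 't_min'")
  }
  structure(list(kind = kind, t_start = t_start, rate = rate,
                 tau = tau, t_min = t_min),
            class = "cooling_schedule")
}

#' Evaluate a cooling schedule
#'
#' @param schedule a [cooling_schedule()].
#' @param h hours since sunset (vectorized).
#' @return Temperature (degC) at each `h`.
#' @export
schedule_temperature <- function(schedule, h) {
  stopifnot(inherits(schedule, "cooling_schedule"))
  switch(schedule$kind,
         constant = rep_len(schedule$t_start, length(h)),
         linear = pmax(schedule$t_start - schedule$rate * h, schedule$t_min),
         relaxation = schedule$t_min +
           (schedule$t_start - schedule$t_min) * exp(-h / schedule$tau))
}

# Run `code` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream), restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Assemble the canonical trace data frame.
make_trace <- function(h, temp, resp, profile, replicate, condition,
                       scale = "leaf",
                       t0 = as.POSIXct("2022-01-01 18:00:00", tz = "UTC")) {
  structure(data.frame(timestamp = t0 + h * 3600,
                       species = profile$name,
                       replicate = replicate,
                       condition = condition,
                       growth_form = profile$growth_form,
                       biome = profile$biome,
                       scale = scale,
                       h = h,
                       temperature_C = temp,
                       respiration = resp,
                       stringsAsFactors = FALSE),
            class = c("resp_trace", "data.frame"))
}

#' @export
print.resp_trace <- function(x, ...) {
  cat(sprintf(
    "Respiration trace: %s / %s (%s, %s, %s, %s scale), %d samples, h %.2g..%.2g\n",
    x$species[1], x$replicate[1], x$condition[1], x$growth_form[1],
    x$biome[1], x$scale[1], nrow(x), min(x$h), max(x$h)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Generate a constant-temperature laboratory trace
#'
#' Simulates one replicate's dark-respiration time series at constant
#' measurement temperature: the initial rate times the nocturnal decline,
#' with multiplicative Gaussian measurement noise, and optionally a
#' light-enhanced dark respiration (LEDR) transient superposed on the first
#' 30 minutes (an additive exponential burst with a 10-min decay, standing in
#' for the post-illumination transient that the 30-min exclusion window is
#' designed to remove).
#'
#' Samples are placed every `sampling` minutes from `h = 0` over the
#' half-open interval `[0, duration)`.
#'
#' @param profile a [species_profile()].
#' @param t_o constant measurement temperature (degC).
#' @param duration night length covered (h, <= 16).
#' @param sampling sampling interval (min).
#' @param noise_sd standard deviation of the multiplicative Gaussian noise.
#' @param ledr superpose the LEDR transient?
#' @param replicate replicate label.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#'
#' @return A `resp_trace` data frame.
#' @export
gen_lab_trace <- function(profile, t_o = 25, duration = 10, sampling = 30,
                          noise_sd = 0.03, ledr = FALSE, replicate = "rep1",
                          seed = NULL) {
  stopifnot(inherits(profile, "species_profile"))
  if (duration > 16) stop("'duration' must be <= 16 h")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  with_seed(seed, {
    h <- seq(0, duration - sampling / 60, by = sampling / 60)
    r_init <- profile$r_initial_mean *
      (1 + stats::rnorm(1L, 0, profile$replicate_cv))
    dec <- decline_fraction(h, decline_params(profile$a, profile$b))
    resp <- r_init * dec * (1 + stats::rnorm(length(h), 0, noise_sd))
    if (ledr) {
      t_min <- h * 60
      burst <- 0.5 * r_init * exp(-t_min / 10)
      resp <- resp + ifelse(t_min < 30, burst, 0)
    }
    make_trace(h, rep_len(t_o, length(h)), resp, profile, replicate, "lab")
  })
}

#' Generate a field trace under nocturnal cooling
#'
#' Simulates one replicate's night-time respiration under ambient temperature
#' following a [cooling_schedule()]: the initial (sunset) rate times the
#' inherent-Q10 temperature response to the temperature departure from sunset
#' times the nocturnal decline, with multiplicative Gaussian noise. With a
#' constant schedule and the same seed the result matches [gen_lab_trace()].
#'
#' @inheritParams gen_lab_trace
#' @param schedule a [cooling_schedule()].
#' @param q10 temperature sensitivity used by the generator: a number, a
#'   [q10_spec()], or `NULL` to use the profile's inherent Q10.
#' @param decline apply the profile's nocturnal decline?
#'
#' @return A `resp_trace` data frame.
#' @export
gen_field_trace <- function(profile, schedule = cooling_schedule("linear"),
                            duration = 10, sampling = 30, noise_sd = 0.03,
                            q10 = NULL, decline = TRUE, replicate = "rep1",
                            seed = NULL) {
  stopifnot(inherits(profile, "species_profile"),
            inherits(schedule, "cooling_schedule"))
  if (duration > 16) stop("'duration' must be <= 16 h")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (is.null(q10)) q10 <- profile$q10_inh
  with_seed(seed, {
    h <- seq(0, duration - sampling / 60, by = sampling / 60)
    r_init <- profile$r_initial_mean *
      (1 + stats::rnorm(1L, 0, profile$replicate_cv))
    temp <- schedule_temperature(schedule, h)
    dp <- decline_params(profile$a, profile$b, enabled = decline)
    resp <- r_init *
      q10_value(q10, temp)^(0.1 * (temp - schedule$t_start)) *
      decline_fraction(h, dp) *
      (1 + stats::rnorm(length(h), 0, noise_sd))
    make_trace(h, temp, resp, profile, replicate, "field")
  })
}

#' Generate whole-tree chamber traces
#'
#' Simulates a family of nightly whole-tree CO2-efflux traces with hourly
#' sampling, night-to-night (lognormal) variation in the initial signal and
#' strong multiplicative noise, emulating the high noise-to-signal ratio of
#' whole-tree chamber measurements. The output is suitable for exercising the
#' top-decile initial-signal filter ([filter_top_initial()]).
#'
#' @inheritParams gen_field_trace
#' @param noise_to_signal multiplicative noise standard deviation.
#' @param n_nights number of nights (>= 1).
#' @param night_sdlog lognormal sd of night-to-night variation in the initial
#'   signal.
#'
#' @return A list of `resp_trace` data frames (one per night), `scale =
#'   "tree"`.
#' @export
gen_tree_trace <- function(profile, schedule = cooling_schedule("linear"),
                           noise_to_signal = 0.3, n_nights = 62,
                           duration = 10, night_sdlog = 0.4, seed = NULL) {
  stopifnot(inherits(profile, "species_profile"))
  if (n_nights < 1) stop("'n_nights' must be >= 1")
  with_seed(seed, {
    h <- seq(0, duration - 1, by = 1)
    temp <- schedule_temperature(schedule, h)
    dp <- decline_params(profile$a, profile$b)
    shape <- q10_value(profile$q10_inh, temp)^
      (0.1 * (temp - schedule$t_start)) * decline_fraction(h, dp)
    lapply(seq_len(n_nights), function(i) {
      r_init <- stats::rlnorm(1L, log(profile$r_initial_mean), night_sdlog)
      resp <- r_init * shape *
        (1 + stats::rnorm(length(h), 0, noise_to_signal))
      make_trace(h, temp, pmax(resp, 1e-6), profile,
                 sprintf("night%02d", i), "field", scale = "tree")
    })
  })
}

#' Generate a multi-species dataset of constant-temperature traces
#'
#' Draws a heterogeneous collection of species and replicates measured at
#' constant temperature, the raw material of the decline-fitting pipeline.
#' Defaults describe the study conditions: 31 species, 4-20 replicates per
#' species, samples every 6 minutes over hours 0-10 of darkness,
#' multiplicative Gaussian noise of sd 0.03, and every species on the
#' universal decline coefficients (set `a_sd`/`b_sd` > 0 for between-species
#' heterogeneity). Species are tagged lab/field (15/16), tree/herbaceous
#' (13/18) and temperate/tropical (11/20) for the group-comparison
#' statistics.
#'
#' @param n_species number of species (>= 2).
#' @param replicates integer range `c(min, max)` of replicates per species.
#' @param duration,sampling,noise_sd as in [gen_lab_trace()].
#' @param a,b central decline coefficients.
#' @param a_sd,b_sd between-species standard deviations of the coefficients
#'   (truncated so that a >= 0, b > 0).
#' @param seed integer seed.
#'
#' @return A list of `resp_trace` data frames (all replicates of all
#'   species).
#' @export
gen_dataset <- function(n_species = 31, replicates = c(4, 20), duration = 10,
                        sampling = 6, noise_sd = 0.03, a = 0.08, b = 0.54,
                        a_sd = 0, b_sd = 0, seed = NULL) {
  if (n_species < 2) stop("'n_species' must be >= 2")
  with_seed(seed, {
    n_cond <- round(n_species * 15 / 31)
    n_tree <- round(n_species * 13 / 31)
    n_temp <- round(n_species * 11 / 31)
    conditions <- rep(c("lab", "field"), c(n_cond, n_species - n_cond))
    forms <- rep(c("tree", "herbaceous"), c(n_tree, n_species - n_tree))
    biomes <- rep(c("temperate", "tropical"), c(n_temp, n_species - n_temp))
    # stripe the secondary groupings so they do not coincide with condition
    forms <- forms[order(seq_len(n_species) %% 2, seq_len(n_species))]
    biomes <- biomes[order(seq_len(n_species) %% 3, seq_len(n_species))]
    traces <- list()
    for (i in seq_len(n_species)) {
      pr <- species_profile(
        name = sprintf("species%02d", i),
        a = max(0, stats::rnorm(1L, a, a_sd)),
        b = max(1e-3, stats::rnorm(1L, b, b_sd)),
        r_initial_mean = stats::runif(1L, 0.5, 4),
        replicate_cv = 0.15, q10_inh = 2,
        growth_form = forms[i], biome = biomes[i])
      n_rep <- sample(seq(replicates[1], replicates[2]), 1L)
      for (r in seq_len(n_rep)) {
        traces[[length(traces) + 1L]] <-
          gen_lab_trace(pr, t_o = 25, duration = duration,
                        sampling = sampling, noise_sd = noise_sd,
                        replicate = sprintf("rep%02d", r))
        traces[[length(traces)]]$condition <- conditions[i]
      }
    }
    traces
  })
}

#' Generate diurnal meteorological forcing
#'
#' Builds a site forcing series on a regular sub-daily timestep: sinusoidal
#' diurnal air temperature peaking in the early afternoon (14:00), and a
#' gross-primary-production proxy that follows a half-sine between sunrise
#' and sunset and is exactly zero at night. Day length comes from
#' [sun_times()].
#'
#' @param latitude site latitude (degrees, positive north).
#' @param n_days number of days.
#' @param doy_start first day of year.
#' @param timestep timestep (min; must divide 24 h).
#' @param t_mean,t_amplitude mean and half-amplitude of the diurnal
#'   temperature cycle (degC).
#' @param gpp_peak midday GPP maximum (umol CO2 m-2 s-1).
#' @param t_noise_sd day-to-day Gaussian noise on the daily mean temperature.
#' @param seed integer seed (only used when `t_noise_sd > 0`).
#'
#' @return A `resp_forcing` data frame with columns `day`, `doy`, `hour`,
#'   `time_h`, `t_air`, `gpp`, `latitude`.
#' @export
gen_forcing <- function(latitude = 0, n_days = 1, doy_start = 80,
                        timestep = 15, t_mean = 20, t_amplitude = 0,
                        gpp_peak = 15, t_noise_sd = 0, seed = NULL) {
  if (1440 %% timestep != 0) stop("'timestep' must divide 24 h")
  with_seed(seed, {
    hour <- seq(0, 24 - timestep / 60, by = timestep / 60)
    days <- lapply(seq_len(n_days), function(d) {
      doy <- (doy_start + d - 2) %% 365 + 1
      st <- sun_times(latitude, doy)
      tm <- t_mean + if (t_noise_sd > 0) stats::rnorm(1L, 0, t_noise_sd) else 0
      t_air <- tm + t_amplitude * cos(2 * pi * (hour - 14) / 24)
      gpp <- numeric(length(hour))
      if (st$night_length < 24) {
        day_len <- st$sunset - st$sunrise
        idx <- hour >= st$sunrise & hour <= st$sunset
        gpp[idx] <- gpp_peak *
          pmax(sin(pi * (hour[idx] - st$sunrise) / day_len), 0)
      }
      data.frame(day = d, doy = doy, hour = hour,
                 time_h = (d - 1) * 24 + hour, t_air = t_air, gpp = gpp,
                 latitude = latitude)
    })
    structure(do.call(rbind, days),
              class = c("resp_forcing", "data.frame"))
  })
}
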