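#' Respiration model formulation
#'
#' One of the four nocturnal respiration formulations compared in the model
#' evaluation: the standard temperature-only model with fixed Q10 = 2
#' (`"standard"`), the same with the temperature-dependent Q10
#' (`"standard-modified"`), and their merges with the universal nocturnal
#' decline (`"new"`, `"new-modified"`).
#'
#' @param name formulation name.
#' @param decline decline parameters used by the `new*` variants.
#'
#' @return An object of class `resp_formulation`: list with `name`, `q10`
#'   (a [q10_spec()]) and `decline` (a [decline_params()]; disabled for the
#'   standard variants).
#' @export
#' @examples
#' formulation("new")
formulation <- function(name = c("standard", "standard-modified",
                                 "new", "new-modified"),
                        decline = decline_params()) {
  name <- match.arg(name)
  modified <- grepl("modified", name)
  uses_decline <- grepl("^new", name)
  q10 <- if (modified) q10_spec("temperature_dependent") else q10_spec(q10 = 2)
  dp <- decline
  dp$enabled <- uses_decline
  structure(list(name = name, q10 = q10, decline = dp),
            class = "resp_formulation")
}

#' @export
print.resp_formulation <- function(x, ...) {
  cat(sprintf("Formulation '%s': %s Q10, nocturnal decline %s\n", x$name,
              if (x$q10$mode == "fixed") sprintf("fixed (%g)", x$q10$q10)
              else "temperature-dependent",
              if (x$decline$enabled) "on" else "off"))
  invisible(x)
}

#' All four formulations
#' @return Named list of the four [formulation()] objects.
#' @export
all_formulations <- function() {
  nms <- c("standard", "standard-modified", "new", "new-modified")
  stats::setNames(lapply(nms, formulation), nms)
}

#' Predict a normalized nocturnal trace under a formulation
#'
#' Drives a formulation with the observed temperatures and elapsed hours of
#' a trace. The first sample is the sunset anchor: elapsed time and the
#' temperature departure are measured from it and the prediction there is
#' exactly 1. Apply [normalize_trace()] first if early samples are to be
#' excluded.
#'
#' @param trace a `resp_trace` data frame with temperature at every sample.
#' @param form a [formulation()].
#'
#' @return Numeric vector of predicted normalized respiration.
#' @export
simulate_trace <- function(trace, form) {
  stopifnot(is.data.frame(trace), inherits(form, "resp_formulation"))
  if (!"temperature_C" %in% names(trace) || anyNA(trace$temperature_C))
    stop("trace must carry a temperature at every sample")
  temp <- trace$temperature_C
  h <- trace$h - trace$h[1]
  q10_value(form$q10, temp)^(0.1 * (temp - temp[1])) *
    decline_fraction(h, form$decline)
}

#' One-to-one regression statistics
#'
#' Ordinary least squares regression of predicted on observed normalized
#' respiration, as drawn on a one-to-one plot: slope, intercept, R-squared,
#' the two-sided p value of the slope, and the root-mean-square error of the
#' predictions. The first point of the night is excluded by default since it
#' equals unity by construction.
#'
#' @param pred,obs predicted and observed normalized series.
#' @param exclude_first drop the first (anchor) pair?
#'
#' @return List with `slope`, `intercept`, `r_squared`, `p`, `rmse`, `n`.
#' @export
one_to_one_stats <- function(pred, obs, exclude_first = TRUE) {
  stopifnot(length(pred) == length(obs))
  if (exclude_first) { pred <- pred[-1]; obs <- obs[-1] }
  if (length(pred) < 3L) stop("need at least 3 paired points")
  if (stats::sd(obs) == 0) stop("observed series has zero variance")
  fit <- stats::lm(pred ~ obs)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       rmse = sqrt(mean((pred - obs)^2)),
       n = length(pred))
}

#' Standardized residuals of a model-observation comparison
#'
#' Residuals of the anchored normalized series, scaled by the root mean
#' square residual per degree of freedom:
#' \deqn{S_i = (pred_i/pred_1 - obs_i/obs_1) /
#'   \sqrt{\sum_j (pred_j/pred_1 - obs_j/obs_1)^2 / df}.}
#' The degrees of freedom default to N - 1 (one constraint: the anchored
#' first residual is zero by construction); no parameters are fitted in the
#' comparison.
#'
#' @param pred,obs predicted and observed series (length >= 2); divided by
#'   their own first elements before differencing, which is a no-op on
#'   already-anchored series.
#' @param df degrees of freedom in the denominator.
#'
#' @return Numeric vector of standardized residuals (all zero for a perfect
#'   prediction).
#' @export
standardized_residuals <- function(pred, obs, df = length(pred) - 1L) {
  stopifnot(length(pred) == length(obs), length(pred) >= 2L, df > 0)
  r <- pred / pred[1] - obs / obs[1]
  ss <- sum(r^2)
  if (ss == 0) return(rep(0, length(r)))
  r / sqrt(ss / df)
}

#' Taylor-diagram statistics
#'
#' The three summary statistics a Taylor diagram displays for a
#' prediction-observation pair: Pearson correlation, the ratio of the
#' (population) standard deviations, and the centered pattern RMS
#' difference. They satisfy the Taylor identity
#' \eqn{cRMS^2 = \sigma_p^2 + \sigma_o^2 - 2\sigma_p\sigma_o r}.
#'
#' @param pred,obs predicted and observed series (length >= 3, non-zero
#'   variance).
#'
#' @return List with `correlation`, `sd_ratio`, `sd_pred`, `sd_obs`, `crms`.
#' @export
taylor_stats <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  if (length(pred) < 3L) stop("need at least 3 points")
  n <- length(pred)
  sd_p <- sqrt(mean((pred - mean(pred))^2))
  sd_o <- sqrt(mean((obs - mean(obs))^2))
  if (sd_p == 0 || sd_o == 0) stop("zero variance in a series")
  r <- stats::cor(pred, obs)
  crms <- sqrt(mean(((pred - mean(pred)) - (obs - mean(obs)))^2))
  list(correlation = r, sd_ratio = sd_p / sd_o, sd_pred = sd_p,
       sd_obs = sd_o, crms = crms)
}

#' Evaluate the four formulations against one observed trace
#'
#' Runs every formulation over the observed temperatures and times of a
#' trace and collects the one-to-one regression, RMSE, standardized
#' residuals and Taylor statistics of each against the observed normalized
#' respiration.
#'
#' @param trace a `resp_trace` (normalize first to apply an exclusion
#'   window).
#' @param forms list of formulations (default: all four).
#' @param exclude_first exclude the anchor pair from the regressions?
#'
#' @return An object of class `resp_eval`: list with `table` (one row of
#'   statistics per formulation), `residuals` (standardized residual series
#'   per formulation), `taylor`, `obs`, `pred`.
#' @export
evaluate_formulations <- function(trace, forms = all_formulations(),
                                  exclude_first = TRUE) {
  obs <- trace$respiration / trace$respiration[1]
  preds <- lapply(forms, function(f) simulate_trace(trace, f))
  stats_tab <- do.call(rbind, lapply(names(preds), function(nm) {
    s <- one_to_one_stats(preds[[nm]], obs, exclude_first)
    data.frame(formulation = nm, slope = s$slope, intercept = s$intercept,
               r_squared = s$r_squared, p = s$p, rmse = s$rmse, n = s$n)
  }))
  structure(list(table = stats_tab,
                 residuals = lapply(preds, standardized_residuals, obs = obs),
                 taylor = lapply(preds, taylor_stats, obs = obs),
                 obs = obs, pred = preds, h = trace$h),
            class = "resp_eval")
}

#' @export
print.resp_eval <- function(x, digits = 3, ...) {
  cat("Formulation evaluation against observed normalized respiration\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot a formulation evaluation
#'
#' One-to-one scatter of predicted against observed normalized respiration
#' for each formulation.
#'
#' @param x a `resp_eval` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.resp_eval <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(x$pred)) {
    rng <- range(c(x$obs, x$pred[[nm]]))
    graphics::plot(x$obs, x$pred[[nm]], xlim = rng, ylim = rng,
                   xlab = "observed", ylab = "predicted", main = nm,
                   pch = 16, ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
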