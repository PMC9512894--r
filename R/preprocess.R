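#' Normalize a trace to its initial basal rate
#'
#' Implements the normalization convention of the decline analysis: samples
#' earlier than the exclusion window (default 30 min, guarding against
#' light-enhanced dark respiration) are dropped; the first remaining sample
#' defines the initial basal rate; all retained samples are expressed as
#' ratios to it, so the first retained ratio is exactly 1.
#'
#' @param trace a `resp_trace` data frame (columns `h`, `respiration`).
#' @param exclusion_min exclusion window after darkness onset (minutes).
#'
#' @return The retained rows of `trace` with an added `ratio` column.
#' @export
normalize_trace <- function(trace, exclusion_min = 30) {
  stopifnot(is.data.frame(trace), all(c("h", "respiration") %in% names(trace)))
  keep <- trace$h >= exclusion_min / 60
  if (!any(keep))
    stop("no sample at or after the exclusion window; empty trace")
  out <- trace[keep, , drop = FALSE]
  out$ratio <- out$respiration / out$respiration[1]
  rownames(out) <- NULL
  out
}

#' Hourly means of a normalized trace
#'
#' Averages a single replicate's normalized respiration into hourly bins
#' (`bin k` covers hours `[k, k + 1)`); empty bins are omitted. The bin
#' records both the nominal bin centre and the hours actually sampled, which
#' the fitting step can use to evaluate the model as a within-bin average.
#'
#' @param trace a normalized trace from [normalize_trace()] (needs a `ratio`
#'   column).
#'
#' @return A data frame with columns `bin`, `h` (bin centre), `ratio` (bin
#'   mean), `n` (samples in bin) and list column `h_samples`.
#' @export
bin_hourly <- function(trace) {
  stopifnot(is.data.frame(trace))
  if (!"ratio" %in% names(trace))
    stop("'trace' has no ratio column; run normalize_trace() first")
  if (nrow(trace) == 0L) stop("empty trace")
  bin <- floor(trace$h)
  bins <- sort(unique(bin))
  out <- data.frame(bin = bins, h = bins + 0.5,
                    ratio = as.numeric(tapply(trace$ratio, bin, mean)[as.character(bins)]),
                    n = as.integer(table(bin)[as.character(bins)]))
  out$h_samples <- I(split(trace$h, bin)[as.character(bins)])
  rownames(out) <- NULL
  out
}

#' Species-level aggregation of replicate hourly bins
#'
#' Combines the hourly means of all replicates of one species into a
#' species-level hourly average with its standard error (SEM = sd/sqrt(n);
#' the single-replicate convention is SEM = 0).
#'
#' @param bins a list of per-replicate bin tables from [bin_hourly()].
#' @param species species label carried into the output.
#'
#' @return A `species_aggregate` data frame with columns `species`, `bin`,
#'   `h` (bin centre), `mean_ratio`, `sem`, `n_rep` and list column
#'   `h_samples` (one sampled-hour vector per contributing replicate).
#' @export
aggregate_species <- function(bins, species = "species") {
  if (is.data.frame(bins)) bins <- list(bins)
  if (length(bins) < 1L) stop("need at least one replicate")
  all_bins <- sort(unique(unlist(lapply(bins, `[[`, "bin"))))
  rows <- lapply(all_bins, function(k) {
    vals <- unlist(lapply(bins, function(b) b$ratio[b$bin == k]))
    hs <- lapply(bins, function(b) {
      w <- which(b$bin == k)
      if (length(w)) b$h_samples[[w]] else NULL
    })
    hs <- hs[!vapply(hs, is.null, logical(1))]
    n <- length(vals)
    data.frame(species = species, bin = k, h = k + 0.5,
               mean_ratio = mean(vals),
               sem = if (n > 1) stats::sd(vals) / sqrt(n) else 0,
               n_rep = n, h_samples = I(list(hs)))
  })
  structure(do.call(rbind, rows),
            class = c("species_aggregate", "data.frame"))
}

#' Full aggregation pipeline over a trace collection
#'
#' Convenience wrapper running normalize -> hourly bin -> species aggregate
#' over a list of traces and stacking the species aggregates, ready for
#' [fit_power_law()].
#'
#' @param traces list of `resp_trace` data frames.
#' @param exclusion_min exclusion window passed to [normalize_trace()].
#'
#' @return A stacked `species_aggregate` data frame over all species.
#' @export
aggregate_dataset <- function(traces, exclusion_min = 0) {
  stopifnot(is.list(traces), length(traces) > 0L)
  sp <- vapply(traces, function(t) t$species[1], character(1))
  aggs <- lapply(split(traces, sp), function(trs) {
    bins <- lapply(trs, function(t)
      bin_hourly(normalize_trace(t, exclusion_min)))
    aggregate_species(bins, species = trs[[1]]$species[1])
  })
  out <- do.call(rbind, aggs)
  rownames(out) <- NULL
  structure(out, class = c("species_aggregate", "data.frame"))
}

#' Retain nights with the strongest initial signal
#'
#' Whole-tree chamber night traces are noisy; only nights whose initial
#' efflux is in the top fraction (default decile) of initial signals are
#' retained, `ceiling(frac * n)` nights in total.
#'
#' @param traces list of `resp_trace` data frames (one per night).
#' @param frac fraction retained (default 0.10).
#'
#' @return The retained subset of `traces`, strongest first.
#' @export
filter_top_initial <- function(traces, frac = 0.10) {
  stopifnot(is.list(traces), length(traces) > 0L, frac > 0, frac <= 1)
  init <- vapply(traces, function(t) t$respiration[1], numeric(1))
  keep <- order(init, decreasing = TRUE)[seq_len(ceiling(frac * length(traces)))]
  traces[keep]
}

#' Log-linearized decline slope
#'
#' Linearizes a species' hourly decline by regressing
#' `log(1 - mean_ratio + eps)` on `log(h)` by ordinary least squares and
#' returns the slope with its standard error. For an exact power-law decline
#' `1 - a h^b` the slope is the exponent `b`. Bins with non-positive
#' transformed response (ratios at or above 1) are dropped with a warning;
#' `h = 0` never occurs because bin centres are positive.
#'
#' @param agg a `species_aggregate` for one species.
#' @param eps offset guarding the logarithm (default 1e-6).
#'
#' @return An object of class `slope_estimate`: list with `slope`, `se`, `n`.
#' @export
linearize_and_slope <- function(agg, eps = 1e-6) {
  stopifnot(is.data.frame(agg))
  y <- 1 - agg$mean_ratio + eps
  ok <- y > 0 & agg$h > 0
  if (any(!ok)) {
    warning(sum(!ok), " bin(s) with non-positive transformed response dropped")
  }
  if (sum(ok) < 3L) stop("need >= 3 usable bins for the slope")
  fit <- stats::lm(log(y[ok]) ~ log(agg$h[ok]))
  est <- suppressWarnings(summary(fit))$coefficients
  structure(list(slope = unname(est[2, 1]), se = unname(est[2, 2]),
                 n = sum(ok)),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("Log-linearized decline slope: %.4f (SE %.4f, n = %d)\n",
              x$slope, x$se, x$n))
  invisible(x)
}

#' Welch two-sample t-test on group slopes
#'
#' Compares the mean log-linearized decline slope between two groups of
#' species (e.g. lab vs field) with Welch's unequal-variance t-test
#' (Welch-Satterthwaite degrees of freedom, two-sided p).
#'
#' @param slopes_a,slopes_b numeric vectors of per-species slopes (each of
#'   length >= 2).
#'
#' @return List with `t`, `df`, `p`.
#' @export
welch_test <- function(slopes_a, slopes_b) {
  if (length(slopes_a) < 2L || length(slopes_b) < 2L)
    stop("each group needs at least two slopes")
  tt <- stats::t.test(slopes_a, slopes_b)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Bonferroni-corrected pairwise slope comparisons
#'
#' Tests every within-group pair of decline slopes with a two-sample t
#' statistic built from the slopes, their standard errors and point counts
#' (`t = (s_i - s_j)/sqrt(se_i^2 + se_j^2)`, `df = n_i + n_j - 4`), applying
#' a Bonferroni-corrected significance threshold `alpha / m` over the `m`
#' comparisons performed. With `groups = NULL` all pairs are compared.
#'
#' @param slopes,ses,ns numeric vectors: slope, standard error and number of
#'   fitted points per series.
#' @param alpha family significance level.
#' @param groups optional vector of group labels; only pairs within the same
#'   group are tested.
#'
#' @return List with `m` (comparisons), `n_significant`, `alpha_adjusted`,
#'   `pairs` (per-pair table) and `p_matrix`.
#' @export
pairwise_slope_tests <- function(slopes, ses, ns, alpha = 0.05,
                                 groups = NULL) {
  k <- length(slopes)
  if (k < 2L) stop("need at least two series")
  stopifnot(length(ses) == k, length(ns) == k)
  if (is.null(groups)) groups <- rep(1L, k)
  idx <- utils::combn(k, 2)
  same <- groups[idx[1, ]] == groups[idx[2, ]]
  idx <- idx[, same, drop = FALSE]
  m <- ncol(idx)
  if (m == 0L) stop("no within-group pairs to test")
  i <- idx[1, ]; j <- idx[2, ]
  tstat <- (slopes[i] - slopes[j]) / sqrt(ses[i]^2 + ses[j]^2)
  df <- ns[i] + ns[j] - 4
  p <- 2 * stats::pt(-abs(tstat), df)
  sig <- p < alpha / m
  pm <- matrix(NA_real_, k, k)
  pm[cbind(i, j)] <- p; pm[cbind(j, i)] <- p
  list(m = m, n_significant = sum(sig), alpha_adjusted = alpha / m,
       pairs = data.frame(i = i, j = j, t = tstat, df = df, p = p,
                          significant = sig),
       p_matrix = pm)
}
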