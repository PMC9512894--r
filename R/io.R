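trace_columns <- c("timestamp", "species", "replicate", "condition",
                   "growth_form", "biome", "scale", "hours_since_dark",
                   "temperature_C", "respiration_umol_m2_s")

#' Write respiration traces to the canonical CSV schema
#'
#' One schema serves leaf and whole-tree data (the `scale` column
#' distinguishes them): comma-separated, header row, decimal points, UTF-8,
#' ISO-8601 timestamps. Writing then reading then writing again is
#' byte-identical.
#'
#' @param traces a `resp_trace` data frame or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (is.data.frame(traces)) traces <- list(traces)
  tab <- do.call(rbind, lapply(traces, function(t) {
    data.frame(timestamp = format(t$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"),
               species = t$species, replicate = t$replicate,
               condition = t$condition, growth_form = t$growth_form,
               biome = t$biome, scale = t$scale,
               hours_since_dark = t$h,
               temperature_C = t$temperature_C,
               respiration_umol_m2_s = t$respiration)
  }))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read respiration traces from the canonical CSV schema
#'
#' Validates the schema on the way in: all columns present, respiration
#' strictly positive, timestamps parseable and strictly increasing within
#' each species/replicate trace; violations raise an error naming the
#' offending row.
#'
#' @param path CSV path written by [write_traces()] (or any file in the
#'   canonical schema).
#' @return A list of `resp_trace` data frames, one per species/replicate.
#' @export
read_traces <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(trace_columns, names(tab))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  ts <- as.POSIXct(tab$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (anyNA(ts))
    stop("unparseable timestamp at row ", which(is.na(ts))[1])
  bad <- which(!is.finite(tab$respiration_umol_m2_s) |
                 tab$respiration_umol_m2_s <= 0)
  if (length(bad))
    stop("non-positive respiration at row ", bad[1])
  key <- paste(tab$species, tab$replicate)
  out <- lapply(split(seq_len(nrow(tab)), factor(key, unique(key))),
                function(rows) {
    if (any(diff(as.numeric(ts[rows])) <= 0))
      stop("timestamps not strictly increasing at row ",
           rows[which(diff(as.numeric(ts[rows])) <= 0)[1] + 1L])
    structure(data.frame(timestamp = ts[rows],
                         species = tab$species[rows],
                         replicate = tab$replicate[rows],
                         condition = tab$condition[rows],
                         growth_form = tab$growth_form[rows],
                         biome = tab$biome[rows],
                         scale = tab$scale[rows],
                         h = tab$hours_since_dark[rows],
                         temperature_C = tab$temperature_C[rows],
                         respiration = tab$respiration_umol_m2_s[rows],
                         stringsAsFactors = FALSE, row.names = NULL),
              class = c("resp_trace", "data.frame"))
  })
  unname(out)
}

#' Write/read meteorological forcing CSV
#'
#' @param forcing a `resp_forcing` data frame.
#' @param path CSV path.
#' @return `path` (write) or a `resp_forcing` data frame (read).
#' @export
write_forcing <- function(forcing, path) {
  utils::write.csv(as.data.frame(forcing), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_forcing
#' @export
read_forcing <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("doy", "hour", "t_air", "gpp")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  structure(tab, class = c("resp_forcing", "data.frame"))
}

#' Write a JSON fit report
#'
#' Coefficients, covariance, fit quality and provenance of a
#' [fit_power_law()] result, as a small machine-readable JSON document.
#'
#' @param fit a `power_law_fit`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "power_law_fit"))
  ci <- confint(fit)
  jsonlite::write_json(
    list(model = "ratio = 1 - a * h^b",
         coefficients = as.list(fit$coefficients),
         vcov = unclass(fit$vcov),
         conf_int = list(a = unname(ci["a", ]), b = unname(ci["b", ])),
         r_squared = fit$r_squared, n_bins = fit$n,
         weighted = fit$weighted, abscissa = fit$abscissa),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration
#'
#' Reads a YAML configuration holding any of the parameter blocks `q10`,
#' `decline`, `jules`, `site`, `generator` and `seed`, builds the
#' corresponding parameter objects, and rejects unknown keys (a typo in a
#' configuration should fail loudly, not silently fall back to defaults).
#'
#' @param path YAML path.
#' @return List with any of `q10` ([q10_spec()]), `decline`
#'   ([decline_params()]), `jules` ([jules_params()]), `site` (list of
#'   [site_config()] arguments), `generator` (list), `seed` (integer).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("q10", "decline", "jules", "site", "generator", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  out <- list()
  if (!is.null(cfg$q10)) out$q10 <- do.call(q10_spec, cfg$q10)
  if (!is.null(cfg$decline)) out$decline <- do.call(decline_params, cfg$decline)
  if (!is.null(cfg$jules)) out$jules <- do.call(jules_params, cfg$jules)
  if (!is.null(cfg$site)) out$site <- cfg$site
  if (!is.null(cfg$generator)) out$generator <- cfg$generator
  if (!is.null(cfg$seed)) out$seed <- as.integer(cfg$seed)
  out
}
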