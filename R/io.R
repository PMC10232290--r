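# File formats: ERF traces as CSV, structured results as JSON, run
# configuration as YAML. All formats are plain text and diff-able.

stop_microdcm <- function(code, msg) {
  stop(structure(class = c(paste0("microdcm_", code), "microdcm_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Write / read an ERF trace (CSV)
#'
#' Traces are stored as two-column CSV files with the mandatory header
#' `time_ms,amplitude`. Values round-trip at full double precision.
#'
#' @param trace an [erf_trace()].
#' @param path file path.
#' @param condition condition label to attach on read.
#' @return `write_erf` returns `path` invisibly; `read_erf` returns an
#'   [erf_trace()].
#' @export
write_erf <- function(trace, path) {
  stopifnot(inherits(trace, "erf_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_ms,amplitude", con)
  writeLines(paste(format_full(trace$time_ms), format_full(trace$amplitude),
                   sep = ","), con)
  invisible(path)
}

format_full <- function(x) {
  formatC(x, digits = 17, format = "g", drop0trailing = TRUE)
}

#' @rdname write_erf
#' @export
read_erf <- function(path, condition = "standard") {
  if (!file.exists(path)) stop_microdcm("missing_file",
                                        paste("no such file:", path))
  header <- readLines(path, n = 1)
  if (!identical(trimws(header), "time_ms,amplitude"))
    stop_microdcm("missing_header",
                  "expected header line 'time_ms,amplitude'")
  d <- read.csv(path, header = TRUE)
  if (anyNA(d$amplitude) || !all(is.finite(d$amplitude))) {
    bad <- which(!is.finite(d$amplitude))[1]
    stop_microdcm("nonfinite_amplitude",
                  sprintf("non-finite amplitude at data row %d of %s",
                          bad, path))
  }
  if (length(d$time_ms) > 1) {
    dt <- diff(d$time_ms)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9)
      stop_microdcm("nonuniform_grid",
                    paste("non-uniform or unsorted time grid in", path))
  }
  erf_trace(d$time_ms, d$amplitude, condition)
}

#' Write trial-level epochs (CSV)
#'
#' One column `time_ms` followed by one column per trial (`trial_1`, ...).
#'
#' @param trials an `erf_trials` object (see [erf_trials()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_erf_trials <- function(trials, path) {
  stopifnot(inherits(trials, "erf_trials"))
  m <- cbind(time_ms = trials$time_ms, trials$trials)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(m), collapse = ","), con)
  writeLines(apply(m, 1, function(r) paste(format_full(r), collapse = ",")),
             con)
  invisible(path)
}

#' @rdname write_erf_trials
#' @export
read_erf_trials <- function(path, condition = "standard") {
  d <- read.csv(path, header = TRUE)
  if (!identical(colnames(d)[1], "time_ms"))
    stop_microdcm("missing_header", "expected first column 'time_ms'")
  erf_trials(d$time_ms, as.matrix(d[, -1, drop = FALSE]), condition)
}

#' Trial-level epoch container
#'
#' @param time_ms shared time grid (ms).
#' @param trials matrix, time points x trials.
#' @param condition condition label.
#' @return Object of class `erf_trials`.
#' @export
erf_trials <- function(time_ms, trials, condition = "standard") {
  trials <- as.matrix(trials)
  if (nrow(trials) != length(time_ms))
    stop("trial matrix rows must match the time grid")
  if (is.null(colnames(trials)) && ncol(trials) > 0)
    colnames(trials) <- paste0("trial_", seq_len(ncol(trials)))
  structure(list(time_ms = as.numeric(time_ms), trials = trials,
                 condition = condition), class = "erf_trials")
}

# ---- structured results --------------------------------------------------

write_json_result <- function(x, path) {
  writeLines(jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}

#' Serialize / restore an inversion result
#'
#' The posterior mean, free energy, decomposition and iteration trace go to
#' JSON; the posterior covariance goes to a companion CSV matrix. The round
#' trip is exact to double precision.
#'
#' @param result an inversion result from [invert()].
#' @param path JSON file path (the covariance is stored alongside with
#'   suffix `_cov.csv`).
#' @return `write_inversion` returns `path` invisibly; `read_inversion`
#'   returns the restored result.
#' @export
write_inversion <- function(result, path) {
  cov_path <- sub("\\.json$", "", path)
  cov_path <- paste0(cov_path, "_cov.csv")
  doc <- list(
    parameter_names = result$posterior$names,
    posterior_mean = as.list(result$posterior$mean),
    prior_mean = as.list(result$prior$mean),
    prior_variance = as.list(diag(result$prior$cov)),
    free_energy = result$F,
    decomposition = as.list(result$decomposition),
    noise = result$noise_posterior,
    iterations = result$iterations,
    converged = result$converged,
    F_trace = result$F_trace,
    covariance_file = basename(cov_path)
  )
  write_json_result(doc, path)
  m <- result$posterior$cov
  con <- file(cov_path, "w")
  writeLines(paste(colnames(m), collapse = ","), con)
  writeLines(apply(m, 1, function(r) paste(format_full(r), collapse = ",")),
             con)
  close(con)
  invisible(path)
}

#' @rdname write_inversion
#' @export
read_inversion <- function(path) {
  doc <- jsonlite::fromJSON(path)
  cov_path <- file.path(dirname(path), doc$covariance_file)
  cov <- as.matrix(read.csv(cov_path, header = TRUE, check.names = FALSE))
  nm <- doc$parameter_names
  posterior <- gaussian_belief(setNames(unlist(doc$posterior_mean), nm), cov)
  prior <- gaussian_belief(setNames(unlist(doc$prior_mean), nm),
                           diag(unlist(doc$prior_variance), length(nm)))
  structure(list(
    posterior = posterior, prior = prior, F = doc$free_energy,
    decomposition = unlist(doc$decomposition),
    noise_posterior = doc$noise,
    iterations = doc$iterations, converged = doc$converged,
    F_trace = doc$F_trace
  ), class = "mc_inversion")
}
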