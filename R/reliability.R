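# Split-half reliability: odd/even trial averages, Shrout-Fleiss ICC(2,1)
# from the two-way ANOVA decomposition, and a report over free energy, its
# accuracy/complexity components and individual parameter estimates.

#' Split trials into odd and even halves
#'
#' Trials are partitioned by their 1-based position parity within the
#' condition and each half is averaged.
#'
#' @param trials an [erf_trials()] object (>= 2 trials).
#' @return List with `odd` and `even` [erf_trace()]s.
#' @export
split_halves <- function(trials) {
  stopifnot(inherits(trials, "erf_trials"))
  k <- ncol(trials$trials)
  if (k < 2) stop("need at least 2 trials (one per half)")
  idx <- seq_len(k)
  odd <- trials$trials[, idx %% 2 == 1, drop = FALSE]
  even <- trials$trials[, idx %% 2 == 0, drop = FALSE]
  list(odd = erf_trace(trials$time_ms, rowMeans(odd), trials$condition),
       even = erf_trace(trials$time_ms, rowMeans(even), trials$condition))
}

#' Intraclass correlation ICC(2,1)
#'
#' Shrout-Fleiss two-way random-effects single-measurement ICC from the
#' ANOVA decomposition:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E)}}
#' with the F test on \eqn{MS_R / MS_E} for the subject effect.
#'
#' @param m ratings matrix, n subjects x k raters (here k = 2: odd, even);
#'   no missing cells, n >= 3.
#' @return List with `icc` and `p` (upper-tail F-test p-value).
#' @export
icc2 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3 || k < 2) stop("need n >= 3 subjects and k >= 2 raters")
  if (anyNA(m) || !all(is.finite(m))) stop("ratings must be finite")
  gm <- mean(m)
  if (sum((m - gm)^2) == 0) stop("zero total variance: ICC undefined")
  rm_ <- rowMeans(m)
  cm <- colMeans(m)
  MSR <- k * sum((rm_ - gm)^2) / (n - 1)
  MSC <- n * sum((cm - gm)^2) / (k - 1)
  resid <- m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  Fstat <- MSR / MSE
  p <- if (MSE == 0) 0 else pf(Fstat, n - 1, (n - 1) * (k - 1),
                               lower.tail = FALSE)
  list(icc = icc, p = p)
}

significance_label <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) return("p < 0.0001")
  if (p < 0.005) return("p < 0.005")
  if (p < 0.05) return("p < 0.05")
  "n.s."
}

#' Split-half reliability report
#'
#' Computes ICC(2,1) across subjects between odd- and even-trial
#' inversions for: the free energy, its six accuracy/complexity
#' components, and each selected parameter's posterior mean; plus the
#' squared Pearson correlation of the free energy across halves. Measures
#' with no between-subject variance (e.g. identically zero components)
#' are reported as `NA`.
#'
#' @param odd_results,even_results named lists of `mc_inversion` results,
#'   one per subject; names (subject ids) must match in order.
#' @param parameters parameter names to include (default: all posterior
#'   parameters of the first result).
#' @return Object of class `mc_reliability`: data frame `measures`
#'   (measure, icc, p, significance) and scalar `fe_r2`.
#' @export
reliability_report <- function(odd_results, even_results,
                               parameters = NULL) {
  if (is.null(names(odd_results)) || is.null(names(even_results)) ||
      !identical(names(odd_results), names(even_results)))
    stop("subject lists are not aligned (names must match in order)")
  n <- length(odd_results)
  if (n < 3) stop("need at least 3 subjects")
  if (is.null(parameters))
    parameters <- odd_results[[1]]$posterior$names
  pull <- function(results, fn) vapply(results, fn, numeric(1))
  measures <- c(list(F = function(r) r$F),
                setNames(lapply(names(odd_results[[1]]$decomposition),
                                function(cmp) function(r)
                                  r$decomposition[[cmp]]),
                         names(odd_results[[1]]$decomposition)),
                setNames(lapply(parameters, function(pn) function(r)
                  r$posterior$mean[[pn]]), parameters))
  rows <- lapply(names(measures), function(nm) {
    m <- cbind(odd = pull(odd_results, measures[[nm]]),
               even = pull(even_results, measures[[nm]]))
    res <- tryCatch(icc2(m), error = function(e)
      list(icc = NA_real_, p = NA_real_))
    data.frame(measure = nm, icc = res$icc, p = res$p,
               significance = significance_label(res$p),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  fe <- cbind(pull(odd_results, function(r) r$F),
              pull(even_results, function(r) r$F))
  fe_r2 <- stats::cor(fe[, 1], fe[, 2])^2
  structure(list(measures = tab, fe_r2 = fe_r2), class = "mc_reliability")
}

#' @export
print.mc_reliability <- function(x, ...) {
  cat(sprintf("Split-half reliability over %d measures; F r^2 = %.3f\n",
              nrow(x$measures), x$fe_r2))
  invisible(x)
}
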