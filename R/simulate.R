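# Epoch integration and the observation model mapping neuronal states to a
# source-level evoked response field (ERF). Each condition is integrated
# from (and observed relative to) its own resting fixed point, so traces
# are baseline-corrected by construction and the difference wave is purely
# evoked.

#' Default epoch time grid
#'
#' The modelled epoch runs from -100 to 400 ms around stimulus onset at a
#' 500 Hz sampling rate (2 ms step), i.e. 251 samples.
#'
#' @param t_start,t_end epoch limits (ms).
#' @param fs sampling rate (Hz).
#' @return Numeric vector of sample times (ms).
#' @export
erf_times <- function(t_start = -100, t_end = 400, fs = 500) {
  seq(t_start, t_end, by = 1000 / fs)
}

#' ERF trace container
#'
#' @param time_ms numeric, strictly increasing uniform time grid (ms).
#' @param amplitude numeric amplitudes (arbitrary source units).
#' @param condition `"standard"` or `"deviant"`.
#' @return Object of class `erf_trace` (a data frame with attributes).
#' @export
erf_trace <- function(time_ms, amplitude, condition = "standard") {
  if (length(time_ms) != length(amplitude))
    stop("time and amplitude lengths differ")
  if (length(time_ms) > 1) {
    dt <- diff(time_ms)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9)
      stop_microdcm("nonuniform_grid",
                    "time grid must be strictly increasing and uniform")
  }
  if (!all(is.finite(amplitude))) {
    bad <- which(!is.finite(amplitude))[1]
    stop_microdcm("nonfinite_amplitude",
                  sprintf("non-finite amplitude at row %d", bad))
  }
  structure(data.frame(time_ms = as.numeric(time_ms),
                       amplitude = as.numeric(amplitude)),
            condition = condition, class = c("erf_trace", "data.frame"))
}

#' Exogenous stimulus drive
#'
#' Non-negative Gaussian-bump input current, truncated to zero before
#' stimulus onset at t = 0.
#'
#' @param times sample times (ms).
#' @param input list with `onset` (ms), `width` (Gaussian SD, ms),
#'   `amplitude`.
#' @return Numeric input series aligned with `times`.
#' @export
stimulus_input <- function(times, input = mc_parameters()$input) {
  if (input$width <= 0) stop("input width must be positive")
  u <- input$amplitude * exp(-0.5 * ((times - input$onset) / input$width)^2)
  u[times < 0] <- 0
  u
}

#' Integrate the microcircuit over an epoch
#'
#' Starts at the condition's resting steady state and integrates the
#' conductance-based dynamics with fixed-step RK4 (1 ms internal step by
#' default), sampling the trajectory onto the output grid.
#'
#' @param params an [mc_parameters()] object.
#' @param condition `"standard"` or `"deviant"`.
#' @param times output time grid (ms).
#' @param dt internal integration step (ms); must divide the grid step.
#' @return Matrix (length(times) x 24) of states; attributes `times` and
#'   `steady` carry the grid and initial state.
#' @export
integrate_microcircuit <- function(params, condition = "standard",
                                   times = erf_times(), dt = 1) {
  deviant <- check_condition(condition)
  step <- if (length(times) > 1) diff(times)[1] else dt
  if (abs(step / dt - round(step / dt)) > 1e-9)
    stop("internal step must divide the output grid step")
  ss <- steady_state(params, condition)
  spec <- mc_cpp_spec(params, times = times, dt = dt)
  traj <- mc_integrate_cpp(spec, as.numeric(params$lambda), deviant,
                           as.numeric(ss))
  colnames(traj) <- state_names()
  attr(traj, "times") <- times
  attr(traj, "steady") <- ss
  traj
}

#' Observe a trajectory as an ERF
#'
#' The source-level signal is a weighted sum of the population membrane
#' potentials, measured as deviation from the resting state (so traces are
#' baseline-corrected by construction), scaled and offset:
#' \eqn{y(t) = gain \sum_p w_p (V_p(t) - V_p^{rest}) + baseline}.
#'
#' @param trajectory state matrix from [integrate_microcircuit()].
#' @param obs observation model: list with `w` (named weights), `gain`,
#'   `baseline`.
#' @param condition condition label attached to the trace.
#' @return An [erf_trace()].
#' @export
observe <- function(trajectory, obs = mc_parameters()$obs,
                    condition = "standard") {
  times <- attr(trajectory, "times")
  steady <- attr(trajectory, "steady")
  if (is.null(times) || is.null(steady))
    stop("trajectory must carry 'times' and 'steady' attributes")
  pops <- mc_populations()$label
  w <- obs$w[pops]
  if (length(w) != 6 || any(is.na(w)))
    stop("observation weights must cover all six populations")
  V <- trajectory[, paste0("V_", pops), drop = FALSE]
  dev <- sweep(V, 2, steady[paste0("V_", pops)])
  amp <- obs$gain * as.numeric(dev %*% w) + obs$baseline
  erf_trace(times, amp, condition)
}

#' Simulate a standard/deviant ERF pair
#'
#' The two conditions differ only through the condition log-gains `b` on
#' flagged edges; each is integrated from its own resting state so both
#' traces start exactly at baseline (with all `b = 0` the traces are
#' identical).
#'
#' @param params an [mc_parameters()] object.
#' @param times output time grid (ms).
#' @param dt internal integration step (ms).
#' @return List with elements `standard` and `deviant` ([erf_trace()]s).
#' @export
simulate_erf_pair <- function(params, times = erf_times(), dt = 1) {
  spec <- mc_cpp_spec(params, times = times, dt = dt)
  y <- mc_predict_cpp(spec, as.numeric(params$lambda))
  n <- length(times)
  list(standard = erf_trace(times, y[seq_len(n)], "standard"),
       deviant = erf_trace(times, y[n + seq_len(n)], "deviant"))
}

#' Peak mismatch deflection
#'
#' The single maximal absolute deflection of the deviant-minus-standard
#' difference wave inside the mismatch window (default 130--180 ms,
#' endpoints inclusive).
#'
#' @param standard,deviant [erf_trace()]s on a shared grid.
#' @param window numeric(2), window limits in ms.
#' @return Scalar, the maximum of `abs(deviant - standard)` in the window.
#' @export
ymax <- function(standard, deviant, window = c(130, 180)) {
  if (!isTRUE(all.equal(standard$time_ms, deviant$time_ms)))
    stop("traces must share a time grid")
  t <- standard$time_ms
  if (window[1] < min(t) || window[2] > max(t))
    stop("mismatch window outside the trace grid")
  sel <- t >= window[1] & t <= window[2]
  if (!any(sel)) stop("no samples inside the mismatch window")
  max(abs(deviant$amplitude[sel] - standard$amplitude[sel]))
}
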