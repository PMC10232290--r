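#' @useDynLib microdcm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize pf pnorm rnorm runif setNames var
#' @importFrom utils read.csv write.csv modifyList
NULL

# ---- populations and connectivity template -------------------------------

#' Cortical populations of the canonical microcircuit
#'
#' Six neuronal populations of a single cortical column: granular spiny
#' stellate cells (`ss`), superficial pyramidal cells (`sp`), superficial
#' inhibitory interneurons (`si`), deep regular-firing pyramidal cells
#' (`dp`), deep burst-firing pyramidal cells (`tp`) and deep inhibitory
#' interneurons (`di`). The order is fixed and defines the layout of the
#' state vector.
#'
#' @return A data frame with columns `label` and `layer`.
#' @export
mc_populations <- function() {
  data.frame(
    label = c("ss", "sp", "si", "dp", "tp", "di"),
    layer = c("granular", "superficial", "superficial",
              "deep", "deep", "deep"),
    stringsAsFactors = FALSE
  )
}

#' Receptor kinds
#'
#' Receptor channels carried by the model, in the fixed order used for the
#' conductance states: AMPA, NMDA, GABA. A passive leak channel exists per
#' population but carries no estimated parameter.
#'
#' @return Character vector `c("AMPA", "NMDA", "GABA")`.
#' @export
mc_receptors <- function() c("AMPA", "NMDA", "GABA")

#' Default intrinsic connectivity template
#'
#' Directed edges (source population, target population, receptor) of the
#' within-column circuit. Excitatory projections carry both an AMPA and an
#' NMDA edge; inhibitory interneurons project GABAergic edges (including
#' self-inhibition). The `flagged` column marks edges whose gain may change
#' between the standard and deviant conditions (by default every
#' glutamatergic edge).
#'
#' @param flag_excitatory logical; flag all AMPA/NMDA edges as
#'   condition-modulated (default `TRUE`).
#' @return A data frame with columns `src`, `tgt`, `receptor`, `flagged`.
#' @export
mc_template <- function(flag_excitatory = TRUE) {
  exc <- rbind(
    c("ss", "sp"), c("ss", "si"), c("sp", "ss"), c("sp", "dp"),
    c("sp", "di"), c("dp", "tp"), c("tp", "di"), c("tp", "ss")
  )
  inh <- rbind(
    c("si", "sp"), c("si", "ss"), c("si", "si"),
    c("di", "dp"), c("di", "tp"), c("di", "di")
  )
  edges <- rbind(
    data.frame(src = exc[, 1], tgt = exc[, 2], receptor = "AMPA",
               stringsAsFactors = FALSE),
    data.frame(src = exc[, 1], tgt = exc[, 2], receptor = "NMDA",
               stringsAsFactors = FALSE),
    data.frame(src = inh[, 1], tgt = inh[, 2], receptor = "GABA",
               stringsAsFactors = FALSE)
  )
  edges$flagged <- flag_excitatory & edges$receptor %in% c("AMPA", "NMDA")
  validate_template(edges)
  edges
}

validate_template <- function(edges) {
  pops <- mc_populations()$label
  stopifnot(all(edges$src %in% pops), all(edges$tgt %in% pops),
            all(edges$receptor %in% mc_receptors()))
  inhibitory <- c("si", "di")
  gaba <- edges$receptor == "GABA"
  if (any(gaba & !(edges$src %in% inhibitory)))
    stop("GABA edges must originate from inhibitory populations (si, di)")
  if (any(!gaba & edges$src %in% inhibitory))
    stop("AMPA/NMDA edges must originate from excitatory populations")
  if (anyDuplicated(edges[c("src", "tgt", "receptor")]))
    stop("duplicate edges in template")
  invisible(edges)
}

# ---- parameter container --------------------------------------------------

#' Microcircuit parameter set
#'
#' Bundles the biophysical constants, connectivity template, free-parameter
#' layout and priors of one cortical source. Free parameters are log-scale
#' factors \eqn{\lambda} acting multiplicatively on their base value,
#' \eqn{\theta = \theta_0 e^\lambda}, except the condition log-gains `b`
#' which are natively on the log scale (a deviant-condition edge gain is
#' \eqn{\gamma e^{b}}).
#'
#' Free parameters (default layout):
#' \itemize{
#'   \item `g_<REC>_<src>_<tgt>`: log-scale factor on each edge gain;
#'   \item `b_<REC>_<src>_<tgt>`: condition log-gain for each flagged edge;
#'   \item `g_input`: log-scale factor on the stimulus amplitude.
#' }
#'
#' @param template connectivity template, see [mc_template()].
#' @param constants named list overriding biophysical constants: reversal
#'   potentials `VL`, `VE`, `VI` (mV), capacitance `C`, leak `cL`, receptor
#'   time constants `tau` (ms; AMPA, NMDA, GABA), firing sigmoid `slope`
#'   (1/mV) and `thresh` (mV), magnesium-gate coefficients `mg_a` (1/mV)
#'   and `mg_b`.
#' @param gamma named numeric of base edge gains, names
#'   `<REC>_<src>_<tgt>`; unnamed scalar recycles over all edges. Defaults
#'   are receptor-specific (AMPA 0.35, NMDA 2, GABA 1.2).
#' @param input list with `onset` (ms), `width` (ms, Gaussian SD),
#'   `amplitude` (input current units), `pops` (receiving populations).
#' @param obs list with per-population weights `w`, scalar `gain`,
#'   `baseline`.
#' @param prior_var named list of prior variances for the three free
#'   parameter families: `gain`, `b`, `input`.
#' @param lambda optional named vector of free-parameter values (defaults
#'   to all zero, i.e. parameters at their prior expectation).
#' @return An object of class `mc_parameters`.
#' @export
mc_parameters <- function(template = mc_template(),
                          constants = list(),
                          gamma = NULL,
                          input = list(),
                          obs = list(),
                          prior_var = list(),
                          lambda = NULL) {
  validate_template(template)
  const <- modifyList(list(
    VL = -70, VE = 60, VI = -90,
    C = rep(8, 6), cL = rep(1, 6),
    tau = c(AMPA = 4, NMDA = 100, GABA = 16),
    slope = 1 / 8, thresh = -40,
    mg_a = 0.062, mg_b = 0.2
  ), constants)
  if (!(const$VI < const$VL && const$VL < const$VE))
    stop("reversal potentials must satisfy VI < VL < VE")
  if (any(const$tau <= 0) || any(const$C <= 0))
    stop("time constants and capacitances must be positive")
  edge_id <- paste(template$receptor, template$src, template$tgt, sep = "_")
  base <- c(AMPA = 0.35, NMDA = 2, GABA = 1.2)[template$receptor]
  g <- unname(base)
  if (!is.null(gamma)) {
    if (is.null(names(gamma))) {
      g <- rep_len(gamma, nrow(template))
    } else {
      miss <- setdiff(names(gamma), edge_id)
      if (length(miss)) stop("unknown edge gains: ",
                             paste(miss, collapse = ", "))
      g[match(names(gamma), edge_id)] <- gamma
    }
  }
  if (any(g < 0)) stop("edge gains must be non-negative")
  inp <- modifyList(list(onset = 100, width = 32, amplitude = 2,
                         pops = "ss"), input)
  if (inp$width <= 0) stop("input width must be positive")
  ob <- modifyList(list(
    w = c(ss = 0.2, sp = 1, si = 0, dp = 0.4, tp = 0.4, di = 0),
    gain = 1, baseline = 0
  ), obs)
  pops <- mc_populations()$label
  if (is.null(names(ob$w)) && length(ob$w) == 6)
    names(ob$w) <- pops
  if (!all(pops %in% names(ob$w)))
    stop("observation weights must be named by population")
  ob$w <- ob$w[pops]
  if (all(ob$w == 0)) stop("observation model needs a nonzero weight")
  pv <- modifyList(list(gain = 1 / 16, b = 1 / 16, input = 1 / 16),
                   prior_var)

  free_names <- c(paste0("g_", edge_id),
                  paste0("b_", edge_id[template$flagged]),
                  "g_input")
  prior_mean <- setNames(rep(0, length(free_names)), free_names)
  prior_variance <- setNames(c(rep(pv$gain, nrow(template)),
                               rep(pv$b, sum(template$flagged)),
                               pv$input), free_names)
  lam <- setNames(rep(0, length(free_names)), free_names)
  if (!is.null(lambda)) {
    miss <- setdiff(names(lambda), free_names)
    if (length(miss)) stop("unknown free parameters: ",
                           paste(miss, collapse = ", "))
    lam[names(lambda)] <- lambda
  }
  structure(list(
    template = template, edge_id = edge_id, constants = const,
    gamma = setNames(g, edge_id), input = inp, obs = ob,
    free_names = free_names, prior_mean = prior_mean,
    prior_variance = prior_variance, lambda = lam
  ), class = "mc_parameters")
}

#' @export
print.mc_parameters <- function(x, ...) {
  cat("Six-population conductance-based microcircuit\n")
  cat(sprintf("  %d edges (%d condition-modulated), %d free parameters\n",
              nrow(x$template), sum(x$template$flagged),
              length(x$free_names)))
  invisible(x)
}

#' Set free-parameter values
#'
#' @param params an [mc_parameters()] object.
#' @param lambda named numeric vector of log-scale values to set.
#' @return Updated `mc_parameters` object.
#' @export
with_lambda <- function(params, lambda) {
  stopifnot(inherits(params, "mc_parameters"))
  if (is.null(names(lambda)) &&
      length(lambda) == length(params$free_names)) {
    names(lambda) <- params$free_names
  }
  miss <- setdiff(names(lambda), params$free_names)
  if (length(miss)) stop("unknown free parameters: ",
                         paste(miss, collapse = ", "))
  params$lambda[names(lambda)] <- lambda
  params
}

#' Prior belief over the free parameters
#'
#' @param params an [mc_parameters()] object.
#' @return A [gaussian_belief()] with the prior mean and (diagonal)
#'   covariance over all free parameters.
#' @export
mc_priors <- function(params) {
  gaussian_belief(params$prior_mean, diag(params$prior_variance,
                                          length(params$prior_mean)))
}

# spec list consumed by the C++ core
mc_cpp_spec <- function(params, times = erf_times(), dt = 1) {
  pops <- mc_populations()$label
  tmpl <- params$template
  edges <- cbind(match(tmpl$src, pops), match(tmpl$tgt, pops),
                 match(tmpl$receptor, mc_receptors()))
  storage.mode(edges) <- "integer"
  nm <- params$free_names
  gain_idx <- match(paste0("g_", params$edge_id), nm)
  b_idx <- match(paste0("b_", params$edge_id), nm)
  list(
    VL = params$constants$VL, VE = params$constants$VE,
    VI = params$constants$VI,
    C = as.numeric(params$constants$C), cL = as.numeric(params$constants$cL),
    tau = as.numeric(params$constants$tau),
    slope = params$constants$slope, thresh = params$constants$thresh,
    mg_a = params$constants$mg_a, mg_b = params$constants$mg_b,
    edges = edges, gamma = as.numeric(params$gamma),
    flagged = as.integer(tmpl$flagged),
    gain_idx = as.integer(ifelse(is.na(gain_idx), 0L, gain_idx)),
    b_idx = as.integer(ifelse(is.na(b_idx), 0L, b_idx)),
    input = list(onset = params$input$onset, width = params$input$width,
                 amplitude = params$input$amplitude,
                 amp_idx = as.integer(match("g_input", nm, nomatch = 0L)),
                 pops = match(params$input$pops, pops)),
    obs = list(w = as.numeric(params$obs$w[pops]), gain = params$obs$gain,
               baseline = params$obs$baseline),
    times = times, dt = dt
  )
}

state_names <- function() {
  pops <- mc_populations()$label
  c(paste0("V_", pops),
    as.vector(t(outer(pops, mc_receptors(),
                      function(p, r) paste0("g_", p, "_", r)))))
}

check_condition <- function(condition) {
  if (!condition %in% c("standard", "deviant"))
    stop("unknown condition label: ", condition)
  identical(condition, "deviant")
}

# ---- elementary operations -----------------------------------------------

#' Presynaptic firing-rate function
#'
#' Logistic sigmoid mapping a population's mean membrane potential to its
#' non-negative output firing rate on a 0--1 scale.
#'
#' @param V membrane potential (mV), vectorized.
#' @param params an [mc_parameters()] object.
#' @return Values in (0, 1), strictly increasing in `V`.
#' @export
firing_rate <- function(V, params = mc_parameters()) {
  1 / (1 + exp(-(V - params$constants$thresh) * params$constants$slope))
}

#' Voltage-dependent NMDA (magnesium-block) gate
#'
#' Fraction of the NMDA conductance available at membrane potential `V`,
#' \eqn{1 / (1 + \beta e^{-\alpha V})}: depolarization relieves the
#' magnesium block.
#'
#' @inheritParams firing_rate
#' @return Values in (0, 1), strictly increasing in `V`.
#' @export
nmda_gate <- function(V, params = mc_parameters()) {
  1 / (1 + params$constants$mg_b * exp(-params$constants$mg_a * V))
}

#' Effective connectivity for one condition
#'
#' Applies the log-scale gain factors and, for the deviant condition, the
#' condition log-gains of flagged edges, returning one 6 x 6 gain matrix
#' per receptor with entry `[target, source]`.
#'
#' @param params an [mc_parameters()] object (its `lambda` supplies the
#'   free-parameter values).
#' @param condition `"standard"` or `"deviant"`.
#' @return Named list of three 6 x 6 matrices (`AMPA`, `NMDA`, `GABA`).
#' @export
build_connectivity <- function(params, condition = "standard") {
  deviant <- check_condition(condition)
  pops <- mc_populations()$label
  lam <- params$lambda
  out <- lapply(mc_receptors(), function(r) {
    m <- matrix(0, 6, 6, dimnames = list(pops, pops))
    sel <- params$template$receptor == r
    for (i in which(sel)) {
      g <- params$gamma[i] * exp(lam[paste0("g_", params$edge_id[i])])
      if (deviant && params$template$flagged[i])
        g <- g * exp(lam[paste0("b_", params$edge_id[i])])
      m[params$template$tgt[i], params$template$src[i]] <- g
    }
    m
  })
  names(out) <- mc_receptors()
  out
}

#' Time derivative of the neuronal state
#'
#' Conductance-based dynamics of the six populations: per population
#' \eqn{C \dot V = c_L (V_L - V) + g_A (V_E - V) + g_G (V_I - V) +
#' g_N m(V) (V_E - V) + u}, and per (population, receptor)
#' \eqn{\dot g = (\varsigma - g)/\tau} where \eqn{\varsigma} is the
#' connectivity-weighted presynaptic firing. Exogenous input `u` enters
#' only the designated input population(s).
#'
#' @param state numeric(24) state vector (6 potentials then 18
#'   conductances, population-major, receptor order AMPA/NMDA/GABA).
#' @param params an [mc_parameters()] object.
#' @param input_value scalar exogenous input current.
#' @param condition `"standard"` or `"deviant"`.
#' @return numeric(24) derivative.
#' @export
state_derivative <- function(state, params, input_value = 0,
                             condition = "standard") {
  if (!all(is.finite(state))) stop("non-finite state")
  deviant <- check_condition(condition)
  d <- mc_deriv_cpp(mc_cpp_spec(params), as.numeric(state),
                    as.numeric(params$lambda), input_value, deviant)
  setNames(as.numeric(d), state_names())
}

#' Resting (fixed-point) state of the circuit
#'
#' Finds the autonomous (zero-input) fixed point by relaxation followed by
#' damped Newton iterations. The fixed point depends (weakly) on the
#' condition through the condition log-gains of flagged edges.
#'
#' @param params an [mc_parameters()] object.
#' @param condition `"standard"` or `"deviant"`.
#' @param tol infinity-norm tolerance on the state derivative.
#' @param max_iter Newton iteration cap.
#' @return Named numeric(24) steady state.
#' @export
steady_state <- function(params, condition = "standard", tol = 1e-9,
                         max_iter = 50) {
  deviant <- check_condition(condition)
  res <- mc_steady_cpp(mc_cpp_spec(params), as.numeric(params$lambda),
                       tol, max_iter, deviant)
  if (!res$converged)
    stop(sprintf("steady-state search did not converge: residual %.3e",
                 res$residual))
  setNames(as.numeric(res$state), state_names())
}

# ---- serialization -------------------------------------------------------

#' Write / read a microcircuit parameter set (JSON)
#'
#' Serializes constants, template edges, free-parameter layout, priors and
#' current values to a JSON document; the round trip is bit-exact.
#'
#' @param params an [mc_parameters()] object.
#' @param path file path.
#' @return `write_mc_parameters` returns `path` invisibly;
#'   `read_mc_parameters` returns an `mc_parameters` object.
#' @export
write_mc_parameters <- function(params, path) {
  doc <- list(
    constants = params$constants,
    template_edges = params$template,
    free_parameter_names = params$free_names,
    prior_means = as.list(params$prior_mean),
    prior_variances = as.list(params$prior_variance),
    gamma = as.list(params$gamma),
    input = params$input,
    obs = list(w = as.list(params$obs$w), gain = params$obs$gain,
               baseline = params$obs$baseline),
    lambda = as.list(params$lambda)
  )
  writeLines(jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_mc_parameters
#' @export
read_mc_parameters <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  const <- lapply(doc$constants, function(v)
    if (is.numeric(v)) as.numeric(unlist(v)) else v)
  names(const$tau) <- mc_receptors()
  p <- mc_parameters(
    template = doc$template_edges,
    constants = const,
    gamma = unlist(doc$gamma),
    input = doc$input,
    obs = list(w = unlist(doc$obs$w), gain = doc$obs$gain,
               baseline = doc$obs$baseline),
    lambda = unlist(doc$lambda)
  )
  p$prior_mean[names(doc$prior_means)] <- unlist(doc$prior_means)
  p$prior_variance[names(doc$prior_variances)] <- unlist(doc$prior_variances)
  p
}
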