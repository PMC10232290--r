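# Variational Laplace inversion: Levenberg-Marquardt-regularized
# Gauss-Newton updates of the parameter means, closed-form covariance
# updates, scalar Newton updates of the observation log-precision, and a
# free energy decomposed into accuracy and complexity terms.

#' Forward model for a microcircuit parameter set
#'
#' Wraps an [mc_parameters()] object as a deterministic forward model
#' mapping the free-parameter vector to the concatenated
#' (standard, deviant) ERF prediction.
#'
#' @param params an [mc_parameters()] object.
#' @param times output grid (ms).
#' @param dt internal integration step (ms).
#' @return Object of class `mc_forward` with `predict(lambda)` and
#'   `jacobian(lambda, step)` functions and `param_names`.
#' @export
mc_model <- function(params, times = erf_times(), dt = 1) {
  spec <- mc_cpp_spec(params, times = times, dt = dt)
  nm <- params$free_names
  structure(list(
    param_names = nm,
    times = times,
    predict = function(lambda) {
      as.numeric(mc_predict_cpp(spec, as.numeric(lambda[nm])))
    },
    jacobian = function(lambda, step = 1e-4) {
      J <- mc_jacobian_cpp(spec, as.numeric(lambda[nm]), step)
      colnames(J) <- nm
      J
    }
  ), class = "mc_forward")
}

#' Generic forward model from a prediction function
#'
#' Used for analytic toy problems (e.g. linear-Gaussian models); the
#' Jacobian defaults to central finite differences.
#'
#' @param predict function taking a named parameter vector, returning the
#'   predicted data vector.
#' @param param_names character vector of parameter names.
#' @param jacobian optional function `(lambda, step)`; default central
#'   finite differences of `predict`.
#' @return Object of class `mc_forward`.
#' @export
forward_model <- function(predict, param_names, jacobian = NULL) {
  if (is.null(jacobian)) {
    jacobian <- function(lambda, step = 1e-4) {
      p <- length(param_names)
      cols <- lapply(seq_len(p), function(j) {
        lp <- lm <- lambda
        lp[j] <- lp[j] + step
        lm[j] <- lm[j] - step
        (predict(lp) - predict(lm)) / (2 * step)
      })
      J <- do.call(cbind, cols)
      colnames(J) <- param_names
      J
    }
  }
  structure(list(param_names = param_names, predict = predict,
                 jacobian = jacobian), class = "mc_forward")
}

#' Finite-difference Jacobian of a forward model
#'
#' @param model an `mc_forward` model.
#' @param lambda named parameter vector (point of evaluation).
#' @param step per-parameter central-difference step (log scale for the
#'   microcircuit model).
#' @return Matrix, rows = predicted samples, columns = parameters.
#' @export
jacobian <- function(model, lambda, step = 1e-4) {
  J <- model$jacobian(lambda, step)
  if (!all(is.finite(J))) stop("non-finite Jacobian")
  J
}

#' Observation noise model
#'
#' A single global log-precision hyperparameter `h` for the observation
#' noise (shared across both conditions), with a Gaussian hyperprior;
#' noise is independent across samples with precision `exp(h)`.
#'
#' @param log_precision_mean hyperprior mean of `h`.
#' @param log_precision_var hyperprior variance of `h`.
#' @return Object of class `mc_noise`.
#' @export
noise_model <- function(log_precision_mean = 2, log_precision_var = 1) {
  if (log_precision_var < 0) stop("hyperprior variance must be >= 0")
  structure(list(mean = log_precision_mean, var = log_precision_var),
            class = "mc_noise")
}

as_data_vector <- function(data) {
  if (is.numeric(data)) return(as.numeric(data))
  if (is.list(data) && inherits(data$standard, "erf_trace") &&
      inherits(data$deviant, "erf_trace"))
    return(c(data$standard$amplitude, data$deviant$amplitude))
  stop("data must be a numeric vector or a standard/deviant trace pair")
}

# Free-energy pieces given squared residuals E, curvature trace term T and
# the posterior over parameters and log-precision. The decomposition
# convention (documented in the methods vignette):
#   accuracy(states)     expected log-likelihood at the posterior means
#   accuracy(parameters) curvature penalty from parameter uncertainty
#   accuracy(precision)  curvature penalty from log-precision uncertainty
#   complexity(states)   0 (the states are deterministic here)
#   complexity(parameters), complexity(precision): KL divergences
fe_pieces <- function(E, Tterm, N, h_mean, h_var, belief, priors, noise) {
  pi_bar <- exp(h_mean)
  pi_tld <- exp(h_mean + h_var / 2)
  acc_states <- -0.5 * pi_bar * E + (N / 2) * h_mean - (N / 2) * log(2 * pi)
  acc_params <- -0.5 * pi_bar * Tterm
  acc_prec <- -0.5 * (pi_tld - pi_bar) * (E + Tterm)
  comp_states <- 0
  comp_params <- kl_gaussian(belief, priors)
  comp_prec <- if (noise$var > 0) {
    0.5 * (h_var / noise$var + (h_mean - noise$mean)^2 / noise$var - 1 +
             log(noise$var) - log(h_var))
  } else 0
  dec <- c(accuracy_states = acc_states, accuracy_parameters = acc_params,
           accuracy_precision = acc_prec, complexity_states = comp_states,
           complexity_parameters = comp_params,
           complexity_precision = comp_prec)
  list(F = acc_states + acc_params + acc_prec -
         comp_states - comp_params - comp_prec,
       decomposition = dec)
}

# Scalar Newton updates of the log-precision posterior given s = E + T
update_noise <- function(s, N, noise, h_mean) {
  if (noise$var == 0) return(list(mean = noise$mean, var = 0))
  h <- h_mean
  v <- noise$var
  for (k in 1:12) {
    curv <- 0.5 * s * exp(h + v / 2) + 1 / noise$var
    v <- 1 / curv
    grad <- -0.5 * s * exp(h + v / 2) + N / 2 - (h - noise$mean) / noise$var
    h <- h + grad / curv
  }
  list(mean = h, var = 1 / (0.5 * s * exp(h + v / 2) + 1 / noise$var))
}

# Symmetric positive-definite inverse with progressive diagonal jitter
# (extreme log-precisions can drive the conditioning past Cholesky's
# tolerance).
spd_inverse <- function(H) {
  Hs <- (H + t(H)) / 2
  for (j in c(0, 1e-12, 1e-10, 1e-8)) {
    out <- tryCatch(chol2inv(chol(Hs + diag(j * max(diag(Hs)), nrow(Hs)))),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("posterior precision is numerically singular")
}

# Evaluate residuals, Jacobian, covariance, noise posterior and free energy
# at a parameter mean.
vl_evaluate <- function(mu, y, model, priors, noise, P0, step, h_init) {
  f <- model$predict(mu)
  if (!all(is.finite(f))) stop("non-finite prediction")
  e <- y - f
  E <- sum(e^2)
  J <- model$jacobian(mu, step)
  M <- crossprod(J)
  h <- list(mean = h_init, var = noise$var)
  Sq <- NULL
  for (k in 1:8) {
    H <- exp(h$mean) * M + P0
    Sq <- spd_inverse(H)
    Tterm <- sum(M * Sq)
    h <- update_noise(E + Tterm, length(y), noise, h$mean)
  }
  Tterm <- sum(M * Sq)
  belief <- gaussian_belief(setNames(mu, model$param_names), Sq)
  fe <- fe_pieces(E, Tterm, length(y), h$mean, h$var, belief, priors, noise)
  list(mu = mu, e = e, E = E, J = J, M = M, Sq = Sq, h = h,
       belief = belief, F = fe$F, decomposition = fe$decomposition)
}

#' Free energy of a belief given data
#'
#' Laplace-approximated evidence bound: accuracy (expected log-likelihood
#' of the residuals, with curvature corrections for parameter and
#' precision uncertainty) minus complexity (KL divergences of the
#' parameter and hyperparameter posteriors from their priors). The six
#' decomposition fields always sum to `F`.
#'
#' @param data standard/deviant [erf_trace()] pair (list) or numeric data
#'   vector.
#' @param belief posterior [gaussian_belief()] to evaluate.
#' @param priors prior [gaussian_belief()] sharing the parameter index.
#' @param noise an [noise_model()]; its posterior defaults to the prior
#'   unless `noise_posterior` is given (list with `mean`, `var`).
#' @param model an `mc_forward` model.
#' @param noise_posterior optional posterior over the log-precision.
#' @return List with `F` and the named six-element `decomposition`.
#' @export
free_energy <- function(data, belief, priors, noise, model,
                        noise_posterior = NULL) {
  check_same_index(belief, priors)
  y <- as_data_vector(data)
  f <- model$predict(belief$mean)
  e <- y - f
  E <- sum(e^2)
  J <- model$jacobian(belief$mean, 1e-4)
  Tterm <- sum(crossprod(J) * belief$cov)
  if (is.null(noise_posterior))
    noise_posterior <- list(mean = noise$mean,
                            var = max(noise$var, 1e-12))
  if (noise$var == 0) noise_posterior$var <- 0
  fe_pieces(E, Tterm, length(y), noise_posterior$mean, noise_posterior$var,
            belief, priors, noise)
}

#' Invert a subject's ERF pair
#'
#' Variational Laplace: alternates Levenberg-Marquardt-regularized
#' Gauss-Newton updates of the posterior means with closed-form covariance
#' updates and scalar Newton updates of the observation log-precision. A
#' candidate step is accepted only if the free energy increases; on
#' rejection the regularization doubles. Stops when an accepted step
#' improves F by less than `tol` nats or after `max_iter` iterations.
#'
#' @param data standard/deviant [erf_trace()] pair (list) or numeric data
#'   vector.
#' @param model an `mc_forward` model ([mc_model()] or [forward_model()]).
#' @param priors prior [gaussian_belief()] over the model's parameters.
#' @param noise an [noise_model()].
#' @param max_iter iteration cap (default 64).
#' @param tol free-energy convergence tolerance (nats, default 0.01).
#' @param step finite-difference step for the Jacobian.
#' @param init_damping initial Levenberg-Marquardt damping (default 1/32).
#' @return Object of class `mc_inversion`: `posterior`, `prior`, `F`,
#'   six-element `decomposition`, `noise_posterior`, `iterations`,
#'   `converged` (`TRUE`, `"local_optimum"`, or `FALSE`), `F_trace`.
#' @export
invert <- function(data, model, priors, noise = noise_model(),
                   max_iter = 64, tol = 0.01, step = 1e-4,
                   init_damping = 1 / 32) {
  y <- as_data_vector(data)
  if (!identical(priors$names, model$param_names))
    stop("priors must cover exactly the model's parameters")
  P0 <- chol2inv(chol(priors$cov))
  cur <- vl_evaluate(priors$mean, y, model, priors, noise, P0, step,
                     noise$mean)
  F_trace <- cur$F
  damping <- init_damping
  rejections <- 0
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    pi_bar <- exp(cur$h$mean)
    H <- pi_bar * cur$M + P0
    g <- pi_bar * crossprod(cur$J, cur$e) - P0 %*% (cur$mu - priors$mean)
    delta <- tryCatch(
      solve(H + damping * diag(diag(H), nrow(H)), g),
      error = function(e) NULL)
    if (!is.null(delta)) {
      cand <- tryCatch(
        vl_evaluate(cur$mu + as.numeric(delta), y, model, priors, noise,
                    P0, step, cur$h$mean),
        error = function(e) NULL)
    } else cand <- NULL
    if (!is.null(cand) && cand$F > cur$F) {
      dF <- cand$F - cur$F
      cur <- cand
      F_trace <- c(F_trace, cur$F)
      damping <- max(damping / 2, 2^-16)
      rejections <- 0
      if (dF < tol) { converged <- TRUE; break }
    } else {
      damping <- damping * 2
      rejections <- rejections + 1
      # give up only once the damped step is numerically negligible
      if (rejections >= 24) { converged <- "local_optimum"; break }
    }
  }
  structure(list(
    posterior = cur$belief, prior = priors, F = cur$F,
    decomposition = cur$decomposition,
    noise_posterior = cur$h, iterations = iter, converged = converged,
    F_trace = F_trace
  ), class = "mc_inversion")
}

#' @export
print.mc_inversion <- function(x, ...) {
  cat(sprintf(
    "Variational Laplace inversion: F = %.2f after %d iterations (%s)\n",
    x$F, x$iterations,
    if (isTRUE(x$converged)) "converged" else as.character(x$converged)))
  invisible(x)
}

#' Correlation between posterior prediction and data
#'
#' Pearson correlation between the model prediction at the posterior mean
#' and the observed data vector; a simple fit-quality summary.
#'
#' @param result an `mc_inversion`.
#' @param data the data used for the inversion.
#' @param model the forward model used.
#' @return Scalar correlation.
#' @export
fit_correlation <- function(result, data, model) {
  y <- as_data_vector(data)
  stats::cor(y, model$predict(result$posterior$mean))
}
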