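# Parametric empirical Bayes second level: a hierarchical linear-Gaussian
# model in which each subject's synaptic log-gain parameters are a group
# mean plus covariate effects plus a between-subject random effect,
# observed through that subject's first-level posterior.

#' Second-level design matrix
#'
#' First column is the group-average constant; subsequent columns are
#' mean-centered covariates.
#'
#' @param covariates numeric vector (one covariate) or a named list /
#'   data frame of covariates, one value per subject.
#' @param names covariate names (defaults to names of the input or `c1`,
#'   `c2`, ...).
#' @param subjects optional subject identifiers used as row names.
#' @return Matrix of class `peb_design`, columns `mean`, then covariates.
#' @export
build_design_matrix <- function(covariates, names = NULL, subjects = NULL) {
  if (is.numeric(covariates)) covariates <- list(covariates)
  covariates <- as.list(covariates)
  n <- length(covariates[[1]])
  if (n < 3) stop("need at least 3 subjects")
  if (is.null(names)) {
    names <- base::names(covariates)
    if (is.null(names)) names <- paste0("c", seq_along(covariates))
  }
  cols <- lapply(seq_along(covariates), function(i) {
    v <- as.numeric(covariates[[i]])
    if (length(v) != n) stop("covariates must share length")
    if (!all(is.finite(v))) stop("covariates must be finite")
    if (var(v) == 0) stop("constant covariate: ", names[i])
    v - mean(v)
  })
  X <- cbind(1, do.call(cbind, cols))
  colnames(X) <- c("mean", names)
  rownames(X) <- subjects
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  class(X) <- c("peb_design", class(X))
  X
}

#' Map synaptic parameters to the six laminar/receptor groups
#'
#' Each intrinsic gain parameter is assigned to one of
#' `{superficial, deep} x {AMPA, NMDA, GABA}` by its postsynaptic
#' population (granular counts as superficial) and its receptor kind.
#'
#' @param params an [mc_parameters()] object.
#' @param superficial populations counted as superficial targets.
#' @return Named character vector mapping each gain parameter
#'   (`g_<REC>_<src>_<tgt>`) to a group label such as `sup_AMPA`.
#' @export
parameter_group_map <- function(params,
                                superficial = c("sp", "si", "ss")) {
  tmpl <- params$template
  layer <- ifelse(tmpl$tgt %in% superficial, "sup", "deep")
  setNames(paste(layer, tmpl$receptor, sep = "_"),
           paste0("g_", params$edge_id))
}

#' Fixed order of the six parameter groups
#' @return Character vector of the six group labels.
#' @export
peb_groups <- function() {
  c("sup_AMPA", "sup_NMDA", "sup_GABA", "deep_AMPA", "deep_NMDA",
    "deep_GABA")
}

beta_names <- function(X, param_names) {
  as.vector(vapply(colnames(X), function(r) paste(r, param_names, sep = ":"),
                   character(length(param_names))))
}

#' Fit the parametric empirical Bayes model
#'
#' Hierarchical model \eqn{\theta_n = (x_n' \otimes I)\beta + \epsilon_n}
#' with between-subject covariance \eqn{e^{-h_b} Q}, where
#' \eqn{Q = \Sigma_{prior}/16} anchors the random-effect spread to a
#' fixed fraction of the first-level prior spread and the shared
#' log-precision \eqn{h_b} fine-tunes it (the usual empirical-Bayes
#' convention). Each subject's parameters are observed through that
#' subject's first-level posterior (mean and covariance). \eqn{\beta}
#' then has a closed-form Gaussian posterior given \eqn{h_b}, and
#' \eqn{h_b} is optimized by maximizing the second-level free energy
#' with a Laplace correction.
#'
#' @param posteriors named list of first-level posterior
#'   [gaussian_belief()]s (one per subject, shared parameter index).
#' @param X design matrix from [build_design_matrix()]; rows align with
#'   `posteriors`.
#' @param groupmap parameter-to-group map from [parameter_group_map()];
#'   its names define which parameters enter the second level.
#' @param first_level_prior the prior [gaussian_belief()] used at the
#'   first level (anchors the random-effect covariance scale).
#' @param beta_prior_var prior variance of each second-level effect.
#' @param h_prior hyperprior (list `mean`, `var`) on the between-subject
#'   log precision.
#' @param observation how each subject's first-level posterior enters the
#'   second level: `"likelihood"` (default) removes the first-level prior
#'   from the posterior precision, so first-level shrinkage does not
#'   attenuate second-level effects; `"posterior"` uses the posterior
#'   as-is.
#' @return Object of class `mc_peb`: `beta` (posterior belief), `F`
#'   (second-level free energy), `h_b`, `beta_prior`, `empirical_priors`
#'   (per-subject beliefs), `param_names`, `groupmap`, `X`.
#' @export
fit_peb <- function(posteriors, X, groupmap, first_level_prior,
                    beta_prior_var = 1,
                    h_prior = list(mean = 0, var = 1 / 16),
                    observation = c("likelihood", "posterior")) {
  observation <- match.arg(observation)
  n <- length(posteriors)
  if (nrow(X) != n) stop("design matrix rows must align with subjects")
  pn <- names(groupmap)
  for (b in posteriors) {
    if (!all(pn %in% b$names))
      stop("mismatched parameter indices across subjects")
  }
  p <- length(pn)
  r <- ncol(X)
  prior_sub <- belief_subset(first_level_prior, pn)
  P0 <- chol2inv(chol(prior_sub$cov))
  # each subject observed through its first-level posterior: precision and
  # information vector, with the first-level prior removed (likelihood
  # convention) or kept (posterior convention)
  subj <- lapply(posteriors, function(b) {
    bs <- belief_subset(b, pn)
    Pn <- chol2inv(chol(bs$cov + diag(1e-10, p)))
    if (observation == "posterior")
      return(list(P = Pn, r = as.numeric(Pn %*% bs$mean)))
    # de-shrunk likelihood, floored: directions the data measured well
    # keep their likelihood precision; near-null directions fall back to a
    # weak observation of the posterior mean at the second-level effect
    # prior precision, bounding the generalized-least-squares problem.
    floor_prec <- 1 / beta_prior_var
    S <- Pn - P0
    raw <- as.numeric(Pn %*% bs$mean - P0 %*% prior_sub$mean)
    eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
    keep <- eg$values > max(eg$values, 0) * 1e-12
    if (any(keep)) {
      U <- eg$vectors[, keep, drop = FALSE]
      Pl <- U %*% (eg$values[keep] * t(U))
      rl <- as.numeric(U %*% crossprod(U, raw))
    } else {
      Pl <- matrix(0, p, p)
      rl <- rep(0, p)
    }
    list(P = Pl + diag(floor_prec, p),
         r = rl + floor_prec * bs$mean)
  })
  Bn <- beta_names(X, pn)
  B_prior <- gaussian_belief(setNames(rep(0, r * p), Bn),
                             diag(beta_prior_var, r * p))
  Ip <- diag(1, p)
  qvar <- diag(prior_sub$cov) / 16   # random-effect base covariance Q

  evidence <- function(h_b) {
    ginv <- exp(h_b) / qvar          # diagonal of (e^{-h} Q)^{-1}
    Lam <- diag(1 / beta_prior_var, r * p)
    u <- rep(0, r * p)
    csum <- 0
    for (i in seq_len(n)) {
      A <- subj[[i]]$P + diag(ginv)
      Ainv <- chol2inv(chol(A))
      W <- diag(ginv) - diag(ginv) %*% Ainv %*% diag(ginv)
      v <- ginv * (Ainv %*% subj[[i]]$r)
      xi <- X[i, ]
      Lam <- Lam + kronecker(tcrossprod(xi), W)
      u <- u + kronecker(xi, as.numeric(v))
      csum <- csum + 0.5 * sum(subj[[i]]$r * (Ainv %*% subj[[i]]$r)) +
        0.5 * sum(log(ginv)) - 0.5 * logdet_spd(A, "second-level precision")
    }
    mu_b <- solve(Lam, u)
    F <- csum - 0.5 * (r * p) * log(beta_prior_var) -
      0.5 * logdet_spd(Lam, "second-level posterior precision") +
      0.5 * sum(u * mu_b) +
      stats::dnorm(h_b, h_prior$mean, sqrt(h_prior$var), log = TRUE)
    list(F = F, mu = as.numeric(mu_b), Lam = Lam)
  }

  opt <- optimize(function(h) evidence(h)$F, interval = c(-8, 8),
                  maximum = TRUE, tol = 1e-6)
  h_hat <- opt$maximum
  fit <- evidence(h_hat)
  eps <- 1e-3
  curv <- -(evidence(h_hat + eps)$F - 2 * fit$F +
              evidence(h_hat - eps)$F) / eps^2
  h_var <- if (is.finite(curv) && curv > 0) 1 / curv else h_prior$var
  F_total <- fit$F + 0.5 * log(2 * pi * h_var)

  Sigma_b <- chol2inv(chol(fit$Lam))
  beta_post <- gaussian_belief(setNames(fit$mu, Bn), Sigma_b)
  emp <- lapply(seq_len(n), function(i) {
    M <- kronecker(matrix(X[i, ], 1), Ip)
    gaussian_belief(setNames(as.numeric(M %*% fit$mu), pn),
                    diag(exp(-h_hat) * qvar) + M %*% Sigma_b %*% t(M))
  })
  names(emp) <- names(posteriors)
  structure(list(
    beta = beta_post, beta_prior = B_prior, F = F_total,
    h_b = list(mean = h_hat, var = h_var),
    empirical_priors = emp, param_names = pn, groupmap = groupmap,
    X = X
  ), class = "mc_peb")
}

#' @export
print.mc_peb <- function(x, ...) {
  cat(sprintf(
    "PEB fit: %d subjects, %d parameters, %d regressors, F = %.2f\n",
    nrow(x$X), length(x$param_names), ncol(x$X), x$F))
  invisible(x)
}

#' Restrict second-level priors to a model
#'
#' Pins the covariate-effect priors of parameters outside the model's
#' included groups to zero (zero prior variance and zero mean); the
#' group-average effects are always retained.
#'
#' @param beta_prior second-level prior [gaussian_belief()] over the
#'   stacked effects (names `<regressor>:<parameter>`).
#' @param model a [peb_model_spec()].
#' @param groupmap parameter-to-group map.
#' @return The reduced prior belief.
#' @export
restrict_model <- function(beta_prior, model, groupmap) {
  stopifnot(inherits(model, "peb_model_spec"))
  included <- names(model$mask)[model$mask]
  if (!length(included)) stop("empty model mask")
  nm <- beta_prior$names
  reg <- sub(":.*$", "", nm)
  par <- sub("^[^:]*:", "", nm)
  pin <- reg != "mean" & !is.na(groupmap[par]) &
    !(groupmap[par] %in% included)
  out <- beta_prior
  out$mean[pin] <- 0
  out$cov[pin, ] <- 0
  out$cov[, pin] <- 0
  out
}
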