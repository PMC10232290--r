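# Shared oracles and fixtures for the test suite. Everything here is
# closed-form or brute-force reference code, independent of the package
# implementation under test.

# Linear-Gaussian forward model y = A %*% lambda (+ noise), wrapped as an
# mc_forward object. Exact Jacobian supplied so inversion is conjugate.
linear_model <- function(A, param_names = paste0("p", seq_len(ncol(A)))) {
  colnames(A) <- param_names
  forward_model(
    predict = function(lambda) as.numeric(A %*% lambda[param_names]),
    param_names = param_names,
    jacobian = function(lambda, step = 1e-4) A
  )
}

# Closed-form conjugate posterior and log evidence for the linear model
# with KNOWN noise precision exp(h0):
#   y ~ N(A lambda, exp(-h0) I),  lambda ~ N(m0, C0)
linear_conjugate <- function(y, A, m0, C0, h0) {
  pi0 <- exp(h0)
  P0 <- solve(C0)
  P <- pi0 * crossprod(A) + P0
  C <- solve(P)
  m <- as.numeric(C %*% (pi0 * crossprod(A, y) + P0 %*% m0))
  S <- exp(-h0) * diag(length(y)) + A %*% C0 %*% t(A)
  ch <- chol(S)
  z <- backsolve(ch, y - as.numeric(A %*% m0), transpose = TRUE)
  logev <- -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(z^2)
  list(mean = m, cov = C, log_evidence = logev)
}

# Random linear inversion problem with fixed noise precision, solved by
# the package's invert(); used for the BMR refit-agreement suite.
random_linear_problem <- function(p = 4, n = 25, h0 = 1) {
  A <- matrix(rnorm(n * p), n, p)
  nm <- paste0("p", seq_len(p))
  m0 <- setNames(rnorm(p, 0, 0.3), nm)
  C0 <- diag(runif(p, 0.5, 2), p)
  truth <- m0 + rnorm(p, 0, 0.5)
  y <- as.numeric(A %*% truth) + rnorm(n, 0, exp(-h0 / 2))
  list(A = A, names = nm, y = y,
       priors = gaussian_belief(m0, C0),
       model = linear_model(A, nm),
       noise = noise_model(h0, 0))
}

# Brute-force ICC(2,1) through R's ANOVA machinery (reference for icc2).
icc2_bruteforce <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ subject + rater, data = d)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  p <- stats::pf(MSR / MSE, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, p = p)
}

# Fabricated first-level posteriors theta_i ~ X beta with tight, slightly
# rotated covariances: a fast stand-in cohort for second-level tests that
# does not require microcircuit inversions.
fake_posteriors <- function(X, beta_matrix, sd = 0.05, post_var = 0.01,
                            seed = 1) {
  set.seed(seed)
  pn <- colnames(beta_matrix)
  lapply(seq_len(nrow(X)), function(i) {
    mu <- as.numeric(X[i, ] %*% beta_matrix) + rnorm(length(pn), 0, sd)
    Q <- qr.Q(qr(matrix(rnorm(length(pn)^2), length(pn))))
    C <- Q %*% diag(runif(length(pn), 0.5, 1.5) * post_var) %*% t(Q)
    gaussian_belief(setNames(mu, pn), (C + t(C)) / 2)
  })
}

# Cache heavier fixtures across test files within one run.
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}
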