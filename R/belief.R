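# Gaussian belief: the mean/covariance pair used for priors, posteriors and
# empirical priors at both levels of the hierarchy.

#' Gaussian belief over named parameters
#'
#' @param mean named numeric vector.
#' @param cov covariance matrix (symmetric positive semi-definite); a
#'   numeric vector is taken as a diagonal.
#' @param names optional parameter names (overrides `names(mean)`).
#' @return Object of class `gaussian_belief` with elements `mean`, `cov`,
#'   `names`.
#' @export
gaussian_belief <- function(mean, cov, names = NULL) {
  mean <- as.numeric2(mean, names)
  if (is.null(dim(cov))) cov <- diag(as.numeric(cov), length(mean))
  cov <- as.matrix(cov)
  if (nrow(cov) != length(mean) || ncol(cov) != length(mean))
    stop("covariance order must equal mean length")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance must be symmetric")
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev))))
    stop("covariance must be positive semi-definite")
  nm <- names(mean)
  if (is.null(nm)) stop("belief parameters must be named")
  if (anyDuplicated(nm)) stop("belief parameter names must be unique")
  dimnames(cov) <- list(nm, nm)
  structure(list(mean = mean, cov = cov, names = nm),
            class = "gaussian_belief")
}

as.numeric2 <- function(x, names = NULL) {
  nm <- if (!is.null(names)) names else base::names(x)
  setNames(as.numeric(x), nm)
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("Gaussian belief over %d parameters\n", length(x$mean)))
  invisible(x)
}

#' Restrict a belief to a subset of parameters (marginal)
#'
#' @param belief a [gaussian_belief()].
#' @param names parameter names to keep (order respected).
#' @return The marginal `gaussian_belief`.
#' @export
belief_subset <- function(belief, names) {
  miss <- setdiff(names, belief$names)
  if (length(miss)) stop("parameters not in belief: ",
                         paste(miss, collapse = ", "))
  gaussian_belief(belief$mean[names], belief$cov[names, names, drop = FALSE])
}

check_same_index <- function(a, b) {
  if (!identical(a$names, b$names))
    stop("beliefs do not share a parameter index")
  invisible(TRUE)
}

# log determinant of a symmetric positive-definite matrix, with error on
# numerical singularity
logdet_spd <- function(S, label = "covariance") {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) stop("numerically singular ", label)
  2 * sum(log(diag(ch)))
}

#' Kullback--Leibler divergence between two Gaussian beliefs
#'
#' \eqn{KL(q \| p)} over a shared parameter index.
#'
#' @param q,p [gaussian_belief()] objects with identical names.
#' @return Non-negative scalar (nats).
#' @export
kl_gaussian <- function(q, p) {
  check_same_index(q, p)
  d <- length(q$mean)
  Pp <- chol2inv(chol(p$cov))
  dm <- q$mean - p$mean
  0.5 * (sum(Pp * q$cov) + sum(dm * (Pp %*% dm)) - d +
           logdet_spd(p$cov, "prior covariance") -
           logdet_spd(q$cov, "posterior covariance"))
}
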