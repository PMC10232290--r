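# Model space over the six synaptic parameter groups: enumeration of the
# 2^6 - 1 = 63 non-empty group combinations, closed-form Bayesian model
# reduction, softmax model comparison, per-group relative evidence, and
# greedy pruning of redundant second-level effects.

#' Second-level model specification
#'
#' A Boolean mask over the six parameter groups (fixed order: sup-AMPA,
#' sup-NMDA, sup-GABA, deep-AMPA, deep-NMDA, deep-GABA). The model index
#' is the binary encoding: bit i of the index is the inclusion of group i,
#' so index 63 is the full model.
#'
#' @param mask logical vector over the groups (named or in the fixed
#'   order), or a character vector of included group labels.
#' @param groups group labels (defaults to [peb_groups()]).
#' @return Object of class `peb_model_spec` with `mask` and `index`.
#' @export
peb_model_spec <- function(mask, groups = peb_groups()) {
  if (is.character(mask)) {
    miss <- setdiff(mask, groups)
    if (length(miss)) stop("unknown groups: ", paste(miss, collapse = ", "))
    mask <- groups %in% mask
  }
  if (!is.null(names(mask))) mask <- mask[groups]
  mask <- as.logical(mask)
  if (length(mask) != length(groups) || anyNA(mask))
    stop("mask must cover every group")
  if (!any(mask)) stop("empty model mask: at least one group must be included")
  names(mask) <- groups
  index <- sum(2^(seq_along(groups) - 1) * mask)
  structure(list(mask = mask, index = index), class = "peb_model_spec")
}

#' @export
print.peb_model_spec <- function(x, ...) {
  cat(sprintf("Model %d: {%s}\n", x$index,
              paste(names(x$mask)[x$mask], collapse = ", ")))
  invisible(x)
}

#' Enumerate the non-empty group-combination models
#'
#' @param n_groups number of parameter groups (6 gives the 63-model
#'   space).
#' @param groups group labels.
#' @return List of [peb_model_spec()]s in index order 1..(2^n - 1).
#' @export
enumerate_models <- function(n_groups = 6,
                             groups = peb_groups()[seq_len(n_groups)]) {
  if (n_groups < 1) stop("n_groups must be >= 1")
  lapply(seq_len(2^n_groups - 1), function(i) {
    mask <- as.logical(bitwAnd(i, 2^(seq_len(n_groups) - 1)))
    peb_model_spec(setNames(mask, groups), groups)
  })
}

gaussian_logpdf <- function(x, mean, cov) {
  d <- length(x)
  ch <- tryCatch(chol(cov), error = function(e)
    stop("numerically singular covariance in model reduction"))
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

#' Bayesian model reduction
#'
#' Closed-form change in log evidence (and implied posterior) when the
#' prior of an already-fitted Gaussian model is swapped for a reduced
#' prior, without refitting. Parameters whose reduced prior variance is
#' exactly zero are treated as pinned to the reduced prior mean (a
#' point-null reduction, evaluated by the Savage-Dickey ratio, which
#' requires the full prior to be independent between pinned and free
#' parameters); any remaining prior changes use the Gaussian
#' evidence-ratio identity.
#'
#' @param prior,posterior,reduced_prior [gaussian_belief()]s sharing one
#'   parameter index.
#' @return List with `dF` (log-evidence change, nats) and `posterior`
#'   (the implied reduced posterior belief; pinned parameters have zero
#'   variance).
#' @export
bayesian_model_reduction <- function(prior, posterior, reduced_prior) {
  check_same_index(prior, posterior)
  check_same_index(prior, reduced_prior)
  nm <- prior$names
  pin <- diag(reduced_prior$cov) == 0
  dF <- 0
  m <- posterior$mean
  C <- posterior$cov
  m0 <- prior$mean
  C0 <- prior$cov
  m0r <- reduced_prior$mean
  if (any(pin)) {
    if (any(!pin) && max(abs(C0[pin, !pin, drop = FALSE])) > 1e-12)
      stop("pinned parameters must be a priori independent of the rest")
    a <- m0r[pin]
    dF <- gaussian_logpdf(a, m[pin], C[pin, pin, drop = FALSE]) -
      gaussian_logpdf(a, m0[pin], C0[pin, pin, drop = FALSE])
    if (any(!pin)) {
      # condition the posterior on the pinned values
      Czz <- C[pin, pin, drop = FALSE]
      Ckz <- C[!pin, pin, drop = FALSE]
      adj <- Ckz %*% solve(Czz, cbind(a - m[pin]))
      m <- m[!pin] + as.numeric(adj)
      C <- C[!pin, !pin, drop = FALSE] -
        Ckz %*% solve(Czz, t(Ckz))
      C <- (C + t(C)) / 2
      m0 <- m0[!pin]
      C0 <- C0[!pin, !pin, drop = FALSE]
      m0r <- m0r[!pin]
    } else {
      out <- reduced_prior
      out$mean[] <- reduced_prior$mean
      out$cov[] <- 0
      return(list(dF = dF, posterior = out))
    }
  }
  C0r <- reduced_prior$cov[!pin, !pin, drop = FALSE]
  if (max(abs(C0r - C0)) > 0 || max(abs(m0r - m0)) > 0) {
    P <- chol2inv(chol((C + t(C)) / 2))
    P0 <- chol2inv(chol(C0))
    P0r <- chol2inv(chol(C0r))
    Pr <- P + P0r - P0
    mr <- solve(Pr, P %*% m + P0r %*% m0r - P0 %*% m0)
    dF <- dF + 0.5 * (logdet_spd(P0r, "reduced prior precision") -
                        logdet_spd(P0, "prior precision") +
                        logdet_spd(P, "posterior precision") -
                        logdet_spd(Pr, "reduced posterior precision")) -
      0.5 * (sum(m0r * (P0r %*% m0r)) - sum(m0 * (P0 %*% m0)) +
               sum(m * (P %*% m)) - sum(mr * (Pr %*% mr)))
    mK <- as.numeric(mr)
    CK <- chol2inv(chol((Pr + t(Pr)) / 2))
  } else {
    mK <- m
    CK <- C
  }
  full_mean <- setNames(numeric(length(nm)), nm)
  full_cov <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  full_mean[pin] <- reduced_prior$mean[pin]
  full_mean[!pin] <- mK
  full_cov[!pin, !pin] <- CK
  list(dF = dF,
       posterior = gaussian_belief(full_mean, full_cov))
}

#' Softmax model comparison
#'
#' Converts a vector of per-model free energies to posterior model
#' probabilities, \eqn{p_i \propto e^{F_i}}, computed shift-invariantly.
#'
#' @param free_energies numeric vector of per-model free energies (nats).
#' @return Object of class `mc_model_comparison`: `F`, `prob`, `winner`
#'   (index of the highest-probability model; ties resolved to the lowest
#'   index, with all tied indices reported in `tied`).
#' @export
compare_models <- function(free_energies) {
  if (length(free_energies) < 1) stop("empty free-energy vector")
  if (!all(is.finite(free_energies))) stop("free energies must be finite")
  z <- free_energies - max(free_energies)
  p <- exp(z) / sum(exp(z))
  tied <- which(free_energies == max(free_energies))
  structure(list(F = free_energies, prob = p, winner = tied[1],
                 tied = tied), class = "mc_model_comparison")
}

#' @export
print.mc_model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison over %d models: winner %d (p = %.3f)\n",
              length(x$F), x$winner, x$prob[x$winner]))
  invisible(x)
}

#' Score the full model space of a PEB fit
#'
#' Evaluates every model's free energy by Bayesian model reduction of the
#' fitted full PEB model and converts them to posterior probabilities.
#'
#' @param peb a fitted [fit_peb()] result.
#' @param models list of [peb_model_spec()]s (default: the full 63-model
#'   space).
#' @return List with `models`, `F` (per-model), `comparison`
#'   ([compare_models()] result), `winner_mask`.
#' @export
score_model_space <- function(peb, models = enumerate_models(6)) {
  dF <- vapply(models, function(m) {
    rp <- restrict_model(peb$beta_prior, m, peb$groupmap)
    bayesian_model_reduction(peb$beta_prior, peb$beta, rp)$dF
  }, numeric(1))
  F <- peb$F + dF
  cmp <- compare_models(F)
  list(models = models, F = F, comparison = cmp,
       winner_mask = models[[cmp$winner]]$mask)
}

#' Per-group relative evidence
#'
#' Free energy of each single-group model (covariate effects allowed only
#' in that group), reported relative to the worst group; higher values
#' mean more evidence that the covariate acts through that group.
#'
#' @param peb a fitted [fit_peb()] result.
#' @param groups group labels.
#' @return List with `relative_F` (named, minimum 0) and `ranking`
#'   (group labels, best first).
#' @export
group_relative_evidence <- function(peb, groups = peb_groups()) {
  F1 <- vapply(groups, function(g) {
    m <- peb_model_spec(g, groups)
    rp <- restrict_model(peb$beta_prior, m, peb$groupmap)
    bayesian_model_reduction(peb$beta_prior, peb$beta, rp)$dF
  }, numeric(1))
  rel <- F1 - min(F1)
  list(relative_F = rel, ranking = groups[order(rel, decreasing = TRUE)])
}

#' Greedy pruning of redundant second-level effects
#'
#' Repeatedly removes (pins to zero) the single covariate effect whose
#' removal most increases the reduced free energy, stopping when no
#' removal improves it. Surviving effects are reported with a posterior
#' probability of inclusion, \eqn{1/(1 + e^{\Delta F_{rm}})}, where
#' \eqn{\Delta F_{rm}} is the evidence change if that effect were also
#' removed from the final model.
#'
#' @param peb a fitted [fit_peb()] result.
#' @return List with `posterior` (reduced belief), `dF` (total evidence
#'   gain over the full model), `removed`, `retained`, `probability`
#'   (named, for retained effects).
#' @export
prune_parameters <- function(peb) {
  nm <- peb$beta$names
  reg <- sub(":.*$", "", nm)
  candidates <- nm[reg != "mean" & diag(peb$beta_prior$cov) > 0]
  pinned <- character(0)
  reduce_with <- function(pins) {
    rp <- peb$beta_prior
    sel <- nm %in% pins
    rp$mean[sel] <- 0
    rp$cov[sel, ] <- 0
    rp$cov[, sel] <- 0
    bayesian_model_reduction(peb$beta_prior, peb$beta, rp)
  }
  current <- 0
  repeat {
    remaining <- setdiff(candidates, pinned)
    if (!length(remaining)) break
    gains <- vapply(remaining, function(eff)
      reduce_with(c(pinned, eff))$dF - current, numeric(1))
    best <- which.max(gains)
    if (gains[best] <= 0) break
    pinned <- c(pinned, remaining[best])
    current <- current + gains[best]
  }
  red <- reduce_with(pinned)
  retained <- setdiff(candidates, pinned)
  prob <- vapply(retained, function(eff) {
    drm <- reduce_with(c(pinned, eff))$dF - red$dF
    1 / (1 + exp(drm))
  }, numeric(1))
  list(posterior = red$posterior, dF = red$dF, removed = pinned,
       retained = retained, probability = prob)
}
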