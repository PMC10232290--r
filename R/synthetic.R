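# Synthetic-cohort generator: subjects whose laminar/receptor-specific
# synaptic gains covary with a scalar covariate (a standardized
# synaptic-density analogue), observed as noisy trial-level ERF epochs for
# the two oddball conditions.

#' Cohort generator configuration
#'
#' @param n_subjects number of subjects (>= 3; default 12).
#' @param beta named numeric of true second-level covariate effects per
#'   parameter group (log-gain units per covariate SD); groups absent
#'   from the names have no effect.
#' @param b_mean mean condition log-gain on flagged edges (the deviant
#'   response generator; default 0.2).
#' @param re_sd between-subject random-effect SD on the gain log-scale
#'   parameters (default 0.1).
#' @param re_sd_b between-subject SD of the condition log-gains.
#' @param n_trials trials per condition (default 60).
#' @param noise_sd white trial-noise SD on the ERF samples (observation
#'   units; default 0.35, roughly half the standard-response peak).
#' @param fab_cor correlation between the density analogue and the
#'   clinical-score analogue.
#' @param seed random seed (recorded in all outputs).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 12, beta = c(sup_AMPA = 0),
                          b_mean = 0.2, re_sd = 0.1, re_sd_b = 0.05,
                          n_trials = 60, noise_sd = 0.35, fab_cor = 0.5,
                          seed = 1) {
  if (n_subjects < 3) stop("need at least 3 subjects")
  if (noise_sd < 0 || re_sd < 0 || re_sd_b < 0)
    stop("standard deviations must be non-negative")
  if (n_trials < 1) stop("need at least one trial per condition")
  miss <- setdiff(names(beta), peb_groups())
  if (length(miss)) stop("unknown groups in beta: ",
                         paste(miss, collapse = ", "))
  full_beta <- setNames(rep(0, 6), peb_groups())
  full_beta[names(beta)] <- beta
  structure(list(n_subjects = n_subjects, beta = full_beta,
                 b_mean = b_mean, re_sd = re_sd, re_sd_b = re_sd_b,
                 n_trials = n_trials, noise_sd = noise_sd,
                 fab_cor = fab_cor, seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws a standardized covariate per subject, builds subject-level
#' log-gain parameters as covariate effect plus random effect, simulates
#' trial-level ERF epochs for both conditions (model prediction plus
#' independent white Gaussian noise per trial), and returns a manifest
#' together with the generating ground truth. Fully reproducible from the
#' seed.
#'
#' @param config a [cohort_config()].
#' @param params base [mc_parameters()] shared by the cohort.
#' @param out_dir optional directory; when given, per-subject trial CSVs,
#'   the manifest JSON and the ground-truth JSON are written there.
#' @return List with `manifest` (per-subject ids, covariates and
#'   trial-level epochs), `ground_truth` (true per-subject log-scale
#'   parameters, true beta, generating mask) and `config`. Inference code
#'   must only read `manifest`.
#' @export
generate_cohort <- function(config, params = mc_parameters(),
                            out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  raw <- runif(n, -1, 1)
  density <- (raw - mean(raw)) / stats::sd(raw)
  fab <- config$fab_cor * density +
    sqrt(max(0, 1 - config$fab_cor^2)) * rnorm(n)
  groupmap <- parameter_group_map(params)
  gain_names <- names(groupmap)
  b_names <- grep("^b_", params$free_names, value = TRUE)
  times <- erf_times()
  ids <- sprintf("sub%02d", seq_len(n))
  lambda_true <- matrix(0, n, length(params$free_names),
                        dimnames = list(ids, params$free_names))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    lam <- setNames(rep(0, length(params$free_names)), params$free_names)
    lam[gain_names] <- config$beta[groupmap[gain_names]] * density[i] +
      rnorm(length(gain_names), 0, config$re_sd)
    lam[b_names] <- config$b_mean + rnorm(length(b_names), 0, config$re_sd_b)
    lambda_true[i, ] <- lam
    pair <- simulate_erf_pair(with_lambda(params, lam), times = times)
    make_trials <- function(trace, condition) {
      noise <- matrix(rnorm(length(times) * config$n_trials, 0,
                            config$noise_sd),
                      length(times), config$n_trials)
      erf_trials(times, trace$amplitude + noise, condition)
    }
    subjects[[i]] <- list(
      id = ids[i],
      covariates = list(density = density[i], fab = fab[i]),
      trials_standard = make_trials(pair$standard, "standard"),
      trials_deviant = make_trials(pair$deviant, "deviant")
    )
  }
  names(subjects) <- ids
  manifest <- list(subjects = subjects, seed = config$seed,
                   n_trials = config$n_trials)
  ground_truth <- list(
    lambda = lambda_true, beta = config$beta,
    mask = names(config$beta)[config$beta != 0], seed = config$seed
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    entries <- lapply(subjects, function(s) {
      std <- file.path(out_dir, paste0(s$id, "_standard.csv"))
      dev <- file.path(out_dir, paste0(s$id, "_deviant.csv"))
      write_erf_trials(s$trials_standard, std)
      write_erf_trials(s$trials_deviant, dev)
      list(id = s$id, erf_standard_path = basename(std),
           erf_deviant_path = basename(dev), covariates = s$covariates)
    })
    write_json_result(list(subjects = unname(entries), seed = config$seed,
                           n_trials = config$n_trials),
                      file.path(out_dir, "manifest.json"))
    write_json_result(list(
      lambda = as.data.frame(lambda_true), beta = as.list(config$beta),
      mask = ground_truth$mask, seed = config$seed
    ), file.path(out_dir, "ground_truth.json"))
  }
  list(manifest = manifest, ground_truth = ground_truth, config = config)
}

#' Load a cohort manifest from disk
#'
#' @param path path to a `manifest.json` written by [generate_cohort()].
#' @return Manifest list with trial-level epochs loaded from the CSVs.
#' @export
read_cohort_manifest <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dir <- dirname(path)
  subjects <- lapply(doc$subjects, function(s) {
    list(id = s$id,
         covariates = lapply(s$covariates, as.numeric),
         trials_standard = read_erf_trials(
           file.path(dir, s$erf_standard_path), "standard"),
         trials_deviant = read_erf_trials(
           file.path(dir, s$erf_deviant_path), "deviant"))
  })
  names(subjects) <- vapply(subjects, `[[`, character(1), "id")
  list(subjects = subjects, seed = doc$seed, n_trials = doc$n_trials)
}

#' Average trial-level epochs
#'
#' Pointwise mean over trials; averaged noise SD shrinks as
#' \eqn{1/\sqrt{k}}.
#'
#' @param trials an [erf_trials()] object with at least one trial.
#' @return An [erf_trace()].
#' @export
trial_average <- function(trials) {
  stopifnot(inherits(trials, "erf_trials"))
  if (ncol(trials$trials) < 1) stop("no trials to average")
  erf_trace(trials$time_ms, rowMeans(trials$trials), trials$condition)
}
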