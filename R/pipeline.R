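# Run configuration and the end-to-end pipeline: per-subject inversion
# (all / odd / even trials), PEB per covariate, 63-model comparison,
# greedy pruning and the split-half reliability report.

#' Run configuration
#'
#' Resolves and validates a pipeline configuration; unknown fields raise
#' an error. Can be loaded from YAML with [read_run_config()].
#'
#' @param config named list overriding defaults: `epoch` (list
#'   `t_start`, `t_end` in ms, `fs` in Hz), `window` (mismatch window,
#'   ms), `inversion` (list `max_iter`, `tol`), `peb` (list
#'   `beta_prior_var`, `h_prior_mean`, `h_prior_var`), `covariates`
#'   (those entered one at a time at the second level), `seed`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(config = list()) {
  defaults <- list(
    epoch = list(t_start = -100, t_end = 400, fs = 500),
    window = c(130, 180),
    inversion = list(max_iter = 64, tol = 0.01),
    peb = list(beta_prior_var = 1, h_prior_mean = 0, h_prior_var = 1 / 16),
    covariates = c("density", "fab", "ymax"),
    seed = 1
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  if (cfg$epoch$t_start >= cfg$epoch$t_end)
    stop("config field epoch: t_start must precede t_end")
  if (cfg$epoch$fs <= 0) stop("config field epoch: fs must be positive")
  if (length(cfg$window) != 2 || cfg$window[1] >= cfg$window[2])
    stop("config field window: expected increasing pair of times (ms)")
  if (cfg$inversion$max_iter < 1)
    stop("config field inversion: max_iter must be >= 1")
  if (cfg$inversion$tol <= 0)
    stop("config field inversion: tol must be positive")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), digits = NA, auto_unbox = TRUE)
  h <- 0
  for (v in utf8ToInt(as.character(s))) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

log_info <- function(...) {
  if (!identical(getOption("microdcm.log_level", "INFO"), "QUIET"))
    message(sprintf(...))
}

stamp <- function(x, cfg) {
  x$config_hash <- config_hash(cfg)
  x$seed <- cfg$seed
  x
}

peb_to_json <- function(peb) {
  list(beta_names = peb$beta$names,
       beta_mean = as.list(peb$beta$mean),
       beta_sd = as.list(sqrt(diag(peb$beta$cov))),
       free_energy = peb$F, h_b = peb$h_b)
}

#' Run the full analysis pipeline on a cohort
#'
#' For every subject: trial averages for all, odd and even trials and a
#' variational Laplace inversion of each; then (on the all-trial
#' inversions) one PEB analysis per covariate, a 63-model comparison and
#' greedy pruning for the first covariate, and a split-half reliability
#' report from the odd/even inversions. Deterministic given the inputs;
#' every result JSON embeds the resolved configuration hash and seed.
#'
#' @param cohort a manifest as returned in `generate_cohort()$manifest`,
#'   or a path to a `manifest.json`.
#' @param out_dir output directory for the result JSONs.
#' @param config a [run_config()].
#' @param params base [mc_parameters()] defining model and priors.
#' @return Invisibly, a list with `inversions`, `odd`, `even`, `ymax`,
#'   `peb` (per covariate), `model_comparison`, `pruned`, `reliability`.
#' @export
run_pipeline <- function(cohort, out_dir, config = run_config(),
                         params = mc_parameters()) {
  if (is.character(cohort)) cohort <- read_cohort_manifest(cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  times <- erf_times(config$epoch$t_start, config$epoch$t_end,
                     config$epoch$fs)
  model <- mc_model(params, times = times)
  priors <- mc_priors(params)
  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed for subject '%s': %s",
                   name, id, conditionMessage(e)), call. = FALSE))
  }
  invert_pair <- function(std, dev, id, label) {
    res <- stage(label, id,
                 invert(list(standard = std, deviant = dev), model, priors,
                        max_iter = config$inversion$max_iter,
                        tol = config$inversion$tol))
    log_info("[%s] %s: F = %.2f after %d iterations", label, id, res$F,
             res$iterations)
    res
  }
  subjects <- cohort$subjects
  ids <- names(subjects)
  inv_all <- list(); inv_odd <- list(); inv_even <- list()
  ymax_vals <- numeric(0)
  inv_dir <- file.path(out_dir, "inversions")
  dir.create(inv_dir, showWarnings = FALSE)
  for (id in ids) {
    s <- subjects[[id]]
    avg_s <- stage("average", id, trial_average(s$trials_standard))
    avg_d <- stage("average", id, trial_average(s$trials_deviant))
    halves_s <- stage("split", id, split_halves(s$trials_standard))
    halves_d <- stage("split", id, split_halves(s$trials_deviant))
    inv_all[[id]] <- invert_pair(avg_s, avg_d, id, "invert")
    inv_odd[[id]] <- invert_pair(halves_s$odd, halves_d$odd, id,
                                 "invert-odd")
    inv_even[[id]] <- invert_pair(halves_s$even, halves_d$even, id,
                                  "invert-even")
    ymax_vals[id] <- stage("ymax", id, ymax(avg_s, avg_d, config$window))
    write_inversion(inv_all[[id]], file.path(inv_dir,
                                             paste0(id, ".json")))
  }
  groupmap <- parameter_group_map(params)
  covar_values <- function(nm) {
    if (nm == "ymax") return(unname(ymax_vals))
    vapply(subjects, function(s) as.numeric(s$covariates[[nm]]),
           numeric(1))
  }
  posteriors <- lapply(inv_all, `[[`, "posterior")
  peb_fits <- list()
  for (cv in config$covariates) {
    X <- build_design_matrix(covar_values(cv), names = cv, subjects = ids)
    peb_fits[[cv]] <- stage("peb", cv,
      fit_peb(posteriors, X, groupmap, priors,
              beta_prior_var = config$peb$beta_prior_var,
              h_prior = list(mean = config$peb$h_prior_mean,
                             var = config$peb$h_prior_var)))
    write_json_result(stamp(peb_to_json(peb_fits[[cv]]), config),
                      file.path(out_dir, paste0("peb_", cv, ".json")))
  }
  primary <- peb_fits[[config$covariates[1]]]
  space <- stage("compare", "-", score_model_space(primary))
  write_json_result(stamp(list(
    F = space$F, prob = as.numeric(space$comparison$prob),
    winner = space$comparison$winner,
    winner_groups = names(space$winner_mask)[space$winner_mask],
    group_relative_F = as.list(group_relative_evidence(primary)$relative_F)
  ), config), file.path(out_dir, "model_comparison.json"))
  pruned <- stage("prune", "-", prune_parameters(primary))
  write_json_result(stamp(list(
    removed = pruned$removed, retained = pruned$retained,
    probability = as.list(pruned$probability), dF = pruned$dF
  ), config), file.path(out_dir, "pruned.json"))
  rel <- stage("reliability", "-",
               reliability_report(inv_odd, inv_even,
                                  parameters = names(groupmap)))
  write_json_result(stamp(list(
    measures = rel$measures, fe_r2 = rel$fe_r2
  ), config), file.path(out_dir, "reliability.json"))
  write_json_result(stamp(unclass(config), config),
                    file.path(out_dir, "resolved_config.json"))
  invisible(list(inversions = inv_all, odd = inv_odd, even = inv_even,
                 ymax = ymax_vals, peb = peb_fits,
                 model_comparison = space, pruned = pruned,
                 reliability = rel))
}
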