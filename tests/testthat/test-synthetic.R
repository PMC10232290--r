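test_that("cohort_config validates its fields", {
  expect_error(cohort_config(n_subjects = 2), "at least 3")
  expect_error(cohort_config(noise_sd = -1), "non-negative")
  expect_error(cohort_config(n_trials = 0), "at least one trial")
  expect_error(cohort_config(beta = c(astro_GLU = 1)), "unknown groups")
  cfg <- cohort_config(beta = c(deep_NMDA = 0.2))
  expect_equal(unname(cfg$beta["deep_NMDA"]), 0.2)
  expect_equal(sum(cfg$beta != 0), 1)
})

test_that("generate_cohort is reproducible and well-formed", {
  cfg <- cohort_config(n_subjects = 4, n_trials = 6, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$ground_truth, b$ground_truth)
  subs <- a$manifest$subjects
  expect_length(subs, 4)
  dens <- vapply(subs, function(s) s$covariates$density, numeric(1))
  expect_equal(mean(dens), 0, tolerance = 1e-12)
  expect_equal(sd(dens), 1, tolerance = 1e-12)
  expect_equal(ncol(subs[[1]]$trials_standard$trials), 6)
  expect_equal(nrow(subs[[1]]$trials_deviant$trials), 251)
})

test_that("covariate effects enter the generating parameters", {
  cfg <- cohort_config(n_subjects = 6, n_trials = 2, re_sd = 0,
                       beta = c(sup_GABA = 0.4), seed = 9)
  coh <- generate_cohort(cfg)
  gm <- parameter_group_map(mc_parameters())
  dens <- vapply(coh$manifest$subjects, function(s) s$covariates$density,
                 numeric(1))
  lam <- coh$ground_truth$lambda
  for (pn in names(gm)[gm == "sup_GABA"])
    expect_equal(unname(lam[, pn]), unname(0.4 * dens), tolerance = 1e-12)
  expect_true(all(lam[, names(gm)[gm != "sup_GABA"]] == 0))
  expect_equal(coh$ground_truth$mask, "sup_GABA")
})

test_that("trial noise has the configured scale", {
  cfg <- cohort_config(n_subjects = 3, n_trials = 200, noise_sd = 0.25,
                       re_sd = 0, re_sd_b = 0, seed = 4)
  coh <- generate_cohort(cfg)
  s <- coh$manifest$subjects[[1]]
  resid <- sweep(s$trials_standard$trials, 1,
                 rowMeans(s$trials_standard$trials))
  expect_equal(sd(resid), 0.25, tolerance = 0.02)
  # averaged noise shrinks as 1/sqrt(k)
  avg <- trial_average(s$trials_standard)
  pred <- simulate_erf_pair(
    with_lambda(mc_parameters(),
                coh$ground_truth$lambda[1, ]))$standard
  expect_equal(sd(avg$amplitude - pred$amplitude), 0.25 / sqrt(200),
               tolerance = 0.2)
})

test_that("trial averaging follows its contract", {
  tr <- erf_trials(0:3, matrix(1:4, 4, 1))
  expect_equal(trial_average(tr)$amplitude, as.numeric(1:4))
  noise <- rnorm(4)
  tr2 <- erf_trials(0:3, cbind(1:4 + noise, 1:4 - noise))
  expect_equal(trial_average(tr2)$amplitude, as.numeric(1:4))
  expect_error(trial_average(erf_trials(0:3, matrix(0, 4, 0))), "no trials")
})

test_that("cohorts round-trip through disk and hide the ground truth", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_subjects = 3, n_trials = 4, seed = 77)
  coh <- generate_cohort(cfg, out_dir = dir)
  man <- read_cohort_manifest(file.path(dir, "manifest.json"))
  expect_equal(names(man$subjects), names(coh$manifest$subjects))
  expect_equal(man$subjects$sub02$trials_deviant$trials,
               coh$manifest$subjects$sub02$trials_deviant$trials,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(man$subjects$sub03$covariates$fab,
               coh$manifest$subjects$sub03$covariates$fab)
  # generator/inference separation: the manifest carries no true parameters
  raw <- readLines(file.path(dir, "manifest.json"))
  expect_false(any(grepl("lambda|beta|ground", raw)))
  # inference runs without the ground-truth file present
  file.remove(file.path(dir, "ground_truth.json"))
  expect_silent(man2 <- read_cohort_manifest(file.path(dir,
                                                       "manifest.json")))
  expect_equal(names(man2$subjects), names(man$subjects))
})
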