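test_that("design matrix is mean + centered covariates", {
  X <- build_design_matrix(list(density = c(1, 2, 3, 6), fab = 4:1),
                           subjects = paste0("s", 1:4))
  expect_equal(colnames(X), c("mean", "density", "fab"))
  expect_equal(unname(X[, "mean"]), rep(1, 4))
  expect_equal(mean(X[, "density"]), 0)
  expect_equal(mean(X[, "fab"]), 0)
  expect_error(build_design_matrix(c(1, 1, 1, 1)), "constant covariate")
  expect_error(build_design_matrix(list(a = 1:4, b = 2 * (1:4))),
               "rank deficient")
  expect_error(build_design_matrix(1:2), "at least 3")
})

test_that("parameter groups split by depth of the target and receptor", {
  gm <- parameter_group_map(mc_parameters())
  expect_equal(length(gm), 22)
  counts <- table(gm)[peb_groups()]
  expect_equal(unname(as.integer(counts)), c(4, 4, 3, 4, 4, 3))
  expect_equal(unname(gm["g_AMPA_ss_sp"]), "sup_AMPA")   # target sp
  expect_equal(unname(gm["g_NMDA_sp_dp"]), "deep_NMDA")  # target dp
  expect_equal(unname(gm["g_GABA_di_tp"]), "deep_GABA")
})

test_that("fit_peb recovers planted second-level effects", {
  gm <- parameter_group_map(mc_parameters())
  pn <- names(gm)
  n <- 16
  set.seed(5)
  x <- as.numeric(scale(runif(n, -1, 1)))
  X <- build_design_matrix(x, names = "density")
  beta_matrix <- rbind(mean = setNames(rep(0.1, length(pn)), pn),
                       density = setNames(0.4 * (gm == "sup_AMPA"), pn))
  posts <- fake_posteriors(X, beta_matrix, sd = 0.03, seed = 5)
  prior <- gaussian_belief(setNames(rep(0, length(pn)), pn),
                           diag(1 / 16, length(pn)))
  # fabricated posteriors are not true posteriors under `prior`, so use
  # the posterior-observation convention (exact for this construction)
  peb <- fit_peb(posts, X, gm, prior, observation = "posterior")
  est <- peb$beta$mean[paste0("density:", pn)]
  expect_equal(unname(tapply(est, gm[pn], mean)["sup_AMPA"]), 0.4,
               tolerance = 0.05)
  others <- est[gm[pn] != "sup_AMPA"]
  expect_lt(max(abs(others)), 0.1)
  mean_est <- peb$beta$mean[paste0("mean:", pn)]
  expect_equal(unname(mean(mean_est)), 0.1, tolerance = 0.03)
})

test_that("between-subject log-precision tracks the random-effect scale", {
  gm <- parameter_group_map(mc_parameters())
  pn <- names(gm)
  prior <- gaussian_belief(setNames(rep(0, length(pn)), pn),
                           diag(1 / 16, length(pn)))
  X <- build_design_matrix(as.numeric(scale(1:12)), names = "c")
  beta0 <- rbind(mean = setNames(rep(0, length(pn)), pn),
                 c = setNames(rep(0, length(pn)), pn))
  tight <- fit_peb(fake_posteriors(X, beta0, sd = 0.01, seed = 2),
                   X, gm, prior, observation = "posterior")
  loose <- fit_peb(fake_posteriors(X, beta0, sd = 0.2, seed = 2),
                   X, gm, prior, observation = "posterior")
  # larger between-subject spread => lower log precision h_b
  expect_gt(tight$h_b$mean, loose$h_b$mean)
})

test_that("fit_peb validates alignment and indices", {
  gm <- parameter_group_map(mc_parameters())
  pn <- names(gm)
  prior <- gaussian_belief(setNames(rep(0, length(pn)), pn),
                           diag(1 / 16, length(pn)))
  X <- build_design_matrix(1:4, names = "c")
  posts <- fake_posteriors(X, rbind(mean = setNames(rep(0, length(pn)), pn),
                                    c = setNames(rep(0, length(pn)), pn)))
  expect_error(fit_peb(posts[1:3], X, gm, prior), "align")
  wrong <- posts
  wrong[[1]] <- gaussian_belief(c(a = 0), matrix(1))
  expect_error(fit_peb(wrong, X, gm, prior), "mismatched")
})

test_that("restrict_model pins only excluded covariate effects", {
  gm <- parameter_group_map(mc_parameters())
  pn <- names(gm)
  Bn <- as.vector(vapply(c("mean", "density"),
                         function(r) paste(r, pn, sep = ":"),
                         character(length(pn))))
  bp <- gaussian_belief(setNames(rep(0, length(Bn)), Bn),
                        diag(1, length(Bn)))
  m <- peb_model_spec(c("sup_AMPA", "deep_GABA"))
  rp <- restrict_model(bp, m, gm)
  v <- diag(rp$cov)
  kept_groups <- gm[sub("^density:", "", names(v)[grepl("^density:", names(v))
                                                  & v > 0])]
  expect_true(all(kept_groups %in% c("sup_AMPA", "deep_GABA")))
  # group-average effects are never pinned
  expect_true(all(v[grepl("^mean:", names(v))] == 1))
  expect_equal(sum(v[grepl("^density:", names(v))] > 0), 4 + 3)
})
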