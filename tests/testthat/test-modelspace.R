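test_that("model specs encode masks as binary indices", {
  m <- peb_model_spec(c("sup_AMPA", "sup_GABA"))
  expect_equal(m$index, 1 + 4)
  expect_equal(names(m$mask)[m$mask], c("sup_AMPA", "sup_GABA"))
  full <- peb_model_spec(peb_groups())
  expect_equal(full$index, 63)
  expect_error(peb_model_spec(character(0)), "empty model")
  expect_error(peb_model_spec(rep(FALSE, 6)), "empty model")
  expect_error(peb_model_spec("sup_DOPAMINE"), "unknown groups")
})

test_that("enumerate_models covers every non-empty combination once", {
  models <- enumerate_models(6)
  expect_length(models, 63)
  idx <- vapply(models, `[[`, numeric(1), "index")
  expect_equal(idx, as.numeric(1:63))
  masks <- vapply(models, function(m) paste(as.integer(m$mask),
                                            collapse = ""), character(1))
  expect_equal(anyDuplicated(masks), 0L)
})

test_that("BMR identity reduction leaves evidence unchanged", {
  set.seed(3)
  pr <- random_linear_problem(p = 5, n = 25)
  res <- invert(pr$y, pr$model, pr$priors, pr$noise)
  out <- bayesian_model_reduction(pr$priors, res$posterior, pr$priors)
  expect_lt(abs(out$dF), 1e-9)
  expect_equal(out$posterior$mean, res$posterior$mean, tolerance = 1e-9)
})

test_that("BMR point-null matches the Savage-Dickey ratio in 1-d", {
  prior <- gaussian_belief(c(a = 0), matrix(1))
  post <- gaussian_belief(c(a = 0.8), matrix(0.2))
  red <- gaussian_belief(c(a = 0), matrix(0))
  out <- bayesian_model_reduction(prior, post, red)
  expect_equal(out$dF,
               dnorm(0, 0.8, sqrt(0.2), log = TRUE) -
                 dnorm(0, 0, 1, log = TRUE))
  expect_equal(unname(out$posterior$mean), 0)
  expect_equal(unname(out$posterior$cov[1, 1]), 0)
})

test_that("softmax comparison is shift-invariant and normalized", {
  F <- c(-100, -98, -105)
  cmp <- compare_models(F)
  expect_equal(sum(cmp$prob), 1)
  expect_equal(cmp$winner, 2)
  shifted <- compare_models(F + 1000)
  expect_equal(cmp$prob, shifted$prob)
  tie <- compare_models(c(1, 1, 0))
  expect_equal(tie$winner, 1)
  expect_equal(tie$tied, c(1, 2))
  expect_error(compare_models(c(1, Inf)), "finite")
  expect_error(compare_models(numeric(0)), "empty")
})

test_that("model scoring finds a planted single-group effect", {
  gm <- parameter_group_map(mc_parameters())
  pn <- names(gm)
  set.seed(21)
  X <- build_design_matrix(as.numeric(scale(runif(14, -1, 1))),
                           names = "density")
  beta_matrix <- rbind(mean = setNames(rep(0, length(pn)), pn),
                       density = setNames(0.5 * (gm == "deep_GABA"), pn))
  posts <- fake_posteriors(X, beta_matrix, sd = 0.03, seed = 21)
  prior <- gaussian_belief(setNames(rep(0, length(pn)), pn),
                           diag(1 / 16, length(pn)))
  peb <- fit_peb(posts, X, gm, prior)
  sc <- score_model_space(peb)
  expect_length(sc$F, 63)
  expect_true(sc$winner_mask["deep_GABA"])
  gre <- group_relative_evidence(peb)
  expect_equal(gre$ranking[1], "deep_GABA")
  expect_equal(min(gre$relative_F), 0)
})

test_that("greedy pruning removes null effects and keeps real ones", {
  gm <- parameter_group_map(mc_parameters())
  pn <- names(gm)
  set.seed(22)
  X <- build_design_matrix(as.numeric(scale(runif(14, -1, 1))),
                           names = "density")
  beta_matrix <- rbind(mean = setNames(rep(0, length(pn)), pn),
                       density = setNames(0.5 * (gm == "sup_AMPA"), pn))
  posts <- fake_posteriors(X, beta_matrix, sd = 0.03, seed = 22)
  prior <- gaussian_belief(setNames(rep(0, length(pn)), pn),
                           diag(1 / 16, length(pn)))
  peb <- fit_peb(posts, X, gm, prior)
  pruned <- prune_parameters(peb)
  expect_gte(pruned$dF, 0)
  planted <- paste0("density:", pn[gm == "sup_AMPA"])
  expect_true(all(planted %in% pruned$retained))
  expect_true(all(pruned$probability[planted] > 0.9))
  # most null effects should be pruned away
  nulls <- paste0("density:", pn[gm != "sup_AMPA"])
  expect_gt(sum(nulls %in% pruned$removed), length(nulls) / 2)
})
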