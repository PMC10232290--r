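test_that("populations and template have the canonical layout", {
  pops <- mc_populations()
  expect_equal(pops$label, c("ss", "sp", "si", "dp", "tp", "di"))
  expect_equal(mc_receptors(), c("AMPA", "NMDA", "GABA"))
  tmpl <- mc_template()
  expect_equal(nrow(tmpl), 22)            # 8 AMPA + 8 NMDA + 6 GABA
  expect_equal(sum(tmpl$flagged), 16)     # every glutamatergic edge
  expect_true(all(tmpl$src[tmpl$receptor == "GABA"] %in% c("si", "di")))
  expect_false(any(tmpl$src[tmpl$receptor != "GABA"] %in% c("si", "di")))
  bad <- tmpl
  bad$src[1] <- "si"                      # interneuron sourcing AMPA
  expect_error(mc_parameters(template = bad), "excitatory")
})

test_that("mc_parameters exposes 39 free parameters and validates", {
  p <- mc_parameters()
  expect_equal(length(p$free_names), 39)  # 22 gains + 16 b + input
  expect_equal(sum(grepl("^g_", p$free_names)), 23)
  expect_equal(sum(grepl("^b_", p$free_names)), 16)
  expect_true("g_input" %in% p$free_names)
  expect_error(mc_parameters(constants = list(VE = -100)), "reversal")
  expect_error(mc_parameters(gamma = -1), "non-negative")
  expect_error(mc_parameters(gamma = c(bogus_edge = 1)), "unknown edge")
  expect_error(mc_parameters(obs = list(w = rep(0, 6))), "nonzero weight")
  expect_error(mc_parameters(lambda = c(nope = 1)), "unknown free")
  expect_error(with_lambda(p, c(nope = 1)), "unknown free")
})

test_that("firing rate and NMDA gate have the right shape", {
  p <- mc_parameters()
  V <- seq(-90, 0, by = 1)
  fr <- firing_rate(V, p)
  expect_true(all(fr > 0 & fr < 1))
  expect_true(all(diff(fr) > 0))
  expect_equal(firing_rate(p$constants$thresh, p), 0.5)
  g <- nmda_gate(V, p)
  expect_true(all(g > 0 & g < 1))
  expect_true(all(diff(g) > 0))
  expect_lt(nmda_gate(-70, p), 0.1)      # mostly Mg-blocked at rest
  expect_gt(nmda_gate(40, p), 0.9)       # block relieved when depolarized
})

test_that("connectivity applies gains and condition effects", {
  lam <- c(g_AMPA_ss_sp = 0.5, b_AMPA_ss_sp = 0.3)
  p <- mc_parameters(lambda = lam)
  std <- build_connectivity(p, "standard")
  dev <- build_connectivity(p, "deviant")
  g0 <- p$gamma["AMPA_ss_sp"]
  expect_equal(unname(std$AMPA["sp", "ss"]), unname(g0 * exp(0.5)))
  expect_equal(unname(dev$AMPA["sp", "ss"]), unname(g0 * exp(0.8)))
  # GABA edges are never condition-modulated
  expect_equal(std$GABA, dev$GABA)
  expect_error(build_connectivity(p, "odd"), "unknown condition")
})

test_that("steady state is a fixed point of the dynamics", {
  p <- mc_parameters()
  for (cond in c("standard", "deviant")) {
    ss <- steady_state(p, cond)
    d <- state_derivative(ss, p, input_value = 0, condition = cond)
    expect_lt(max(abs(d)), 1e-8)
    expect_true(all(ss[1:6] > p$constants$VI & ss[1:6] < p$constants$VE))
  }
})

test_that("state_derivative rejects non-finite states", {
  p <- mc_parameters()
  s <- rep(0, 24); s[3] <- NaN
  expect_error(state_derivative(s, p), "non-finite")
})

test_that("parameter serialization round-trips exactly", {
  p <- mc_parameters(lambda = c(g_AMPA_ss_sp = 0.25, g_input = -0.1))
  path <- withr::local_tempfile(fileext = ".json")
  write_mc_parameters(p, path)
  q <- read_mc_parameters(path)
  expect_identical(q$lambda, p$lambda)
  expect_identical(q$gamma, p$gamma)
  expect_identical(q$prior_variance, p$prior_variance)
  expect_identical(q$constants$tau, p$constants$tau)
  expect_equal(simulate_erf_pair(q)$standard$amplitude,
               simulate_erf_pair(p)$standard$amplitude)
})
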