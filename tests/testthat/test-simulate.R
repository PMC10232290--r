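test_that("epoch grid matches the paradigm", {
  t <- erf_times()
  expect_equal(length(t), 251)
  expect_equal(t[1], -100)
  expect_equal(t[length(t)], 400)
  expect_equal(unique(diff(t)), 2)
})

test_that("stimulus input is a truncated non-negative bump", {
  t <- erf_times()
  u <- stimulus_input(t, list(onset = 100, width = 20, amplitude = 2))
  expect_true(all(u[t < 0] == 0))
  expect_true(all(u >= 0))
  expect_equal(t[which.max(u)], 100)
  expect_error(stimulus_input(t, list(onset = 100, width = 0,
                                      amplitude = 1)), "width")
})

test_that("erf_trace validates its grid and values", {
  expect_error(erf_trace(c(0, 2, 1), rep(0, 3)), class =
                 "microdcm_nonuniform_grid")
  expect_error(erf_trace(c(0, 1, 2), c(0, NaN, 0)), class =
                 "microdcm_nonfinite_amplitude")
  expect_error(erf_trace(1:3, 1:2), "lengths differ")
})

test_that("pre-stimulus samples stay at baseline", {
  p <- mc_parameters(lambda = c(b_AMPA_ss_sp = 0.3, g_AMPA_ss_sp = 0.2))
  pair <- simulate_erf_pair(p)
  pre <- pair$standard$time_ms < 0
  expect_lt(max(abs(pair$standard$amplitude[pre])), 1e-6)
  expect_lt(max(abs(pair$deviant$amplitude[pre])), 1e-6)
})

test_that("conditions are identical when all b = 0", {
  p <- mc_parameters()           # all lambda zero, including every b
  pair <- simulate_erf_pair(p)
  expect_equal(pair$standard$amplitude, pair$deviant$amplitude,
               tolerance = 1e-12)
})

test_that("halving the integration step barely changes the trace", {
  p <- mc_parameters(lambda = c(b_AMPA_ss_sp = 0.2))
  a1 <- simulate_erf_pair(p, dt = 1)$deviant$amplitude
  a2 <- simulate_erf_pair(p, dt = 0.5)$deviant$amplitude
  expect_lt(sqrt(mean((a1 - a2)^2)) / max(abs(a1)), 1e-3)
})

test_that("integrate + observe reproduces the fused prediction", {
  p <- mc_parameters(lambda = c(b_AMPA_ss_sp = 0.2))
  traj <- integrate_microcircuit(p, "deviant")
  tr <- observe(traj, p$obs, "deviant")
  pair <- simulate_erf_pair(p)
  expect_lt(max(abs(tr$amplitude - pair$deviant$amplitude)), 1e-8)
  expect_error(integrate_microcircuit(p, dt = 0.3), "divide")
})

test_that("ymax picks the windowed peak of the difference wave", {
  t <- erf_times()
  d <- numeric(length(t))
  d[t == 150] <- -0.7            # inside the window, negative deflection
  d[t == 300] <- 2               # larger but outside the window
  s <- erf_trace(t, numeric(length(t)), "standard")
  v <- erf_trace(t, d, "deviant")
  expect_equal(ymax(s, v), 0.7)
  expect_equal(ymax(s, v, window = c(250, 350)), 2)
  expect_error(ymax(s, v, window = c(-500, 0)), "outside")
  s2 <- erf_trace(t + 1, numeric(length(t)))
  expect_error(ymax(s2, v), "share a time grid")
})

test_that("the evoked difference peaks inside the mismatch window", {
  # condition effects on all flagged edges, as in the cohort generator
  p <- mc_parameters()
  lam <- setNames(rep(0, length(p$free_names)), p$free_names)
  lam[grep("^b_", names(lam))] <- 0.2
  pair <- simulate_erf_pair(with_lambda(p, lam))
  diffw <- abs(pair$deviant$amplitude - pair$standard$amplitude)
  y <- ymax(pair$standard, pair$deviant)
  expect_gt(y, 0.05)                      # a clear mismatch response
  expect_gt(y, 0.9 * max(diffw))          # window captures the global peak
})
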