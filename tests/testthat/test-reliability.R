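test_that("icc2 matches the ANOVA brute force", {
  set.seed(31)
  m <- matrix(rnorm(24), 8, 3) + rnorm(8)
  ours <- icc2(m)
  ref <- icc2_bruteforce(m)
  expect_equal(ours$icc, ref$icc, tolerance = 1e-12)
  expect_equal(ours$p, ref$p, tolerance = 1e-12)
})

test_that("icc2 behaves at the extremes and validates", {
  subj <- rnorm(10, sd = 3)
  perfect <- cbind(subj, subj)
  expect_equal(icc2(perfect)$icc, 1)
  expect_equal(icc2(perfect)$p, 0)
  set.seed(32)
  indep <- matrix(rnorm(2000), 1000, 2)     # no subject effect
  expect_lt(abs(icc2(indep)$icc), 0.1)
  expect_error(icc2(matrix(0, 2, 2)), "n >= 3")
  expect_error(icc2(matrix(c(1, NA, 2, 3, 4, 5), 3, 2)), "finite")
  expect_error(icc2(matrix(5, 4, 2)), "zero total variance")
})

test_that("split_halves partitions by trial parity", {
  m <- matrix(seq_len(5 * 6), 5, 6)
  tr <- erf_trials(0:4 * 2, m, "deviant")
  h <- split_halves(tr)
  expect_equal(h$odd$amplitude, rowMeans(m[, c(1, 3, 5)]))
  expect_equal(h$even$amplitude, rowMeans(m[, c(2, 4, 6)]))
  expect_equal(attr(h$odd, "condition"), "deviant")
  expect_error(split_halves(erf_trials(0:4, m[, 1, drop = FALSE])),
               "at least 2")
})

test_that("reliability_report scores F, components and parameters", {
  # fabricated inversion results: subject signal + small split noise
  set.seed(33)
  n <- 10
  subj_F <- rnorm(n, -100, 10)
  subj_p <- rnorm(n, 0.2, 0.3)
  mk <- function(jitter) lapply(seq_len(n), function(i) {
    dec <- c(accuracy_states = subj_F[i] + rnorm(1, 0, jitter),
             accuracy_parameters = -1, accuracy_precision = 0,
             complexity_states = 0,
             complexity_parameters = 5, complexity_precision = 0.1)
    structure(list(F = subj_F[i] + rnorm(1, 0, jitter),
                   posterior = gaussian_belief(
                     c(g_a = subj_p[i] + rnorm(1, 0, jitter / 10),
                       g_b = 0.5), diag(0.01, 2)),
                   decomposition = dec), class = "mc_inversion")
  })
  odd <- setNames(mk(1), paste0("s", 1:n))
  even <- setNames(mk(1), paste0("s", 1:n))
  rep_ <- reliability_report(odd, even)
  expect_s3_class(rep_, "mc_reliability")
  tab <- rep_$measures
  expect_true(all(c("F", "accuracy_states", "complexity_parameters",
                    "g_a", "g_b") %in% tab$measure))
  expect_gt(tab$icc[tab$measure == "F"], 0.9)
  expect_gt(rep_$fe_r2, 0.9)
  # a measure with no between-subject variance reports NA
  expect_true(is.na(tab$icc[tab$measure == "g_b"]))
  expect_true(is.na(tab$icc[tab$measure == "complexity_precision"]))
  names(even)[1] <- "zz"
  expect_error(reliability_report(odd, even), "aligned")
})

test_that("significance labels follow the reported thresholds", {
  expect_equal(microdcm:::significance_label(1e-5), "p < 0.0001")
  expect_equal(microdcm:::significance_label(0.001), "p < 0.005")
  expect_equal(microdcm:::significance_label(0.03), "p < 0.05")
  expect_equal(microdcm:::significance_label(0.2), "n.s.")
})
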