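vol <- haggard_conditions()$voluntary

test_that("baseline sampling reproduces the reported moments and is deterministic", {
  tab <- sample_trials(vol, n = 35000, seed = 2)
  se_mean <- 66 / sqrt(35000)
  expect_lt(abs(mean(tab$tau_A) - 6), 3 * se_mean)
  expect_lt(abs(sd(tab$tau_A) - 66), 3 * 66 / sqrt(2 * 35000))
  expect_lt(abs(mean(tab$tau_O) - 265), 3 * 72 / sqrt(35000))
  # identical (spec, n, seed) give identical tables
  expect_identical(tab, sample_trials(vol, n = 35000, seed = 2))
  expect_false(identical(tab$tau_A, sample_trials(vol, 35000, seed = 3)$tau_A))
})

test_that("baseline mode forces the acausal branch", {
  tab <- sample_trials(vol, n = 500, seed = 1)
  expect_true(all(tab$xi_hat == 0L))
  expect_identical(tab$t_hat_A, tab$tau_A)
  expect_identical(tab$t_hat_O, tab$tau_O)
  expect_true(all(tab$r == 0) && all(tab$cce == 0))
})

test_that("a near-degenerate jitter collapses samples onto the delayed truth", {
  tight <- condition_spec("tight",
                          baseline_params(6, 1e-6, 15, 1e-6),
                          causal_prior(230, 10, 0.9))
  tab <- sample_trials(tight, n = 100, seed = 1)
  expect_equal(tab$tau_A, rep(6, 100), tolerance = 1e-4)
  expect_equal(tab$tau_O, rep(265, 100), tolerance = 1e-4)
})

test_that("operant runs fill MAP estimates and show net binding for m > 0", {
  op <- run_operant(vol, n = 35000, seed = 4)
  # detection frequency agrees with the closed-form probability
  p_c <- causality_probability(vol$truth, vol$baseline, vol$prior)
  expect_lt(abs(mean(op$xi_hat) - p_c),
            3 * sqrt(p_c * (1 - p_c) / nrow(op)) + 1e-3)
  # net binding: estimated intervals compressed relative to sensed ones
  expect_lt(mean(op$t_hat_O - op$t_hat_A), mean(op$tau_O - op$tau_A))
})

test_that("a zero causal prior makes the operant run a relabelled baseline", {
  none <- condition_spec("none", vol$baseline, causal_prior(230, 10, 0))
  base <- sample_trials(none, n = 1000, seed = 9)
  op <- run_operant(none, n = 1000, seed = 9)
  for (col in names(base)) expect_identical(base[[col]], op[[col]])
  s <- summarize_shifts(base, op)
  expect_identical(s$p_causal_empirical, 0)
  expect_lt(abs(s$mean_action_shift), 3 * 66 / sqrt(1000) * sqrt(2))
  expect_lt(abs(s$mean_outcome_shift), 3 * 72 / sqrt(1000) * sqrt(2))
})

test_that("shift summaries validate their inputs and decompose the interval", {
  base <- sample_trials(vol, 2000, seed = 1)
  op <- run_operant(vol, 2000, seed = 2)
  s <- summarize_shifts(base, op)
  expect_equal(s$interval_shift, s$mean_outcome_shift - s$mean_action_shift,
               tolerance = 1e-10)
  other <- haggard_conditions()$involuntary
  expect_error(summarize_shifts(base, run_operant(other, 2000, seed = 2)),
               "different conditions")
  expect_error(summarize_shifts(op, op), "baseline-mode")
})

test_that("disparity binning recovers global and local structure", {
  op <- run_operant(vol, n = 20000, seed = 6)
  disp <- op$tau_O - op$tau_A
  # one bin spanning the full range recovers the global mean and SD
  whole <- bin_by_disparity(op, bin_width = diff(range(disp)) + 1)
  expect_identical(nrow(whole), 1L)
  expect_equal(whole$mean, mean(op$t_hat_O - op$t_hat_A))
  expect_equal(whole$sd, sd(op$t_hat_O - op$t_hat_A))
  # bins near mu_AO: estimated intervals pulled onto the prior delay
  bins <- bin_by_disparity(op, bin_width = 50)
  near <- bins[abs(bins$bin_mid - 230) <= 25, ]
  expect_true(all(abs(near$mean - 230) < 5))
  # baseline table: identity mapping, per-bin mean tracks the bin centre
  base <- sample_trials(vol, n = 20000, seed = 6)
  bb <- bin_by_disparity(base, bin_width = 100)
  big <- bb[bb$n > 200, ]
  expect_true(all(abs(big$mean - big$bin_mid) < 30))
  expect_error(bin_by_disparity(op, bin_width = 0), "bin_width")
})
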