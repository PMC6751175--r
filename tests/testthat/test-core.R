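vol_base <- baseline_params(6, 66, 15, 72)
vol_prior <- causal_prior(230, 10, 0.9)

test_that("total variance sums the three jitter variances", {
  expect_equal(total_variance(vol_base, vol_prior), 9640)
  expect_equal(total_variance(baseline_params(83, 83, 15, 72), vol_prior),
               12173)
})

test_that("log prior odds match the normalised-prior expression", {
  expect_equal(log_prior_odds(vol_prior), 4.497162, tolerance = 1e-6)
  expect_equal(log_prior_odds(causal_prior(230, 10, 0.5)), 2.299937,
               tolerance = 1e-6)
  # p chosen so that p*T = (1-p)*sqrt(2*pi)*sigma_AO gives odds of exactly 1
  p0 <- sqrt(2 * pi) * 10 / (250 + sqrt(2 * pi) * 10)
  expect_equal(log_prior_odds(causal_prior(230, 10, p0)), 0, tolerance = 1e-12)
})

test_that("posterior ratio follows the closed form and its limits", {
  expect_equal(posterior_ratio(0, 260, vol_base, vol_prior), 85.66817,
               tolerance = 1e-6)
  # boundary: disparity exactly sqrt(2*theta)*sigma_tot from mu_AO gives r = 1
  w <- sqrt(2 * log_prior_odds(vol_prior) * total_variance(vol_base, vol_prior))
  expect_equal(posterior_ratio(0, 230 + w, vol_base, vol_prior), 1,
               tolerance = 1e-12)
  # zero prior mass on causality forces r = 0 for any sample
  none <- causal_prior(230, 10, 0)
  expect_identical(posterior_ratio(c(0, 50), c(260, 100), vol_base, none),
                   c(0, 0))
})

test_that("MAP estimate shifts timings only when causality is detected", {
  est <- map_estimate(0, 260, vol_base, vol_prior)
  expect_equal(est$t_hat_A, 13.55602, tolerance = 1e-5)
  expect_equal(est$t_hat_O, 243.86722, tolerance = 1e-5)
  expect_identical(est$xi_hat, 1L)

  # perfect consistency with the prior delay: detected but zero shift
  est0 <- map_estimate(10, 240, vol_base, vol_prior)
  expect_identical(est0$xi_hat, 1L)
  expect_equal(est0$t_hat_A, 10)
  expect_equal(est0$t_hat_O, 240)

  # acausal branch: estimates equal the sensory samples exactly
  est_far <- map_estimate(0, 800, vol_base, vol_prior)
  expect_identical(est_far$xi_hat, 0L)
  expect_identical(est_far$t_hat_A, 0)
  expect_identical(est_far$t_hat_O, 800)
  expect_lt(est_far$r, 1)
})

test_that("detected shifts conserve the interval change and pull towards mu_AO", {
  set.seed(11)
  st2 <- total_variance(vol_base, vol_prior)
  for (i in 1:50) {
    tau_A <- rnorm(1, 6, 66); tau_O <- rnorm(1, 265, 72)
    est <- map_estimate(tau_A, tau_O, vol_base, vol_prior)
    if (est$xi_hat == 1L) {
      dev <- tau_O - tau_A - 230
      # action and outcome shifts differ by the full interval compression
      expect_equal((est$t_hat_A - tau_A) - (est$t_hat_O - tau_O),
                   (66^2 + 72^2) / st2 * dev, tolerance = 1e-10)
      # estimated interval lies strictly between the sensed one and mu_AO
      if (abs(dev) > 1e-9) {
        int <- est$t_hat_O - est$t_hat_A
        expect_true(int > min(tau_O - tau_A, 230) &&
                    int < max(tau_O - tau_A, 230))
      }
    } else {
      expect_identical(est$t_hat_A, tau_A)
      expect_identical(est$t_hat_O, tau_O)
    }
  }
})

test_that("detection probability follows the erf closed form", {
  expect_equal(causality_probability(true_timings(), vol_base, vol_prior),
               0.9962506, tolerance = 1e-6)
  # zero causal prior closes the detection window entirely
  expect_identical(
    causality_probability(true_timings(), vol_base, causal_prior(230, 10, 0)),
    0)
  # m = 0 collapses the two erf terms into one
  b0 <- baseline_params(d_A = 20, sigma_A = 66, d_O = 0, sigma_O = 72)
  w <- sqrt(2 * log_prior_odds(vol_prior) * total_variance(b0, vol_prior))
  expect_equal(causality_probability(true_timings(), b0, vol_prior),
               2 * pnorm(w / sqrt(66^2 + 72^2)) - 1, tolerance = 1e-12)
})

test_that("CCE is positive, peaked at the prior delay, and vanishes at p = 0", {
  expect_equal(cce(0, 230, vol_base, vol_prior), 2.964156e-4,
               tolerance = 1e-5)
  expect_identical(cce(0, 230, vol_base, causal_prior(230, 10, 0)), 0)
  # strictly decreasing in the deviation of the disparity from mu_AO
  vals <- cce(0, 230 + c(0, 50, 100, 200), vol_base, vol_prior)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0))
})

test_that("very diffuse causal jitter drives detected shifts to zero smoothly", {
  # p high enough that causality is still detected as sigma_AO grows;
  # the shift coefficients sigma^2 / sigma_tot^2 then collapse smoothly
  shifts <- sapply(c(10, 100, 1000), function(s_AO) {
    est <- map_estimate(0, 330, vol_base, causal_prior(230, s_AO, 0.99))
    expect_identical(est$xi_hat, 1L)
    abs(est$t_hat_A - est$tau_A)
  })
  expect_true(all(diff(shifts) < 0))
  expect_lt(shifts[3], 0.5)
})
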