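# Independent oracles: brute-force maximisation and numeric integration of
# the joint density P(tau_A, tau_O, t_A, t_O, xi) =
# P(tau_A|t_A) P(tau_O|t_O) P(t_A, t_O|xi) P(xi), without using any of the
# package's closed forms.

oracle_joint_causal <- function(t_A, t_O, tau_A, tau_O, b, pr) {
  Z1 <- sqrt(2 * pi) * pr$sigma_AO * pr$T
  pr$p_causal / Z1 *
    dnorm(tau_A, t_A, b$sigma_A) * dnorm(tau_O, t_O, b$sigma_O) *
    exp(-(t_O - t_A - pr$mu_AO)^2 / (2 * pr$sigma_AO^2))
}

oracle_joint_acausal <- function(t_A, t_O, tau_A, tau_O, b, pr) {
  Z0 <- pr$T^2
  (1 - pr$p_causal) / Z0 *
    dnorm(tau_A, t_A, b$sigma_A) * dnorm(tau_O, t_O, b$sigma_O)
}

# grid maximisation of the causal joint over (t_A, t_O), refined around the
# running argmax until the spacing is below `tol`
oracle_causal_peak <- function(tau_A, tau_O, b, pr, tol = 0.005) {
  half_A <- 4 * b$sigma_A + abs(pr$mu_AO)
  half_O <- 4 * b$sigma_O + abs(pr$mu_AO)
  cA <- tau_A; cO <- tau_O
  repeat {
    tA <- seq(cA - half_A, cA + half_A, length.out = 121)
    tO <- seq(cO - half_O, cO + half_O, length.out = 121)
    vals <- outer(tA, tO, oracle_joint_causal,
                  tau_A = tau_A, tau_O = tau_O, b = b, pr = pr)
    idx <- arrayInd(which.max(vals), dim(vals))
    cA <- tA[idx[1]]; cO <- tO[idx[2]]
    step <- tA[2] - tA[1]
    if (step < tol) break
    half_A <- 3 * step; half_O <- 3 * (tO[2] - tO[1])
  }
  list(t_A = cA, t_O = cO, peak = max(vals))
}

# brute-force MAP: compare the causal grid peak with the analytic acausal
# peak at (tau_A, tau_O) and return estimate + peak ratio
oracle_map <- function(tau_A, tau_O, b, pr) {
  peak0 <- oracle_joint_acausal(tau_A, tau_O, tau_A, tau_O, b, pr)
  cp <- oracle_causal_peak(tau_A, tau_O, b, pr)
  r <- cp$peak / peak0
  if (r > 1) list(t_A = cp$t_A, t_O = cp$t_O, xi = 1L, r = r)
  else list(t_A = tau_A, t_O = tau_O, xi = 0L, r = r)
}

# direct CCE: causal grid peak divided by the 2-D trapezoid marginalisation
# of both branches. The integration domain is wide enough (+/- 8 SD around
# the sensory samples) to capture effectively all posterior mass, matching
# the full-plane Gaussian integrals behind the closed form.
oracle_cce <- function(tau_A, tau_O, b, pr, n_grid = 501) {
  tA <- seq(tau_A - 8 * b$sigma_A, tau_A + 8 * b$sigma_A,
            length.out = n_grid)
  tO <- seq(tau_O - 8 * b$sigma_O, tau_O + 8 * b$sigma_O,
            length.out = n_grid)
  wA <- rep(tA[2] - tA[1], n_grid); wA[c(1, n_grid)] <- wA[1] / 2
  wO <- rep(tO[2] - tO[1], n_grid); wO[c(1, n_grid)] <- wO[1] / 2
  m1 <- outer(tA, tO, oracle_joint_causal,
              tau_A = tau_A, tau_O = tau_O, b = b, pr = pr)
  m0 <- outer(tA, tO, oracle_joint_acausal,
              tau_A = tau_A, tau_O = tau_O, b = b, pr = pr)
  marginal <- as.numeric(wA %*% (m1 + m0) %*% wO)
  oracle_causal_peak(tau_A, tau_O, b, pr)$peak / marginal
}

# random-but-reproducible parameter/sample draws for property tests
random_case <- function() {
  b <- baseline_params(d_A = runif(1, -50, 120), sigma_A = runif(1, 25, 110),
                       d_O = runif(1, -50, 120), sigma_O = runif(1, 25, 110))
  pr <- causal_prior(mu_AO = runif(1, 150, 300), sigma_AO = runif(1, 5, 40),
                     p_causal = runif(1, 0.05, 0.95))
  truth <- true_timings()
  tau_A <- rnorm(1, truth$t_A + b$d_A, b$sigma_A)
  tau_O <- rnorm(1, truth$t_O + b$d_O, b$sigma_O)
  list(b = b, pr = pr, truth = truth, tau_A = tau_A, tau_O = tau_O)
}

# the six published experimental conditions
all_paper_conditions <- function() {
  c(haggard_conditions(), wolpe_conditions())
}
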