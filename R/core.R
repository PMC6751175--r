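#' Total variance of the causal timing geometry
#'
#' Returns `sigma_tot^2 = sigma_A^2 + sigma_O^2 + sigma_AO^2`, the variance
#' that scales both the perceptual-shift coefficients and the width of the
#' causality-detection window.
#'
#' @param baseline A [baseline_params()] object.
#' @param prior A [causal_prior()] object.
#' @return Total variance (ms^2).
#' @examples
#' total_variance(baseline_params(6, 66, 15, 72), causal_prior(230, 10, 0.9))
#' @export
total_variance <- function(baseline, prior) {
  stopifnot(inherits(baseline, "baseline_params"),
            inherits(prior, "causal_prior"))
  baseline$sigma_A^2 + baseline$sigma_O^2 + prior$sigma_AO^2
}

#' Log prior odds of the causal hypothesis
#'
#' Returns `theta = log[p * Z0 / ((1 - p) * Z1)]` with `Z0 = T^2` and
#' `Z1 = sqrt(2*pi) * sigma_AO * T`, i.e. the log odds of the two prior
#' branches after normalisation over the finite window. `theta` is finite
#' for `p_causal` in `(0, 1)` and `-Inf` for the degenerate `p_causal = 0`
#' (causality is then never inferred).
#'
#' @param prior A [causal_prior()] object.
#' @return The dimensionless log prior odds `theta`.
#' @examples
#' log_prior_odds(causal_prior(230, 10, 0.9))  # ~4.497
#' @export
log_prior_odds <- function(prior) {
  stopifnot(inherits(prior, "causal_prior"))
  p <- prior$p_causal
  if (p == 0) return(-Inf)
  log(p * prior$T / ((1 - p) * sqrt(2 * pi) * prior$sigma_AO))
}

#' Posterior peak ratio between the causal and acausal hypotheses
#'
#' For sensory arrival times `tau_A`, `tau_O`, returns
#' `r = exp(theta - (tau_O - tau_A - mu_AO)^2 / (2 * sigma_tot^2))`,
#' the ratio of the posterior density at the causal peak to that at the
#' acausal peak. Causality is detected when `r > 1`. With `p_causal = 0`
#' the ratio is 0 for any sample.
#'
#' @param tau_A,tau_O Sensory arrival times (ms); vectors of equal length
#'   (or one may be length 1 and is recycled).
#' @param baseline A [baseline_params()] object.
#' @param prior A [causal_prior()] object.
#' @return The ratio `r >= 0`, one value per trial.
#' @examples
#' posterior_ratio(0, 260, baseline_params(6, 66, 15, 72),
#'                 causal_prior(230, 10, 0.9))  # ~85.7
#' @export
posterior_ratio <- function(tau_A, tau_O, baseline, prior) {
  stopifnot(is.numeric(tau_A), is.numeric(tau_O))
  theta <- log_prior_odds(prior)
  if (!is.finite(theta) && theta < 0)
    return(rep_len(0, max(length(tau_A), length(tau_O))))
  dev <- tau_O - tau_A - prior$mu_AO
  exp(theta - dev^2 / (2 * total_variance(baseline, prior)))
}

#' Maximum-a-posteriori timing and causality estimate
#'
#' Computes the MAP estimate `(t_hat_A, t_hat_O, xi_hat)` of the physical
#' action/outcome timings and the binary causal variable given one or more
#' sensory samples. If the posterior ratio exceeds 1, causality is inferred
#' and the two timing estimates attract each other towards the prior delay:
#' \deqn{\hat t_A = \tau_A + \frac{\sigma_A^2}{\sigma_{tot}^2}
#'       (\tau_O - \tau_A - \mu_{AO}), \quad
#'       \hat t_O = \tau_O - \frac{\sigma_O^2}{\sigma_{tot}^2}
#'       (\tau_O - \tau_A - \mu_{AO}).}
#' Otherwise (`r <= 1`, the tie resolving to the acausal branch) the
#' estimates equal the sensory samples. The optimum is the unconstrained
#' quadratic peak; the finite prior window enters only through the
#' normalisation constants inside `r`.
#'
#' @inheritParams posterior_ratio
#' @return A data frame with one row per trial and columns `tau_A`, `tau_O`,
#'   `t_hat_A`, `t_hat_O`, `xi_hat` (0/1), `r` and `cce`.
#' @examples
#' map_estimate(0, 260, baseline_params(6, 66, 15, 72),
#'              causal_prior(230, 10, 0.9))
#' @export
map_estimate <- function(tau_A, tau_O, baseline, prior) {
  stopifnot(is.numeric(tau_A), is.numeric(tau_O))
  n <- max(length(tau_A), length(tau_O))
  tau_A <- rep_len(as.numeric(tau_A), n)
  tau_O <- rep_len(as.numeric(tau_O), n)
  st2 <- total_variance(baseline, prior)
  dev <- tau_O - tau_A - prior$mu_AO
  r <- posterior_ratio(tau_A, tau_O, baseline, prior)
  causal <- r > 1
  t_hat_A <- ifelse(causal, tau_A + baseline$sigma_A^2 / st2 * dev, tau_A)
  t_hat_O <- ifelse(causal, tau_O - baseline$sigma_O^2 / st2 * dev, tau_O)
  data.frame(tau_A = tau_A, tau_O = tau_O,
             t_hat_A = t_hat_A, t_hat_O = t_hat_O,
             xi_hat = as.integer(causal), r = r,
             cce = cce(tau_A, tau_O, baseline, prior))
}

#' Probability of detecting causality
#'
#' Closed-form probability that a trial's posterior ratio exceeds 1.
#' The disparity `tau_O - tau_A - mu_AO` is Gaussian with mean
#' `m = t_O* - t_A* + d_O - d_A - mu_AO` and variance
#' `sigma_A^2 + sigma_O^2`; causality is detected when its magnitude falls
#' below `sqrt(2*theta) * sigma_tot`, hence
#' \deqn{P_c = \tfrac12\left[\mathrm{erf}\!\left(\frac{\sqrt{2\theta}\,
#'   \sigma_{tot} - m}{\sqrt{2(\sigma_A^2+\sigma_O^2)}}\right) +
#'   \mathrm{erf}\!\left(\frac{\sqrt{2\theta}\,\sigma_{tot} + m}
#'   {\sqrt{2(\sigma_A^2+\sigma_O^2)}}\right)\right],}
#' clipped to `[0, 1]`. With `p_causal = 0` (or `theta <= 0` more generally
#' producing an empty window) the detection probability is 0.
#'
#' @param truth A [true_timings()] object.
#' @param baseline A [baseline_params()] object.
#' @param prior A [causal_prior()] object.
#' @return Detection probability in `[0, 1]`.
#' @examples
#' causality_probability(true_timings(), baseline_params(6, 66, 15, 72),
#'                       causal_prior(230, 10, 0.9))  # ~0.996
#' @export
causality_probability <- function(truth, baseline, prior) {
  stopifnot(inherits(truth, "true_timings"))
  theta <- log_prior_odds(prior)
  if (theta <= 0) return(0)
  m <- truth$t_O - truth$t_A + baseline$d_O - baseline$d_A - prior$mu_AO
  w <- sqrt(2 * theta) * sqrt(total_variance(baseline, prior))
  s <- sqrt(2 * (baseline$sigma_A^2 + baseline$sigma_O^2))
  p <- 0.5 * (erf((w - m) / s) + erf((w + m) / s))
  min(max(p, 0), 1)
}

#' Confidence in the causal estimate (CCE)
#'
#' The peak posterior density of the causal hypothesis given the sensory
#' inputs, proposed as a quantitative measure of the feeling of agency:
#' \deqn{CCE = \frac{\sigma_{tot}}{2\pi\,\sigma_A\sigma_O\sigma_{AO}}\,
#'   \mathrm{Sigmoid}\!\left(\theta -
#'   \frac{(\tau_O - \tau_A - \mu_{AO})^2}{2\sigma_{tot}^2} +
#'   \log\frac{\sigma_{AO}}{\sigma_{tot}}\right)} in density units
#' (ms^-2). CCE is strictly positive for `p_causal` in `(0, 1)`, maximal
#' when the sensory disparity matches the prior delay, and 0 when
#' `p_causal = 0`.
#'
#' @inheritParams posterior_ratio
#' @return CCE values (ms^-2), one per trial.
#' @examples
#' cce(0, 230, baseline_params(6, 66, 15, 72), causal_prior(230, 10, 0.9))
#' @export
cce <- function(tau_A, tau_O, baseline, prior) {
  stopifnot(is.numeric(tau_A), is.numeric(tau_O))
  theta <- log_prior_odds(prior)
  n <- max(length(tau_A), length(tau_O))
  if (!is.finite(theta) && theta < 0) return(rep_len(0, n))
  st2 <- total_variance(baseline, prior)
  st <- sqrt(st2)
  dev <- tau_O - tau_A - prior$mu_AO
  pref <- st / (2 * pi * baseline$sigma_A * baseline$sigma_O * prior$sigma_AO)
  pref * sigmoid(theta - dev^2 / (2 * st2) + log(prior$sigma_AO / st))
}

# error function via pnorm; erf(x) = 2*Phi(x*sqrt(2)) - 1
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

sigmoid <- function(x) 1 / (1 + exp(-x))
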