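#' Baseline sensory parameters
#'
#' Each timing judgement in a single-event baseline condition is modelled as
#' the arrival time of a noisy sensory signal: the action signal arrives at
#' `tau_A ~ N(t_A* + d_A, sigma_A^2)` and the outcome (tone) signal at
#' `tau_O ~ N(t_O* + d_O, sigma_O^2)`. The delay `d` and jitter SD `sigma`
#' are read off the mean and SD of the reported baseline judgement errors.
#'
#' @param d_A Sensory delay of the action signal (ms). May be negative.
#' @param sigma_A SD of the action-signal jitter (ms, > 0).
#' @param d_O Sensory delay of the outcome signal (ms).
#' @param sigma_O SD of the outcome-signal jitter (ms, > 0).
#' @return An object of class `baseline_params`.
#' @examples
#' baseline_params(d_A = 6, sigma_A = 66, d_O = 15, sigma_O = 72)
#' @export
baseline_params <- function(d_A, sigma_A, d_O, sigma_O) {
  stopifnot(is.numeric(d_A), is.numeric(sigma_A),
            is.numeric(d_O), is.numeric(sigma_O))
  if (!is.finite(sigma_A) || sigma_A <= 0)
    stop("'sigma_A' must be a positive, finite SD (ms)", call. = FALSE)
  if (!is.finite(sigma_O) || sigma_O <= 0)
    stop("'sigma_O' must be a positive, finite SD (ms)", call. = FALSE)
  structure(list(d_A = as.numeric(d_A), sigma_A = as.numeric(sigma_A),
                 d_O = as.numeric(d_O), sigma_O = as.numeric(sigma_O)),
            class = "baseline_params")
}

#' @export
print.baseline_params <- function(x, ...) {
  cat("Baseline sensory parameters (ms):\n")
  cat(sprintf("  action : d_A = %g, sigma_A = %g\n", x$d_A, x$sigma_A))
  cat(sprintf("  outcome: d_O = %g, sigma_O = %g\n", x$d_O, x$sigma_O))
  invisible(x)
}

#' Causal prior over action-outcome timing
#'
#' Under the causal hypothesis (`xi = 1`) the outcome is believed to follow
#' the action by a typical delay `mu_AO` with Gaussian jitter of SD
#' `sigma_AO`; under the acausal hypothesis (`xi = 0`) the two timings are
#' independent and uniform. Both prior branches are normalised over a finite
#' square window of side `T` centred on the true timings, giving
#' normalisation constants `Z0 = T^2` and `Z1 ~ sqrt(2*pi)*sigma_AO*T`.
#'
#' `p_causal = 1` is rejected: the log prior odds diverge and the acausal
#' branch vanishes. `p_causal = 0` is allowed and means causality is never
#' inferred.
#'
#' @param mu_AO Typical action-to-outcome delay under the causal belief (ms).
#' @param sigma_AO SD of the causal timing jitter (ms, > 0).
#' @param p_causal Prior probability of the causal hypothesis, in `[0, 1)`.
#' @param T Window length defining the normalisation range (ms, > 0).
#' @return An object of class `causal_prior`.
#' @examples
#' causal_prior(mu_AO = 230, sigma_AO = 10, p_causal = 0.9)
#' @export
causal_prior <- function(mu_AO, sigma_AO, p_causal, T = 250) {
  stopifnot(is.numeric(mu_AO), is.numeric(sigma_AO),
            is.numeric(p_causal), is.numeric(T))
  if (!is.finite(sigma_AO) || sigma_AO <= 0)
    stop("'sigma_AO' must be a positive, finite SD (ms)", call. = FALSE)
  if (!is.finite(p_causal) || p_causal < 0 || p_causal >= 1)
    stop("'p_causal' must lie in [0, 1); p_causal = 1 makes the log prior odds diverge",
         call. = FALSE)
  if (!is.finite(T) || T <= 0)
    stop("'T' must be a positive, finite window length (ms)", call. = FALSE)
  structure(list(mu_AO = as.numeric(mu_AO), sigma_AO = as.numeric(sigma_AO),
                 p_causal = as.numeric(p_causal), T = as.numeric(T)),
            class = "causal_prior")
}

#' @export
print.causal_prior <- function(x, ...) {
  cat("Causal prior:\n")
  cat(sprintf("  mu_AO = %g ms, sigma_AO = %g ms, P(xi = 1) = %g, T = %g ms\n",
              x$mu_AO, x$sigma_AO, x$p_causal, x$T))
  cat(sprintf("  log prior odds theta = %g\n", log_prior_odds(x)))
  invisible(x)
}

#' True event timings
#'
#' The physical action and outcome times, unknown to the observer. In the
#' experiments modelled the button press defines `t_A = 0` ms and the tone
#' follows at `t_O = 250` ms.
#'
#' @param t_A True action time (ms).
#' @param t_O True outcome time (ms); must exceed `t_A`.
#' @return An object of class `true_timings`.
#' @export
true_timings <- function(t_A = 0, t_O = 250) {
  stopifnot(is.numeric(t_A), is.numeric(t_O))
  if (!is.finite(t_A) || !is.finite(t_O) || t_O <= t_A)
    stop("'t_O' must be finite and later than 't_A'", call. = FALSE)
  structure(list(t_A = as.numeric(t_A), t_O = as.numeric(t_O)),
            class = "true_timings")
}

#' @export
print.true_timings <- function(x, ...) {
  cat(sprintf("True timings: t_A* = %g ms, t_O* = %g ms\n", x$t_A, x$t_O))
  invisible(x)
}

#' Experimental condition
#'
#' Bundles the true timings, baseline sensory parameters and causal prior
#' that define one experimental condition (e.g. a voluntary button press
#' followed by a tone at 250 ms).
#'
#' @param name Condition label, a single non-empty string.
#' @param baseline A [baseline_params()] object.
#' @param prior A [causal_prior()] object.
#' @param truth A [true_timings()] object.
#' @return An object of class `condition_spec`.
#' @examples
#' condition_spec("voluntary",
#'                baseline_params(6, 66, 15, 72),
#'                causal_prior(230, 10, 0.9))
#' @export
condition_spec <- function(name, baseline, prior, truth = true_timings()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string", call. = FALSE)
  if (!inherits(baseline, "baseline_params"))
    stop("'baseline' must be a baseline_params object", call. = FALSE)
  if (!inherits(prior, "causal_prior"))
    stop("'prior' must be a causal_prior object", call. = FALSE)
  if (!inherits(truth, "true_timings"))
    stop("'truth' must be a true_timings object", call. = FALSE)
  structure(list(name = name, truth = truth,
                 baseline = baseline, prior = prior),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("Condition '%s'\n", x$name))
  print(x$truth)
  print(x$baseline)
  print(x$prior)
  m <- disparity_mean(x)
  cat(sprintf("  mean prior-relative disparity m = %g ms (%s expected on average)\n",
              m, if (m > 0) "binding" else if (m < 0) "repulsion" else "no shift"))
  invisible(x)
}

#' Mean prior-relative disparity of a condition
#'
#' Returns `m = t_O* - t_A* + d_O - d_A - mu_AO`, the mean of the per-trial
#' disparity `tau_O - tau_A - mu_AO`. Its sign determines whether binding
#' (`m > 0`) or repulsion (`m < 0`) dominates on average.
#'
#' @param spec A [condition_spec()] object.
#' @return Mean disparity relative to the prior delay (ms).
#' @export
disparity_mean <- function(spec) {
  stopifnot(inherits(spec, "condition_spec"))
  spec$truth$t_O - spec$truth$t_A +
    spec$baseline$d_O - spec$baseline$d_A - spec$prior$mu_AO
}
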