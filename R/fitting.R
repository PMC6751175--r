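#' Reported empirical perceptual shifts
#'
#' Container for the published mean perceptual shifts of one condition,
#' used as the reference the grid-search fits minimise against.
#'
#' @param condition Condition label.
#' @param action_shift Reported mean action perceptual shift (ms).
#' @param outcome_shift Reported mean outcome perceptual shift (ms).
#' @return An object of class `empirical_shifts`.
#' @examples
#' empirical_shifts("voluntary", 15, -46)
#' @export
empirical_shifts <- function(condition, action_shift, outcome_shift) {
  stopifnot(is.character(condition), length(condition) == 1L,
            is.numeric(action_shift), is.numeric(outcome_shift))
  structure(list(condition = condition,
                 action_shift = as.numeric(action_shift),
                 outcome_shift = as.numeric(outcome_shift)),
            class = "empirical_shifts")
}

#' @export
print.empirical_shifts <- function(x, ...) {
  cat(sprintf("Empirical shifts '%s': action %+g ms, outcome %+g ms\n",
              x$condition, x$action_shift, x$outcome_shift))
  invisible(x)
}

#' Admissible range of the prior action-outcome delay
#'
#' The sign of the mean prior-relative disparity
#' `m = t_O* - t_A* + d_O - d_A - mu_AO` determines whether a condition
#' produces binding (`m > 0`) or repulsion (`m < 0`) on average. Requiring
#' `m > 0` in every binding-labelled condition bounds `mu_AO` from above by
#' the smallest `t_O* - t_A* + d_O - d_A` among them; requiring `m < 0` in
#' every repulsion-labelled condition bounds it from below by the largest.
#' The result is the open interval of `mu_AO` values compatible with all
#' labels. Purely analytic; no simulation involved.
#'
#' @param conditions A list of [condition_spec()] objects.
#' @param labels Character vector (recycled names allowed), one of
#'   `"binding"` or `"repulsion"` per condition; conditions labelled
#'   anything else are ignored.
#' @return Named numeric vector `c(lower, upper)` (ms, open interval).
#' @examples
#' conds <- haggard_conditions()
#' admissible_mu_range(conds[c("voluntary", "involuntary")],
#'                     c("binding", "repulsion"))  # (182, 259)
#' @export
admissible_mu_range <- function(conditions, labels) {
  stopifnot(is.list(conditions), length(conditions) == length(labels))
  lapply(conditions, function(cc) stopifnot(inherits(cc, "condition_spec")))
  if (!any(labels == "binding") || !any(labels == "repulsion"))
    stop("need at least one binding- and one repulsion-labelled condition",
         call. = FALSE)
  delta <- vapply(conditions, function(cc) {
    cc$truth$t_O - cc$truth$t_A + cc$baseline$d_O - cc$baseline$d_A
  }, numeric(1))
  lower <- max(delta[labels == "repulsion"])
  upper <- min(delta[labels == "binding"])
  if (lower >= upper)
    stop(sprintf("infeasible: no mu_AO satisfies all labels (lower %g >= upper %g)",
                 lower, upper), call. = FALSE)
  c(lower = lower, upper = upper)
}

#' Model estimation error against reported shifts
#'
#' Absolute difference between the model's mean perceptual shifts and the
#' reported ones, in one of three variants: the action shift alone, the
#' outcome shift alone, or the mean of the two absolute differences.
#'
#' @param predicted A `shift_summary` (from [summarize_shifts()]) or any
#'   list with `mean_action_shift` and `mean_outcome_shift` elements.
#' @param empirical An [empirical_shifts()] object.
#' @param mode `"both"` (default), `"action_only"` or `"outcome_only"`.
#' @return The model estimation error (ms).
#' @examples
#' estimation_error(list(mean_action_shift = 10, mean_outcome_shift = -40),
#'                  empirical_shifts("x", 15, -46), mode = "both")  # 5.5
#' @export
estimation_error <- function(predicted, empirical,
                             mode = c("both", "action_only", "outcome_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(empirical, "empirical_shifts"),
            is.list(predicted),
            is.numeric(predicted$mean_action_shift),
            is.numeric(predicted$mean_outcome_shift))
  if (!is.null(predicted$condition) &&
      !identical(predicted$condition, empirical$condition))
    stop(sprintf("condition mismatch: predicted '%s' vs empirical '%s'",
                 predicted$condition, empirical$condition), call. = FALSE)
  da <- abs(predicted$mean_action_shift - empirical$action_shift)
  do <- abs(predicted$mean_outcome_shift - empirical$outcome_shift)
  switch(mode, action_only = da, outcome_only = do, both = (da + do) / 2)
}

#' Grid search for the prior action-outcome delay
#'
#' For each candidate `mu_AO` on the grid, simulates every condition of the
#' experiment (one baseline and one operant run per condition), computes the
#' mean perceptual shifts, measures the estimation error against the
#' reported shifts, averages the error across conditions, and returns the
#' grid value attaining the minimum. The same sensory samples are reused
#' across grid points (common random numbers), so the argmin is not blurred
#' by independent Monte-Carlo noise per grid value. Each condition keeps the
#' `p_causal`, `sigma_AO` and `T` of its own prior; only `mu_AO` is scanned.
#'
#' @param experiment A list of entries, each a list with elements `spec`
#'   (a [condition_spec()]) and `empirical` (an [empirical_shifts()]).
#' @param grid Candidate `mu_AO` values (ms); sorted ascending internally,
#'   ties in the minimum break toward the smaller value.
#' @param n Trials per condition and grid value.
#' @param seed Root seed; per-condition streams derive via [child_seed()].
#' @param mode Error variant passed to [estimation_error()].
#' @param admissible Optional `c(lower, upper)` interval (e.g. from
#'   [admissible_mu_range()]); grid values outside it trigger a warning.
#' @return A `fit_result`: list with `parameter`, `grid`, `errors`, `best`,
#'   `mode`, `n`, `seed`.
#' @export
fit_mu_ao <- function(experiment, grid = seq(190, 250, by = 10),
                      n = 35000, seed = 1L,
                      mode = c("both", "action_only", "outcome_only"),
                      admissible = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.list(experiment), length(experiment) >= 1L,
            is.numeric(grid), length(grid) >= 1L)
  grid <- sort(grid)
  if (!is.null(admissible) &&
      (any(grid <= admissible[[1]]) || any(grid >= admissible[[2]])))
    warning("some grid values fall outside the admissible mu_AO interval",
            call. = FALSE)
  draws <- lapply(experiment, function(e) fit_draws(e$spec, n, seed))
  errors <- vapply(grid, function(mu) {
    per_cond <- mapply(function(e, d) {
      prior <- causal_prior(mu, e$spec$prior$sigma_AO,
                            e$spec$prior$p_causal, e$spec$prior$T)
      estimation_error(shift_from_draws(d, e$spec$baseline, prior),
                       e$empirical, mode)
    }, experiment, draws)
    mean(per_cond)
  }, numeric(1))
  fit_result("mu_AO", grid, errors, mode, n, seed)
}

#' Grid search for the causal-prior probability
#'
#' For each candidate `p_causal` on the grid, recomputes the MAP estimates
#' of a fixed set of sensory samples (common random numbers across grid
#' points), measures the estimation error of the resulting mean shifts
#' against the reported ones, and returns the grid value attaining the
#' minimum. `mu_AO`, `sigma_AO` and `T` are taken from the condition's
#' prior and held fixed.
#'
#' @param spec A [condition_spec()]; its prior supplies `mu_AO`, `sigma_AO`
#'   and `T`.
#' @param empirical An [empirical_shifts()] object for the same condition.
#' @param grid Candidate probabilities in `[0, 1)`; ties break toward the
#'   smaller value.
#' @inheritParams fit_mu_ao
#' @return A `fit_result` (see [fit_mu_ao()]).
#' @export
fit_prior <- function(spec, empirical, grid = seq(0.1, 0.9, by = 0.1),
                      n = 35000, seed = 1L,
                      mode = c("both", "action_only", "outcome_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "condition_spec"),
            inherits(empirical, "empirical_shifts"),
            is.numeric(grid), length(grid) >= 1L,
            all(grid >= 0), all(grid < 1))
  grid <- sort(grid)
  d <- fit_draws(spec, n, seed)
  errors <- vapply(grid, function(p) {
    prior <- causal_prior(spec$prior$mu_AO, spec$prior$sigma_AO, p,
                          spec$prior$T)
    estimation_error(shift_from_draws(d, spec$baseline, prior),
                     empirical, mode)
  }, numeric(1))
  fit_result("p_causal", grid, errors, mode, n, seed)
}

# one baseline and one operant draw per condition, shared across grid points
fit_draws <- function(spec, n, seed) {
  list(baseline = sample_trials(spec, n, child_seed(seed, paste0(spec$name, "/baseline"))),
       operant_taus = draw_taus(spec, n, child_seed(seed, paste0(spec$name, "/operant"))),
       condition = spec$name)
}

shift_from_draws <- function(d, baseline, prior) {
  est <- map_estimate(d$operant_taus$tau_A, d$operant_taus$tau_O,
                      baseline, prior)
  list(condition = d$condition,
       mean_action_shift = mean(est$t_hat_A) - mean(d$baseline$tau_A),
       mean_outcome_shift = mean(est$t_hat_O) - mean(d$baseline$tau_O))
}

fit_result <- function(parameter, grid, errors, mode, n, seed) {
  structure(list(parameter = parameter, grid = grid, errors = errors,
                 best = grid[which.min(errors)], mode = mode,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Grid-search fit of %s (mode %s, n = %d, seed = %d)\n",
              x$parameter, x$mode, x$n, x$seed))
  tab <- data.frame(value = x$grid, error_ms = round(x$errors, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("best %s = %g\n", x$parameter, x$best))
  invisible(x)
}

#' Write a fit result to JSON
#'
#' @param fit A `fit_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
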