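#' Preset conditions: voluntary, involuntary and sham actions
#'
#' The three conditions of the classic intentional-binding experiment: a
#' voluntary button press, a TMS-induced involuntary muscle twitch, and a
#' sham TMS click, each followed by a tone 250 ms after the action event.
#' Baseline sensory parameters come from the reported means and SDs of the
#' baseline judgement errors (action: voluntary 6/66, involuntary 83/83,
#' sham 32/78; tone 15/72, all ms); the default causal priors are the
#' fitted values 0.9/0.9 and the assumed 0.1 for the under-constrained sham
#' condition.
#'
#' @param p_causal Named probabilities for `voluntary`, `involuntary`,
#'   `sham`.
#' @param mu_AO,sigma_AO,T Causal-prior parameters (ms), shared by all
#'   conditions.
#' @return Named list of [condition_spec()] objects.
#' @examples
#' names(haggard_conditions())
#' @export
haggard_conditions <- function(p_causal = c(voluntary = 0.9,
                                            involuntary = 0.9,
                                            sham = 0.1),
                               mu_AO = 230, sigma_AO = 10, T = 250) {
  stopifnot(all(c("voluntary", "involuntary", "sham") %in% names(p_causal)))
  base <- list(voluntary = c(d_A = 6, sigma_A = 66),
               involuntary = c(d_A = 83, sigma_A = 83),
               sham = c(d_A = 32, sigma_A = 78))
  conds <- lapply(names(base), function(nm) {
    b <- base[[nm]]
    condition_spec(nm,
                   baseline_params(b[["d_A"]], b[["sigma_A"]],
                                   d_O = 15, sigma_O = 72),
                   causal_prior(mu_AO, sigma_AO, p_causal[[nm]], T))
  })
  names(conds) <- names(base)
  conds
}

#' Preset conditions: graded outcome (tone) uncertainty
#'
#' Three conditions in which the reliability of the outcome tone is
#' manipulated against background noise (low, intermediate and high
#' uncertainty), all sharing the same voluntary-action baseline (-8/75 ms).
#' Tone baselines are 35/61, 46/66 and 95/90 ms; the default causal priors
#' are the fitted 0.9, 0.6 and 0.5, weakening as the tone becomes less
#' reliable.
#'
#' @param p_causal Named probabilities for `low`, `intermediate`, `high`.
#' @inheritParams haggard_conditions
#' @return Named list of [condition_spec()] objects.
#' @export
wolpe_conditions <- function(p_causal = c(low = 0.9,
                                          intermediate = 0.6,
                                          high = 0.5),
                             mu_AO = 230, sigma_AO = 10, T = 250) {
  stopifnot(all(c("low", "intermediate", "high") %in% names(p_causal)))
  tones <- list(low = c(d_O = 35, sigma_O = 61),
                intermediate = c(d_O = 46, sigma_O = 66),
                high = c(d_O = 95, sigma_O = 90))
  conds <- lapply(names(tones), function(nm) {
    tn <- tones[[nm]]
    condition_spec(nm,
                   baseline_params(d_A = -8, sigma_A = 75,
                                   d_O = tn[["d_O"]], sigma_O = tn[["sigma_O"]]),
                   causal_prior(mu_AO, sigma_AO, p_causal[[nm]], T))
  })
  names(conds) <- names(tones)
  conds
}

#' Packaged table of reported perceptual shifts
#'
#' Loads the published mean action and outcome perceptual shifts used as
#' fitting references, for either experiment.
#'
#' @param set `"haggard"` or `"wolpe"`.
#' @return A data frame with columns `condition`, `action_shift_ms`,
#'   `outcome_shift_ms`.
#' @export
empirical_shift_table <- function(set = c("haggard", "wolpe")) {
  set <- match.arg(set)
  path <- system.file("extdata", "empirical_shifts.csv",
                      package = "causalbind", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab[tab$set == set, c("condition", "action_shift_ms", "outcome_shift_ms")]
}

#' Empirical shifts of one condition from the packaged table
#'
#' @param set `"haggard"` or `"wolpe"`.
#' @param condition Condition name within the set.
#' @return An [empirical_shifts()] object.
#' @export
empirical_shifts_for <- function(set, condition) {
  tab <- empirical_shift_table(set)
  row <- tab[tab$condition == condition, , drop = FALSE]
  if (nrow(row) != 1L)
    stop(sprintf("no condition '%s' in set '%s'", condition, set),
         call. = FALSE)
  empirical_shifts(condition, row$action_shift_ms, row$outcome_shift_ms)
}
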