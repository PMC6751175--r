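#' Simulate baseline trials for a condition
#'
#' Draws `n` independent sensory samples `tau_A ~ N(t_A* + d_A, sigma_A^2)`
#' and `tau_O ~ N(t_O* + d_O, sigma_O^2)`. In the baseline mode the observer
#' judges each event in isolation, so the timing estimates equal the sensory
#' samples and the acausal branch is forced: `xi_hat = 0`, `r = 0`,
#' `cce = 0` for every trial.
#'
#' @param spec A [condition_spec()] object.
#' @param n Number of trials (>= 1).
#' @param seed Integer seed; identical `(spec, n, seed)` give identical
#'   tables.
#' @return A `trial_table`: a data frame with columns `trial`, `tau_A`,
#'   `tau_O`, `t_hat_A`, `t_hat_O`, `xi_hat`, `r`, `cce` and attributes
#'   `condition`, `mode`, `n`, `seed`.
#' @examples
#' vol <- haggard_conditions()$voluntary
#' head(sample_trials(vol, n = 100, seed = 1))
#' @export
sample_trials <- function(spec, n, seed = 1L) {
  tab <- draw_taus(spec, n, seed)
  tab$t_hat_A <- tab$tau_A
  tab$t_hat_O <- tab$tau_O
  tab$xi_hat <- 0L
  tab$r <- 0
  tab$cce <- 0
  trial_table(tab, spec, mode = "baseline", n = n, seed = seed)
}

#' Simulate operant trials for a condition
#'
#' Draws sensory samples exactly as [sample_trials()] and then applies the
#' closed-form MAP estimator ([map_estimate()]) to every trial, filling in
#' the estimated timings, the inferred causality, the posterior ratio and
#' the CCE.
#'
#' @inheritParams sample_trials
#' @return A `trial_table` in operant mode (see [sample_trials()]).
#' @examples
#' vol <- haggard_conditions()$voluntary
#' op <- run_operant(vol, n = 1000, seed = 1)
#' mean(op$xi_hat)  # close to causality_probability for the condition
#' @export
run_operant <- function(spec, n, seed = 1L) {
  tab <- draw_taus(spec, n, seed)
  est <- map_estimate(tab$tau_A, tab$tau_O, spec$baseline, spec$prior)
  tab <- cbind(tab["trial"], est)
  trial_table(tab, spec, mode = "operant", n = n, seed = seed)
}

draw_taus <- function(spec, n, seed) {
  stopifnot(inherits(spec, "condition_spec"))
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)
  set.seed(as.integer(seed))
  b <- spec$baseline
  data.frame(
    trial = seq_len(n),
    tau_A = stats::rnorm(n, spec$truth$t_A + b$d_A, b$sigma_A),
    tau_O = stats::rnorm(n, spec$truth$t_O + b$d_O, b$sigma_O))
}

trial_table <- function(tab, spec, mode, n, seed) {
  structure(tab,
            condition = spec,
            mode = mode,
            n = as.integer(n),
            seed = as.integer(seed),
            class = c("trial_table", "data.frame"))
}

#' @export
print.trial_table <- function(x, ...) {
  spec <- attr(x, "condition")
  cat(sprintf("Trial table: condition '%s', mode %s, n = %d, seed = %d\n",
              spec$name, attr(x, "mode"), attr(x, "n"), attr(x, "seed")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more trials\n", nrow(x) - 6L))
  invisible(x)
}

#' Summarise perceptual shifts between a baseline and an operant run
#'
#' The perceptual shift of an event is the change in its mean judged timing
#' from the baseline to the operant condition: `E[t_hat] - E[tau]`, with the
#' operant estimates in the first expectation and the baseline samples in
#' the second. Positive shifts indicate delayed awareness, negative shifts
#' anticipated awareness.
#'
#' @param baseline A baseline-mode `trial_table`.
#' @param operant An operant-mode `trial_table` of the same condition.
#' @return An object of class `shift_summary`: a list with elements
#'   `condition`, `mean_action_shift`, `mean_outcome_shift`,
#'   `interval_shift` (difference of mean operant and baseline intervals),
#'   `p_causal_empirical` (fraction of operant trials with `xi_hat = 1`),
#'   and the trial counts.
#' @export
summarize_shifts <- function(baseline, operant) {
  stopifnot(inherits(baseline, "trial_table"), inherits(operant, "trial_table"))
  if (!identical(attr(baseline, "mode"), "baseline") ||
      !identical(attr(operant, "mode"), "operant"))
    stop("expected a baseline-mode and an operant-mode trial table",
         call. = FALSE)
  b_spec <- attr(baseline, "condition")
  o_spec <- attr(operant, "condition")
  if (!identical(unclass(b_spec), unclass(o_spec)))
    stop("baseline and operant tables come from different conditions",
         call. = FALSE)
  structure(list(
    condition = o_spec$name,
    mean_action_shift = mean(operant$t_hat_A) - mean(baseline$tau_A),
    mean_outcome_shift = mean(operant$t_hat_O) - mean(baseline$tau_O),
    interval_shift = mean(operant$t_hat_O - operant$t_hat_A) -
      mean(baseline$tau_O - baseline$tau_A),
    p_causal_empirical = mean(operant$xi_hat),
    n_baseline = nrow(baseline),
    n_operant = nrow(operant)),
    class = "shift_summary")
}

#' @export
print.shift_summary <- function(x, ...) {
  cat(sprintf("Perceptual shifts for '%s' (n = %d operant / %d baseline trials):\n",
              x$condition, x$n_operant, x$n_baseline))
  cat(sprintf("  action shift : %8.2f ms\n", x$mean_action_shift))
  cat(sprintf("  outcome shift: %8.2f ms\n", x$mean_outcome_shift))
  cat(sprintf("  interval shift: %7.2f ms\n", x$interval_shift))
  cat(sprintf("  causality detected on %.1f%% of trials\n",
              100 * x$p_causal_empirical))
  invisible(x)
}

#' Bin a per-trial quantity by sensory disparity
#'
#' Groups trials into bins of `bin_width` ms along the sensory disparity
#' axis `tau_O - tau_A` and returns the per-bin count, mean and SD of a
#' chosen per-trial quantity. This is the aggregation used to display
#' estimated intervals, shifts or CCE as functions of the disparity.
#'
#' @param table A `trial_table`.
#' @param bin_width Bin width along `tau_O - tau_A` (ms, > 0).
#' @param value Which quantity to aggregate: the estimated interval
#'   `t_hat_O - t_hat_A` (`"interval"`), the per-trial action or outcome
#'   shift, or the `cce` column.
#' @return A data frame with columns `bin_mid`, `n`, `mean`, `sd`.
#' @export
bin_by_disparity <- function(table, bin_width = 200,
                             value = c("interval", "action_shift",
                                       "outcome_shift", "cce")) {
  stopifnot(inherits(table, "trial_table"))
  if (nrow(table) == 0L) stop("'table' has no trials", call. = FALSE)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("'bin_width' must be a single positive number (ms)", call. = FALSE)
  value <- match.arg(value)
  disp <- table$tau_O - table$tau_A
  y <- switch(value,
              interval = table$t_hat_O - table$t_hat_A,
              action_shift = table$t_hat_A - table$tau_A,
              outcome_shift = table$t_hat_O - table$tau_O,
              cce = table$cce)
  origin <- min(disp)
  idx <- floor((disp - origin) / bin_width)
  agg <- tapply(y, idx, function(v) c(n = length(v), mean = mean(v),
                                      sd = stats::sd(v)))
  keys <- as.numeric(names(agg))
  out <- data.frame(bin_mid = origin + (keys + 0.5) * bin_width,
                    do.call(rbind, agg), row.names = NULL)
  out[order(out$bin_mid), , drop = FALSE]
}

#' Derive a per-condition child seed from a root seed
#'
#' Hashes the condition name into the root seed so that each condition in an
#' experiment receives its own reproducible stream and adding conditions
#' never perturbs the draws of existing ones.
#'
#' @param root Root integer seed.
#' @param name Condition name.
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1L,
            is.character(name), length(name) == 1L)
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483629
  as.integer((abs(as.numeric(root)) + h) %% 2147483629 + 1)
}

#' Write a trial table to CSV
#'
#' Writes the per-trial columns `trial, tau_A, tau_O, that_A, that_O,
#' xi_hat, r, cce` with a header row; times carry 4 decimal places.
#'
#' @param table A `trial_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(table, path) {
  stopifnot(inherits(table, "trial_table"))
  out <- data.frame(trial = table$trial,
                    tau_A = round(table$tau_A, 4),
                    tau_O = round(table$tau_O, 4),
                    that_A = round(table$t_hat_A, 4),
                    that_O = round(table$t_hat_O, 4),
                    xi_hat = table$xi_hat,
                    r = table$r,
                    cce = table$cce)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
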