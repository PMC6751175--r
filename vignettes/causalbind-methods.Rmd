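---
title: "Methods: Bayesian causal inference of action-outcome timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian causal inference of action-outcome timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The generative model and its assumptions

`causalbind` models a timing-judgement experiment in which an action
(button press, muscle twitch or audible click) at true time $t_A^* = 0$ ms
is followed by a tone at $t_O^* = 250$ ms. The observer never sees these
true times; each event produces a sensory signal arriving at

$$\tau_A \sim \mathcal N(t_A^* + d_A,\ \sigma_A^2), \qquad
  \tau_O \sim \mathcal N(t_O^* + d_O,\ \sigma_O^2),$$

independently across events and trials. The delay $d$ and jitter SD
$\sigma$ are *not* free: in a single-event baseline condition the model
predicts the judged time is simply $\tau$, so $d$ and $\sigma$ equal the
mean and SD of the reported baseline judgement errors. A key assumption is
that the observer cannot compensate for $d$ — otherwise baseline judgements
would be unbiased, which they are not.

In the operant condition the observer additionally holds a prior over
whether the action caused the tone, encoded by $\xi \in \{0, 1\}$ with
$P(\xi = 1) = p$. Under causation the timings are coupled,
$t_O - t_A \sim \mathcal N(\mu_{AO}, \sigma_{AO}^2)$; under independence
the prior is flat. Because a flat prior on the plane is improper, both
branches are normalised over a square window of side $T$ centred on the
true timings, giving $Z_0 = T^2$ and $Z_1 \approx \sqrt{2\pi}\,
\sigma_{AO} T$ (the Gaussian approximation to the window integral; for the
default $\sigma_{AO} = 10$, $T = 250$ the neglected finite-window
correction is far below every tolerance used here).

The MAP estimate compares the posterior peaks of the two branches through
the ratio $r = \exp\!\big(\theta - (\tau_O - \tau_A - \mu_{AO})^2 /
2\sigma_{tot}^2\big)$ with $\theta = \log[p Z_0 / ((1-p) Z_1)]$ and
$\sigma_{tot}^2 = \sigma_A^2 + \sigma_O^2 + \sigma_{AO}^2$. If $r > 1$,
causality is detected and both timing estimates shift towards consistency
with $\mu_{AO}$, each by its own reliability-weighted coefficient
$\sigma^2/\sigma_{tot}^2$; otherwise the estimates equal the samples. Per
trial the detection region is $|\tau_O - \tau_A - \mu_{AO}| <
\sqrt{2\theta}\,\sigma_{tot}$, which integrates to the closed-form
detection probability $P_c$ implemented in `causality_probability()`. The
confidence in the causal estimate, `cce()`, is the peak posterior density
of the causal branch and is the model's proposed quantitative measure of
the sense of agency.

## Parameters

| parameter | units | default | role |
|---|---|---|---|
| `d_A`, `d_O` | ms | per condition | sensory delays; may be negative |
| `sigma_A`, `sigma_O` | ms | per condition | sensory jitter SDs (> 0) |
| `mu_AO` | ms | 230 | believed action-to-outcome delay |
| `sigma_AO` | ms | 10 | causal-coupling jitter; small enough to permit noticeable shifts |
| `p_causal` | – | per condition | prior belief in causation, in $[0, 1)$ |
| `T` | ms | 250 | prior normalisation window |

`p_causal = 1` is rejected by the constructor: $\theta$ diverges and the
acausal branch disappears, so no finite posterior ratio exists.
`p_causal = 0` is the degenerate "never causal" prior: `log_prior_odds()`
returns $-\infty$ and the ratio, detection probability and CCE all
evaluate to 0. $\sigma_{AO}$ and $p$ overlap in their effect on detection;
following the usual practice for this model, $\sigma_{AO}$ is fixed at
10 ms and only $p$ is fitted per condition.

## What the simulator emulates — and what it does not

`sample_trials()`/`run_operant()` simulate a single ideal observer:
35,000 trials per condition by default (the protocol size used in the
reference simulations; tests that only check signs or invariants scale
down to 1,000–20,000). Baseline and operant runs draw independently —
perceptual shifts are differences of run means, not paired trials, which
is how the underlying experiments compute them. Sensory samples are not
truncated to the prior window: only the prior normalisation sees $T$.

Real datasets differ in ways the generator deliberately omits: there is no
between-subject variability (one parameter set per condition), no lapses
or response biases, no drift over the session, and the reported shifts the
fits target are group means. A passing fit therefore shows the machinery
recovers parameters *under the model's own assumptions*, not that the
model is the true generative process for any subject.

## Fitting

`admissible_mu_range()` is purely analytic: binding on average requires
$m = t_O^* - t_A^* + d_O - d_A - \mu_{AO} > 0$, repulsion $m < 0$, which
brackets $\mu_{AO}$ between the largest repulsion and smallest binding
value of $t_O^* - t_A^* + d_O - d_A$ (182–259 ms for the
voluntary/involuntary pair). The grid searches (`fit_mu_ao()`,
`fit_prior()`) minimise the mean absolute difference between simulated and
reported mean shifts; `mode = "both"` averages the action and outcome
errors (the default objective), `"action_only"` and `"outcome_only"` use
a single event, provided because the action shift alone is often the more
diagnostic target for the tone-uncertainty conditions.

Numerical choices that matter:

* **Common random numbers.** Within one fit, the same $\tau$ draws are
  reused across all grid points, so the argmin is decided by the
  systematic effect of the parameter, not by independent Monte-Carlo noise
  per grid value.
* **Tie-breaking.** Exactly equal errors resolve to the smaller grid value
  (weaker prior / shorter delay) — a conservative convention for a
  measure-zero event.
* **Seeding.** Every condition derives a child seed from the root seed and
  its own name (`child_seed()`), so adding a condition never perturbs the
  draws of existing ones, and identical configurations reproduce
  bit-identical reports.
* **$r = 1$ ties** resolve to the acausal branch; the event has
  probability zero under the continuous sampling model.
* The $\mu_{AO}$ scan runs before per-condition priors are fitted; it uses
  each condition's default prior strength during the scan. The selected
  230 ms is insensitive to that choice across $p \in \{0.5, \dots, 0.9\}$.

At the default problem sizes, the 35,000-trial shift estimates carry a
Monte-Carlo SE of roughly 0.4–0.6 ms. For the intermediate
tone-uncertainty condition the error profile of the action-only objective
is nearly flat between $p = 0.5$ and $p = 0.6$ (the two errors differ by
about 1 ms, i.e. ~2 SE), and the argmin computed here is 0.5. Comparisons
with fits of 0.6 obtained elsewhere for this condition should keep that
resolution limit in mind; the neighbouring low- and high-uncertainty
conditions (0.9 and 0.5) and the voluntary condition (0.9) are stable
across seeds.

## Known limitations and internal inconsistencies

* The MAP location uses the unconstrained quadratic optimum; the finite
  window $R$ enters only through $Z_0$, $Z_1$. For extreme samples
  ($|\tau| \gg T$) this is formally inconsistent with the truncated prior.
  The closed forms are followed verbatim; results are robust to shifting
  the centre of $R$.
* The closed-form CCE extends all marginalisation integrals to the full
  plane. A marginalisation literally truncated to $R$ disagrees
  substantially for conditions with large sensory delays (the sensory
  samples then sit near the window edge, e.g. +16% for the involuntary
  and +47% for the high-uncertainty condition at typical samples), because
  $R$ is centred on the *true* timings while the samples centre on the
  *delayed* means. The oracle tests therefore integrate over a wide domain
  ($\tau \pm 8\sigma$), where the closed form agrees to < 0.5%.
* The causality-detection window $\sqrt{2\theta}\,\sigma_{tot}$ is widest
  for the low-uncertainty tone condition at the fitted priors, but is not
  monotone across all three tone conditions ($\theta$ falls with $p$ while
  $\sigma_{tot}$ rises with $\sigma_O$); the tests assert only the
  monotone-in-$p$ behaviour and the low-condition maximum.
* Binning for disparity plots defaults to 200 ms bins on the
  $\tau_O - \tau_A$ axis (the axis variable's unit); the width is exposed
  as a parameter and affects presentation only.

## Verification strategy

Three independent oracles back the closed forms in the test suite: MAP
locations and posterior-ratio values against brute-force 2-D grid
maximisation of the joint density (refined to < 0.01 ms); detection
probabilities against Monte-Carlo detection frequencies at $n \ge 10^5$;
CCE against grid maximisation divided by 2-D trapezoid marginalisation.
Self-consistency is checked by parameter recovery: synthetic reference
shifts generated at known $(\mu_{AO}, p)$ are recovered exactly on the
published grids from independent seeds. The predicted trial-to-trial
bimodality of the estimated interval near $P_c \approx 0.5$ is verified
with a Gaussian-mixture BIC comparison plus a direct mode-separation
check.
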