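---
title: "Models of fixation-biased value choice: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of fixation-biased value choice: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pucddm)
```

## The scientific problem

In two-item consumer choice with eye tracking, people tend to choose the
item they fixated longer, even at equal subjective ratings. `pucddm`
implements and compares two families of process models for this effect,
fitted to the *joint* distribution of choice and total fixation time:

* the **attentional drift-diffusion model (aDDM)** and its
  collapsing-bound variant (**acbDDM**), in which a decision variable
  drifts toward the currently fixated item's value with the unfixated
  item's value discounted by $\theta \in [0,1]$:
  $DV_t = DV_{t-1} + d\,(r_\mathrm{fix} - \theta\, r_\mathrm{unfix}) +
  \epsilon_t$, $\epsilon_t \sim \mathcal N(0, \sigma^2)$, absorbed at
  $\pm B_t$;
* the **Posterior-Utility-Choice (PUC) model**, an explicitly Bayesian
  account: each 100 ms of fixation on an item yields one noisy value
  measurement $x \sim \mathcal N(v, \sigma^2)$; the agent maintains a
  conjugate Gaussian posterior per item,
  $$\mu_\mathrm{post} = \frac{\mu_p/\sigma_p^2 + T\bar x/\sigma^2}
  {1/\sigma_p^2 + T/\sigma^2}, \qquad
  \sigma_\mathrm{post} = \Big(\tfrac{1}{\sigma_p^2} +
  \tfrac{T}{\sigma^2}\Big)^{-1/2},$$
  and values each item by $U = \mu_\mathrm{post} - A\,
  \sigma_\mathrm{post}$, where $A$ is an uncertainty-aversion weight.
  The decision variable is $U_\mathrm{left} - U_\mathrm{right}$,
  absorbed at a Weibull collapsing bound
  $B_t = B_0 e^{-(t/\lambda)^k}$. Because fixating an item can only
  shrink its posterior standard deviation, an uncertainty-averse agent
  ($A > 0$) acquires a preference for the longer-fixated item even when
  the posterior means are identical — this is the mechanism that
  produces the fixation bias without an attentional drift asymmetry.

Both model families share two nuisance components: a guessing rate $g$
(a trial is, with probability $g$, a random 50/50 choice at a moment
drawn from a Weibull fitted to the subject's empirical total fixation
times), and a non-decision time $\tau$ — here interpreted as time spent
looking *after* the internal decision, so the modelled decision moment
is $T - \tau$ within the observed total fixation time $T$.

An optional threshold utility, $U = \Pr(v > v_\mathrm{crit}\mid
\mathbf x) = \Phi\!\big((\mu_\mathrm{post} - v_\mathrm{crit}) /
\sigma_\mathrm{post}\big)$ (`utility_threshold()`), is provided for
loss-domain extensions: for an item with a negative running mean it
*decreases* with further looking, which the mean–sd utility cannot
produce.

## Likelihood by density propagation

The per-trial likelihood of (choice, total fixation time) has no
analytic form, so it is computed by discrete-time Chapman–Kolmogorov
propagation of the decision-variable distribution over the trial's
*empirical* fixation schedule, discretized to 100 ms steps (one
measurement epoch per step; the quantizer uses cumulative rounding so
rounding errors never accumulate across fixations). After every step the
mass at or beyond the bound is truncated into that time bin's absorption
probability; the surviving, non-renormalized remainder is propagated
further. The decision bin may fall anywhere in the series — total
fixation time is not constrained to come after the last observed
fixation — and all mass that survives the final bin is a single
"later than observed" residual.

Two structural points deserve emphasis:

* **The PUC decision variable is not Markov.** $U_L - U_R$ depends on
  two evolving posterior means, so the propagation runs on the joint
  2-D grid over $(\mu_{\mathrm{post},L}, \mu_{\mathrm{post},R})$. Each
  step applies, along the fixated item's axis only, the conjugate
  contraction $\mu \mapsto \alpha\mu$ followed by convolution with
  $\mathcal N(\beta v, \beta^2\sigma^2)$, where $\alpha =
  \kappa_T/\kappa_{T+1}$, $\beta = (1/\sigma^2)/\kappa_{T+1}$,
  $\kappa_T = 1/\sigma_p^2 + T/\sigma^2$. Before an item's first
  measurement its axis is an exact point mass at $\mu_p$, so the state
  machine runs 0-D → 1-D → 2-D. The posterior standard deviations are
  deterministic in the measurement counts and enter only through the
  absorption threshold. Correctness is anchored to an independent
  Monte-Carlo simulator of the measurement process in the test suite.
* **Partial-cell truncation.** Absorbing whole grid cells quantizes the
  bound at grid resolution and biases choice probabilities by more than
  Monte-Carlo agreement at $10^5$ replicates tolerates. Instead, each
  cell sheds the fraction of its mass beyond the bound under a
  within-cell uniform (1-D) or triangular (2-D diagonal) approximation.
  Transition kernels are cell-integrated normal CDFs with the outermost
  cells open to $\pm\infty$, so each step conserves total mass to
  floating-point precision — the conservation identity
  $\sum_t p_L(t) + \sum_t p_R(t) + p_\mathrm{survive} = 1$ is exact by
  construction and asserted to $10^{-6}$ in the tests.

### Grids and numerical choices

* aDDM/acbDDM: 601 points over $[-1.5, 1.5]\,B_0$ with $B_0 = 1$ (the
  DDM scale is arbitrary). Convolution kernels are truncated at
  $\pm 8\sigma$ with the tails lumped into the end weights.
* PUC: each axis spans $[\min(\mu_p, r) - 6\sigma_p,\ \max(\mu_p, r) +
  6\sigma_p]$ over both ratings (a shared grid keeps left/right
  exchange symmetry exact), with **401 points per axis**. This default
  was set by a grid-refinement study: at 201 points, doubling the grid
  moves choice probabilities by up to $3.5\times 10^{-3}$, violating
  the package's own refinement criterion of $10^{-3}$ and exceeding
  3 binomial SE against $10^5$-replicate Monte-Carlo runs in some
  parameter draws; at 401 points the refinement deviation is below
  $\sim 6\times 10^{-4}$.
* Per-trial log-probabilities are floored at $\log 10^{-300}$; the
  substantive guard against zero likelihood is the guessing mixture.
* The guess-time Weibull is fitted per subject to the *observed* total
  fixation times, once, before optimization, so the likelihood is fixed
  during fitting and does not depend on the parameters being optimized.

## Fitting

Fitting is per-subject maximum likelihood. Free parameters: PUC —
$\sigma, A, B_0, k, \lambda, g, \tau$ (7; the prior is fixed to the
pooled empirical mean and sample SD of the subject's ratings); acbDDM —
$\sigma, d, \theta, k, \lambda, g, \tau$ (7); aDDM — $\sigma, d,
\theta, g, \tau$ (5, fixed unit bound). The source literature is
ambiguous about these counts; the 7/7/5 reading is the only one that
makes the PUC and acbDDM counts equal, which the comparison of those
two models presumes, and the counts are exposed via the variant flags.
PUC variants (free prior SD, free prior mean and SD, $A = 0$) add or
remove free parameters accordingly.

The optimizer is a multi-start bounded local search: Latin-hypercube
start points, Nelder–Mead on transformed coordinates (log for
$\sigma, d, B_0, k, \lambda$ and $\tau + 10$ ms; logit over the box for
$\theta, g$; identity for $A$), boxes as in `default_param_boxes()`.
A derivative-free method is required because the likelihood is
piecewise constant in $\tau$ (it only moves the 100 ms decision bin).
Two further design choices matter for runtime:

* $(g, \tau)$ are **profiled out**: the propagated absorption records
  do not depend on either, so at every outer evaluation their
  conditional maximum is found on a fine $\tau$ grid (quarter-step
  resolution) with 1-D optimization over $g$. The outer search then
  covers only the 3–5 propagation parameters.
* `fit_config(n_grid = )` lets optimization run on a coarser
  propagation grid than the reporting default; recovery experiments
  below use 201 points (aDDM), where the likelihood differs from the
  601-point value by well under 0.01 log-units.

## Model comparison

`information_criteria()` implements
$\mathrm{AICc} = -2\log L + 2k + 2k(k+1)/(n-k-1)$ and
$\mathrm{BIC} = -2\log L + k\log n$ with $n$ the number of trials — the
independent units of the likelihood. `compare_models()` sums
per-subject differences (first model minus second, so negative values
favor the first) and attaches percentile 95% confidence intervals from
resampling subjects with replacement (default $10^4$ draws). When two
models have equal $k$ and equal $n$, the AICc and BIC differences
coincide exactly.

## Synthetic experiments and what they do (not) show

`generate_synthetic_experiment()` emulates the target study design: 39
subjects × 95 trials by default, integer ratings uniform on $-10..10$,
strictly alternating fixations with log-normal durations (median
400 ms — the study does not print duration distributions, so this is a
declared configurable default), guess times from a configured Weibull
(shape 2, scale 1600 ms, median ≈ 1.3 s). Per-subject true parameters
are drawn from `default_param_ranges()`; those ranges were calibrated
once, by forward simulation, so the synthetic data reproduce the
reported scale of the behavioral data (median total fixation time
≈ 1.4 s, mean ≈ 1.9 s, ≈ 0.9 of unequal-rating trials choosing the
higher-rated item) and then frozen. Trials that reach the simulation
horizon undecided are re-simulated up to a retry cap; the generated
fixation series is truncated at the simulated total fixation time so
every trial satisfies the data-model invariants exactly.

What the generator does *not* emulate: empirical rating-pair
frequencies (the original data are not public; ratings are drawn from
a declared distribution), fixation-duration dependence on trial
progress or stimulus, saccade/transition gaps (inputs are defined to
exclude them), and any active-sampling structure in fixation behavior
(neither model family predicts fixation times). Passing recovery and
summary-statistic tests on these data therefore validates the
*fitting machinery*, not the models' adequacy for real data.

### Scales used by the shipped checks

The test suite and `scripts/acceptance.R` run parameter recovery at 8
subjects × 200 trials (the aDDM with full assertions in both; the PUC
model additionally in the tests, fitted on a deliberately coarse
optimization grid and reported without thresholds) — enough trials per
subject for informative per-subject estimates while keeping a full run
in the tens of minutes on one CPU. Note that a Pearson correlation over
8 subjects is itself a noisy statistic: the weakly-spread attentional
discount can dip below 0.7 at some generation seeds while the
better-identified noise and drift parameters stay above 0.9. At this scale the aDDM core parameters
($\sigma, d, \theta$) recover with Pearson $r$ well above 0.7; $g$ and
$\tau$ are weakly identified (few guess trials at $g \le 0.08$, and
$\tau$ enters only through bin shifts). PUC recovery is reported but
noticeably weaker — soft trade-offs between $A$, $B_0$, $k$,
$\lambda$ — mirroring what the source work reports for its more complex
models; conclusions should rest on log-likelihoods and summary
statistics, not PUC point estimates.

## Summary statistics

`choice_vs_fixation_advantage()` (choice proportion vs signed total
fixation-time advantage, 200 ms bins over ±2000 ms by default),
`choice_vs_advantage_by_rating()` (the same conditioned on the mean
absolute rating of the two items), `last_fixation_effect()` (choice
proportion vs rating difference split by the side fixated last), and
`fixation_time_distribution()` aggregate over individual trials, not
rating pairs, so each rating pair is represented proportionally to its
frequency. Model-predicted summaries use `predict_trial_ensemble()`:
each observed trial is continued past its empirical fixation series
with durations resampled from the subject's own pool (sides strictly
alternating), 10 replicates per trial by default, which yields
unrestricted predicted total fixation times. Bin definitions are
declared defaults, not inferred from the source figures.

## Known limitations

* The 2-D PUC propagation is exact in structure but $O(n^2)$ per step
  in grid points; very tight bounds with very small measurement noise
  would need finer grids than the default.
* Within-step bound crossings are not interpolated (consistent with the
  100 ms measurement discretization); the 1 ms-step Wiener check shows
  the propagator converges to the continuous-time limit as the step
  shrinks.
* With $A \ne 0$, equal ratings and an alternating schedule, PUC choice
  probabilities are *not* exactly symmetric: the first-fixated item
  carries a transient uncertainty advantage at odd steps. Exact
  symmetry holds at $A = 0$, and that is what the symmetry checks
  assert; the $A > 0$ asymmetry is itself the modelled fixation effect.
* Guess choices are 50/50; matching guesses to empirical choice rates
  is unsupported (the source description implies a random decision).
* Hierarchical (random-effects) model selection across subjects is out
  of scope; comparisons are fixed-effects sums with subject-level
  bootstrap CIs.
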