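---
title: "Stochastic satisficing models of choice and confidence in two-armed bandits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic satisficing models of choice and confidence in two-armed bandits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssatbandit)
```

## The problem

In a two-armed bandit with continuous Gaussian payoffs, a decision maker
must learn not only which option pays more on average but also how
*reliable* each option is. `ssatbandit` implements a family of trial-by-trial
learning models for such tasks, together with the experimental designs,
synthetic cohorts, per-subject Bayesian fitting and behavioural analyses
needed to study one question: what quantity do confidence reports track when
outcomes are stochastic and continuous?

The central hypothesis is *stochastic satisficing*: options are evaluated by
the probability that their payoff exceeds an acceptability threshold
$T$ — "is this option likely to be good enough?" — and confidence in a
choice reports that satisficing probability for the chosen option.

## Models

All modelling is done on rewards normalized to $[0,1]$ (points / 100);
on this scale an acceptability threshold of 0.35 corresponds to 35 points,
directly comparable to the bad option's mean. Every family tracks the
chosen option's mean payoff $Q_a$ with a delta rule with learning rate
$\alpha \in (0,1)$:

$$Q_a(t+1) = Q_a(t) + \alpha\,(R(t) - Q_a(t)).$$

The families that use payoff variance (utility, ssat) also track

$$V_a(t+1) = V_a(t) + \gamma\,\big((R(t) - Q_a(t))^2 - V_a(t)\big),$$

with its own learning rate $\gamma$. A softmax with inverse temperature
$\beta \ge 0$ maps the two options' decision variables onto a choice
probability. The families differ only in the decision variable:

* **reward** — the tracked mean $Q$ itself.
* **utility** — the mean–variance certainty equivalent
  $Q - \lambda V / 2$, which orders Gaussian gambles exactly as expected
  exponential utility $-e^{-\lambda Q + \lambda^2 V / 2}$ does;
  $\lambda > 0$ is risk aversion and the penalty is *symmetric*: variance
  always lowers the value of both options.
* **ssat** — the satisficing probability
  $\Phi\!\big((Q - T)/\sqrt{V}\big)$, the Gaussian upper-tail mass above
  the threshold. Variance acts *asymmetrically*: it hurts an option whose
  mean is above threshold and helps one below it. This single property
  separates the families behaviourally.
* **power** — like reward, but learning from power-utility-transformed
  payoffs $U(R) = R^{1-\rho}/(1-\rho)$, $\rho \in [0,1)$; at $\rho = 0$
  it is the reward model and as $\rho \to 1$ its ordering approaches
  $\log R$.

Each family has a "-T" variant in which the *unchosen* option's mean
drifts toward the acceptability threshold,
$Q_b(t+1) = Q_b(t) + \alpha (T - Q_b(t))$: the threshold doubles as the
agent's standing expectation about options it is not sampling. For the
power family the drift target is the utility transform $U(T)$ of the same
threshold, so the fitted $T$ stays interpretable on the reward scale.
Model-predicted confidence is always the chosen option's decision
variable.

One printed form of the satisficing probability carries an exponential
utility factor inside the integrand; the package follows the accompanying
description — a plain cumulative Gaussian — which is also the only reading
under which the threshold construction below works.

## Task designs

`build_design()` encodes two experiments. Experiment 1 (240 trials): good
and bad option means fixed at 65 and 35 points, variances independently
high ($25^2$) or low ($10^2$), a 2×2 design; six stable blocks (the four
conditions plus two seeded-random repeats). Condition labels put the
*good* option's variance letter first (`vH-vL` = variable good option,
reliable bad option). Experiment 2 (160 trials): bad option fixed at
(35, $10^2$); good option mean 57 or 72 crossed with variance $5^2$ or
$20^2$. Stable blocks last 27–35 trials (uniform, final block adjusted so
totals are exact); consecutive blocks are joined by 10-trial linear
transitions of every parameter. Rewards are Gaussian draws rounded and
clipped to 1–100 points.

Experiment 2's design is the critical test. With normalized beliefs at the
true values, the threshold solving
$(0.57 - T)/0.05 = (0.72 - T)/0.20$ is $T = 0.52$, at which the `mL-vL`
and `mH-vH` good options have *identical* satisficing probability
$\Phi(1) \approx 0.8413$ despite very different expected values:

```{r equality}
satisficing_probability(0.57, 0.05^2, 0.52)
satisficing_probability(0.72, 0.20^2, 0.52)
```

A mean-tracking account predicts different confidence in these two
conditions; stochastic satisficing predicts a tie.

## Synthetic cohorts

`generate_cohort()` simulates subjects with known ground truth. Parameter
values are drawn from truncated normals centred on magnitudes typical of
fitted subjects in this task (learning rates ≈ 0.5, inverse temperatures
≈ 6–8, thresholds ≈ 0.35–0.4 normalized); individual analyses state their
generating values explicitly. Confidence reports map the chosen option's
decision variable linearly onto the 1–6 scale, add Gaussian noise
(default sd 0.5 report units) and round. This reporting convention is a
generator-side assumption only: fitting regresses reports on model
predictions and never inverts the map, so conclusions are insensitive to
its exact form. The generator also injects the two pathologies real
cohorts contain — chance performers ($\beta = 0$) and single-level
confidence reporters — and `apply_exclusion_filters()` removes them the
way a cohort would be cleaned: a one-sided exact binomial test of
good-choice proportion over stable trials 10–25 against 0.5
($\alpha = 0.05$), and a single-used-confidence-level check. The trial
window for the chance test is a package choice (the criterion is not
operationally defined elsewhere); post-learning trials are used so slow
learners are not excluded for their first block.

What the generator does *not* emulate: reaction times (no generative RT
model is claimed; RT correlations operate only on supplied columns),
sequential report biases, lapses, or door-position effects. Passing tests
on synthetic cohorts therefore demonstrate that the pipeline recovers
what it simulates — not that human data obey these models.

## Fitting

`fit_bandit()` fits one model to one subject by replaying the recorded
choices and rewards through the belief dynamics and scoring each trial's
recorded choice under the softmax (confidence never enters the choice
likelihood). The posterior over the free parameters is sampled with an
adaptive random-walk Metropolis sampler on transformed parameters
(logit for rates and thresholds, log for $\beta$ and $\lambda$):
the proposal covariance is re-estimated from the warmup history and the
global scale tuned toward 30% acceptance, after which the kernel is
frozen. Priors are weakly informative: $\alpha, \gamma \sim
\mathrm{Beta}(1.1, 1.1)$, $\beta \sim \mathrm{HalfNormal}(10)$,
$\lambda \sim \mathrm{HalfNormal}(2)$, $T \sim U(0,1)$,
$\rho \sim U(0, 0.99)$. Diagnostics (acceptance rate, split R-hat,
ACF-based effective sample sizes, MCSE) ship with every fit; a variance
floor of $10^{-6}$ keeps the satisficing probability defined when
constant rewards drive the tracked variance to zero, and beliefs start at
$Q_0 = 0.5$ (scale midpoint), $V_0 = 0.04$ (sd 0.2), both configurable at
the engine level.

Model comparison uses WAIC computed from per-trial log-likelihood draws,
with the variance form of the penalty:
$\mathrm{WAIC} = -2(\mathrm{lppd} - p_\mathrm{waic})$, lower better.
Confidence predictions are scored separately: the chosen option's decision
variable at the posterior-mean parameters is regressed against the 1–6
reports over within-block stable trials 10–25 (the post-learning window all
condition summaries use), and the $R^2$ reported. `compare_models()`
assembles WAIC sums, mean ± sd tables, paired two-sided t-tests against the
best model (raw p-values, no multiplicity correction — differences are
reported pairwise), per-subject best-model tallies and cross-model
parameter correlations.

The two scores deliberately dissociate: on satisficing-generated cohorts
the drifting mean-tracking model can fit the *choices* almost as well
(the drift-to-threshold mechanism dominates choice likelihood), while the
satisficing model is clearly best at predicting *confidence* — the same
signature the pipeline is designed to detect.

## Behavioural and optimality analyses

* `condition_summaries()` — good-choice frequency and confidence split by
  chosen option, trials 10–25 of each stable block, averaged within then
  across subjects; empty cells are missing, not zero.
* `choice_stability()` — 5 minus the number of consecutive-choice switches
  in a 5-trial sliding window (range 1–5). Windows never span block
  boundaries or transitions — the conservative reading, taken as a package
  convention.
* `critical_r()` / `correlate_with_threshold()` — the analytic two-sided
  critical Pearson correlation $t^*/\sqrt{n - 2 + t^{*2}}$; at
  $\alpha = 0.05$ it rounds to 0.13 for $n = 240$ and 0.16 for $n = 160$.
* `optimize_for_reward()` — Nelder-Mead search (10 seeded restarts by
  default; the search is local) for the parameters maximizing mean accrued
  points over seeded simulations (common random numbers across objective
  evaluations), evaluated against an omniscient benchmark that knows the
  true trial-wise means, transitions included. The objective is mean total
  points over the full design, transitions included.
* `steady_state_value_difference()` — decision-variable differences with
  beliefs pinned at each condition's true normalized parameters, over a
  threshold grid; this is the map that shows where a noisy (softmax)
  chooser would err under each family even though a greedy one would not.

## Numerical and design choices

* Rewards are integers clipped to [1, 100]; all belief updates use the
  normalized value. The clipped mean is slightly below the nominal mean
  for high-variance arms; the omniscient benchmark's expectation accounts
  for this, and tests check it with a censored-Gaussian closed form.
* Transition trial $j$ of $L$ sits at fraction $j/(L+1)$ between block
  values, so parameters are continuous at both block edges;
  `transition_length = 0` degenerates to a step change.
* Block lengths: stable lengths are drawn from {27, …, 35} and the final
  block absorbs the remainder (kept within [25, 35] by redrawing), which
  satisfies both the "at least 25" and the "27–35 uniform" statements.
* Problem sizes in the shipped tests and acceptance script (30-subject
  recovery at 4,000 draws; 10 replications × 10 subjects × 6 models at
  1,000 draws for model recovery; 100-repetition optimality runs with 3
  restarts) were chosen as the smallest cohorts at which the recovery
  correlations and win rates are stable across seeds.
* The sampler's warmup is discarded; WAIC always uses actual draws, never
  a point approximation.

## Known limitations

* The variance learning rate $\gamma$ is weakly identified from choices
  alone (it moves the decision variable only through the satisficing
  probability's tail); recovery correlations for $\gamma$ are near zero
  at 240 trials and no analysis here relies on recovering it.
* $\beta$ is family-specific: decision variables live on different scales
  (probabilities vs certainty equivalents), so inverse temperatures are
  not comparable across families and are never pooled.
* Per-subject fitting only; no hierarchical pooling.
* No generative reaction-time model; stability, not RT, is the
  within-package correlate of confidence.
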