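---
title: "Models and methods behind the metacontrol package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the metacontrol package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacontrol)
```

This vignette documents the scientific content of the package: the task,
the hybrid reinforcement-learning model and its likelihood, the estimation
and inference machinery, what the synthetic-data generator does and does
not emulate, and the numerical and design choices that were genuinely open
and had to be decided.

## The two-stage task

Each trial cues a stakes condition (low: 1 point per reward unit; high: 5
points), presents one of two first-stage states with a pair of spaceship
stimuli, and the chosen spaceship travels deterministically to one of two
planets where 0–9 reward units are collected.  Planet rewards follow
independent Gaussian random walks (increment SD 2) with *reflecting
boundaries* at 0 and 9.  Reflection acts on the continuous latent value —
excursions are folded back (`v → 2·bound − v`, iterated) — and only the
*displayed* reward is rounded to an integer.  Treating rounding as
display-side keeps the latent dynamics exact and matches the task's visual
presentation of integer treasure counts.

Two session layouts are provided.  The 320-trial layout has four 80-trial
blocks alternating between stable transitions and variable transitions; in
variable blocks one of the two spaceship pairs swaps destinations at
inter-swap gaps drawn uniformly from 6–14 trials.  The 280-trial layout is
entirely stable and splits trials 140/140 between stakes conditions.

Several schedule details are unspecified in the paradigm description and
are fixed here as seeded design choices: walk starting values are drawn
uniformly on [0, 9]; the first-stage-state sequence is a balanced random
permutation (half each state), avoiding confounds from unequal state
exposure; stakes labels are balanced *within every block* and permuted at
random; the swapped pair at each swap event is chosen uniformly; and a
pending swap is cancelled at a block boundary, since swaps are only
defined for variable blocks.  Counterbalancing is a small documented set
of cells — block-condition order (stable-first vs. variable-first) crossed
with a complementation of the stakes labels — while reward walks and
state sequences depend only on the seed and are therefore shared across
participants, mirroring the yoked design of the experiments.

## The hybrid learner

State-action values are initialized at 4.5 (the midpoint of the reward
range), transition beliefs at 0.5, and eligibility traces at 0.

*Model-free learning.*  After each stage transition the just-visited pair
gets eligibility 1, the reward prediction error
`δ = r + Q_MF(s', a') − Q_MF(s, a)` is formed (with `r = 0` after
first-stage choices, and successor value 0 after second-stage events,
planets being terminal), every pair is updated by `α · e · δ`, and all
traces decay by `λ`.  Traces reset at trial start, so `λ` only carries
second-stage prediction errors back to the first-stage choice within the
same trial.

*Transition learning.*  The probability of the observed planet moves up by
`η · (1 − T)`; the complementary planet is rescaled by `1 − η` so each
row stays normalized.  Because the two spaceships of a state always lead
to different planets, the not-chosen action is updated toward the other
planet with a counterfactual rate `η_CF`.  Stable-transitions blocks
always use rate 1 (the mapping is known and announced), so `η`/`η_CF` act
only in variable blocks; in the stable-only layout the transition matrix
is set to the true mapping and never updated, which removes both rates
from the model entirely.

*Choice.*  First-stage values mix as `(1 − ω) Q_MF + ω Q_MB` with a
condition-specific model-based weight, plus `π` for repeating the
previously chosen stimulus and `ρ` for repeating the previously pressed
key, through a softmax with inverse temperature `β`.  Which stimulus sits
on which side (and hence which key selects it) is randomized per trial.
The stickiness indicators compare against the immediately preceding trial
regardless of block, and are reset at session start and after a missing
first-stage response — the simplest consistent rule, as no other is
specified.

*Missing responses.*  A trial without a first-stage response contributes
no likelihood term and no updates.  A trial without a second-stage
response still shows the planet, so it contributes the first-stage choice
probability, the first-stage value backup, and the transition update, but
no reward-based update (no reward is given).  These trials are retained
precisely because they remain informative about the transition structure.

*Update order within a trial.*  The order is fixed as part of the
likelihood contract, so the replay is well defined: (1) first-stage TD
backup with `r = 0` at transition time, using the planet's value *before*
this trial's reward update; (2) transition update on observing the planet;
(3) second-stage reward update.  The alternative (backing up the planet
value after its reward update) is not distinguishable from the task
description; one order had to be chosen and is kept fixed everywhere.

*Reward scale.*  Learning operates on the raw displayed reward (0–9), not
on the stakes-multiplied points: initialization at 4.5 is explicitly the
midpoint of the *reward* range, and stakes effects are carried exclusively
by the condition-specific `ω`.  Letting points enter the value updates
would confound the stakes manipulation with reward magnitude learning.

The generative simulator and the likelihood replay share one compiled
update engine, so replaying a simulated session reproduces the simulator's
internal state trajectory exactly; this identity is tested.

## Fitting

Per-participant MAP estimation uses `Beta(2, 2)` priors for all
unit-interval parameters, standard normal priors for `π` and `ρ`, and a
Gamma prior for `β` read as shape 3, *scale* 0.2 (mode 0.4), the density
convention of the MATLAB fitting toolboxes common in this literature — the
shape–rate reading would concentrate the prior near 15, an implausible
softmax temperature for a 0–9 reward scale.  Optimization runs on
unconstrained scales (logit for unit-interval parameters, log for `β`)
with the priors evaluated on the natural scale, so the result is the MAP
in natural coordinates and bounded estimates stay strictly inside their
bounds without constrained-optimizer edge cases.  Each fit uses 100
prior-sampled restarts by default (BFGS, relative tolerance 1e-6, at most
500 iterations), returns the best converged run, and breaks exact ties by
the lexicographically smallest parameter vector.

Model variants fix or free `λ`, `η`, `η_CF`, `π`, `ρ` (with `α`, `β` and
all `ω` always free); `variant_study1()` and `variant_study2()` are the
AIC-selected structures for the two layouts.  AIC is computed from the
log-*likelihood* at the MAP (`2k − 2·logLik`) — AIC is a likelihood-based
criterion, and using the posterior would double-count the priors — and
aggregated across participants by summation, the standard group-level
criterion; neither convention is dictated by the fitting description, so
both are stated here.

## Behavioral metrics

Task performance scores each completed trial as the reward obtained
(before stakes multiplication) minus the mean of the two planets'
displayed rewards on that trial — the excess over a uniformly random
policy, whose expectation is exactly zero — averaged per condition cell.
Metacontrol is `ω(high) − ω(low)` per transition condition; where one
number per participant is needed (e.g. correlating with NFC in the
four-cell layout), the mean across transition conditions is used.

## Bayes factors

Correlation Bayes factors place a stretched beta prior on the population
correlation: `(ρ + 1)/2 ~ Beta(1/κ, 1/κ)`, uniform at `κ = 1` and
concentrating near 0 for smaller `κ`.  The marginal likelihood integrates
the *exact* sampling density of the Pearson correlation under bivariate
normality (the hypergeometric form, evaluated by series in log space), not
the Fisher-z approximation — at n above 100 the approximation visibly
shifts the second decimal, which is the display precision at which these
values are compared.  Directional tests restrict and renormalize the prior
to the requested half-line and compare against the same point null; under
the symmetric prior the two one-sided factors average to the two-sided
one, which is tested.  Numerical integration uses a relative tolerance of
1e-8.  Paired-test Bayes factors use the JZS prior (Cauchy on the
standardized effect, scale √2/2) integrated against the noncentral-t
density.  Evidence labels follow the conventional 1/10, 1/3, 3, 10 cut
points, and `bf_robustness()` sweeps `κ` over a grid (0.01–1 by
convention) for prior-sensitivity checks.

## Design analysis (Bayesian power analogue)

For each true population correlation ρ on a grid, one finite population of
N = 1000 standardized score pairs is built whose *empirical* correlation
equals ρ exactly (orthogonalized Gaussian construction); a "true population
correlation" is a property of the population, and constructing it exactly
removes a nuisance variance layer that would blur the thresholds.  From
that fixed population, samples of size n are drawn *without replacement*
(samples from a finite population), the stretched-beta Bayes factor is
computed per sample, and the proportions with `BF10 ≥ 3` and `BF10 ≤ 1/3`
are tallied.  Thresholds are then read off at 0.01 grid resolution: the
smallest |ρ| with an 80% alternative-evidence probability, and the largest
|ρ| with an 80% null-evidence probability.  Within `power_curve()` the
per-sample Bayes factor is evaluated through a dense spline interpolant of
`log BF10(r)` (1201 support points, interior accuracy around 1e-6, checked
against direct evaluation in the tests), which makes 10,000-sample grids a
matter of seconds without altering the tallies.

## Synthetic cohorts

The cohort generator stands in for the study samples.  Its parameter
population (no distributional summary of fitted parameters is available to
match): `α ~ Beta(3, 3)`, `β ~ Gamma(shape 4, scale 0.25)`,
`π, ρ ~ Normal(0, 0.3)`, low-stakes `ω ~ Beta(2, 3)`, and a stakes effect
`~ Normal(0.15, 0.15)` added and clipped into [0, 1] — wide,
prior-compatible settings that produce the characteristic
scatter-above-the-identity-line pattern of model-based weights (most
simulated participants upregulate under high stakes, some do not).  `λ`
follows `Beta(2, 2)` in the four-block layout and is 0 in the stable-only
layout, matching the model variants selected for each.  All settings are
overridable through `cohort_spec()`.

NFC totals are generated directly on the chosen scale (16-item German
version: −3..+3 per item, totals −48..48, population mean 14.63, SD 13.48;
18-item English version: 1..5 per item, totals 18..90, mean 64.81, SD
9.68, the observed student-sample moments) rather than item by item — only
totals enter any analysis.  The continuous scores are constructed to hit
the target NFC–metacontrol correlation *exactly* (same orthogonalization
as the power module); integer rounding and range clipping perturb that
correlation by a negligible amount, so exactness claims and tests refer to
the continuous scores.  Missing responses are injected at the observed
rates (1% and 3% per stage for the two layouts) and the exclusion filter
applies the strictly-greater-than-20%-missing rule (a participant at
exactly 20% is retained) plus an optional >95% key-repetition rule.

What the generator does **not** emulate: item-level questionnaire
psychometrics, reaction times, demographics, learning over the
instruction/training phase, and any drift of strategy use over the
session.  Passing recovery and null-pipeline tests therefore show that the
estimation and inference machinery is sound on data generated *by the
model under study*; they cannot show that the model family is the right
description of real participants.

## Problem sizes and runtimes

The test suite and the acceptance script use these simulation scales, all
chosen as the package's own defaults for a laptop-class single core: Bayes
factor worked examples are sub-second; design-analysis curves use 10,000
Monte-Carlo samples per grid point; parameter recovery uses 40
participants × 280 trials with 60 restarts per fit; the end-to-end null
check runs 20 replicate cohorts of 126 participants with 5 restarts per
fit (restarts beyond a handful change the recovered metacontrol only
marginally on these smooth 6-parameter posteriors, and the multi-start
monotonicity is tested separately).

## Known limitations

* MAP point estimates carry no uncertainty; a hierarchical Bayesian
  treatment of the same model is out of scope here.
* The correlation Bayes factor assumes bivariate normality through the
  sampling density of r; heavy-tailed score distributions are not modeled.
* The one-sided Bayes factor compares a half-line prior against the point
  null (not an order-restriction pair), the convention that reproduces the
  published directional values.
* Recovery quality degrades for `ω` cells with few effective trials; the
  four-cell layout recovers noticeably less precisely than the two-cell
  layout at equal trial counts.
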