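---
title: "Methods: simulating and modelling relational guidance in visual foraging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and modelling relational guidance in visual foraging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the synthetic-data generator, the
numerical choices, and the design decisions behind `relforage`. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The task and the two accounts

A forager works through "patches" of 90 moving stimuli (15 targets, 15
distractors, 60 non-targets) and collects targets by clicking them, for a
total goal of 1000 points. Patches come in four within-subject conditions
defined by the distractor colour. The four stimulus colours are equidistant
neighbours on a green-to-blue line in CIELAB space; non-targets always carry
the colour adjacent to the target colour and dominate the display, forming
the colour context. Writing the line as green–olive–aqua–blue and taking
olive targets with aqua non-targets as the example:

| condition | distractor colour   | target–distractor distance | same direction as target? |
|-----------|---------------------|:--------------------------:|:-------------------------:|
| `rel`     | green (beyond target)       | 1 | yes |
| `sim`     | olive (= target)            | 0 | yes |
| `nont`    | aqua (= non-targets)        | 1 | —   |
| `opp`     | blue (beyond non-targets)   | 2 | no  |

A **feature-specific** template predicts distraction inversely ordered by
feature distance: `sim` maximal, `opp` minimal, and — because `rel` and
`nont` sit at the *same* distance — `rel` and `nont` equal somewhere in
between. A **relational** template predicts distraction by direction only:
`rel = sim` high, `nont = opp` low. These orderings are what the
constrained models below encode; "distraction" maps to a lower rate of
return and a higher proportion of targets left behind.

## 2. Outcome measures

- **Rate of return (RoR)**: targets collected in a patch divided by time in
  the patch plus the fixed 1 s travel time. Trial time ends at the
  terminating event: the "Next" click when the patch was left actively,
  otherwise the final collection. The travel second is charged in both
  cases since it elapsed in both. (The alternative — ending actively left
  trials at the last collection instead of the "Next" click — was
  considered; the "Next" click is the behavioural end of the patch visit,
  and the decision latency it adds is part of the time cost of leaving.)
- **Instantaneous rate**: one over the inter-target time (ITT), the time
  since the previous collection. Erroneous clicks on non-collectable items
  never anchor ITTs or delays; ITTs are literally times between
  collections.
- **pTLB**: targets left behind divided by the 15 available.
- **Selection delays**: time to the first collection, and from the first to
  the second.

## 3. Hierarchical models

### 3.1 Rate of return

Trial-level likelihood with a three-part location:

$$y_{t} \sim \mathrm{Normal}(\theta_{p,c},\ \sigma_w), \qquad
\theta_{p,c} \sim \mathrm{Normal}(\mu_c + b_p,\ \sigma_{int}), \qquad
b_p \sim \mathrm{Normal}(0,\ \sigma_b).$$

The participant offset $b_p$ carries overall speed differences (large,
shared across conditions); $\sigma_{int}$ carries the residual
participant-by-condition interaction (small). This split matters for the
model comparison: if every participant-condition cell had its own freely
pooled mean with a single between-cell spread, the group-level ordering
constraints would barely reach the trial-level predictions and the
constrained variants would be nearly indistinguishable. With a shared
speed offset and a small interaction term, a group-level pattern violation
must be absorbed by the interaction spread, which is exactly the
penalisation that makes the accounts testable.

Priors are identical across conditions and vague at the data's scale
(items/s): $\mu_c \sim \mathrm{Normal}(1, 1.5^2)$ truncated positive (over
99% of its mass below 5 items/s, a physically generous bound for mouse
foraging), all spreads half-Normal(2), the constraint gap half-Normal(1).

### 3.2 Targets left behind

Counts per trial are zero-inflated in practice (most foragers deplete most
patches), so the model is a hierarchical beta-binomial in
mode/concentration form:

$$k_t \sim \mathrm{Binomial}(15,\ \theta_{p,c}), \qquad
\theta_{p,c} \sim \mathrm{Beta}\big(\omega_c(\kappa_c - 2) + 1,\
(1 - \omega_c)(\kappa_c - 2) + 1\big),$$

with $\omega_c \sim \mathrm{Uniform}(0,1)$ and $\kappa_c - 2$
half-Normal(50). $\omega_c$ is the *mode* of the participant-proportion
distribution and $\kappa_c > 2$ its concentration. Note a consequence
stated plainly: on a cohort where most participants leave essentially
nothing behind, the group mode sits near zero — that is the honest central
tendency of such a mixture, and it is what `fit_ptlb()` reports for the
simulator's default cohorts. Parameter recovery for $\omega$ is therefore
tested on data generated from this model's own generative process
(`simulate_ptlb_model()`), where the mode is interior and identified.
Setting `kappa_fixed = 2` collapses the participant level to a flat Beta
prior, giving a conjugate closed form used as a test oracle.

### 3.3 Order constraints

Constraints are enforced by construction, never by rejection:

- equalities share one parameter (e.g. relational RoR:
  $\mu_{rel} = \mu_{sim} = \beta$, $\mu_{nont} = \mu_{opp} = \beta + \Delta$
  with $\Delta \ge 0$ half-Normal);
- the feature-specific intermediate level is
  $\beta + u\,\Delta$, $u \sim \mathrm{Uniform}(0,1)$, **shared** by `rel`
  and `nont`.

The shared $u$ is a deliberate design decision. Under a strict
feature-specific account, equal target–distractor feature distances imply
equal distraction, and `rel` and `nont` have equal distances by the colour
geometry. With two independent intermediates the feature-specific model
could reproduce the relational pattern exactly ($u_{rel}\to 0$,
$u_{nont}\to 1$), the two models would become predictively
indistinguishable, and the comparison would be vacuous. For pTLB the
inequality directions flip (more distraction leaves more behind), with the
same structure on $\omega_c$.

### 3.4 Sampling and reporting

Models are sampled with JAGS (Gibbs/slice). Two profiles:
`test` (2 chains, 500 adaptation, 500 burn-in, 2 500 retained draws —
used by the test suite and the acceptance script) and `full` (4 chains,
2 000/2 000, 20 000 retained draws). Point estimates are posterior modes
(Gaussian kernel density, Silverman bandwidth, pooled chains); credibility
is the 95% highest-density interval (sorted-window algorithm).

Two numerical devices deserve note. First, the Gibbs sampler mixes slowly
over the decomposition $\mu_c + \bar b$, so after sampling, the realised
mean participant offset is folded into the group means (this preserves
every contrast and constraint) and the population-level uncertainty of that
mean offset, $\mathrm{Normal}(0, \sigma_b/\sqrt{P})$, is drawn back in —
shared across conditions, so contrasts are again untouched. This is exact
up to the local flatness of the group-mean prior and lifts the group-mean
effective sample size from tens to over a thousand at the `test` profile.
Second, convergence problems (split-chain PSRF > 1.1 or ESS < 100 on group
parameters) are flagged with a warning but never silently fail: the fit is
returned with its diagnostics.

## 4. Model comparison

`psis_loo()` implements Pareto-smoothed importance-sampling leave-one-out
cross-validation directly on the pointwise log-likelihood matrix: per
observation, raw importance ratios $1/p(y_i\mid\theta^{(s)})$ have their
largest $\min(0.2S,\ 3\sqrt{S})$ values replaced by quantiles of a
generalised Pareto distribution fitted to that tail (profile-posterior
method with a weak prior pulling the shape toward 0.5), then truncated at
the raw maximum. Observations with tail shape $\hat k > 0.7$ trigger a
warning and are never dropped. The beta-binomial likelihood is evaluated at
the sampled $\theta_{p,c}$ (not integrated per draw); this is the standard
conditional pointwise likelihood and is stated here because it defines what
"one observation" means in the comparison.

`compare_models()` reports the comparison-table fields (0-based rank, loo
= elpd, p_loo, d_loo, weight, se, dse). Weights are **log-score stacking**
over the simplex (the weight one would give each model when averaging
predictions); pseudo-BMA is available behind `method = "pseudobma"`. On a
flat objective (indistinguishable models) the optimiser stays at equal
weights, which is the correct tie-break. The dse is computed from the
pointwise elpd differences.

The package never computes a Bayesian repeated-measures ANOVA with
inclusion Bayes factors: those roles are covered by posterior contrasts on
the free fits and by JZS paired Bayes factors (directed where the design's hypothesis
test was directed). The mapping is: condition main effects → pairwise
posterior contrasts with HDIs; the selection-by-condition interaction →
directed paired tests of the first- and second-selection delays
(`rel` vs `sim`); the patch-leaving tests → `mvt_test()`.

## 5. The synthetic-data generator

The generator produces what the analysis consumes — timestamped click
events — with the statistical signatures the models assume.

**Depletion curve.** Within a trial, expected instantaneous rates decline
linearly across the 15 selections by an overall factor
`rate_decline_ratio` (default 2.5: the first target is found about 2.5×
faster than the fifteenth). ITTs are log-normal (`itt_shape`, the log-scale
SD, default 0.5 — right-skewed, as response times are) with
$E[1/ITT_j] = r_j$ on that curve. The curve's scale is calibrated per
participant-condition so that the *expected trial-level RoR equals the
generating mean* `ror_pc`, including the travel second, the
first-selection bonus, the leaving policy's truncation of the trial, and a
second-order correction for $E[m/(D+1)]$. Calibration is a 1-D bisection;
its accuracy (cohort mean RoR within ~0.01 of target for both depleting
and leaving policies) is asserted in the test suite.

**Leaving policies.** Three archetypes, assigned per participant by
`policy_mix`:

- `collect_all` (default share 0.745): depletes every patch;
- `mvt_threshold`: leaves when the *expected* instantaneous rate for the
  current depletion level reaches a threshold (the environment's average
  RoR unless overridden);
- `early_threshold` (default share 0.255, threshold 1.1 items/s): same
  rule, threshold above the average — the "active leaver" archetype.

The decision statistic is the agent's expected rate at its depletion
level, not the single noisy realised interval: foragers track their intake
smoothed over recent experience. Leaving happens at the selection nearest
the threshold crossing with symmetric ±1 jitter, which makes the mean
*realised* last-selection rate an unbiased estimate of the threshold — the
property the marginal-value-theorem checks require, verified by Monte
Carlo in the tests. Because every trial's expected RoR is calibrated to
`ror_pc` regardless of policy, the cohort's average RoR equals the mean of
the generating condition means, so "threshold = environment average" is
self-consistent without iteration.

**Defaults as study conditions.** Group RoR means (0.978, 0.985, 1.136,
1.117 items/s), 47 participants, 1000-point goal checked after every
patch, blocks of 12 trials (three per condition, shuffled; target shape
switching every two blocks), `between_sd = 0.18` (the spread of individual
foraging speed consistent with group-level interval widths of roughly
±0.055 items/s at n = 47), `interaction_sd = 0.05` (condition patterns are
largely parallel across participants), `error_prob = 0.005` (cohort error
rates below 0.8%), `first_delay_bonus_rel_ms = 150` (a plausible magnitude
for the short-lived first-selection capture effect, whose size is
otherwise unconstrained), and `rel_leave_bias = 1.05` (relational patches
are abandoned slightly earlier, the effort-avoidance reading of the small
rel-vs-sim difference in targets left behind). The leaver share 0.255
encodes 12 active leavers among 47 participants. With the per-patch goal
check, the mean number of (fractional) blocks to finish is ~5.9; the
arithmetic of 12 × 15 points per block makes means much below 5.6
impossible, so the generator targets the 5–6 band.

**What the generator does not emulate.** Selection latencies are drawn,
not emergent from spatial search: stimulus positions and kinematics exist
for layout realism but do not cause the timestamps. Depleting trials
therefore end at the *low* tail of the rate curve, whereas real foragers
in easy conditions kept their final-selection rates above the environment
average; the simulator reproduces the policy logic of patch leaving, not
that terminal-rate signature. No colour-rendering fidelity, no
sit-and-wait strategies, no learning across blocks. Passing tests on
synthetic cohorts demonstrate that the estimation and comparison machinery
recovers known generating structure at the study's scale — not that the
behavioural effects themselves are re-established in human data.

## 6. Screening

Participant level: more than 600 wrong clicks in total, or any ITT below
30 ms (humanly impossible; a technical artefact), excludes the
participant. Trial level: more than 10 s before the first selection or
20 s between selections removes the trial. The strategy-outlier filter is
a committed reimplementation choice (no canonical algorithm for this filter
exists): for each trial, the remaining trials of
its participant-condition cell define a beta-binomial posterior predictive
(binomial likelihood, Jeffreys prior), and the trial is removed when the
predictive probability of leaving at least as many targets falls below
`alpha = 0.005`. Only the upper tail is tested — the failure mode of
interest is an accidental "Next" click leaving unusually many targets;
collecting everything is never an outlier. Removal is idempotent, the two
trial-level filters commute on realistic data, and the removed fraction is
monotone in `alpha`; on calibrated synthetic cohorts it stays well under
2% of trials.

## 7. Auxiliary inference

- `hdi()`: narrowest contiguous interval with the target mass
  (sorted-window); width grows with the mass parameter.
- `paired_bf()`: JZS Bayes factor for paired designs — Cauchy(0, 0.707)
  prior on the standardised effect, numerator integrated with R's
  `integrate()` against the non-central t density; directed tests truncate
  the prior to positive effects (and obey
  $BF_{10} = (BF_{+0} + BF_{-0})/2$). All-zero differences are perfectly
  null data and return the corresponding null-favouring factor;
  zero-variance differences with nonzero mean are an error.
- `rm_corr()`: repeated-measures correlation by the ANCOVA formulation
  (participant intercepts plus common slope), dof
  $n_{obs} - n_{participants} - 1$.
- `mvt_test()`: per condition, participant mean last-selection rates are
  tested two-sided against the single grand average RoR (conditions are
  intermixed, so one reference value applies); labels `at_average` /
  `above_average` / `below_average` use a Bayes-factor threshold of 3.

## 8. Problem sizes

The test suite runs cohorts of 47 participants (~3 000–3 400 trials after
screening) for recovery and identification studies — ten seeds for each
recovery criterion, ten relational-generated and five
feature-specific-generated cohorts for identification — at the `test`
sampler profile, plus smaller cohorts (8–30 participants) for unit-level
checks. These sizes were chosen so that a full run completes on a single
CPU in well under half an hour while keeping every check at the study's
native cohort size where the criterion depends on it. The `full` profile
reproduces the long production sampling settings when wanted.

## 9. Known limitations

- The group-level pTLB mode is near zero on zero-inflated mixture cohorts
  (section 3.2); condition ordering information then lives in the
  participant-level proportions and the comparison still identifies the
  generating account, but the group mode is not comparable to a cohort
  mean.
- The strategy-outlier filter is a stand-in with a documented criterion,
  not a canonical algorithm.
- JZS Bayes factors assume approximate normality of the paired
  differences; with n = 47 participant means this is mild.
- PSIS-LOO tail shapes above 0.7 are warned about, not refitted by exact
  cross-validation.
- Fits are persisted as plain CSV draws plus JSON metadata rather than a
  binary posterior container.
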