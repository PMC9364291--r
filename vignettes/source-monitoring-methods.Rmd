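---
title: "Measuring schema-based source memory: models, simulation, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring schema-based source memory: models, simulation, and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptsource)
```

## The problem

In the schema-based source-monitoring paradigm, participants study items
paired with sources for which they are schematically expected (a toothbrush
in a bathroom) or unexpected (a shampoo bottle in a kitchen), and later
attribute test items to the expected source, the unexpected source, or
declare them new. Raw attribution accuracy confounds three processes: item
recognition, genuine source memory, and guessing — and schema-based
expectations push on the guessing process specifically (people guess the
expected source). Separating these processes is the job of the
two-high-threshold multinomial processing-tree (MPT) model of source
monitoring that this package implements, together with everything needed to
analyze — or simulate end to end — a two-group experiment on metamemory
judgments of source (JOS), restudy choices, and source memory.

## The model

Three trees generate the 3×3 table of response counts (trial types:
expected-source, unexpected-source, new; responses: "expected",
"unexpected", "new"):

* `D_E`, `D_U` — probability that an item studied with the
  expected/unexpected source is recognized as old;
* `d_E`, `d_U` — probability that its source is remembered, given
  recognition;
* `b` — probability of guessing "old" for an unrecognized item;
* `g` — probability of guessing the *expected* source when source memory
  fails (`g > .5` is schema-consistent guessing);
* `D_N` — probability of detecting a new item as new.

A recognized item is never called "new": when source memory fails, guessing
resolves it to one of the two sources. With a single table the model has
seven parameters but six free data proportions, so an equality restriction
on `D_N` is required for identifiability; `D_N = D_U` is the default and
`D_N = D_E` is available (conclusions about source memory are insensitive to
the choice on the bundled data — both fits are one function call away).

`category_probabilities()` spells out the nine branch sums;
`fit_mpt_ml()` fits one aggregate table. Because the restricted model is
exactly identified, the maximum-likelihood solution reproduces the observed
proportions and `G² = 0` whenever it is interior; the fit therefore first
inverts the moment equations in closed form (solve `g` from the new-item
row, then `b` and the recognition parameters from the "new"-response
proportions, then `d_E`, `d_U` from the remaining cells) and only falls back
to numeric maximization on the logit scale when the inversion leaves the
unit interval. Boundary solutions (e.g. a new-item row with no "old"
responses forces `b = 0`) are flagged, not fatal. No smoothing is applied to
zero cells; the logit parameterization keeps the numeric path away from
exact 0/1.

## Hierarchical latent-trait estimation

Aggregate fits ignore individual differences, and with 32 items per trial
type individual tables are too sparse to fit alone. The latent-trait
approach places the probit transforms of the six individual parameters under
a multivariate normal: `z_i ~ MVN(mu, Sigma)`, `theta_i = Phi(z_i)`.
`fit_hb()` estimates this hierarchy by Metropolis-within-Gibbs:

* component-wise adaptive random-walk updates of each `z_i` (adaptation
  during burn-in only), plus an independence proposal from each component's
  conditional prior — for weakly informed components (typically `d_E` when
  recognition is moderate) the likelihood is nearly flat and these proposals
  accept almost always, giving near-iid movement exactly where a random walk
  crawls;
* conjugate Gibbs updates for `mu` (prior `N(0, 1)` per component on the
  probit scale) and `Sigma`;
* interweaving (ancillarity–sufficiency) moves that shift `mu` or rescale
  the diagonal of `Sigma` jointly with the individual deviations. Without
  them, the funnel-shaped coupling between hierarchy and individuals keeps
  split R-hat in the 1.2–3 range at desk-scale run lengths; with them the
  same runs reach R-hat ≈ 1.003–1.01 with effective sample sizes in the
  hundreds to thousands.

The covariance prior is the Huang–Wand hierarchical inverse-Wishart with
`nu = 2`, `A = 2.5`, chosen because it gives weakly informative half-t(2)
marginal priors on the individual standard deviations *and* keeps every
hyperparameter update conjugate; a half-Cauchy-plus-correlation
decomposition expresses the same intent but has no conjugate update and
would need additional Metropolis machinery for no practical gain at this
model size.

Run lengths: the default `hb_control("desk")` uses 4 chains × 20,000
iterations (10,000 burn-in, thinning 5; 2,000 retained draws per chain),
which mixes well for 40–72 participants and keeps a full two-group pipeline
run in the tens of seconds. `hb_control("production")` mirrors a long production
configuration (500,000/250,000/10; 25,000 retained per chain) for final
reports. At least two chains are required because split R-hat — the
convergence diagnostic reported by `gelman_rubin()` — is undefined for one;
the monitored quantities are the group-level means and the diagonal of
`Sigma` (individual parameters are deliberately not monitored). Note that at
desk-scale run lengths the split R-hat *estimator* itself fluctuates by
roughly ±0.005–0.01 between chain seeds, so isolated values slightly above
1.01 on short runs indicate estimator noise rather than non-convergence;
doubling or tripling the run length settles them.

One master seed drives everything: per-chain seeds are derived
deterministically from it, and identical input yields bit-identical draws.
Chain starting points are the pooled closed-form estimate plus
chain-specific probit jitter (SD 0.25), giving modest overdispersion for an
honest R-hat.

### Model fit and contrasts

`posterior_predictive_check()` implements the two posterior-predictive
discrepancy statistics conventional for hierarchical MPT models. T1 is a
chi-square-type distance between the observed and expected across-participant
mean category frequencies; T2 is the Frobenius distance between the observed
across-participant covariance matrix of the nine category counts and its
model-implied counterpart (between-participant spread of expected counts
plus mean within-participant multinomial covariance). The named statistics
are conventionally cited rather than restated in print, so these two
discrepancy functions are this package's documented interpretation of them.
For each retained draw, a replicate data set is simulated from that draw's
individual parameters; the p-value is the fraction of replicates whose
statistic exceeds the observed one. Because the posterior is conditioned on
the observed data, these p-values concentrate toward 0.5 under a correct
model (they are conservative); values near 0 signal misfit. With fewer than
two participants T2 is undefined and reported as `NA`.

`parameter_contrast()` evaluates arbitrary expressions over the group-level
probability-scale parameters, draw by draw — within one posterior (the
inconsistency effect `d_U - d_E`) or across two (group differences,
difference-of-differences). Independent groups are paired by draw index;
mismatched draw counts are subsampled with a seed. A contrast is significant
exactly when its central 95% credibility interval excludes zero; the flag is
never computed any other way.

## Behavioral statistics

The monitoring/control layer of such experiments uses a small, fixed
statistical toolkit, all implemented here with their standard definitions:
balanced 2×2 ANOVA (mixed or fully within-subjects) with partial eta squared
per effect (`SS_effect / (SS_effect + SS_error)` with the effect's own error
term); paired and pooled-variance independent t tests with `d_z = t/sqrt(n)`
and Cohen's d; Goodman-Kruskal gamma between 0–100 judgments and binary
restudy choices (ties dropped from both counts — the standard definition;
participants with no concordant or discordant pairs are undefined and must
be excluded listwise, which is why group tests can have fewer degrees of
freedom than participants); Loftus-Masson within-subject confidence
intervals (`t * sqrt(MS_interaction / n)` after removing participant means);
and the a-priori sample-size search for paired designs via the noncentral t
distribution. Follow-up t tests are two-sided throughout; the power analysis
is one-sided when so specified. No multiple-testing correction is applied
anywhere, matching standard practice in this literature.

## The synthetic experiment

`simulate_experiment()` generates trial-level records for the full two-group
design: 72 participants per group, 32 expected + 32 unexpected studied pairs
and 32 distractors, study phase, delayed-judgment phase (delayed group
only), restudy phase (exactly 32 pairs), and the 3AFC test. Its purpose is
to give every downstream stage — aggregation, exclusion screening, ML and
hierarchical fitting, the behavioral layer — realistic, structurally
faithful input without any external data. Defaults were fixed once, from the
published study conditions, and are not tuned to test outcomes:

* group-level memory parameters at the hierarchical point estimates of the
  corresponding groups, with probit-scale heterogeneity SD 0.5 (a moderate,
  typical value for individual differences in this paradigm);
* delayed-group 2AFC retrieval solved in closed form from the printed
  correct-attribution rates: with schema-consistent guessing `g' = .69`,
  `P(correct | expected) = d'_E + (1-d'_E) g' = .75` and
  `P(correct | unexpected) = d'_U + (1-d'_U)(1-g') = .61` give
  `d'_E = .194`, `d'_U = .435`;
* JOS linear model: intercept 50, expectancy effect +15 points (immediate
  group) or −2 (delayed group, a weak inconsistency-direction effect),
  +20 points after a correct 2AFC attribution, participant random intercept
  SD 10, participant random expectancy-slope SD 10, residual SD 12, rounded
  and clamped to 0–100 (integer granularity). The random slope matters: with
  only a residual term the implied within-subjects effect size would be
  d_z ≈ 5; with it, the immediate-group expectancy effect lands at
  d_z ≈ 1.4 and the delayed effect near 0.2, the published magnitudes;
* restudy choices: sequential logistic in the JOS,
  `P(choose) = plogis(-(JOS - 50)/15)`, with the choice screen withheld once
  32 pairs are chosen; if fewer than 32 are chosen the remainder is filled
  by a random 50/50 expected/unexpected substitution (an odd remainder is
  split at random). This yields predominantly negative JOS-restudy gamma
  correlations and a near-binding cap (median 32 chosen);
* an optional restudy boost (additive probit shift on the memory parameters
  of restudied items), default 0 — consistent with the finding that restudy
  differences moved source memory only weakly — and configurable for power
  studies.

What the generator does *not* emulate: item-level effects (items are
exchangeable within expectancy class; counterbalanced lists are not
modeled), reaction times, two distinct named scenes (trial records code
pairings as expected/unexpected, the coding every analysis uses), and any
group difference in how strongly JOSs drive choices (one choice slope serves
both groups, so the between-group gamma difference reported in the
literature is not built in). A passing test suite therefore demonstrates
correctness of the machinery under this generative model, not the truth of
that model for any real data set.

## Numerical choices and degenerate inputs

* Exactly identified ML fits: closed form first, logit-scale BFGS with a
  Nelder-Mead polish as fallback; parameters within 1e-4 of a bound set the
  boundary flag.
* Log-likelihood is `-Inf` when a positive count sits on a zero-probability
  cell; no smoothing anywhere.
* Zero-variance t tests: `t = 0` for zero mean difference, flagged infinite
  otherwise. All-identical restudy choices make gamma undefined rather than
  zero.
* Identical constant MCMC chains report R-hat 1 by convention (0/0 handled).
* The power search walks n upward from 2; power is monotone in n for the
  noncentral t, so the first crossing is the answer.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed, and the pipeline report
records the seed and an MD5 hash of the configuration. The test suite runs
its recovery and calibration studies at reduced scale — 40 participants,
the desk-scale MCMC configuration, 40 recovery replicates and 20
posterior-predictive replicates — sizes chosen to make the whole suite a
coffee-break affair on one core while leaving the Monte Carlo error of each
check well inside its assertion margin. The production-scale configuration
remains available as a preset for production analyses.
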