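---
title: "Survey-weighted counterfactual mediation: models, defaults and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survey-weighted counterfactual mediation: models, defaults and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svymediate)
```

This vignette is the package's account of its statistical machinery: the
estimator it implements, the assumptions that machinery rests on, the
defaults and why they were chosen, what the synthetic-cohort generator does
and does not emulate, and the numerical decisions that a maintainer or
referee would want spelled out.

## The estimation problem

The setting is a cross-sectional population survey with a
stratified-cluster design: each record carries a sampling weight, a stratum
identifier and a primary sampling unit (PSU) nested in its stratum. The
scientific question is bidirectional mediation between heavy substance use
and depression among people exposed to sexual assault: (i) how much of the
exposure–depression association runs through substance use, and (ii) how
much of the exposure–substance-use association runs through depression.
Exposure, mediator and outcome are all binary; mediator and outcome share a
12-month recall window, so neither ordering is observationally privileged
and both recursive models are run on the same data.

All analyses are sex-specific: exposure prevalence and both health
outcomes differ strongly between women and men, so sex is a stratification
variable, never a model term.

## The estimator

For each analysis cell, two logistic models are fitted by maximising the
weight-multiplied log-likelihood on the listwise-complete records:

$$\mathrm{logit}\, P(M=1 \mid A=a, C=c) = \beta_0 + \beta_1 a + \beta_2' c$$
$$\mathrm{logit}\, P(Y=1 \mid A=a, M=m, C=c) = \theta_0 + \theta_1 a +
  \theta_2 m + \theta_3 am + \theta_4' c$$

and combined into conditional natural-effect odds ratios for the contrast
$a=1$ vs $a^*=0$ (see `?combine_effects` for the closed forms). The total
effect satisfies $OR^{TE} = OR^{NDE} \times OR^{NIE}$ exactly — an
algebraic identity of the combination, which the test suite asserts to
1e-10 on every estimate. The proportion mediated is
$\log(OR^{NIE})/\log(OR^{TE})$, reported as a percentage with one decimal
in rendered tables.

**Assumptions.** Beyond the usual no-unmeasured-confounding conditions of
natural-effect identification, the closed-form odds-ratio combination
requires the outcome to be *rare* at every covariate/exposure/mediator
configuration, so that odds ratios approximate risk ratios. The health
outcomes here span roughly 0.7%–12.3% prevalence, so the approximation is
excellent in some cells and visibly strained in others. The package treats
this the way the applied literature does — it uses the formulas throughout —
but records the analysis-sample outcome prevalence in every result object
(`glance()` exposes it) so the reader can judge the cell. Against the exact
counterfactual oracle (below), the relative error of the formulas is about
0.03–0.06% at 1% outcome prevalence and about 2% at 11–12% prevalence
(total-effect OR, default generator coefficients); the acceptance suite
pins both regimes.

**Exposure–mediator interaction.** The outcome model carries the $\theta_3
am$ term by default (`interaction = TRUE`); with the flag off the code sets
$\theta_3 = 0$, recovering the no-interaction product method. The general
form is the default because it is never wrong when the interaction is null,
merely slightly noisier, while the reverse omission biases both effects.
The configuration used is echoed in the output metadata.

**Covariate evaluation.** The natural-effect odds ratios are conditional on
a covariate setting $c$. The default is the weighted mean of the
indicator-coded covariate columns of the analysis sample — the convention
of the regression-based mediation software ecosystem — with `"modal"` (the
weighted-majority covariate cell) and `"explicit"` settings selectable. The
exact oracle supports the same evaluation points so that estimator and
truth are always compared at the same $c$.

## Survey-design handling

Weights enter estimation as frequency-style multipliers of the
log-likelihood; they are carried through bootstrap resamples, never
re-derived. Model-based standard errors are deliberately not computed
anywhere: all interval estimation is by the percentile bootstrap, which is
the only variance machinery whose assumptions survive the weighting.

Resampling honours the design by default (`resampling = "psu"`): within
each stratum, PSUs are drawn with replacement up to the original PSU
count, each draw carrying all member records. A stratum with a single PSU
falls back to independent row resampling within that stratum. The
alternative `"iid"` mode resamples rows and is appropriate when design
columns are absent. Replicate random-number streams are derived from
`(seed, replicate_index)`, so any single replicate is reproducible in
isolation and the full set is independent of execution order.

Percentile intervals use linear interpolation between order statistics
(R's default sample-quantile definition, type 7); the choice is recorded in
the output metadata because percentile dialects differ across software.
Replicates that fail — non-convergence, separation, or an exposure or
response class lost in resampling — are dropped and tallied; if fewer than
`min_success_fraction` (default 95%) survive, the interval is refused with
the tally in the error, rather than silently computed from a selected
subset.

Design-based prevalence estimation (`weighted_prevalence()`) uses Taylor
linearisation of the ratio estimator aggregated to PSU totals within strata
(with-replacement approximation) and a Wald interval on the logit scale,
back-transformed — the interval therefore respects $[0,1]$ and degenerates
to the point for constant variables. The descriptive comparison rule is
deliberately conservative: two prevalences differ only when their 95%
intervals are disjoint, with a shared endpoint counting as overlap.

## The synthetic-cohort generator

The study data the method targets are not publicly deposited, so the
generator stands in for them in every test. It draws covariates (six age
groups 18–75, three education levels) from sex-specific categorical
distributions, then exposure, mediator and outcome from the logistic
structural equations of the assumed causal graph, plus auxiliary health
variables from exposure-and-covariate models. Model intercepts are not
free parameters: they are solved by exact enumeration over the finite
covariate support so that the implied marginal prevalences reproduce the
published sex-specific figures (lifetime exposure 14.0%/2.7%
women/men, depression 10.7%/5.6%, heavy tobacco 7.8%/12.3%, frequent
cannabis 1.0%/2.6%, hazardous alcohol 0.7%/0.9%). The slope coefficients
are the package's own choices — the study reports no structural-scale
coefficients — picked once to give odds ratios in the range of the
published mediation tables (exposure–outcome log-odds 1.1, mediator–outcome
0.65, exposure–mediator 0.6, interaction 0.15) and documented here rather
than tuned.

Childhood-onset exposure is nested inside lifetime exposure with the
conditional probability implied by the published marginals; a
repeated-exposure flag (conditional probability 0.4 given exposure, a
plausibility choice) supports the sensitivity contrast that compares
repeated exposure with none while dropping single-event records.
Missingness is injected completely at random with per-variable rates
mirroring the published missing counts (alcohol ≈ 4.5%, others well below
1%) — the study found no pattern in incomplete responses, and
missing-at-random generators are out of scope. The survey design is a
generic 10-strata × 20-PSU layout with log-normal weights of unit mean
(spread 0.5 on the log scale), independent of all variables: the study's
actual two-stage municipality sampling is not reproduced, and the design
exists to exercise the design-handling code paths, not to claim design
realism.

Consequently, passing tests show that the estimator recovers known truth
under a faithful *structural* emulation with an idealised *design*; they do
not show robustness to informative weights, non-response, or
non-random missingness, none of which the generator produces.

## The exact counterfactual oracle

For any parameter set, `true_effects()` computes the counterfactual risks
$P(Y_{a,M_{a^*}}=1 \mid c) = \sum_{m\in\{0,1\}}
\mathrm{expit}(\theta_0+\theta_1 a+\theta_2 m+\theta_3 am+\theta_4'c)\,
P(M=m\mid a^*,c)$ — a two-term sum, because the mediator is binary — and
converts them to odds ratios without any approximation. This is the
reference truth for recovery tests, and it is itself validated in the
suite against a brute-force Monte-Carlo counterfactual simulation on five
random parameter sets (200,000 potential-outcome draws each, agreement
within three Monte-Carlo standard errors of the underlying risks).

## Numerical choices

- IRLS (implemented in compiled code for bootstrap throughput): relative
  deviance tolerance 1e-8, at most 100 iterations, Newton steps with step
  halving; coefficients cross-checked against R's reference GLM fitter to
  1e-8 in the suite.
- Separation: flagged when any fitted probability is within 1e-8 of 0 or 1
  at convergence, or any coefficient exceeds 15 in absolute value on the
  logit scale. Point estimation refuses on separation; bootstrap replicates
  are dropped and counted. No penalised fallback is offered.
- A null total effect makes the proportion mediated undefined; it is
  returned as `NA` with an explicit warning, never as 0. Opposite-signed
  direct and indirect effects put PM outside [0,1]; the value is returned
  as-is with a warning.
- Categorical covariates are indicator-coded against their first level
  (age 18–25, education high).
- Per-replicate seeds are `(seed · 69069 + replicate) mod (2³¹ − 1)`,
  which stays in exact double arithmetic and within R's integer range.

## Validation design and problem sizes

The simulation studies in the test suite use sizes chosen to make their
tolerances meaningful on a single CPU:

- *Calibration*: one cohort of 10⁶ records per sex; every marginal
  prevalence within three Monte-Carlo standard errors of its target (the
  intercept calibration is exact, so this checks the sampler, not the
  solver).
- *Parameter recovery*: one cohort of 2×10⁵ records from a parameter set
  with ~33% exposure and ~5.5% outcome prevalence, so that sampling error
  and the rare-outcome gap are both small against the 0.05 log-OR
  tolerance; plus 200 cohorts of 2,000 under a null exposure–mediator path,
  whose median indirect-effect OR must be 1 within Monte-Carlo error.
- *Coverage*: 200 outer cohorts of 5,000 records, 500 bootstrap replicates
  each (scaled down from the 1,000 used for real analyses), nominal 95%
  indirect-effect intervals required to cover the estimator's own estimand
  — the formula value at the generating coefficients — between 90% and 99%
  of the time. Coverage is assessed against that estimand rather than the
  exact oracle because an interval estimates its estimator's limit; the
  formula-vs-oracle gap is tested separately. A complementary null-design
  check (120 cohorts of 2,500 with the exposure–mediator path set to zero,
  200 replicates each) requires the indirect-effect interval to contain 1
  at about the nominal rate. Percentile intervals are known to undercover
  modestly for small effects at moderate event counts — at these settings
  the exposed-with-mediator cell holds only ~80 events per cohort — so the
  non-null experiment sits near the lower edge of its band and can fall
  just below it at particular seed sets; the suite keeps its seeds fixed
  rather than selected.

## Known limitations

- The odds-ratio combination inherits the rare-outcome approximation; for
  outcomes above ~10% prevalence the reported ORs drift a few percent from
  the exact counterfactual quantities, in a direction and magnitude the
  package quantifies but does not correct.
- Only binary mediators and outcomes, one mediator at a time, and the
  two-way decomposition are supported; four-way decompositions,
  multiple-mediator path analysis and mediated-confounder sensitivity
  measures are out of scope.
- Listwise deletion is the only missing-data strategy, matching the
  analysis the package reproduces; it assumes missingness unrelated to the
  model variables.
- The bootstrap treats the weights as fixed; designs whose weights would
  be re-derived per replicate (post-stratification, raking) are not
  modelled.
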