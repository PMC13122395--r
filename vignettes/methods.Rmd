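---
title: "Policy contrasts for longitudinal panels: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Policy contrasts for longitudinal panels: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrshift)
```

## The problem

Observational panels that measure a behavioural exposure (here, the
motivating case is monthly religious service attendance in a national annual
attitudes panel) and many well-being outcomes invite causal questions of the
form *"what would happen to outcome Y if exposure became more (or less)
common, compared with the observed course?"*.  sdrshift structures such an
analysis as a target-trial emulation:

1. declare the columns and their temporal roles (`panel_schema()`),
2. restrict to the eligible cohort (`restrict_cohort()`),
3. specify both sides of each contrast as explicit policies (`policy()`),
4. check what the data can support (`positivity_report()`),
5. estimate with a cross-fitted sequentially doubly robust (SDR) estimator
   under censoring weights (`estimate_policy_mean()`),
6. report outcome-wide with familywise-adjusted intervals and E-values
   (`outcome_wide_run()`).

## Policies

For a binary exposure $A_t \in \{0,1\}$ at intervention waves $t = 1,\dots,K$
with natural propensity $g_t(h_t) = P(A_t = 1 \mid H_t = h_t)$, the package
implements:

* **identity** — the natural course, the reference in most contrasts;
* **set-to-value** — deterministic "everyone exposed" / "no one exposed";
* **incremental propensity score (IPS) shift** with intensity $\delta \ge 1$,
  which divides the conditional probability of *non*-initiation by $\delta$:
  $$ g^d_t(h_t) \;=\; 1 - \frac{1 - g_t(h_t)}{\delta}. $$
  When initiation is rare this compression is large: a per-wave initiation
  probability of 0.03 becomes $1 - 0.97/5 = 0.806$ under $\delta = 5$.  A
  five-fold shift therefore describes a world in which most non-initiators
  begin, not a marginal nudge;
* **additive shift** for a continuous exposure: $a \mapsto a + s$ except
  where the shift would leave the observed support (the `support_cap`,
  defaulting to the sample maximum), where the exposure is left unchanged.

Two conventions for "incremental" interventions coexist in the literature:
multiplying the odds of treatment by $\delta$ (which yields density ratios
bounded in $[1/\delta, \delta]$), and dividing the non-initiation probability
by $\delta$.  The package deliberately implements the second.  The choice has
real statistical consequences discussed under *Limitations*: the density
ratio at an observed initiation is $g^d/g \approx 0.8/g$, which is large when
initiation is rare.  Shifts with $\delta < 1$ are rejected rather than
silently supported, since the reverse direction is not defined here.

## Identification and estimation

Identification rests on consistency, sequential exchangeability given the
measured history (baseline covariates, all earlier exposures, and
time-varying confounders up to each wave), and positivity.  Attrition is
handled by treating loss to follow-up as a censoring process intervened to
"remain observed": every estimand is a mean in the hypothetical uncensored
population, and inverse-probability-of-censoring weights with per-node
continuation models $P(\text{observed} \mid \text{history})$ enter the
estimator alongside the policy density ratios.

The estimator is a one-step, cross-fitted SDR construction.  Writing
$r_t$ for the policy density ratio at the observed exposure,
$u_t = 1\{\text{observed}\}/\hat P(\text{observed}\mid\cdot)$ for the
censoring weight at the node before wave $t$ (and $u_{K+1}$ for the outcome
wave), the backward recursion per cross-fitting fold is

$$ \varphi_{K+1} = Y, \qquad
   m_t = \hat E\left[\varphi_{t+1} \mid H_t, A_t\right], \qquad
   \varphi_t = \bar m_t + r_t\, u_{t+1}\, (\varphi_{t+1} - m_t), $$

where $\bar m_t$ evaluates $m_t$ at the policy exposure — for stochastic
policies by exact enumeration over the binary exposure (no sampling), for
additive shifts at the shifted value.  Regressions are fit only on rows
observed at the next node, and a final baseline regression $m_0$ carries the
value to the full cohort.  The estimate is the mean of the per-participant
influence construction $D = m_0 + u_1(\varphi_1 - m_0)$, so the influence
values average exactly to the point estimate and
$\widehat{se} = sd(D)/\sqrt n$.  Contrasts difference the per-participant
influence values, pairing the two policies on participants.  The one-step
(EIF-mean) form was chosen over targeted-update variants because it makes
the influence values directly available for paired contrasts and
familywise-adjusted intervals; the consistency guarantee is the usual
sequential one — at each stage, either the outcome regression or both the
treatment and censoring models must be estimated well.

One caveat the package surfaces rather than hides: an IPS policy is itself a
function of the propensity, so the "outcome model correct, treatment model
wrong" arm of the classical double-robustness guarantee does not apply to
IPS contrasts (the estimand's shifted draw uses $g$).  It does apply to
policies that ignore $g$, such as set-to-zero.

### Nuisance models

Cross-fitting uses `n_folds = 5` by default; every prediction for a
participant comes from models whose training folds excluded that
participant.  The learner menu is deliberately small — `mean`, `glm`,
`ridge`, `stump` (depth-2 tree), `xgb` (shallow boosted trees) — standing in
for a full stacked-ensemble library; menus with several learners resolve by
discrete holdout selection inside each training fold.  The default
*treatment* learner is `ridge` (an L2-penalised logistic regression whose
penalty is chosen on a held-out quarter of the training fold): with ~2–3%
initiation and tens of adjustment columns, unpenalised maximum likelihood
overfits badly and produces near-zero cross-fitted propensities for true
initiators, which the density ratio then inflates catastrophically.  On the
synthetic cohort the ridge propensities recover the true logistic mechanism
with root-mean-square error under 0.01 at moderate sample sizes.

### Numerical safeguards

* Propensities are trimmed to $[5/(\sqrt n \log n),\; 1 - 5/(\sqrt n \log n)]$
  (a standard adaptive rule) before entering ratios.
* Censoring continuation probabilities are bounded below at 0.01.
* Cumulative weighted ratios are capped at their 99.9th percentile
  (`ratio_truncation = 0.999`).
* A training fold containing a single exposure class falls back to the
  marginal rate, and the fallback is logged in the fit object.
* Degenerate inputs error early and specifically: empty cohorts, zero-variance
  outcomes, missing propensities for uncensored rows, mismatched participant
  sets in a contrast.

### Post-stratification weights

Survey calibration weights are accepted as a column, never constructed.  By
default they enter only the final averaging (the influence values are
weight-normalised); `weight_mode = "nuisance"` additionally weights every
nuisance regression.  The default was chosen because the estimand targets
the weighted population while the nuisance models are prediction devices,
but both modes are exposed since practice varies.

## Positivity as a gate, not a footnote

`cumulative_ratios()` computes per-wave density ratios and their running
product — the quantity that actually multiplies the estimator — for every
uncensored participant-wave.  `positivity_report()` declares a policy
supported when the fraction of final-wave cumulative ratios strictly below
`floor` is at most `fraction_threshold`.  There is no canonical numeric
rule for such a verdict, so the defaults here
(`floor = 0.02`, `fraction_threshold = 0.5`) were calibrated once so that
the qualitative ordering reproduces on a two-wave cohort with ~2–3% per-wave
initiation: a never-initiator's cumulative ratio under an IPS shift is
exactly $1/\delta^2$ — 0.25 at $\delta=2$, 0.04 at $\delta=5$, 0.01 at
$\delta=10$ — so any floor strictly between 0.01 and 0.04 separates the
five-fold shift (supported) from the ten-fold shift (unsupported), while
set-to-one collapses to ratio 0 for the ~97% never-exposed and fails, and
identity and set-to-zero sit near 1 and pass.  Both thresholds are plainly
reported in every verdict and exposed as arguments; they are a calibrated
reporting convention, not a property of the data.  `outcome_wide_run()`
gates estimation on the verdict: unsupported contrasts yield rows flagged
`"not estimated: positivity"`, never silent numbers.

## Outcome-wide reporting

Confidence intervals are widened to the per-comparison level $\alpha/m$
(Bonferroni across the `m` outcomes; $z = `r round(qnorm(1 - 0.05/48), 4)`$
at $m = 24$) rather than adjusting p-values, matching the interval-first
reporting style.  E-values convert each standardised mean difference to an
approximate risk ratio $RR = e^{0.91\,\theta}$ and report
$E = RR + \sqrt{RR(RR-1)}$ for the point estimate and for the adjusted
interval limit closer to the null (set to 1 when the interval crosses the
null).  An estimate is flagged *reliable* only under the dual rule: the
adjusted interval excludes zero **and** the bound E-value exceeds 1.10.
The 0.91 constant is the standard approximate conversion for standardised
mean differences; it is a reporting convention recorded in the metadata.

`baseline_associations()` produces the descriptive cross-sectional panel.
By default it adjusts for nothing beyond the weights: on a synthetic cohort
whose confounding is an exact linear function of the observed covariates, a
fully adjusted linear association would absorb the confounding entirely and
erase the association-versus-causation gap the panel exists to display.

## The synthetic cohort and its oracle

`generate_cohort()` emulates the statistical structure the estimator
assumes, not any real population: 62 baseline covariate columns by default
(20 continuous, 17 binary, the baseline exposure, and baseline measurements
of all 24 outcomes); a latent confounder built from the generic covariates
that loads on every exposure logit and outcome
(`confounding_strength = 0.4`); wave-1 initiation calibrated to ~2–3% among
baseline non-exposed (`init_intercept = -3.8`); strong exposure persistence
(`persistence = 6` on the log-odds scale, ~90% year-over-year retention of
the behaviour, which is realistic for attendance-type exposures); lagged
outcomes as wave-4 time-varying confounders that also respond to wave-1
exposure, so adjusting only at baseline is genuinely biased; monotone
attrition whose hazard depends on the latest exposure
(`attrition_exposure_coef = -0.5`), so censoring weighting is genuinely
exercised; and z-scored outcomes with a selective profile — 6 of 24 outcomes
carry `tau = 0.04` SD per exposed wave (total effects ~0.05–0.09 SD under a
five-fold shift), the rest are null.  Effects enter additively per exposed
wave; no dose–response form between the two intervention points is claimed,
and linearity was adopted for oracle tractability.  Outcome autocorrelation
(`outcome_lag_loading = 0.66`, year-to-year correlation ~0.7) matches
trait-like well-being measures.  The generator does **not** emulate item
wording, ordinal response scales, measurement error in the exposure, or the
design features of any real survey; passing tests therefore demonstrate
statistical correctness of the machinery under the assumed structure, not
fidelity to any particular study population.

`oracle_policy_mean()` is the ground truth: it simulates the mechanism
forward with the policy imposed and censoring switched off, standardises by
the natural course's moments, and shares all random draws between the policy
and natural courses (common random numbers), so identity-vs-identity
contrasts are exactly zero at the same seed and policy contrasts have small
Monte-Carlo error.  The wave-4 propensity entering the shift conditions on
the policy-updated wave-1 history by default (consistent with the estimand's
sequential definition); `conditioning = "observed"` exposes the alternative.
The test suite validates the oracle itself against nested-quadrature
integration of the logistic mechanism.

## Problem sizes used by the test suite

Parameter-recovery tests run 200 replicates at $n = 5{,}000$ (bias of the
five-fold contrast against the oracle, and 95% CI coverage), single large
replicates at $n = 20{,}000$ for misspecification and outcome-wide
selectivity checks, $n = 10^5$ for density-ratio calibration, and
$n = 10{,}000$ for the positivity verdict ordering.  These sizes keep the
full suite in the tens of minutes on one core while leaving Monte-Carlo
noise well below the tolerances asserted.

## Limitations

* **Variance of strong shifts on rare exposures.**  Under the
  divide-the-non-initiation-probability convention, an observed initiation
  carries density ratio $\approx 0.8/g$; with $g \approx 0.025$ the
  influence function has standard deviation around 6–7 on the synthetic
  cohort, i.e. $se \approx 0.05$ at $n = 20{,}000$.  Contrasts of ~0.06 SD
  are therefore estimable but not detectable outcome-wide at that size under
  the Bonferroni + E-value dual rule; detecting them requires either much
  larger cohorts, higher outcome predictability, or the bounded-ratio
  odds-multiplier convention.  This is a property of the estimand, and the
  package reports it honestly rather than trimming it away.
* Single imputation (mean/mode or nearest-neighbour donor) replaces chained
  predictive mean matching; defensible at ~1% baseline missingness, and the
  donor variant preserves the observed-value property, but no
  between-imputation variance is propagated.
* The positivity thresholds are a calibrated convention; other corpora may
  warrant different floors.
* Mediation, effect modification, and dynamic (history-responsive beyond the
  propensity) regimes are out of scope.
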