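---
title: "Methods: comparative age-specific morbidity and mortality"
author: "compmort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative age-specific morbidity and mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compmort)
```

This vignette is the package's own account of its statistical machinery:
the models, their assumptions, the tunable parameters and why their
defaults are what they are, the numerical choices, and what the synthetic
cohorts do and do not tell you about real registry data.

## The data model

A cohort is a table of individual death records: cohort label, sex, age
at death (exact in years, or a registry age bin), a semicolon-separated
diagnosis list with a designated primary diagnosis, an assigned cause of
death on two axes — pathophysiological process (PP: congenital,
degenerative, infectious, inflammatory, metabolic, neoplastic, toxic,
traumatic, vascular) and organ system (OS: cardiovascular through
urogenital, eleven categories) — and an event flag (censored records carry
no cause). Both axes admit an `unclassified` label for diagnoses too vague
to place.

The diagnosis-to-cause mapping is deliberately shipped as an *editable
lookup table* (`cause_taxonomy()`, packaged default in
`inst/extdata/default_taxonomy.csv`) rather than a hard-coded clinical
ontology: registry codings of thousands of raw diagnosis strings are
institution-specific and not redistributable, and the record format
already presumes a single pre-assigned primary diagnosis, so this package
classifies by lookup and does not re-derive primacy. Matching is
case-insensitive after whitespace normalization; unknown diagnoses
classify as unclassified on both axes.

Two filtering rules precede every morbidity analysis
(`filter_records()`): deaths whose cause is unclassified on either axis
are removed, as are records whose *only* diagnosis is euthanasia (a
euthanasia entry inside a longer list is kept — the other diagnoses still
describe the terminal state). Each removed record is counted under exactly
one reason, with the unclassified rule taking precedence; the filter is
idempotent.

Registry age bins are resolved to representative ages
(`assign_bin_midpoint()`): bounded bins map to their midpoints, the three
youngest bins of the packaged veterinary scheme all map to 0.25 years, and
the open-ended over-15-years bin maps to a fixed 17.5 years. Downstream
models treat these midpoint ages as continuous — with one exception, the
Gompertz fit, discussed next.

## Gompertz mortality and the rate of aging

The mortality model is the two-parameter Gompertz hazard
$\mu(x) = \alpha e^{\beta x}$: $\alpha$ (per year) is the baseline hazard
at age 0 and $\beta$ (per year) the exponential slope — the rate of
aging. No Makeham (age-independent) term and no early-age truncation are
used; the model is fit exactly as written. `fit_gompertz()` maximizes the
log-likelihood directly:

* exact ages: $\sum_i d_i(\log\alpha + \beta t_i) - \sum_i H(t_i)$ with
  $H(t) = (\alpha/\beta)(e^{\beta t} - 1)$, right-censored records
  contributing only $-H(t_i)$;
* binned ages: each death contributes
  $\log\{S(lo_i) - S(hi_i)\}$, the open-ended top bin $\log S(lo_i)$.

Optimization is quasi-Newton (BFGS) on $(\log\alpha, \beta)$ — the
log-transform makes the problem unconstrained and well scaled — started
from a least-squares line through the log of a crude life-table
(occurrence/exposure) hazard over death-age deciles. $\beta$ is *not*
constrained positive, so mis-specified or declining-hazard data are
visible rather than silently clamped; cumulative-hazard and survival
formulas switch to a series expansion for $|\beta| < 10^{-10}$ so the
exponential limit is exact. Standard errors come from the inverse observed
information; non-convergence raises an error carrying the last iterate.

The pipeline applies the interval likelihood automatically whenever a
cohort's records are all age-binned. This matters: refitting binned
midpoint ages as if exact badly distorts the slope (the open top bin
truncates the oldest ages), which is exactly why interval-censored
parametric fitting exists.

One numerical fact worth knowing: for a short-lived, shallow-slope cohort
(median lifespan 12 years, $\beta \approx 0.02$), $\beta T \approx 0.26$
over a typical lifespan, so the model is nearly exponential and
$\log\alpha$ and $\beta$ are strongly negatively correlated. The slope is
then estimated at an information floor of roughly 2% relative standard
error per 50,000 lifespans — an identifiability feature of the model in
that regime, not an optimizer deficiency. The recovery tests average a few
replicate draws so that bias, not single-draw noise, is what they measure.

`km_estimate()` (product-limit, via the survival package),
`smoothed_hazard()` and `two_group_hazard_ratio()` complete the mortality
toolkit. The smoothed hazard convolves the Nelson–Aalen increments
$dN(t_i)/Y(t_i)$ with an Epanechnikov kernel; each kernel is renormalized
to unit mass inside the observation window (boundary correction), which
makes the curve integrate to the total cumulative hazard at any
bandwidth. The default bandwidth is one tenth of the death-age range — a
deliberately plain default; any consistent smoother serves here, and the
bandwidth is exposed. The sex contrast maximizes a one-covariate Cox
partial likelihood with Breslow tie handling (the simplest standard
choice) by Newton–Raphson and reports a Wald test; the estimate depends
only on time ranks.

## Count models of multimorbidity and comorbidity

Multimorbidity is the number of *distinct* diagnoses at death — every
diagnosis weighted equally regardless of severity, duplicates within a
record counted once, and a single-diagnosis death contributing 1.
Comorbidity for an index condition (e.g. obesity) is that count minus the
index diagnosis itself on records carrying it, so a case's comorbidity
response is always its multimorbidity minus one.

`fit_negbin()` fits log-link negative-binomial GLMs (variance
$\mu + \mu^2/\theta$, $\theta$ estimated jointly by ML through
`MASS::glm.nb`) — the conventional parameterization. Sex is coded
female = 0, male = 1. `multimorbidity_analysis()` fits
`count ~ age + sex` with an optional PP or OS category factor (categories
with fewer than two records are excluded with a warning) and reports
per-category adjusted means at the sample-average age and sex mix;
`comorbidity_analysis()` fits `count ~ condition + age + sex` and reports
adjusted case/non-case means. Binned midpoint ages are treated as
continuous covariates.

A caution for interpretation (it applies to real registry analyses of
this design, not just the package): conditioning on *containment* of a
diagnosis in a finite list induces a mechanical positive association —
longer lists are more likely to contain any given diagnosis — so a
condition with no causal effect on morbidity can show a positive
coefficient when index conditions are drawn as list members. The package's
null-recovery test therefore generates the condition flag outside the
filler vocabulary.

## Cause-of-death age trajectories

The comparative core is the multinomial logistic (softmax) model of
cause-of-death proportions as a function of age at death: for $K$ causes,

$$p_g(\mathrm{age}) = \mathrm{softmax}\Big(\alpha_g + \sum_{i=1}^{4}
\beta_{g,i}\,\mathrm{age}^i\Big).$$

Numerical and identification choices:

* **Age standardization.** The polynomial is expanded in
  $z = (\mathrm{age} - \bar a)/s_a$, not raw age: raw human ages near 100
  would put $\mathrm{age}^4$ near $10^8$ and wreck the optimizer's
  conditioning. This is an exact reparameterization; coefficients are
  stored on the standardized scale with the constants retained.
* **Identification.** The softmax is overparameterized; the
  alphabetically first cause is the reference with all parameters fixed
  at 0. Predictions are invariant to this choice.
* **Optimization.** BFGS with the analytic gradient
  $X^\top(Y - P)$; the likelihood is concave after identification, so the
  optimum is unique — the test suite confirms ten random starts agree to
  $10^{-6}$. Causes with zero deaths are dropped with a warning; apparent
  separation (coefficients running away, or non-convergence) triggers a
  refit with a small ridge penalty ($10^{-4}$) and a warning. Fits on
  fewer than 50 deaths warn.

`predict_proportions()` returns a simplex at any age (rows sum to 1 to
machine precision). Confidence bands (`confidence_band()`) are
nonparametric bootstrap over individuals — resample the (age, cause)
pairs, refit, take percentile intervals; the default is $B = 200$
replicates at the 95% level. The method is a package choice (the band
construction in this kind of figure is rarely stated); the bootstrap
avoids asymptotic approximations for rare causes, is honest about
refitting variability, and is swappable. Replicate refits start from the
full-data solution, and a run with more than 10% failed refits errors
rather than returning a band built on a biased subset.

**Peak finding and the age scale.** `find_peak_age()` scans a 0.1-year
grid and refines the best interior point by golden-section search
(ties break toward the younger age, matching the half-year precision the
peak is usually quoted at); boundary maxima and flat curves are flagged,
and `compute_age_scale()` refuses them. The cross-species age scale is
the ratio of the two cohorts' neoplastic peak ages — dog age $a$ maps to
human age $a \times s$. The scale is derived from the full cohorts, not
breed subsets. The neoplastic curve is used because its peak is sharp and
interior in both species; the machinery accepts any shared cause.

**Log odds ratios.** `log2_odds_ratio()` evaluates
$\mathrm{logit}_2 p_{h}(\mathrm{age}) -
\mathrm{logit}_2 p_{d}(\mathrm{age}/s)$ with probabilities clipped to
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$, before the
base-2 logit: the statistic is undefined at 0 and 1, and clip-and-flag
(the return value carries a `clipped` attribute) keeps curves plottable
while marking where they are extrapolation. Positive values mean the
cause is more likely in the first (human) cohort; $k$ means $2^k$-fold
odds.

## Spectra comparison and age-relatedness

`proportion_table()` tabulates death proportions per cohort over PP, OS,
or — conditioning on a neoplastic process — the organ system in which the
cancer occurred, restricted to categories present in *both* cohorts
(excluding `unclassified`) and renormalized. `spearman_spectra()`
correlates two spectra with average-rank ties; the p-value uses the exact
null distribution for $n \le 8$ categories, where the large-sample
approximation is poor (comparisons on these taxonomies have 7–11
categories), and the t approximation above. Excluding a category (the
canonical example being vascular deaths, which dominate one species) is a
first-class argument, not a data-munging step, so the exclusion is
recorded in the result.

"Age-related" — absolute deaths increasing with age — is classified
visually from stacked density plots in the literature this package
serves. `age_relatedness()` operationalizes it as a one-sided
Mann–Kendall trend test (Kendall correlation of counts against bin order)
on death counts over age bins, restricted to bins past the cohort's first
quartile of death ages so the juvenile mortality mode doesn't mask a
late-life rise, significant at 0.05. The result object flags itself as a
`surrogate`: it is a reproducible stand-in for a judgment call, and
borderline causes deserve a look at the counts it returns.

## The synthetic cohort generator

`simulate_cohort()` composes three samplers, each a reproducible seeded
stream (fixed offsets from the cohort seed, so changing the morbidity
model never changes the lifespans):

1. **Lifespans**: inverse-CDF Gompertz sampling,
   $x = \beta^{-1}\log\{1 - (\beta/\alpha)\log U\}$, per sex.
2. **Causes**: draws from a softmax trajectory model at each death's age.
   `peaked_trajectory()` builds generators whose chosen cause has a
   quadratic logit in raw age (vertex = the peak age), other causes
   constant, re-expressed exactly on the standardized scale.
3. **Morbidity**: index-condition flags at specified prevalences, then a
   negative-binomial count of additional diagnoses with log-link mean in
   age, sex and the flags; each record's list contains its primary cause
   diagnosis (floor of one diagnosis per death), its flagged conditions,
   and fillers sampled without replacement from the taxonomy vocabulary.

Registry-style binning (replace exact ages by bin midpoints) and
contamination are applied last: a configurable fraction of records have
their cause labels blanked to `unclassified` (diagnoses kept), and a
disjoint fraction have their diagnosis list replaced by `euthanasia`
(cause labels kept), so the two filter reasons are identifiable and the
marginal removal rates match the configured fractions.

The packaged reference conditions: a human-like cohort with rates of
aging 0.089 (female) and 0.080 (male) and baseline hazards solved for
median lifespans of 80 and 75 years; a dog-like cohort with slopes 0.0214
and 0.0219 and a 12-year median (the published median for UK primary-care
dogs); neoplastic logit peaks at 53 years (human, width 25) and 11.5
years (dog, width 5), heights 0.5, over five PP causes with constant base
logits chosen to give each cause a non-trivial share; dog morbidity with
intercept log 1.5, +0.05/year age effect, no sex effect, dispersion
θ = 2, and five index chronic conditions at 3–8% prevalence with
comorbidity effects of log 2 (arthritis, obesity, hypothyroidism),
log 1.8 (diabetes mellitus) and 0 (chronic kidney disease). These were
fixed once as the generator's definition of the study conditions.

What the generator does *not* emulate — and therefore what passing tests
do not demonstrate about real data: breed and body-size structure,
secular (calendar-year) trends, referral bias, realistic clinical
vocabularies and their coding noise, dependence of euthanasia on
diagnosis, or correlation between cause of death and the index
conditions beyond the specified coefficients. Recovery results on
synthetic cohorts certify the estimators, not the epidemiology.

## Problem sizes and runtime choices

The test suite exercises recovery at the sizes the estimators are meant
for: 50,000 lifespans per Gompertz recovery check (averaged over five
replicate draws in the shallow-slope dog regime, for the information-floor
reason above), 100,000 deaths per cohort for the end-to-end
peak-alignment recovery (scale factor within 5%), 20,000 counts for
negative-binomial coefficient recovery, and bootstrap coverage assessed
at one age over 100 replicates of a 250-death cohort with $B = 60$
(asserted ≥ 0.85 against the nominal 0.95, reflecting the Monte Carlo
granularity of that design). The full synthetic pipeline on 2×2,000
records runs in seconds; the acceptance script's four recoveries run in
well under a minute.

## Known limitations

* The Gompertz fit is the pure two-parameter model; cohorts with strong
  infant mortality or a Makeham plateau need an extended model.
* The trajectory polynomial is global: degree 4 cannot express more than
  two interior modes, and extrapolation beyond the fitted age range is
  polynomial extrapolation, with the usual consequences (the log-OR
  clipping flag marks the worst of it).
* The proportional-hazards sex contrast is a single binary covariate by
  design; confounding by breed, size or cohort structure is out of scope.
* Comorbidity-by-containment carries the mechanical association discussed
  above; effect sizes from such designs should be read comparatively, not
  causally.
* Spearman comparisons on 7–11 categories have low power; a
  non-significant spectra correlation is weak evidence of dissimilarity.
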