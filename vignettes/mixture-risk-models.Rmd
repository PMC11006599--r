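---
title: "Mixture risk in pollen and colony performance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture risk in pollen and colony performance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pollenrisk` implements a landscape-scale pesticide exposure analysis for
bumble bee (*Bombus terrestris*) sentinel colonies: mixture risk scoring of
residues quantified in colony pollen stores, colony performance endpoints,
and hierarchical models linking risk, focal crop and landscape composition
to those endpoints. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## Mixture risk metrics

For compound $i$ with concentration $c_i$ (µg kg⁻¹) in a pooled pollen
sample and effective acute LD50 $\mathrm{LD}_{50,i}$ (µg per bee), the
toxicity-weighted concentration is $\mathrm{TWC}_i = c_i /
\mathrm{LD}_{50,i}$. Under concentration addition — the default assumption
in regulatory mixture risk assessment — the sample's mixture risk is

$$\mathrm{TWC}_{mix} = \sum_{i=1}^{n} \frac{c_i}{\mathrm{LD}_{50,i}},$$

and the maximum cumulative ratio

$$\mathrm{MCR} = \frac{\mathrm{TWC}_{mix}}{\max_i(\mathrm{TWC}_i)}$$

measures how much riskier the mixture is than its single riskiest
component: 1 when one compound carries all the risk, at most the number of
detected compounds. Concentration addition ignores synergy and antagonism;
the metric may under- or over-state the potency of real mixtures, which is
a known limitation, not a bug.

The effective LD50 is the arithmetic mean of the worst-case (minimum
across the 24, 48 and 72 h observations) oral and contact adult honey bee
LD50s. Limit-test values reported as "greater than" a bound are rounded
down to the bound, which is conservative (it can only increase the
compound's weight in the risk sum); records built on such values carry a
`limit_test` flag. When the source database has only one route, that
route's worst case is used alone rather than dropping the compound — the
alternative would silently remove real risk. Worst cases are taken per
route independently because the routes need not share time points.

Concentrations are left-censored: any value strictly below the compound's
limit of quantification (LOQ), and any missing value, is set to zero.
A value exactly at the LOQ is kept — the censoring rule is "less than",
taken literally. Detection summaries (mean, median, 90th percentile) are
computed over the positive samples only; the 90th percentile uses the
nearest-rank convention (the $\lceil 0.9 n \rceil$-th order statistic),
which reproduces the mean = median = p90 degeneracy expected for
single-detection compounds. Other quantile conventions differ only for
small positive counts and are not distinguishable from published summary
tables; this is an assumption, and it is stated as one.

Individual compound risk — used to rank compounds, not as a model
covariate — is the mean concentration over positive samples divided by the
effective LD50 and multiplied by the site detection frequency. The
frequency denominator defaults to 100 (the per-cent convention used when
frequencies are published as whole per cent of sites); `denominator =
n_sites` switches to exact proportions. With the packaged ten-compound
reference fixture, `report_table2()` reproduces the published risk ranking,
and the worked scores for spinosad, chlorpyrifos-ethyl, dimethoate,
cyfluthrin and etofenprox agree with the published column at three
significant figures under the /100 convention (three further rows —
deltamethrin, imidacloprid, dithianon — are not reproducible at three
significant figures from printed inputs under any simple denominator,
presumably because unrounded means were used upstream; the package
documents rather than chases this).

## Colony endpoints

* **Weight gain**: the log response ratio
  $\mathrm{lnRR} = \ln(g_{max}/g_{initial})$, where $g_{max}$ is the
  maximum of up to three field weighings. lnRR is unit-invariant and
  symmetric for gains and losses; `exp(lnRR)` is the proportional change.
  Ties in the maximum resolve to the latest weighing (the colony is still
  at peak); which weighing won is recorded.
* **Total production**: intact + eclosed cocoons over all castes, a proxy
  for all bees produced that is robust to reproductives having already
  left the colony.
* **Queen production**: intact + eclosed queen cocoons, an index of
  reproduction that is strongly zero-inflated because termination is timed
  to crop bloom, before most colonies reach queen rearing.

Colonies flagged lost or without enough stored pollen for residue
analysis are excluded with a logged reason. Pollen is pooled at site
level, so mixture risk is a site covariate shared by that site's colonies.
Model covariates are prepared once over the included set: risk as
$\ln(\mathrm{TWC}_{mix} + 0.1)$ (the mixture risk is strongly
right-skewed; the 0.1 offset keeps zero-risk samples defined) and then
centred; cropland proportion and initial weight centred. Exclusions
therefore never alter an included colony's raw values, only the centring
constants, and re-centring shifts only intercept-involved coefficients —
the three-way interaction test is invariant to it (this is tested).

## Models

Each endpoint is modelled with initial colony weight plus risk, crop and
cropland main effects, all two-way interactions among risk/crop/cropland,
the three-way interaction, and random intercepts for site nested in
country:

* weight gain — Gaussian LMM, fitted by REML with `lme4`;
* total production — NB2 GLMM (variance $\mu + \mu^2/\theta$, log link),
  maximum likelihood via the Laplace approximation with `glmmTMB`;
* maximum weight — Gaussian LMM on $\ln g_{max}$ (log improves residual
  diagnostics; an untransformed option exists);
* queen production — zero-inflated NB GLMM with one constant mixing
  probability $\pi$ (intercept-only logit).

These are the standard fitting engines for this model class in ecology,
and the package treats them as the estimation method, not a detail: the
test suite cross-checks their marginal likelihoods against an independent
21-node adaptive Gauss–Hermite quadrature oracle on small instances, their
variance components against the balanced-ANOVA closed form, and their
nesting limits (NB with $\theta$ pinned at $10^8$ equals Poisson
regression; ZINB with $\pi$ pinned at 0 equals the NB fit).

Inference per term is a Type II Wald chi-square (each term here has 1 df,
so the statistic for the highest-order term is $(\hat\beta/SE)^2$);
likelihood-ratio tests would be a reasonable alternative and the Wald
choice matters little at these sample sizes (the suite checks the Type I
error of the interaction test is nominal). Variance-explained summaries
are marginal and conditional $R^2$ computed by variance partitioning:
fixed-predictor variance over fixed + random + observation-level
variance, where the observation-level variance is $\sigma^2$ for Gaussian
fits and the trigamma form
$\psi_1\!\left((1/\lambda + 1/\theta)^{-1}\right)$ for NB log-link fits
with $\lambda = \exp(\overline{X\beta} + \tfrac12\sum\sigma^2_{re})$,
falling back to the lognormal approximation when the trigamma value is
not finite. Simple slopes of risk at a crop level and a cropland value
are linear combinations of coefficients with delta-rule confidence
intervals; they are verified against refits on shifted covariates, which
is an exact reparameterization. Marginal means use `emmeans` on a
reference grid (covariates at means, averaging over crops), and the
low-vs-high-risk contrast compares the 25th and 90th percentiles of the
fitted risk covariate on the response scale.

Diagnostics: the dispersion ratio (sum of squared Pearson residuals over
residual df) computed on a Poisson fit demonstrates overdispersion and on
the NB fit adequacy; VIFs are the diagonal of the inverse correlation
matrix of the fixed-effects design; `independence_check()` fits the
country-random-intercept LMM used to confirm risk and cropland (and risk
and initial weight) are unconfounded.

## The synthetic-data generator

No field data ship with the package; `simulate_study()` generates complete
studies with the design the analysis assumes: 8 countries, 50 apple + 56
oilseed-rape sites (round-robin across countries, cropland uniform on
0.03–0.98, stratified within crop so both crops span the gradient), 3
colonies per site, initial weight Normal(648, 70.9²) g.

Exposure is generated **mechanistically**: each of the ten reference
compounds is detected with a crop-specific probability (0.85 apple, 0.75
oilseed rape — apple sites see more compounds) and detected
concentrations are lognormal around the compound's reference median with
sdlog 1.2, then LOQ-censored. Risk is then computed by the package's own
metrics, so `risk_metrics` sits inside every simulation-based test. These
two knobs were chosen once so that the generated mixtures echo the field
pattern: median 8 compounds per sample, strongly right-skewed
$\mathrm{TWC}_{mix}$ (skewness > 1), and a majority of MCRs below 1.5
(one compound usually dominates because the effective LD50s span three
orders of magnitude). With a ten-compound panel the generator cannot
reproduce the full 1–27 range of compound counts seen with a 267-compound
screen; compounds are also simulated independently, with no within-crop
covariance structure — both are known, accepted departures from real
data, which is why passing tests demonstrate the pipeline's statistical
correctness, not field realism.

Colony endpoints are drawn from the fitted model families themselves.
Weight-gain defaults: risk slope −0.13 at apple and 0.02 at oilseed rape
on the transformed centred scale (the headline field effect sizes),
initial-weight slope −8·10⁻⁴ per g, crop effect 0.08, cropland −0.05,
country/site/residual SDs 0.10/0.12/0.25. The risk × cropland coefficient
defaults to −0.29, calibrated once so that the expected Wald statistic of
the interaction at the full 106-site design matches the magnitude
observed in the field study (χ² ≈ 10.6, i.e. z ≈ 3.26); this also places
the 0.8-power crossing for that term in the low hundreds of colony–site
combinations, consistent with the field study's sensitivity analysis that
more than 150 combinations are needed. Count models: production intercept
ln 700, θ = 2; queens intercept ln 45, θ = 1.5, π = 0.3; the count risk
slopes are **derived per draw** from the configured contrast targets — a
52% (production) and 47% (queens) reduction between the 90th and 25th
percentile of the realized risk covariate — so marginal-mean contrasts
have an exactly known truth. Field weighings are constructed so the
maximum lands at the third/second/first weighing with probability
0.62/0.26/0.12. Five colonies default to lost; an optional fraction of
sites can be flagged as yielding too little pollen (at 64+64 sites with
21/128 of sites flagged, the generator reproduces a
384-deployed/316-analysed bookkeeping exercise). With the default
106-site analysed design and 5 losses, the default analysis table has 313
colonies — within a few colonies of the 316 the emulated study analysed,
a deliberate simplification.

One technical caveat: colony cocoon counts are stored by caste
(intact/eclosed × worker-male/queen) and total production is reconstructed
as their sum, which equals the generated NB draw whenever production ≥
queens (essentially always at the defaults).

Determinism: `simulate_study()` derives one sub-seed per stage (landscape,
residues, colonies) from the master seed, so regeneration is bit-identical
and stages are individually reproducible.

## Numerical choices and degenerate inputs

* Zero-risk samples have undefined MCR (`NA` with a warning), never 0 or
  1; they keep $\mathrm{TWC}_{mix} = 0$ and remain modellable thanks to
  the log offset.
* A positive concentration for a compound missing from the toxicity table
  is an error naming the compounds — silent dropping would understate
  risk.
* Non-convergence of any fit warns and flags the fit object; boundary
  θ > 10⁶ is reported as Poisson-like.
* Perfectly collinear fixed effects surface as errors or infinite Wald
  statistics rather than being masked; a degenerate zero-residual
  independence check reports an infinite chi-square.
* The quadrature oracle in the test suite uses instances with enough
  information per group (e.g. 2 groups × 12 observations for counts) that
  the Laplace approximation is expected to agree to 10⁻³; with sparse
  groups the Laplace error is genuinely larger, which is a property of
  the approximation, not an implementation defect.

## Problem sizes used by the test suite

Simulation-based checks run at the study's own scale (106 sites, ~313
analysed colonies): 500 replicates for the null-calibration and
slope-recovery experiments, 30–40 replicates for the count-model contrast
recovery, and 60 replicates per design size for the power curve over
75–318 colony–site combinations. These sizes keep Monte-Carlo error well
inside the tested bands while the whole suite stays comfortably
runnable on a laptop.

## Limitations

Beyond the generator simplifications above: the risk metric assumes
additivity and adult acute toxicity only (no chronic or larval
endpoints); LD50s are honey bee values applied to bumble bees; the models
use random intercepts only (no spatial correlation, no random slopes);
and queen production at bloom-timed termination underestimates full
reproductive output. These mirror the scope of the analysis the package
implements.
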