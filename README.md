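# pollenrisk

Pesticide mixture risk in bee-collected pollen and its association with
bumble bee colony performance.

Agricultural landscapes expose pollinators to many pesticides at once.
For sentinel *Bombus terrestris* colonies placed at flowering apple and
oilseed-rape sites, this package scores the mixture risk of the residues
found in their pollen stores, derives colony performance endpoints, and
fits the hierarchical models that ask whether risk — alone and in
interaction with focal crop and landscape cropland — predicts colony
outcomes. A synthetic-study generator reproduces the whole design so every
stage is testable without field data.

## The metrics and models

Per compound, the toxicity-weighted concentration is TWC_i = c_i / LD50_i
(concentration in pollen, µg kg⁻¹, over the effective acute LD50, µg per
bee: the mean of worst-case oral and contact values across 24/48/72 h,
with "greater than" limit-test values rounded down). Under concentration
addition the per-sample mixture risk and dominance metrics are

    TWC_mix = Σ_i c_i / LD50_i        MCR = TWC_mix / max_i(TWC_i)

with MCR = 1 when a single compound carries all risk. Concentrations
below the compound's LOQ are treated as zero. Individual compounds are
ranked by (mean concentration over positive samples / LD50) × detection
frequency.

Endpoints: weight gain lnRR = ln(g_max/g_initial), total cocoon
production, and queen cocoon production. Models: Gaussian LMM (weight
gain; also ln-max-weight), NB2 GLMM (production) and zero-inflated NB
GLMM (queens), all with risk × crop × cropland fixed effects, initial
weight, and site-nested-in-country random intercepts (lme4 / glmmTMB),
reported with Type II Wald χ², marginal/conditional R², simple slopes,
marginal-mean contrasts and overdispersion/collinearity diagnostics.

## Worked example

```r
library(pollenrisk)

# mixture risk of one pooled pollen sample
toxdb <- reference_toxicity()             # packaged 10-compound LD50 fixture
sample <- c(indoxacarb = 57, dithianon = 244)
twc_by_compound(sample, toxdb)
#> indoxacarb  dithianon
#>  365.38462    3.89155
twc_mix(sample, toxdb)                    # 369.27617
mcr(twc_by_compound(sample, toxdb))       # 1.0106503: indoxacarb dominates

# published-style compound ranking from the packaged survey summary
head(report_table2(reference_residue_summary(), toxdb), 3)[,
     c("compound_id", "ld50", "conc_mean", "n_detect", "compound_risk")]
#>          compound_id   ld50 conc_mean n_detect compound_risk
#> 1         indoxacarb 0.1560      1310       17     1427.5641
#> 2           spinosad 0.0303       658        2      434.3234
#> 3 chlorpyrifos-ethyl 0.1090       282        9      232.8440

# a full synthetic study through the model pipeline
study <- simulate_study(sim_config(), seed = 1)
tab <- build_analysis_table(study$colonies, study$risk, study$sites)
fit <- fit_lmm(tab)                       # weight-gain LMM
simple_slopes(fit, cropland_c = 0)[, c("crop", "slope", "lower", "upper")]
#>           crop       slope        lower       upper
#> 1        apple -0.17206703 -0.213199417 -0.13093465
#> 2 oilseed_rape  0.03399761 -0.000149569  0.06814478
```

The slopes are the effect of a one-unit increase in the centred
log-transformed mixture risk on colony lnRR, at mean cropland: colonies
at apple sites lose weight gain as risk rises (the generator's truth is
−0.13), while oilseed-rape sites are flat (truth 0.02).

`run_pipeline(pipeline_config(seed = 1, out_dir = "run"))` executes
residues → risk → endpoints → all four models and writes per-sample risk,
the ranked compound-risk table, one Wald-χ²/R² table per response,
diagnostics and a manifest.

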