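# bmimr

Mendelian randomization (MR) tooling for the question "does higher body mass
index cause depression?", built the way large biobank MR analyses are run —
and a calibrated synthetic cohort generator so the entire pipeline can be
exercised and tested without access to restricted individual-level data.

`bmimr` is aimed at genetic epidemiologists who want a transparent, tested
implementation of the standard MR toolkit for a continuous exposure and a
binary outcome:

* **Genetic risk scores**: weighted allele-dosage scores with the
  allele-count rescaling
  `GRS = (Σ β_j g_j) × n_SNPs / Σ β_j`, rank-based inverse-normal exposure
  transform, instrument strength (R², first-stage F), and a
  confounder-association screen.
* **One-sample MR**: two-stage estimation for binary outcomes (linear first
  stage, logistic second stage on fitted exposure) with HC1-robust standard
  errors; observational logistic models; sex-stratified runs.
* **Two-sample MR**: Wald ratio, inverse-variance-weighted (fixed/random),
  MR-Egger (slope + pleiotropy intercept), weighted and penalized weighted
  median with seeded bootstrap SEs; Cochran Q / I² heterogeneity; GWAS
  summary-statistic reading, validation and allele harmonization including
  palindromic-variant handling.
* **Auxiliary inference**: Wald p-values from printed estimate/CI pairs,
  Fisher z stratum contrasts, fixed-effect meta-analysis,
  over-identification tests between instrument subsets, a per-variant
  pleiotropy screen with OR→SD conversion, and a negative-control battery.
* **Synthetic cohorts**: Hardy-Weinberg genotypes, a confounded standardized
  exposure whose score R² is calibrated exactly to a target (1.7% for the
  BMI-like score), a logistic outcome with target prevalence solved by
  bisection, optional directional/balanced pleiotropy, sex-specific effects,
  latent-subpopulation stratification and confounder-driven negative-control
  traits.

The model at the core: with dosages `g_j`, exposure
`X = Σ α_j g_j + c_x U + ε` (unit variance) and outcome
`logit P(Y=1) = β0 + θX + Σ δ_j g_j + c_y U`, the package estimates the
causal log-odds `θ` per 1-SD exposure via the GRS instrument, under the
standard IV assumptions; the pleiotropy-robust estimators relax the
"no direct effects δ_j" assumption in the usual ways. See the methods
vignette (`vignettes/bmimr-methods.Rmd`) for the full account.

## Worked example

```r
library(bmimr)

cfg <- sim_config(n_samples = 100000, seed = 11)   # biobank-like defaults
cohort <- simulate_cohort(cfg)
score  <- weighted_grs(cohort$genotypes, true_instruments(cohort))

instrument_strength(score, cohort$samples$exposure)$r2
#> [1] 0.01740568          # 1.7% of exposure variance, as calibrated

iv_two_stage(cohort$samples$outcome, cohort$samples$exposure, score,
             cohort$samples[, "sex", drop = FALSE])
#> MR estimate [tsls]
#>   beta = 0.1703 (SE 0.0678), 95% CI [0.0374, 0.3033], p = 0.012
#>   OR   = 1.186, 95% CI [1.038, 1.354]
```

The two-stage estimate (OR 1.19 per 1-SD higher exposure) recovers the
generator's causal effect (θ = 0.166, OR 1.18) within sampling error, with
the instrument explaining 1.7% of exposure variance — the regime of a
73-variant BMI score in a ~300k-person cohort.

Printed-table arithmetic is reproduced by `worked_examples()`: e.g. a
genetic log-odds of 0.166 with 95% CI (0.084, 0.247) yields Wald
p = 6.5e-05 (printed 7e-05) and OR 1.18.

A YAML-driven end-to-end run (`run_pipeline("config.yaml")`, or
`exec/bmimr run-all --config config.yaml` from a shell) writes tidy TSV
report tables: GRS report, stratified observational/one-sample table,
harmonization audit, two-sample battery, over-identification contrast,
pleiotropy screen, negative-control table, meta-analysis and a manifest.

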