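---
title: "Methods: Mendelian randomization for adiposity and depression in bmimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomization for adiposity and depression in bmimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmimr)
```

## The scientific problem

Observationally, higher body mass index (BMI) is associated with higher odds
of depression, more strongly in women than in men. Because that association
is plausibly confounded (socioeconomic position, health behaviours) or
reverse-causal, Mendelian randomization (MR) uses genetic variants associated
with BMI as instrumental variables: alleles are allocated at conception, so a
genetic score for BMI is not confounded by adult environment, and an
association between the score and depression implicates BMI causally, under
the usual instrument assumptions (relevance; no association with confounders;
no pathway to the outcome except through the exposure).

`bmimr` implements that analysis plan end to end: a weighted genetic risk
score (GRS) first stage, one-sample two-stage IV estimation for a binary
outcome, two-sample summary-statistic estimators with pleiotropy-robust
alternatives, stratified contrasts, meta-analysis, a per-variant pleiotropy
screen and negative-control checks — together with a synthetic cohort
generator that emulates the statistical structure of a biobank-scale
case-control analysis, so the whole pipeline is testable without restricted
individual-level data.

## Genetic risk score

For variants $j = 1,\dots,m$ with trait-increasing-allele dosages
$g_{ij} \in \{0,1,2\}$ and external per-allele weights $\beta_j$,

$$\text{weighted score}_i = \sum_j \beta_j g_{ij}, \qquad
  \text{GRS}_i = \text{weighted score}_i \times \frac{m}{\sum_j \beta_j},$$

the allele-count rescaling that makes an equal-weight GRS equal the raw
count of trait-increasing alleles. Exposures are transformed by the
rank-based inverse-normal map $\Phi^{-1}((r_i - 0.5)/n)$ (average ranks for
ties) so that all effects are per 1 SD of exposure. Instrument strength is
summarized by the $R^2$ of the exposure-on-score regression and the
univariate first-stage $F = R^2 (n-2) / (1 - R^2)$.

The rankit offset $(r - 0.5)/n$ is one of several conventional variants
(Blom, van der Waerden); the choice is immaterial at biobank sample sizes
and is fixed here for reproducibility.

## One-sample estimation

Because the outcome is binary, the two-stage estimator is: stage 1, least
squares of exposure on the GRS (plus covariates); stage 2, logistic
regression of the outcome on the stage-1 fitted exposure (plus the same
covariates). The reported standard error is a heteroskedasticity-robust HC1
sandwich on the second stage, correcting for the generated-regressor
uncertainty; HC1 matches the common statistical-software default behind the
plain phrase "robust standard errors". No control-function residual is
added, matching the two-stage description the package mirrors. Covariates
enter both stages (the source description leaves this open; entering both is
the conservative default). Confidence intervals are normal-theory
$\pm 1.96 \cdot SE$ everywhere, because that is the arithmetic that converts
the printed CIs of published report tables back into their p-values.

## Two-sample estimators

Given harmonized per-variant pairs $(\hat b_{x,j}, \hat b_{y,j})$ with
outcome standard errors $\sigma_j$ and weights $w_j = 1/\sigma_j^2$:

* **IVW**: weighted regression through the origin,
  $\hat\theta = \sum w_j b_{x,j} b_{y,j} / \sum w_j b_{x,j}^2$ with
  fixed-effect $SE = (\sum w_j b_{x,j}^2)^{-1/2}$; the random-effects
  variant multiplies the SE by $\max(1, \sqrt{Q/(k-1)})$ (multiplicative
  dispersion rather than an additive $\tau^2$ — the lighter of the two
  conventions, and the one nested inside the Egger fit below).
* **MR-Egger**: weighted least squares with a free intercept after orienting
  all pairs to $b_{x,j} > 0$ (the estimator is not invariant to joint sign
  flips without that rule, which is therefore imposed). The intercept
  estimates average directional pleiotropy; the slope is the causal estimate
  under the InSIDE assumption. SEs are divided by $\min(1, \hat\sigma)$ so
  under-dispersion cannot shrink them; p-values use $t_{k-2}$.
* **Weighted median**: ratio estimates $r_j = b_{y,j}/b_{x,j}$ with weights
  $w_j = b_{x,j}^2/\sigma_j^2$, sorted, with standardized cumulative-weight
  positions $p_j = (S_j - w_j/2)/S_{total}$; the estimate interpolates
  linearly at $p = 0.5$, and is consistent while under half the weight is
  invalid. The penalized variant multiplies $w_j$ by
  $\min(1, 20\, q_j)$, $q_j$ the upper $\chi^2_1$ tail of variant $j$'s
  contribution to Cochran's $Q$ about the unpenalized estimate (the
  penalization constant of the original median-estimator construction). The
  median SE comes from a seeded parametric bootstrap (default 1000
  replicates) resampling $(b_{x,j}, b_{y,j})$ from normals with their
  reported SEs.

Heterogeneity is reported as Cochran's $Q$, its df and p, and
$I^2 = \max(0, (Q - df)/Q)$.

### Harmonization

Variants are matched by ID only (the instrument lists this package mirrors
are rsID-based). Outcome records with swapped effect/other alleles have
$b_y$ negated and frequency complemented; strand-complement records are
relabelled; palindromic (A/T, C/G) variants whose allele frequency lies
within 0.08 of 0.5 on either side are flagged and excluded (frequency cannot
then resolve the strand), others are aligned by frequency. The 0.08 window
follows common two-sample practice and is configurable; dropped and
irreconcilable variants are always reported, never silently removed.

## Auxiliary inference

* Wald p from printed estimate/CI pairs: $SE = (hi - lo)/(2 \cdot 1.96)$ on
  the analysis (log-OR) scale, $p = 2\Phi(-|\hat\beta|/SE)$.
* Stratum comparison (e.g. women vs men):
  $z = (\beta_1 - \beta_2)/\sqrt{SE_1^2 + SE_2^2}$.
* Fixed-effect meta-analysis with inverse-variance weights; fixed effects by
  default because the analyses mirrored here found no heterogeneity between
  cohort estimates, with a multiplicative random-effects flag.
* Over-identification between disjoint instrument subsets (e.g. variants in
  neuronal vs non-neuronal pathway genes): IVW per subset, then the Fisher z
  contrast of the two estimates.
* Pleiotropy screen: per-variant outcome log-odds are converted to SD units
  by $b_{y,SD} = b_y \sqrt{c(1-c)}$ with $c$ the case fraction, and a
  variant is flagged when $|b_{y,SD}| > |b_x|$ — a variant with a larger
  effect on the outcome than on the exposure is unlikely to be a specific
  instrument. The conversion factor is configurable since several liability
  approximations exist.

## The synthetic cohort generator

The generator is first-class, tested code; it defines the study conditions
under which the estimators are validated.

* **Genotypes**: $m$ independent biallelic variants, dosage
  $g_{ij} \sim \text{Binomial}(2, f_j)$, $f_j \sim U(0.05, 0.5)$. No linkage
  disequilibrium, imputation uncertainty or relatedness is modelled.
* **Exposure**: $X = \sum_j \alpha_j g_{ij} + c_x U + \varepsilon$, with
  $U \sim N(0,1)$ a shared confounder and $\varepsilon$ scaled so
  $\mathrm{Var}(X) = 1$ theoretically. Per-variant effects are drawn
  half-normal and rescaled so the theoretical score variance
  $\sum_j 2 f_j (1-f_j) \alpha_j^2$ equals the target $R^2$ exactly
  (to 1e-9).
* **Outcome**: $\text{logit}\,P(Y=1) = \beta_0 + \theta_i X +
  \sum_j \delta_j g_{ij} + c_y U$, where $\theta_i$ is the causal log-odds
  (multiplied by `sex_effect_modifier` for females) and $\delta_j$ are
  direct (pleiotropic) variant effects. $\beta_0$ is solved by bisection so
  the expected prevalence matches the target case fraction to 1e-4 — no
  closed form exists for the logistic mixture.
* **Negative controls and stratification**: control traits depend on $U$
  (and, when `stratification_effect` is nonzero, on a latent subpopulation
  with allele frequencies shifted by `effect` $\times f(1-f)$) but never on
  $X$; a socioeconomic-position-like covariate loads on the subpopulation
  and on $U$, so adjusting for it attenuates stratification-induced bias,
  emulating the negative-control logic of the mirrored analysis.

Default parameter choices, made once as the emulated study conditions:
73 variants and score $R^2 = 1.7\%$ (the BMI-score instrument; 0.2% is the
weak favourable-adiposity mode), case fraction $41397/287503 = 0.144$,
causal effect $\theta = 0.166$ log-odds per SD (the headline genetic
estimate, OR 1.18), confounder loadings $c_x = 0.3$, $c_y = 0.4$ (moderate
confounding of plausible epidemiological size; the mirrored study reports
none), cohort size $10^5$ as a tractable emulation of the 287 503-person
analysis set, and pleiotropy scale 0.05 log-odds per allele — "strong"
directional pleiotropy of the same order as the largest per-variant
exposure-mediated outcome effects, the regime the robustness experiments are
about. Allele labels default to A/G with a configurable fraction of A/T
palindromes to exercise harmonization.

### The oracle estimand

With a logistic outcome the IV estimand is a *marginal* log-odds and differs
from the conditional $\theta$ (non-collapsibility), so recovery tests would
be ill-posed against $\theta$ itself. The package therefore computes an
oracle estimand $\theta^{*}$ per configuration: the two-stage estimator run
once on a two-million-sample cohort (generated in chunks to bound memory).
Recovery and coverage tests target $\theta^{*}$. This avoids approximation
formulas at the cost of a small Monte-Carlo error in the oracle itself,
which is an order of magnitude below the per-replicate sampling error at the
test cohort sizes.

Two-sample experiments use a parametric summary-level generator
($\hat b_{x,j} \sim N(\alpha_j, se_x)$,
$\hat b_{y,j} \sim N(\theta \alpha_j + \delta_j, se_y)$ with SEs matching
GWAS of the emulated sizes); at the summary level the generative slope is
$\theta$ exactly, giving an exact recovery target and making thousand-fold
replication cheap.

### Randomness and determinism

Every generator takes one root seed; all sub-streams (frequencies, effects,
genotypes, phenotypes, controls, bootstrap) derive deterministically from it,
so fixtures are bit-reproducible and stochastic stages are reproducible
under a fixed seed. Derived seeds stay below $2^{31}$.

## Problem sizes used in the test-suite experiments

Chosen to estimate each property with adequate Monte-Carlo precision while
keeping the default suite quick: calibration at $n = 10^5$; parameter
recovery over 200 replicates of $n = 20\,000$ against the $2 \times 10^6$
oracle; estimator-robustness ordering and Egger power over 200 summary-level
replicates and Egger type-I error over 1000; negative-control coverage over
10 cohort replicates of $n = 20\,000$ plus one stratified cohort of
$n = 50\,000$.

## What the synthetic tests do and do not show

Passing recovery tests demonstrate that the estimators implement their
defining formulas, remove simulated confounding, and behave as theory
predicts under the generator's assumptions: independent variants, binomial
dosages, a single additive normal confounder, logistic outcome, and
pleiotropy independent of instrument strength (InSIDE holds by
construction). Real cohort data violate several of these: linkage
disequilibrium between instruments, assortative mating and dynastic effects,
fine-scale population structure beyond a two-component mixture, selection
into the cohort, and exposure measurement error. Results on real data
therefore inherit the usual MR caveats even when every test here is green.

Other known limitations: the ordinal outcomes of the mirrored
negative-control analysis (e.g. frequency-of-use scales) are handled as
continuous or binary, not ordinal; mixed-model association scans are
replaced by per-variant regressions; and the weighted-median bootstrap SE is
parametric rather than resampling individuals.

## Worked examples

`worked_examples()` recomputes from printed estimate/CI pairs everything in
the mirrored report tables that is recoverable by arithmetic alone, and
records a pass/fail status at a documented tolerance. One row is marked
`reference` rather than asserted: the genetic sex-contrast p-value (printed
0.18) was computed from unrounded estimates, and the 2-dp rounded CIs yield
0.23; the neighbouring neuronal/non-neuronal contrast (printed 0.17)
reproduces to 0.179 and is asserted at a documented tolerance of 0.015.

```{r worked}
worked_examples()[, c("example", "computed", "printed", "status")]
```

## A small end-to-end run

```{r pipeline, eval = FALSE}
cfg <- list(simulation = list(n_samples = 20000), seed = 7,
            out_dir = "mr_demo", bootstrap_reps = 200)
run_pipeline(cfg)
```

This writes the GRS/instrument-strength report, the observational and
one-sample tables per stratum, the harmonization audit, the two-sample
battery, the over-identification contrast, the negative-control table, the
meta-analysis and a manifest whose hash is bit-identical across reruns of
the same config.
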