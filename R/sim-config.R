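#' Simulation configuration for the synthetic biobank cohort
#'
#' Collects the generative parameters of the synthetic cohort: biallelic
#' instrument variants in Hardy-Weinberg proportions, a confounded continuous
#' exposure in 1-SD units whose score-explained variance is calibrated to a
#' target R-squared, a binary outcome with a target case fraction and a tunable
#' causal log-odds, optional directional or balanced pleiotropy, a sex-specific
#' effect modifier, and negative-control traits driven by the confounder (and
#' optionally by a latent subpopulation correlated with genotypes, to emulate
#' population-stratification abuse cases).
#'
#' Defaults emulate the structure of the biobank analysis the package mirrors:
#' 73 instrument variants explaining 1.7% of exposure variance, a causal effect
#' of 0.166 log-odds per SD, and a 14.4% case fraction (41397 cases among
#' 287503 individuals).
#'
#' @param n_samples number of individuals.
#' @param n_variants number of instrument variants (73 mirrors the BMI score).
#' @param maf_range allele-frequency range, each in (0, 0.5].
#' @param target_r2 fraction of exposure variance explained by the score
#'   (0.017 for the BMI-like score, 0.002 for the weak favourable-adiposity
#'   mode).
#' @param causal_effect causal log-odds of the outcome per 1-SD exposure.
#' @param confounder_effect_x,confounder_effect_y loadings of the shared
#'   confounder U on exposure and outcome linear predictors.
#' @param pleiotropy_fraction fraction of variants with direct outcome effects.
#' @param pleiotropy_mode `"balanced"` (zero-mean direct effects) or
#'   `"directional"` (common-sign direct effects).
#' @param pleiotropy_scale scale (SD) of direct outcome effects, log-odds per
#'   allele.
#' @param case_fraction target outcome prevalence in (0, 1).
#' @param sex_effect_modifier multiplicative factor applied to `causal_effect`
#'   for females (sex == 1).
#' @param stratification_effect size of latent-subpopulation allele-frequency
#'   shifts (0 disables the subpopulation).
#' @param palindromic_fraction fraction of variants exported with
#'   strand-ambiguous A/T alleles (to exercise harmonization).
#' @param seed root integer seed; all sub-streams derive from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 100000L,
                       n_variants = 73L,
                       maf_range = c(0.05, 0.5),
                       target_r2 = 0.017,
                       causal_effect = 0.166,
                       confounder_effect_x = 0.3,
                       confounder_effect_y = 0.4,
                       pleiotropy_fraction = 0,
                       pleiotropy_mode = c("balanced", "directional"),
                       pleiotropy_scale = 0.05,
                       case_fraction = 41397 / 287503,
                       sex_effect_modifier = 1,
                       stratification_effect = 0,
                       palindromic_fraction = 0,
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  cfg <- list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    maf_range = as.numeric(maf_range), target_r2 = target_r2,
    causal_effect = causal_effect,
    confounder_effect_x = confounder_effect_x,
    confounder_effect_y = confounder_effect_y,
    pleiotropy_fraction = pleiotropy_fraction,
    pleiotropy_mode = pleiotropy_mode,
    pleiotropy_scale = pleiotropy_scale,
    case_fraction = case_fraction,
    sex_effect_modifier = sex_effect_modifier,
    stratification_effect = stratification_effect,
    palindromic_fraction = palindromic_fraction,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!isTRUE(n_samples > 0)) stop("n_samples must be positive")
    if (!isTRUE(n_variants > 0)) stop("n_variants must be positive")
    if (length(maf_range) != 2 || any(!is.finite(maf_range)) ||
        maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2]) {
      stop("maf_range must be an increasing pair within (0, 0.5]")
    }
    if (!isTRUE(target_r2 >= 0 && target_r2 < 1)) {
      stop("target_r2 must lie in [0, 1)")
    }
    if (!isTRUE(pleiotropy_fraction >= 0 && pleiotropy_fraction <= 1)) {
      stop("pleiotropy_fraction must lie in [0, 1]")
    }
    if (!isTRUE(case_fraction > 0 && case_fraction < 1)) {
      stop("case_fraction must lie in (0, 1)")
    }
    vals <- c(causal_effect, confounder_effect_x, confounder_effect_y,
              pleiotropy_scale, sex_effect_modifier, stratification_effect)
    if (any(!is.finite(vals))) stop("all effect parameters must be finite")
    if (target_r2 + confounder_effect_x^2 >= 1) {
      stop("target_r2 + confounder_effect_x^2 must be < 1 ",
           "(exposure is standardized to unit variance)")
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: n = %d, m = %d variants, R2 = %.3f, theta = %.3f, case fraction = %.3f, seed = %d\n",
    x$n_samples, x$n_variants, x$target_r2, x$causal_effect,
    x$case_fraction, x$seed))
  invisible(x)
}

# Deterministic sub-stream seeds from the root seed; kept below 2^31.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483629)
}
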