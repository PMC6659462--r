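#' Two-sided Wald p-value from an estimate and its 95% CI
#'
#' Recovers the standard error as `(hi - lo) / (2 * 1.96)` on the analysis
#' scale (log scale for odds ratios) and returns the two-sided normal tail
#' probability of `|beta| / SE`; the arithmetic that reproduces printed
#' p-values from published estimate/CI pairs.
#'
#' @param estimate point estimate (an OR when `scale = "log_odds_from_or"`).
#' @param ci_low,ci_high 95% confidence bounds.
#' @param scale `"linear"` (estimate already on an additive scale) or
#'   `"log_odds_from_or"` (inputs are ORs, log-transformed first).
#' @return two-sided p-value.
#' @export
wald_p_from_ci <- function(estimate, ci_low, ci_high,
                           scale = c("linear", "log_odds_from_or")) {
  scale <- match.arg(scale)
  if (ci_low >= ci_high) stop("ci_low must be below ci_high")
  if (scale == "log_odds_from_or") {
    if (min(estimate, ci_low, ci_high) <= 0) {
      stop("odds-ratio inputs must be positive")
    }
    estimate <- base::log(estimate)
    ci_low <- base::log(ci_low)
    ci_high <- base::log(ci_high)
  }
  se <- (ci_high - ci_low) / (2 * 1.96)
  2 * stats::pnorm(-abs(estimate) / se)
}

#' Fisher z comparison of two estimates
#'
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)` with a two-sided normal p-value; the
#' method used to compare stratified (e.g. male vs female) effect estimates.
#'
#' @param a,b lists with `beta` and `se` (e.g. from [est_from_ci()]) or
#'   `mr_estimate` objects.
#' @return list with `z` and `p`.
#' @export
fisher_z_diff <- function(a, b) {
  grab <- function(e) {
    if (inherits(e, "mr_estimate")) list(beta = e$estimate, se = e$se) else e
  }
  a <- grab(a); b <- grab(b)
  if (a$se <= 0 || b$se <= 0) stop("standard errors must be positive")
  z <- (a$beta - b$beta) / sqrt(a$se^2 + b$se^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pooled estimate `sum(w b) / sum(w)` with `w = 1/se^2`,
#' `SE = (sum w)^-1/2`, and Cochran's Q about the pooled mean with k - 1
#' degrees of freedom. Fixed effect is the default because the analyses the
#' package mirrors found no evidence of heterogeneity between cohort
#' estimates; a multiplicative random-effects inflation is available behind a
#' flag.
#'
#' @param estimates list of lists/`mr_estimate`s with `beta`/`estimate` and
#'   `se`.
#' @param random inflate the SE by `max(1, sqrt(Q/(k-1)))`.
#' @return `mr_estimate` with method `"meta_fixed"` and heterogeneity fields.
#' @export
meta_fixed <- function(estimates, random = FALSE) {
  if (length(estimates) == 0) stop("empty estimate list")
  beta <- vapply(estimates, function(e) {
    if (inherits(e, "mr_estimate")) e$estimate else e$beta
  }, numeric(1))
  se <- vapply(estimates, function(e) e$se, numeric(1))
  if (any(se <= 0)) stop("standard errors must be positive")
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  pse <- 1 / sqrt(sum(w))
  k <- length(beta)
  Q <- sum(w * (beta - pooled)^2)
  if (random && k > 1) pse <- pse * max(1, sqrt(Q / (k - 1)))
  het <- heterogeneity(Q, k - 1)
  mr_estimate("meta_fixed", pooled, pse, n_variants = k,
              Q = het$Q, Q_df = het$Q_df, Q_p = het$Q_p, I2 = het$I2)
}

#' Over-identification test between two instrument subsets
#'
#' Estimates the causal effect separately from two disjoint variant subsets
#' (IVW on summary pairs) and compares the estimates with [fisher_z_diff()].
#' Disagreement indicates that at least one subset violates the instrument
#' assumptions (e.g. acts on the outcome through a non-exposure pathway).
#'
#' @param pairs_a,pairs_b harmonized variant-effect pair tables with disjoint
#'   `snp` sets.
#' @param model IVW model for the subset estimates.
#' @return list with `estimate_a`, `estimate_b`, `z`, `p_difference`.
#' @export
overidentification_test <- function(pairs_a, pairs_b, model = "fixed") {
  if (length(intersect(pairs_a$snp, pairs_b$snp)) > 0) {
    stop("instrument subsets overlap")
  }
  ea <- mr_ivw(pairs_a, model)
  eb <- mr_ivw(pairs_b, model)
  fz <- fisher_z_diff(ea, eb)
  list(estimate_a = ea, estimate_b = eb, z = fz$z, p_difference = fz$p)
}

#' Per-variant pleiotropy screen
#'
#' Converts each variant's outcome log-odds to SD units of the (latent)
#' liability via `by_SD = by * sqrt(c (1 - c))` with `c` the case fraction,
#' and flags variants whose outcome effect exceeds their exposure effect
#' (`|by_SD| > |bx|`, exposure already in SD units): such variants are
#' unlikely to be specific instruments for the exposure. The conversion
#' constant is configurable.
#'
#' @param pairs harmonized variant-effect pairs.
#' @param case_fraction outcome case fraction in (0, 1).
#' @param conversion function mapping (by, case_fraction) to SD units;
#'   default `by * sqrt(c * (1 - c))`.
#' @return data.frame: snp, bx, by, by_sd, flagged.
#' @export
pleiotropy_screen <- function(pairs, case_fraction,
                              conversion = function(by, c) by * sqrt(c * (1 - c))) {
  if (case_fraction <= 0 || case_fraction >= 1) {
    stop("case_fraction must lie in (0, 1)")
  }
  d <- prepare_pairs(pairs)
  by_sd <- conversion(d$by, case_fraction)
  data.frame(snp = d$snp, bx = d$bx, by = d$by, by_sd = by_sd,
             flagged = abs(by_sd) > abs(d$bx), stringsAsFactors = FALSE)
}

#' Negative-control battery
#'
#' For each control trait (a trait implausibly caused by the exposure), runs
#' the observational regression and the two-stage IV analysis, each with and
#' without a socioeconomic-position-like covariate. Continuous controls use a
#' linear second stage, binary controls a logistic one. Under a valid
#' instrument the IV confidence intervals should cover zero; residual
#' population structure shows up as nonzero IV estimates that attenuate when
#' the covariate is added.
#'
#' @param cohort an `mr_cohort`.
#' @param controls character vector of control trait column names.
#' @param score per-sample genetic score.
#' @param sep_covariate name of the socioeconomic-position-like column.
#' @param exposure exposure column name.
#' @return data.frame: trait, analysis (observational/genetic), adjusted,
#'   estimate, se, ci_low, ci_high, p.
#' @export
negative_control_battery <- function(cohort, controls = c("control_cont",
                                                          "control_bin",
                                                          "control_noise"),
                                     score, sep_covariate = "sep",
                                     exposure = "exposure") {
  samples <- if (inherits(cohort, "mr_cohort")) cohort$samples else cohort
  miss <- setdiff(c(controls, sep_covariate, exposure), names(samples))
  if (length(miss)) stop("columns not present: ", paste(miss, collapse = ", "))
  rows <- list()
  for (trait in controls) {
    y <- samples[[trait]]
    binary <- all(y %in% c(0, 1))
    for (adjusted in c(FALSE, TRUE)) {
      cv <- if (adjusted) samples[, sep_covariate, drop = FALSE] else NULL
      obs <- if (binary) {
        observational_logistic(y, samples[[exposure]], cv)
      } else {
        dat <- data.frame(.y = y, .x = samples[[exposure]])
        if (!is.null(cv)) dat <- cbind(dat, cv)
        co <- summary(stats::lm(.y ~ ., data = dat))$coefficients[".x", ]
        mr_estimate("observational", co[1], co[2], p = co[4],
                    n_samples = length(y), scale = "linear")
      }
      iv <- iv_two_stage(y, samples[[exposure]], score, cv,
                         family = if (binary) "binomial" else "gaussian")
      for (res in list(c(list(obs), analysis = "observational"),
                       c(list(iv), analysis = "genetic"))) {
        e <- res[[1]]
        rows[[length(rows) + 1L]] <- data.frame(
          trait = trait, analysis = res$analysis, adjusted = adjusted,
          estimate = e$estimate, se = e$se, ci_low = e$ci_low,
          ci_high = e$ci_high, p = e$p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
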