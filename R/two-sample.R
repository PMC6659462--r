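#' @name two_sample
#' @title Two-sample summary-statistic MR estimators
#'
#' @description
#' Estimators operating on harmonized variant-effect pairs (columns `bx`,
#' `se_x`, `by`, `se_y`, optionally `keep`): the single-variant Wald ratio,
#' inverse-variance-weighted (IVW) regression through the origin under fixed
#' or multiplicative random effects, MR-Egger regression with an unconstrained
#' intercept measuring average directional pleiotropy, and the weighted
#' median (optionally penalized) which is consistent while under half of the
#' weight comes from invalid instruments.
NULL

prepare_pairs <- function(pairs) {
  if (!is.null(pairs$keep)) pairs <- pairs[pairs$keep, , drop = FALSE]
  need <- c("bx", "se_x", "by", "se_y")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("pairs missing columns: ", paste(miss, collapse = ", "))
  if (any(pairs$se_x <= 0) || any(pairs$se_y <= 0)) {
    stop("standard errors must be positive")
  }
  pairs
}

heterogeneity <- function(Q, df) {
  list(Q = Q, Q_df = df,
       Q_p = if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_,
       I2 = if (Q > 0) max(0, (Q - df) / Q) else 0)
}

#' Wald ratio estimate from a single variant
#'
#' `by / bx` with first-order delta-method standard error `se_y / |bx|`.
#'
#' @param pair one-row data.frame (or list) with `bx`, `by`, `se_y`.
#' @return `mr_estimate`.
#' @export
wald_ratio <- function(pair) {
  bx <- pair$bx[1]; by <- pair$by[1]; se_y <- pair$se_y[1]
  if (bx == 0) stop("bx = 0: Wald ratio undefined")
  mr_estimate("wald_ratio", by / bx, se_y / abs(bx), n_variants = 1L)
}

#' Inverse-variance-weighted MR
#'
#' Weighted regression of `by` on `bx` through the origin with weights
#' `1/se_y^2`: estimate `sum(w bx by) / sum(w bx^2)`, fixed-effect SE
#' `(sum(w bx^2))^-1/2`. The random-effects model inflates the SE by the
#' multiplicative dispersion `max(1, sqrt(Q/(k-1)))` after heterogeneity is
#' detected among the per-variant causal estimates.
#'
#' @param pairs harmonized variant-effect pairs (>= 2 kept rows).
#' @param model `"fixed"` or `"random"`.
#' @return `mr_estimate` with Cochran Q heterogeneity fields.
#' @export
mr_ivw <- function(pairs, model = c("fixed", "random")) {
  model <- match.arg(model)
  d <- prepare_pairs(pairs)
  k <- nrow(d)
  if (k < 2) stop("IVW needs >= 2 variant pairs; use wald_ratio() for one")
  w <- 1 / d$se_y^2
  sxx <- sum(w * d$bx^2)
  est <- sum(w * d$bx * d$by) / sxx
  se <- 1 / sqrt(sxx)
  Q <- sum(w * (d$by - est * d$bx)^2)
  if (model == "random") se <- se * max(1, sqrt(Q / (k - 1)))
  het <- heterogeneity(Q, k - 1)
  mr_estimate(paste0("ivw_", model), est, se, n_variants = k,
              Q = het$Q, Q_df = het$Q_df, Q_p = het$Q_p, I2 = het$I2)
}

#' MR-Egger regression
#'
#' Weighted least squares `by = b0 + b1 bx` with weights `1/se_y^2`, after
#' orienting every pair so `bx > 0` (the estimator is not invariant to joint
#' sign flips without this convention). The slope is the causal estimate
#' under the InSIDE assumption; the intercept measures average directional
#' pleiotropy. Standard errors are divided by `min(1, sigma)` so dispersion
#' below 1 is not allowed to shrink them; p-values use the t distribution
#' with k - 2 degrees of freedom.
#'
#' @param pairs harmonized variant-effect pairs (>= 3 kept rows).
#' @return list with `slope` and `intercept` (`mr_estimate` objects sharing
#'   the heterogeneity fields of the residual fit).
#' @export
mr_egger <- function(pairs) {
  d <- prepare_pairs(pairs)
  k <- nrow(d)
  if (k < 3) stop("MR-Egger needs >= 3 variant pairs")
  flip <- d$bx < 0
  d$bx[flip] <- -d$bx[flip]
  d$by[flip] <- -d$by[flip]
  if (stats::var(d$bx) == 0) stop("all bx equal after orientation; rank-deficient")
  w <- 1 / d$se_y^2
  fit <- stats::lm(by ~ bx, data = d, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  sigma <- sm$sigma
  adj <- if (sigma > 0) 1 / min(sigma, 1) else 1
  se_b0 <- co[1, 2] * adj
  se_b1 <- co[2, 2] * adj
  Q <- sum(w * stats::residuals(fit)^2)
  het <- heterogeneity(Q, k - 2)
  p_t <- function(b, se) 2 * stats::pt(-abs(b / se), df = k - 2)
  slope <- mr_estimate("egger_slope", co[2, 1], se_b1,
                       p = p_t(co[2, 1], se_b1), n_variants = k,
                       Q = het$Q, Q_df = het$Q_df, Q_p = het$Q_p, I2 = het$I2)
  intercept <- mr_estimate("egger_intercept", co[1, 1], max(se_b0, 1e-300),
                           p = p_t(co[1, 1], max(se_b0, 1e-300)),
                           n_variants = k)
  list(slope = slope, intercept = intercept)
}

# Interpolated weighted median of ratio estimates at standardized cumulative
# weight 0.5 (the construction of the median-based two-sample estimator).
weighted_median_est <- function(ratios, weights) {
  if (sum(weights) <= 0) stop("zero total weight")
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o]
  s <- cumsum(w)
  p <- (s - w / 2) / sum(w)
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median MR (optionally penalized)
#'
#' Per-variant ratio estimates `r_j = by_j / bx_j` with inverse-variance
#' weights `w_j = bx_j^2 / se_y_j^2`; the estimate is the linear interpolation
#' of the sorted ratios at standardized cumulative weight 0.5. The estimator
#' is consistent when under 50% of the weight comes from invalid instruments.
#' Penalized mode down-weights heterogeneous variants by
#' `min(1, 20 q_j)` where `q_j` is the upper chi-square(1) tail probability of
#' variant j's contribution to Cochran's Q about the unpenalized estimate.
#' The standard error comes from a seeded parametric bootstrap resampling
#' `(bx_j, by_j)` from normal distributions with their reported SEs.
#'
#' @param pairs harmonized variant-effect pairs (>= 3 kept rows).
#' @param penalized apply the heterogeneity penalty.
#' @param bootstrap_reps parametric bootstrap replicates for the SE.
#' @param seed bootstrap seed.
#' @return `mr_estimate`.
#' @export
mr_weighted_median <- function(pairs, penalized = FALSE,
                               bootstrap_reps = 1000, seed = 1L) {
  d <- prepare_pairs(pairs)
  k <- nrow(d)
  if (k < 3) stop("weighted median needs >= 3 variant pairs")
  if (any(d$bx == 0)) stop("bx = 0 in pairs; ratio undefined")

  point <- function(bx, by, se_y) {
    r <- by / bx
    w <- bx^2 / se_y^2
    est <- weighted_median_est(r, w)
    if (penalized) {
      qj <- w * (r - est)^2
      pen <- pmin(1, 20 * stats::pchisq(qj, 1, lower.tail = FALSE))
      est <- weighted_median_est(r, w * pen)
    }
    est
  }
  est <- point(d$bx, d$by, d$se_y)
  set.seed(derive_seed(seed, "median-bootstrap"))
  boots <- vapply(seq_len(bootstrap_reps), function(i) {
    point(stats::rnorm(k, d$bx, d$se_x), stats::rnorm(k, d$by, d$se_y),
          d$se_y)
  }, numeric(1))
  se <- stats::sd(boots)
  mr_estimate(if (penalized) "penalized_weighted_median" else "weighted_median",
              est, max(se, 1e-300), n_variants = k)
}

#' Run the full two-sample estimator battery
#'
#' Convenience wrapper returning IVW (fixed and random), MR-Egger slope and
#' intercept, and the weighted and penalized weighted medians as one tidy
#' table.
#'
#' @param pairs harmonized variant-effect pairs.
#' @param bootstrap_reps,seed forwarded to [mr_weighted_median()].
#' @return data.frame of estimates.
#' @export
mr_two_sample_battery <- function(pairs, bootstrap_reps = 1000, seed = 1L) {
  eg <- mr_egger(pairs)
  mr_results_table(
    mr_ivw(pairs, "fixed"), mr_ivw(pairs, "random"),
    eg$slope, eg$intercept,
    mr_weighted_median(pairs, FALSE, bootstrap_reps, seed),
    mr_weighted_median(pairs, TRUE, bootstrap_reps, seed)
  )
}
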