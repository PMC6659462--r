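#' Construct an MR estimate object
#'
#' Container used by every estimator in the package: a causal (or
#' observational) effect on the log-odds or linear scale together with its
#' standard error, normal-theory 95% confidence interval, Wald p-value and,
#' where applicable, heterogeneity diagnostics.
#'
#' Confidence intervals use the `estimate +/- 1.96 * se` convention throughout,
#' which is how printed odds-ratio CIs in biobank MR reports convert back to
#' their p-values.
#'
#' @param method method tag, e.g. `"ivw_fixed"`, `"tsls"`, `"egger_slope"`.
#' @param estimate point estimate (log-odds per 1-SD exposure unless the
#'   caller declares a linear scale).
#' @param se positive standard error.
#' @param p optional p-value; computed from the normal Wald statistic when
#'   missing.
#' @param n_variants,n_samples problem size bookkeeping.
#' @param Q,Q_df,Q_p,I2 Cochran heterogeneity statistics, if available.
#' @param scale `"log_odds"` or `"linear"`.
#' @param extra named list merged into the object (e.g. first-stage F).
#' @return An object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, estimate, se, p = NULL,
                        n_variants = NA_integer_, n_samples = NA_integer_,
                        Q = NA_real_, Q_df = NA_real_, Q_p = NA_real_,
                        I2 = NA_real_, scale = "log_odds", extra = list()) {
  stopifnot(is.character(method), length(method) == 1L)
  if (!is.finite(estimate)) stop("estimate must be finite")
  if (!is.finite(se) || se <= 0) stop("se must be a positive number")
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(estimate) / se)
  p <- max(min(p, 1), .Machine$double.xmin)
  out <- list(
    method = method, estimate = estimate, se = se,
    ci_low = estimate - 1.96 * se, ci_high = estimate + 1.96 * se,
    p = p, n_variants = n_variants, n_samples = n_samples,
    Q = Q, Q_df = Q_df, Q_p = Q_p, I2 = I2, scale = scale
  )
  out <- utils::modifyList(out, extra)
  class(out) <- "mr_estimate"
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  or <- identical(x$scale, "log_odds")
  cat(sprintf("MR estimate [%s]\n", x$method))
  cat(sprintf("  beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$estimate, x$se, x$ci_low, x$ci_high, x$p))
  if (or) {
    cat(sprintf("  OR   = %.3f, 95%% CI [%.3f, %.3f]\n",
                exp(x$estimate), exp(x$ci_low), exp(x$ci_high)))
  }
  if (is.finite(x$Q)) {
    cat(sprintf("  heterogeneity: Q = %.3f (df %d), p_Q = %.3g, I2 = %.1f%%\n",
                x$Q, as.integer(x$Q_df), x$Q_p, 100 * x$I2))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(
    method = x$method, estimate = x$estimate, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
    n_variants = x$n_variants, n_samples = x$n_samples,
    Q = x$Q, Q_df = x$Q_df, Q_p = x$Q_p, I2 = x$I2,
    scale = x$scale, stringsAsFactors = FALSE
  )
}

#' Bind MR estimates into a tidy results table
#'
#' @param ... `mr_estimate` objects or lists of them.
#' @return data.frame with one row per estimate.
#' @export
mr_results_table <- function(...) {
  ests <- list(...)
  flat <- list()
  for (e in ests) {
    if (inherits(e, "mr_estimate")) flat[[length(flat) + 1L]] <- e
    else flat <- c(flat, e)
  }
  do.call(rbind, lapply(flat, as.data.frame))
}

#' Estimate-with-SE helper from a printed odds ratio and 95% CI
#'
#' Converts a published odds ratio with its 95% confidence interval back to a
#' log-odds estimate and standard error via `se = (log(hi) - log(lo)) / (2 *
#' 1.96)`, the inverse of the usual CI construction. Used to reproduce printed
#' Wald p-values and stratified contrasts from report tables.
#'
#' @param or,ci_low,ci_high odds ratio and CI bounds (all positive), or a
#'   linear-scale estimate with bounds when `log = FALSE`.
#' @param log if `TRUE` (default) inputs are ORs and are log-transformed.
#' @param label optional label.
#' @return list with `beta`, `se`, `label`.
#' @export
est_from_ci <- function(or, ci_low, ci_high, log = TRUE, label = NULL) {
  if (ci_low >= ci_high) stop("ci_low must be below ci_high")
  if (log) {
    if (min(or, ci_low, ci_high) <= 0) stop("odds-ratio inputs must be positive")
    beta <- base::log(or)
    se <- (base::log(ci_high) - base::log(ci_low)) / (2 * 1.96)
  } else {
    beta <- or
    se <- (ci_high - ci_low) / (2 * 1.96)
  }
  if (se <= 0) stop("degenerate interval")
  list(beta = beta, se = se, label = label)
}
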