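#' Observational logistic association
#'
#' Maximum-likelihood logistic regression of a binary outcome on the exposure
#' with optional covariates; the exposure coefficient (log-odds per exposure
#' unit) is returned with its normal-theory CI. Complete separation is
#' detected and reported as an error advising a penalized fit.
#'
#' @param outcome binary 0/1 vector.
#' @param exposure numeric exposure (1-SD units after
#'   [inverse_normalize()]).
#' @param covariates optional data.frame of adjustment covariates.
#' @return `mr_estimate` with method `"observational"`.
#' @export
observational_logistic <- function(outcome, exposure, covariates = NULL) {
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(outcome)) < 2) stop("outcome is degenerate")
  dat <- data.frame(.y = outcome, .x = exposure)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
  if (!fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    stop("possible separation in logistic fit; use a penalized model")
  }
  co <- summary(fit)$coefficients[".x", ]
  mr_estimate("observational", co[1], co[2], p = co[4],
              n_samples = length(outcome))
}

#' One-sample two-stage instrumental-variable estimate
#'
#' Stage 1 regresses the exposure on the genetic score (plus covariates) by
#' least squares; stage 2 regresses the binary outcome on the stage-1 fitted
#' exposure (plus the same covariates) by logistic regression, i.e. the
#' two-stage procedure for binary outcomes. The reported standard error is a
#' heteroskedasticity-robust HC1 sandwich on the second stage, correcting for
#' the uncertainty in the predicted exposure. The first-stage F statistic is
#' reported and a warning emitted below F = 10.
#'
#' A linear second stage (`family = "gaussian"`) is available for continuous
#' outcomes such as negative-control traits; the estimate is then on the
#' outcome's own scale.
#'
#' @param outcome outcome vector (binary for the logistic second stage).
#' @param exposure exposure vector (or a binary indicator, e.g. obesity).
#' @param score per-sample genetic risk score.
#' @param covariates optional data.frame entering both stages.
#' @param family `"binomial"` (default) or `"gaussian"` second stage.
#' @return `mr_estimate` with method `"tsls"`, robust `se`, classical
#'   `se_classical` and first-stage `f_stat`.
#' @export
iv_two_stage <- function(outcome, exposure, score, covariates = NULL,
                         family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  if (stats::var(score) == 0) stop("score has zero variance")
  d1 <- data.frame(.x = exposure, .score = score)
  if (!is.null(covariates)) d1 <- cbind(d1, as.data.frame(covariates))
  stage1 <- stats::lm(.x ~ ., data = d1)
  strength <- instrument_strength(score, exposure, covariates)
  if (is.finite(strength$f_stat) && strength$f_stat < 10) {
    warning(sprintf("weak instrument: first-stage F = %.2f", strength$f_stat))
  }
  d2 <- data.frame(.y = outcome, .xhat = stats::fitted(stage1))
  if (!is.null(covariates)) d2 <- cbind(d2, as.data.frame(covariates))
  fam <- if (family == "binomial") stats::binomial() else stats::gaussian()
  stage2 <- stats::glm(.y ~ ., data = d2, family = fam)
  est <- stats::coef(stage2)[".xhat"]
  vc <- sandwich::vcovHC(stage2, type = "HC1")
  se <- sqrt(vc[".xhat", ".xhat"])
  se_cl <- summary(stage2)$coefficients[".xhat", 2]
  mr_estimate("tsls", unname(est), se, n_samples = length(outcome),
              scale = if (family == "binomial") "log_odds" else "linear",
              extra = list(f_stat = strength$f_stat, r2 = strength$r2,
                           se_classical = se_cl))
}

#' Sex-stratified observational and IV analyses
#'
#' Repeats the observational logistic and two-stage IV analyses within each
#' level of a stratification variable using the same score and covariates
#' (the same instruments are used in every stratum). Strata with fewer than
#' two outcome classes are skipped with a note.
#'
#' @param cohort an `mr_cohort` (or a data.frame with the named columns).
#' @param score per-sample score aligned with the cohort rows.
#' @param outcome,exposure,strata column names.
#' @param covariates optional data.frame.
#' @return named list per stratum, each with `observational` and `tsls`
#'   `mr_estimate`s (or a `note` for skipped strata).
#' @export
sexstratified_run <- function(cohort, score, outcome = "outcome",
                              exposure = "exposure", strata = "sex",
                              covariates = NULL) {
  samples <- if (inherits(cohort, "mr_cohort")) cohort$samples else cohort
  sv <- samples[[strata]]
  if (is.null(sv)) stop("stratification variable not found: ", strata)
  levels <- sort(unique(sv))
  if (length(levels) < 2) stop("need at least two non-empty strata")
  out <- list()
  for (lv in levels) {
    idx <- which(sv == lv)
    key <- paste0(strata, "=", lv)
    if (length(idx) == 0) { out[[key]] <- list(note = "empty stratum"); next }
    y <- samples[[outcome]][idx]
    if (length(unique(y)) < 2) {
      out[[key]] <- list(note = "stratum has < 2 outcome classes; skipped")
      next
    }
    cv <- if (is.null(covariates)) NULL else covariates[idx, , drop = FALSE]
    out[[key]] <- list(
      observational = observational_logistic(y, samples[[exposure]][idx], cv),
      tsls = iv_two_stage(y, samples[[exposure]][idx], score[idx], cv)
    )
  }
  out
}
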