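#' Weighted genetic risk score with allele-count rescaling
#'
#' Builds the weighted score `sum_j beta_j g_ij` and rescales it to the
#' trait-increasing allele-count scale by multiplying with
#' `n_SNPs / sum_j beta_j`, so that under equal weights the score equals the
#' raw allele count exactly.
#'
#' @param dosages numeric matrix of 0/1/2 dosages with variant IDs as column
#'   names.
#' @param instruments instrument data.frame with columns `snp` and `weight`
#'   (per-allele exposure effects from an external GWAS), optionally `subset`.
#' @param rescale apply the allele-count rescaling (default TRUE).
#' @return numeric per-sample score.
#' @export
weighted_grs <- function(dosages, instruments, rescale = TRUE) {
  stopifnot(is.matrix(dosages), is.data.frame(instruments))
  missing <- setdiff(instruments$snp, colnames(dosages))
  if (length(missing)) {
    stop("instrument variants missing from dosage matrix: ",
         paste(missing, collapse = ", "))
  }
  w <- instruments$weight
  if (any(!is.finite(w))) stop("instrument weights must be finite")
  raw <- drop(dosages[, instruments$snp, drop = FALSE] %*% w)
  if (!rescale) return(raw)
  sw <- sum(w)
  if (sw == 0) stop("sum of instrument weights is zero; cannot rescale")
  raw * length(w) / sw
}

#' Rank-based inverse-normal transform
#'
#' Maps values to normal quantiles of their offset ranks,
#' `qnorm((rank - 0.5) / n)`, with ties assigned average ranks; the transform
#' applied to the exposure before analysis so effects are in 1-SD units.
#'
#' @param values numeric vector (NAs preserved).
#' @return transformed vector, mean ~0 and SD ~1, rank order preserved.
#' @export
inverse_normalize <- function(values) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < 2) stop("need at least two non-missing values")
  if (length(unique(v)) == 1) {
    stop("all values identical; inverse-normal transform undefined")
  }
  r <- rank(v, ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - 0.5) / length(v))
  out
}

#' Instrument strength: variance explained and first-stage F
#'
#' Regresses the exposure on the score (after residualizing both on any
#' covariates) and reports R-squared and the univariate first-stage
#' F statistic `R2 (n - 2) / (1 - R2)`. `F = Inf` is returned when the score
#' explains the exposure exactly.
#'
#' @param score,exposure numeric vectors of equal length.
#' @param covariates optional data.frame/matrix residualized out first.
#' @return list with `r2`, `f_stat`, `n`.
#' @export
instrument_strength <- function(score, exposure, covariates = NULL) {
  if (length(score) != length(exposure)) {
    stop("score and exposure must have the same length")
  }
  n <- length(score)
  if (n < 3) stop("need at least 3 observations")
  if (!is.null(covariates)) {
    cm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    score <- stats::lm.fit(cm, score)$residuals
    exposure <- stats::lm.fit(cm, exposure)$residuals
  }
  r <- stats::cor(score, exposure)
  r2 <- r^2
  f <- if (r2 >= 1) Inf else r2 * (n - 2) / (1 - r2)
  list(r2 = r2, f_stat = f, n = n)
}

#' Screen a genetic score against potential confounders
#'
#' For each covariate, regresses the covariate on the score with and without
#' exposure adjustment. Attenuation of an association after adjusting for the
#' exposure indicates the covariate sits downstream of the exposure rather
#' than confounding the instrument.
#'
#' @param score per-sample GRS.
#' @param covariates data.frame of numeric/binary covariates.
#' @param exposure exposure vector for the adjusted models.
#' @return data.frame: covariate, beta, se, p (unadjusted) and
#'   beta_adj, se_adj, p_adj (exposure-adjusted); constant covariates are
#'   reported with a note and NA estimates.
#' @export
confounder_scan <- function(score, covariates, exposure) {
  covariates <- as.data.frame(covariates)
  rows <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (!is.numeric(v)) v <- as.numeric(v)
    if (stats::var(v, na.rm = TRUE) == 0) {
      return(data.frame(covariate = nm, beta = NA_real_, se = NA_real_,
                        p = NA_real_, beta_adj = NA_real_, se_adj = NA_real_,
                        p_adj = NA_real_, note = "constant covariate; skipped",
                        stringsAsFactors = FALSE))
    }
    f1 <- stats::lm(v ~ score)
    f2 <- stats::lm(v ~ score + exposure)
    s1 <- summary(f1)$coefficients["score", ]
    s2 <- summary(f2)$coefficients["score", ]
    data.frame(covariate = nm, beta = s1[1], se = s1[2], p = s1[4],
               beta_adj = s2[1], se_adj = s2[2], p_adj = s2[4], note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Categorize raw BMI values into the binary-obesity contrast
#'
#' Normal weight is 18.5-24.9 kg/m^2, obese is above 30 kg/m^2; everything in
#' between (and underweight below 18.5) is excluded from the binary contrast.
#' Values outside (10, 80) kg/m^2 are rejected as likely unit errors.
#'
#' @param values BMI in kg/m^2.
#' @return factor with levels normal, obese, excluded (NA preserved).
#' @export
categorize_bmi <- function(values) {
  ok <- !is.na(values)
  if (any(values[ok] < 0)) stop("negative BMI value")
  if (any(values[ok] <= 10 | values[ok] >= 80)) {
    stop("BMI outside (10, 80) kg/m^2; check units")
  }
  out <- rep(NA_character_, length(values))
  out[ok] <- "excluded"
  out[ok & values >= 18.5 & values <= 24.9] <- "normal"
  out[ok & values > 30] <- "obese"
  factor(out, levels = c("normal", "obese", "excluded"))
}

#' Read / write instrument files
#'
#' Tab-separated instrument lists: columns `snp`, `effect_allele`, `weight`,
#' optional `subset_label` (stored as `subset`).
#'
#' @param path file path.
#' @return data.frame of instruments.
#' @export
read_instruments <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp", "effect_allele", "weight")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("instrument file missing columns: ",
                         paste(miss, collapse = ", "))
  if ("subset_label" %in% names(d) && !"subset" %in% names(d)) {
    d$subset <- d$subset_label
  }
  d
}

#' @rdname read_instruments
#' @param instruments instrument data.frame.
#' @export
write_instruments <- function(instruments, path) {
  utils::write.table(instruments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
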