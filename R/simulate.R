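#' Simulate biallelic genotype dosages in Hardy-Weinberg proportions
#'
#' Draws allele frequencies uniformly from `maf_range` and dosages as
#' independent Binomial(2, f_j) counts per variant, the coding used for
#' trait-increasing alleles (0/1/2 copies).
#'
#' @param config a [sim_config()].
#' @param freq optional frequency vector; drawn from the config stream when
#'   omitted.
#' @param n optional row count override.
#' @return list with `dosages` (n x m integer matrix, columns named by variant
#'   ID) and `freq`.
#' @export
simulate_genotypes <- function(config, freq = NULL, n = config$n_samples) {
  validate_sim_config(config)
  if (is.null(freq)) freq <- draw_frequencies(config)
  m <- length(freq)
  set.seed(derive_seed(config$seed, "genotypes"))
  g <- matrix(stats::rbinom(n * m, 2L, rep(freq, each = n)), nrow = n, ncol = m)
  colnames(g) <- variant_ids(m)
  list(dosages = g, freq = stats::setNames(freq, variant_ids(m)))
}

draw_frequencies <- function(config) {
  set.seed(derive_seed(config$seed, "freq"))
  stats::runif(config$n_variants, config$maf_range[1], config$maf_range[2])
}

variant_ids <- function(m) sprintf("rs%03d", seq_len(m))

#' Calibrate per-variant effects to a target score R-squared
#'
#' Draws per-variant exposure effects from a half-normal distribution and
#' rescales them so the theoretical variance explained by the score,
#' `sum(2 f_j (1 - f_j) alpha_j^2)`, equals `target_r2` exactly on the
#' unit-variance exposure scale. Direct (pleiotropic) outcome effects
#' `delta_j` are zero outside the configured pleiotropy fraction; directional
#' mode draws them with a common positive sign, balanced mode with mean zero.
#'
#' @param config a [sim_config()].
#' @return list of class `true_parameters` with elements `freq`, `alpha`,
#'   `delta`, `theta`, `sex_effect_modifier`, `sigma_eps` (residual exposure
#'   SD), confounder loadings, `subset` labels and `variant_ids`.
#' @export
calibrate_effects <- function(config) {
  validate_sim_config(config)
  f <- draw_frequencies(config)
  m <- config$n_variants
  hwe_var <- 2 * f * (1 - f)
  set.seed(derive_seed(config$seed, "effects"))
  if (config$target_r2 == 0) {
    alpha <- rep(0, m)
  } else {
    raw <- abs(stats::rnorm(m))
    raw[raw < 0.05] <- 0.05  # avoid near-null instruments in the score
    alpha <- raw * sqrt(config$target_r2 / sum(hwe_var * raw^2))
  }
  delta <- rep(0, m)
  k <- round(config$pleiotropy_fraction * m)
  if (k > 0) {
    idx <- sample.int(m, k)
    draw <- stats::rnorm(k, 0, config$pleiotropy_scale)
    if (config$pleiotropy_mode == "directional") draw <- abs(draw)
    delta[idx] <- draw
  }
  sigma_eps <- sqrt(1 - config$target_r2 - config$confounder_effect_x^2)
  n_neuro <- if (m == 73L) 43L else round(0.6 * m)
  subset <- rep(c("neuronal", "non_neuronal"),
                c(n_neuro, m - n_neuro))[seq_len(m)]
  structure(list(
    variant_ids = variant_ids(m), freq = f, alpha = alpha, delta = delta,
    theta = config$causal_effect,
    sex_effect_modifier = config$sex_effect_modifier,
    confounder_effect_x = config$confounder_effect_x,
    confounder_effect_y = config$confounder_effect_y,
    sigma_eps = sigma_eps, target_r2 = config$target_r2, subset = subset
  ), class = "true_parameters")
}

#' Simulate an individual-level cohort
#'
#' Generates genotypes, a standardized confounded exposure
#' `X = G alpha + c_x U + eps` (unit theoretical variance), a binary outcome
#' with `logit P(Y = 1) = beta0 + theta_i X + G delta + c_y U` where `theta_i`
#' is sex-modified and `beta0` is solved by bisection so the expected
#' prevalence matches `case_fraction`, covariates (a noisy confounder proxy,
#' an assessment-centre-like factor, a socioeconomic-position-like score), and
#' negative-control traits driven by the confounder -- and, when
#' `stratification_effect != 0`, by a latent subpopulation with shifted allele
#' frequencies -- but never by the exposure.
#'
#' A raw BMI-like column on the kg/m^2 scale (`bmi_kgm2 = 27.2 + 4.7 * X`) is
#' included so binary-obesity analyses via [categorize_bmi()] can be exercised.
#'
#' @param config a [sim_config()].
#' @return object of class `mr_cohort`: list with `samples` (data.frame),
#'   `genotypes` (dosage matrix), `variants` (variant table with alleles and
#'   subset labels) and `true` (the `true_parameters`, plus `beta0`).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  params <- calibrate_effects(config)
  n <- config$n_samples
  m <- config$n_variants
  f <- params$freq

  set.seed(derive_seed(config$seed, "subpop"))
  if (config$stratification_effect != 0) {
    subpop <- stats::rbinom(n, 1L, 0.5)
    shift <- config$stratification_effect * f * (1 - f)
    f_mat <- rbind(pmin(pmax(f, 0.01), 0.99),
                   pmin(pmax(f + shift, 0.01), 0.99))
  } else {
    subpop <- integer(n)
    f_mat <- rbind(f, f)
  }
  set.seed(derive_seed(config$seed, "genotypes"))
  probs <- f_mat[subpop + 1L, , drop = FALSE]
  g <- matrix(stats::rbinom(n * m, 2L, probs), nrow = n, ncol = m)
  colnames(g) <- params$variant_ids

  set.seed(derive_seed(config$seed, "phenotypes"))
  sex <- stats::rbinom(n, 1L, 0.5)
  u <- stats::rnorm(n)
  x <- drop(g %*% params$alpha) + config$confounder_effect_x * u +
    stats::rnorm(n, 0, params$sigma_eps)

  theta_i <- config$causal_effect *
    ifelse(sex == 1L, config$sex_effect_modifier, 1)
  eta <- theta_i * x + drop(g %*% params$delta) +
    config$confounder_effect_y * u
  beta0 <- solve_intercept(eta, config$case_fraction)
  y <- stats::rbinom(n, 1L, stats::plogis(beta0 + eta))

  set.seed(derive_seed(config$seed, "controls"))
  strat_on <- as.numeric(config$stratification_effect != 0)
  control_cont <- 0.8 * u + 0.8 * strat_on * subpop + stats::rnorm(n)
  control_bin <- stats::rbinom(
    n, 1L, stats::plogis(-1 + 0.8 * u + 0.8 * strat_on * subpop))
  control_noise <- stats::rnorm(n)
  sep <- strat_on * subpop + 0.25 * u + stats::rnorm(n, 0, 0.25)
  conf_proxy <- u + stats::rnorm(n, 0, 0.5)
  centre <- sample.int(10L, n, replace = TRUE)

  samples <- data.frame(
    sample_id = sprintf("id%07d", seq_len(n)),
    sex = sex, exposure = x, bmi_kgm2 = 27.2 + 4.7 * x, outcome = y,
    confounder = u, conf_proxy = conf_proxy, sep = sep,
    centre = centre, subpop = subpop,
    control_cont = control_cont, control_bin = control_bin,
    control_noise = control_noise,
    stringsAsFactors = FALSE
  )

  set.seed(derive_seed(config$seed, "alleles"))
  pal <- stats::runif(m) < config$palindromic_fraction
  variants <- data.frame(
    snp = params$variant_ids,
    effect_allele = "A",
    other_allele = ifelse(pal, "T", "G"),
    eaf = f, alpha = params$alpha, delta = params$delta,
    subset = params$subset, stringsAsFactors = FALSE
  )

  params$beta0 <- beta0
  structure(list(samples = samples, genotypes = g, variants = variants,
                 true = params, config = config),
            class = "mr_cohort")
}

#' @export
print.mr_cohort <- function(x, ...) {
  cat(sprintf(
    "mr_cohort: %d samples x %d variants; prevalence %.3f; theta = %.3f\n",
    nrow(x$samples), ncol(x$genotypes), mean(x$samples$outcome),
    x$true$theta))
  invisible(x)
}

# Bisection for the outcome-model intercept: expected prevalence equals the
# target to 1e-4. Closed form is unavailable for a logistic mixture.
solve_intercept <- function(eta, target, tol = 1e-4) {
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  lo <- -30; hi <- 30
  prev <- function(b0) mean(stats::plogis(b0 + eta))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    pm <- prev(mid)
    if (abs(pm - target) < tol) return(mid)
    if (pm < target) lo <- mid else hi <- mid
  }
  stop("intercept bisection failed to converge")
}

#' The true instrument set of a simulated cohort
#'
#' Exposes the generator's per-variant exposure effects as the external-GWAS
#' weights a practitioner would use, with subset labels for the
#' neuronal/non-neuronal style split.
#'
#' @param cohort an `mr_cohort`.
#' @return instrument data.frame (snp, effect_allele, weight, subset).
#' @export
true_instruments <- function(cohort) {
  data.frame(snp = cohort$variants$snp,
             effect_allele = cohort$variants$effect_allele,
             weight = cohort$variants$alpha,
             subset = cohort$variants$subset,
             stringsAsFactors = FALSE)
}

#' Per-variant association scan of a cohort trait
#'
#' Regresses the chosen trait on each variant's dosage with a simple linear
#' (continuous trait) or logistic (binary trait) model, returning the GWAS
#' summary-statistic table downstream two-sample estimators consume.
#' Monomorphic variants are flagged (`flagged = TRUE`, SE undefined) rather
#' than dropped silently.
#'
#' @param cohort an `mr_cohort`.
#' @param trait `"exposure"`, `"outcome"` or the name of any numeric sample
#'   column (e.g. a negative-control trait).
#' @return data.frame with snp, effect_allele, other_allele, eaf, beta, se,
#'   pval, n, flagged.
#' @export
cohort_to_summary_stats <- function(cohort, trait = "exposure") {
  stopifnot(inherits(cohort, "mr_cohort"))
  if (!trait %in% names(cohort$samples)) {
    stop("trait not present in cohort: ", trait)
  }
  y <- cohort$samples[[trait]]
  g <- cohort$genotypes
  binary <- all(y %in% c(0, 1))
  if (binary) res <- logistic_scan(g, y) else res <- linear_scan(g, y)
  data.frame(
    snp = cohort$variants$snp,
    effect_allele = cohort$variants$effect_allele,
    other_allele = cohort$variants$other_allele,
    eaf = colMeans(g) / 2,
    beta = res$beta, se = res$se, pval = res$p,
    n = length(y), flagged = res$flagged,
    stringsAsFactors = FALSE
  )
}

# Vectorized simple linear regression of y on each column of g.
linear_scan <- function(g, y) {
  n <- length(y)
  gm <- colMeans(g)
  ssg <- colSums(g^2) - n * gm^2
  flagged <- ssg <= 0
  yc <- y - mean(y)
  sxy <- drop(crossprod(g, yc))
  beta <- ifelse(flagged, NA_real_, sxy / ssg)
  sse <- sum(yc^2) - ifelse(flagged, 0, beta^2 * ssg)
  s2 <- sse / (n - 2)
  se <- ifelse(flagged, NA_real_, sqrt(s2 / ssg))
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(beta = beta, se = se, p = p, flagged = flagged)
}

# Per-variant univariate logistic fits (IRLS via glm.fit).
logistic_scan <- function(g, y) {
  m <- ncol(g)
  beta <- se <- p <- rep(NA_real_, m)
  flagged <- logical(m)
  for (j in seq_len(m)) {
    gj <- g[, j]
    if (stats::var(gj) == 0) { flagged[j] <- TRUE; next }
    fit <- stats::glm.fit(cbind(1, gj), y, family = stats::binomial())
    r <- fit$rank
    cov <- chol2inv(fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE])
    beta[j] <- fit$coefficients[2L]
    se[j] <- sqrt(cov[2L, 2L])
    p[j] <- 2 * stats::pnorm(-abs(beta[j] / se[j]))
  }
  list(beta = beta, se = se, p = p, flagged = flagged)
}

#' Oracle marginal estimand for a configuration
#'
#' With a logistic outcome the instrumental-variable estimand differs from the
#' conditional causal log-odds (non-collapsibility). The package's recovery
#' tests therefore target the marginal estimand theta*: the probability limit
#' of the one-sample two-stage estimator, computed by running that estimator
#' once on a very large simulated cohort (default two million individuals,
#' generated in chunks to bound memory).
#'
#' @param config a [sim_config()].
#' @param n_total oracle cohort size.
#' @param chunk chunk size for genotype generation.
#' @return numeric theta* (log-odds per 1-SD exposure).
#' @export
oracle_estimand <- function(config, n_total = 2e6, chunk = 2e5) {
  validate_sim_config(config)
  params <- calibrate_effects(config)
  m <- config$n_variants
  f <- params$freq
  set.seed(derive_seed(config$seed, "oracle"))

  # solve the intercept on a pre-pass chunk, reuse across chunks
  pre_n <- min(n_total, chunk)
  draw_chunk <- function(nc) {
    g <- matrix(stats::rbinom(nc * m, 2L, rep(f, each = nc)), nrow = nc)
    sex <- stats::rbinom(nc, 1L, 0.5)
    u <- stats::rnorm(nc)
    x <- drop(g %*% params$alpha) + config$confounder_effect_x * u +
      stats::rnorm(nc, 0, params$sigma_eps)
    theta_i <- config$causal_effect *
      ifelse(sex == 1L, config$sex_effect_modifier, 1)
    eta <- theta_i * x + drop(g %*% params$delta) +
      config$confounder_effect_y * u
    list(score = drop(g %*% params$alpha), x = x, sex = sex, eta = eta)
  }
  first <- draw_chunk(pre_n)
  beta0 <- solve_intercept(first$eta, config$case_fraction)

  n_done <- 0L
  score <- x <- sex <- y <- vector("list", ceiling(n_total / chunk))
  i <- 0L
  current <- first
  repeat {
    i <- i + 1L
    score[[i]] <- current$score
    x[[i]] <- current$x
    sex[[i]] <- current$sex
    y[[i]] <- stats::rbinom(length(current$eta), 1L,
                            stats::plogis(beta0 + current$eta))
    n_done <- n_done + length(current$eta)
    if (n_done >= n_total) break
    current <- draw_chunk(min(chunk, n_total - n_done))
  }
  score <- unlist(score); x <- unlist(x); sex <- unlist(sex); y <- unlist(y)

  z1 <- cbind(1, score, sex)
  xhat <- drop(z1 %*% stats::lm.fit(z1, x)$coefficients)
  fit2 <- stats::glm.fit(cbind(1, xhat, sex), y, family = stats::binomial())
  unname(fit2$coefficients[2L])
}

#' Simulate two-sample summary statistics directly
#'
#' Parametric summary-level generator for two-sample estimator experiments:
#' variant-exposure estimates `bx_j ~ N(alpha_j, se_x_j)` and variant-outcome
#' estimates `by_j ~ N(theta * alpha_j + delta_j, se_y_j)`. Standard errors
#' default to the analytic values for GWAS of the emulated sizes (exposure
#' n = 339224 on the SD scale; outcome n = 340786 case-control with the
#' configured case fraction), so instrument strength matches the
#' individual-level generator. At the summary level the generative slope is
#' `theta` itself, giving an exact recovery target.
#'
#' @param config a [sim_config()]; `causal_effect`, pleiotropy settings and
#'   `target_r2` are honoured.
#' @param n_exposure,n_outcome effective GWAS sizes for the default SEs.
#' @param seed replicate seed (defaults to the config seed).
#' @return list with `pairs` (data.frame snp, bx, se_x, by, se_y), `theta`,
#'   and the drawn `delta`.
#' @export
simulate_summary_pairs <- function(config, n_exposure = 339224,
                                   n_outcome = 340786, seed = config$seed) {
  params <- calibrate_effects(config)
  f <- params$freq
  hwe <- 2 * f * (1 - f)
  c <- config$case_fraction
  se_x <- 1 / sqrt(n_exposure * hwe)
  se_y <- 1 / sqrt(n_outcome * hwe * c * (1 - c))
  set.seed(derive_seed(seed, "summary-pairs"))
  bx <- stats::rnorm(length(f), params$alpha, se_x)
  by <- stats::rnorm(length(f),
                     config$causal_effect * params$alpha + params$delta, se_y)
  list(pairs = data.frame(snp = params$variant_ids, bx = bx, se_x = se_x,
                          by = by, se_y = se_y, stringsAsFactors = FALSE),
       theta = config$causal_effect, delta = params$delta)
}

#' Write / read a cohort as tab-separated text
#'
#' The flat interchange format: one row per sample, phenotype columns first,
#' genotype dosage columns named by variant ID, missing values encoded `NA`.
#'
#' @param cohort an `mr_cohort`.
#' @param path output path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   list with `samples` and `genotypes`.
#' @export
write_cohort <- function(cohort, path) {
  flat <- cbind(cohort$samples, as.data.frame(cohort$genotypes))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @param variant_ids genotype column names; defaults to columns matching
#'   `^rs`.
#' @export
read_cohort <- function(path, variant_ids = NULL) {
  flat <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(variant_ids)) {
    variant_ids <- grep("^rs", names(flat), value = TRUE)
  }
  g <- as.matrix(flat[, variant_ids, drop = FALSE])
  list(samples = flat[, setdiff(names(flat), variant_ids), drop = FALSE],
       genotypes = g)
}
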