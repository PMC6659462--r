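# Shared fixtures: small simulated cohorts built once per test run.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_samples = 5000L, seed = 7L), list(...))
  do.call(sim_config, args)
}

# memoised medium cohort used by several files
cohort_cache <- new.env()
get_cohort <- function(key = "default", ...) {
  if (is.null(cohort_cache[[key]])) {
    cohort_cache[[key]] <- simulate_cohort(small_cfg(...))
  }
  cohort_cache[[key]]
}

# quick summary-pair builder for estimator unit tests
make_pairs <- function(bx, by, se_x = rep(1e-6, length(bx)),
                       se_y = rep(1, length(bx))) {
  data.frame(snp = sprintf("rs%03d", seq_along(bx)),
             bx = bx, se_x = se_x, by = by, se_y = se_y,
             stringsAsFactors = FALSE)
}

# one-sample analysis wrapper used in recovery experiments
run_one_sample <- function(cohort) {
  score <- weighted_grs(cohort$genotypes, true_instruments(cohort))
  iv_two_stage(cohort$samples$outcome, cohort$samples$exposure, score,
               cohort$samples[, "sex", drop = FALSE])
}

# point estimate only (bootstrap SE not needed in recovery loops)
weighted_median_only <- function(pairs) {
  mr_weighted_median(pairs, bootstrap_reps = 20, seed = 1)$estimate
}

cohort_pairs <- function(cohort) {
  harmonize(cohort_to_summary_stats(cohort, "exposure"),
            cohort_to_summary_stats(cohort, "outcome"))
}
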