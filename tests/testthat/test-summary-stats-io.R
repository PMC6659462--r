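write_stats_file <- function(d, path) {
  names(d)[names(d) == "snp"] <- "SNP"
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

demo_records <- function() {
  data.frame(
    snp = paste0("rs", 1:5),
    effect_allele = c("A", "C", "G", "A", "T"),
    other_allele = c("G", "T", "A", "T", "C"),
    eaf = c(0.2, 0.35, 0.6, 0.45, 0.8),
    beta = c(0.02, -0.01, 0.05, 0.03, -0.04),
    se = c(0.01, 0.012, 0.02, 0.015, 0.011),
    pval = c(0.04, 0.4, 0.01, 0.05, 2e-4),
    n = rep(1000, 5), stringsAsFactors = FALSE)
}

test_that("summary-stat reading validates records and round-trips", {
  d <- demo_records()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stats_file(d, path)
  rec <- read_summary_stats(path)
  expect_equal(nrow(rec), 5)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(rec, out)
  again <- read_summary_stats(out)
  expect_equal(again, rec, ignore_attr = TRUE)

  # invalid rows rejected with reasons and line numbers
  bad <- d
  bad$se[2] <- 0
  bad$eaf[4] <- 1.2
  write_stats_file(bad, path)
  rec2 <- read_summary_stats(path, max_bad_fraction = 0.5)
  rej <- attr(rec2, "rejected")
  expect_equal(nrow(rec2), 3)
  expect_true("nonpositive SE" %in% rej$reason)
  expect_equal(rej$line[rej$reason == "nonpositive SE"], 3L)

  # file-level failure above the tolerated bad fraction
  expect_error(read_summary_stats(path, max_bad_fraction = 0.1), "invalid")

  # missing required column
  d2 <- d[, setdiff(names(d), "se")]
  write_stats_file(d2, path)
  expect_error(read_summary_stats(path), "missing required column")

  expect_error(read_summary_stats("/nonexistent/file.tsv"), "not found")
})

test_that("harmonization aligns alleles, flags palindromes, drops mismatches", {
  exp <- data.frame(
    snp = paste0("rs", 1:6),
    effect_allele = c("A", "A", "A", "A", "A", "A"),
    other_allele = c("G", "G", "G", "T", "T", "G"),
    eaf = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3),
    beta = rep(0.1, 6), se = rep(0.01, 6), pval = rep(1e-5, 6),
    n = rep(1e5, 6), stringsAsFactors = FALSE)
  out <- data.frame(
    snp = paste0("rs", 1:6),
    effect_allele = c("A", "G", "T", "A", "T", "A"),
    other_allele = c("G", "A", "C", "T", "A", "C"),
    eaf = c(0.3, 0.7, 0.3, 0.49, 0.3, 0.3),
    beta = c(0.02, 0.02, 0.02, 0.02, 0.02, 0.02),
    se = rep(0.01, 6), pval = rep(0.04, 6), n = rep(1e5, 6),
    stringsAsFactors = FALSE)

  pairs <- harmonize(exp, out, palindrome_eaf_window = 0.08)

  # rs1: identical alleles
  expect_equal(pairs$flag[pairs$snp == "rs1"], "unchanged")
  expect_equal(pairs$by[pairs$snp == "rs1"], 0.02)
  # rs2: EA/OA swapped -> negated beta, complemented frequency
  expect_equal(pairs$flag[pairs$snp == "rs2"], "allele_swap")
  expect_equal(pairs$by[pairs$snp == "rs2"], -0.02)
  expect_equal(pairs$eaf_outcome[pairs$snp == "rs2"], 0.3)
  # rs3: strand complement (T/C vs A/G) -> relabel only
  expect_equal(pairs$flag[pairs$snp == "rs3"], "strand_flip")
  expect_equal(pairs$by[pairs$snp == "rs3"], 0.02)
  # rs4: A/T palindrome with outcome eaf near 0.5 -> dropped
  expect_equal(pairs$flag[pairs$snp == "rs4"], "dropped_palindromic")
  expect_false(pairs$keep[pairs$snp == "rs4"])
  # rs5: A/T palindrome, frequencies agree after label swap -> usable
  expect_true(pairs$keep[pairs$snp == "rs5"])
  # rs6: A/C vs A/G cannot be reconciled
  expect_false("rs6" %in% pairs$snp)
  expect_equal(attr(pairs, "dropped")$snp, "rs6")
})

test_that("harmonization is involutive and sign conventions cancel downstream", {
  co <- simulate_cohort(small_cfg(n_samples = 3000L, seed = 23,
                                  palindromic_fraction = 0.2))
  ex <- cohort_to_summary_stats(co, "exposure")
  ou <- cohort_to_summary_stats(co, "outcome")
  # scramble outcome orientation for half the variants
  flip <- seq(1, nrow(ou), by = 2)
  tmp <- ou$effect_allele[flip]
  ou$effect_allele[flip] <- ou$other_allele[flip]
  ou$other_allele[flip] <- tmp
  ou$beta[flip] <- -ou$beta[flip]
  ou$eaf[flip] <- 1 - ou$eaf[flip]

  pairs <- harmonize(ex, ou)
  # restoring the outcome table from the harmonized pairs and re-harmonizing
  # changes nothing
  ou2 <- data.frame(snp = pairs$snp, effect_allele = pairs$effect_allele,
                    other_allele = pairs$other_allele, eaf = pairs$eaf_outcome,
                    beta = pairs$by, se = pairs$se_y, pval = 0.5,
                    n = 3000, stringsAsFactors = FALSE)
  pairs2 <- harmonize(ex[ex$snp %in% ou2$snp, ], ou2)
  expect_equal(pairs2$by, pairs$by)
  expect_equal(pairs2$bx, pairs$bx)

  # flipping the orientation never changes the kept harmonized effect pairs
  straight <- harmonize(ex, cohort_to_summary_stats(co, "outcome"))
  kept <- straight$snp[straight$keep]
  expect_equal(pairs$by[match(kept, pairs$snp)],
               straight$by[match(kept, straight$snp)])

  # negating all exposure betas and swapping exposure allele labels leaves
  # causal estimates unchanged
  ex_neg <- ex
  tmp <- ex_neg$effect_allele
  ex_neg$effect_allele <- ex_neg$other_allele
  ex_neg$other_allele <- tmp
  ex_neg$beta <- -ex_neg$beta
  ex_neg$eaf <- 1 - ex_neg$eaf
  p1 <- harmonize(ex, cohort_to_summary_stats(co, "outcome"))
  p2 <- harmonize(ex_neg, cohort_to_summary_stats(co, "outcome"))
  expect_equal(mr_ivw(p2)$estimate, mr_ivw(p1)$estimate, tolerance = 1e-12)
  expect_equal(mr_weighted_median(p2, seed = 4)$estimate,
               mr_weighted_median(p1, seed = 4)$estimate, tolerance = 1e-12)

  expect_error(harmonize(ex[0, ], ou), "no shared variant")
})
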