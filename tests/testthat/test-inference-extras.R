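test_that("Wald p from CI inverts the interval arithmetic", {
  # round-trip identity with the direct Wald test
  set.seed(71)
  for (i in 1:20) {
    b <- rnorm(1); se <- runif(1, 0.01, 1)
    expect_equal(wald_p_from_ci(b, b - 1.96 * se, b + 1.96 * se),
                 2 * pnorm(-abs(b) / se), tolerance = 1e-12)
  }
  # symmetric CI around zero gives p = 1
  expect_equal(wald_p_from_ci(0, -0.1, 0.1), 1)
  expect_error(wald_p_from_ci(0.5, 0.9, 0.2), "ci_low")
  expect_error(wald_p_from_ci(1.2, -0.1, 1.5, "log_odds_from_or"), "positive")
})

test_that("Fisher z comparison has the right symmetry and oracle values", {
  a <- list(beta = 1, se = 1); b <- list(beta = 0, se = 1)
  fz <- fisher_z_diff(a, b)
  expect_equal(fz$z, 1 / sqrt(2), tolerance = 1e-10)
  expect_equal(fz$p, 2 * pnorm(-1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(round(fz$z, 4), 0.7071)
  expect_equal(round(fz$p, 4), 0.4795)

  # antisymmetric in z, symmetric in p
  rev <- fisher_z_diff(b, a)
  expect_equal(rev$z, -fz$z)
  expect_equal(rev$p, fz$p)

  same <- fisher_z_diff(a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  expect_error(fisher_z_diff(list(beta = 1, se = 0), b), "positive")
})

test_that("fixed-effect meta-analysis matches hand and metafor oracles", {
  e <- function(b, s) list(beta = b, se = s)
  twin <- meta_fixed(list(e(0.2, 0.1), e(0.2, 0.1)))
  expect_equal(twin$estimate, 0.2)
  expect_equal(twin$se, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(twin$Q, 0)

  m <- meta_fixed(list(e(0.1, 0.1), e(0.3, 0.2)))
  expect_equal(m$estimate, 0.14, tolerance = 1e-12)
  expect_equal(m$se, sqrt(1 / 125), tolerance = 1e-12)
  expect_equal(m$Q, 0.8, tolerance = 1e-12)
  expect_equal(m$Q_p, pchisq(0.8, 1, lower.tail = FALSE), tolerance = 1e-12)

  single <- meta_fixed(list(e(0.31, 0.07)))
  expect_equal(single$estimate, 0.31)
  expect_equal(single$se, 0.07)

  # k copies: SE shrinks by exactly sqrt(k)
  k <- 7
  many <- meta_fixed(rep(list(e(0.12, 0.05)), k))
  expect_equal(many$se, 0.05 / sqrt(k), tolerance = 1e-14)

  # independent implementation: metafor fixed-effect fit
  set.seed(73)
  bs <- rnorm(6, 0.2, 0.1); ses <- runif(6, 0.05, 0.2)
  own <- meta_fixed(Map(e, bs, ses))
  ref <- metafor::rma(yi = bs, sei = ses, method = "FE")
  expect_equal(own$estimate, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(own$se, ref$se, tolerance = 1e-8)
  expect_equal(own$Q, ref$QE, tolerance = 1e-8)

  expect_error(meta_fixed(list()), "empty")
})

test_that("over-identification test contrasts instrument subsets", {
  set.seed(75)
  clean <- make_pairs(bx = runif(30, 0.02, 0.06),
                      by = 0.2 * runif(30, 0.02, 0.06), se_y = rep(0.008, 30))
  clean$by <- 0.2 * clean$bx + rnorm(30, 0, 0.008)
  dirty <- make_pairs(bx = runif(30, 0.02, 0.06), by = NA, se_y = rep(0.008, 30))
  dirty$snp <- paste0("rsb", 1:30)
  dirty$by <- 0.2 * dirty$bx + 0.03 + rnorm(30, 0, 0.008)  # directional shift

  ov <- overidentification_test(clean, dirty)
  expect_lt(ov$p_difference, 0.05)
  expect_gt(ov$estimate_b$estimate, ov$estimate_a$estimate)

  # identical estimates give p = 1
  same <- overidentification_test(clean, within(clean, snp <- paste0("x", snp)))
  expect_equal(same$p_difference, 1)

  expect_error(overidentification_test(clean, clean), "overlap")
})

test_that("pleiotropy screen converts odds ratios to SD units before comparing", {
  p1 <- make_pairs(bx = 0.05, by = 0.3, se_y = 0.01)
  sc <- pleiotropy_screen(rbind(p1), case_fraction = 0.125)
  expect_equal(sc$by_sd, 0.3 * sqrt(0.125 * 0.875), tolerance = 1e-12)
  expect_true(sc$flagged)

  p2 <- make_pairs(bx = 0.15, by = 0.3, se_y = 0.01)
  expect_false(pleiotropy_screen(p2, 0.125)$flagged)

  p3 <- make_pairs(bx = 0.05, by = 0, se_y = 0.01)
  expect_false(pleiotropy_screen(p3, 0.125)$flagged)

  expect_error(pleiotropy_screen(p1, 1.2), "case_fraction")
})

test_that("negative-control battery reports paired observational/IV rows", {
  co <- get_cohort()
  score <- weighted_grs(co$genotypes, true_instruments(co))
  tab <- negative_control_battery(co, score = score)
  expect_equal(nrow(tab), 3 * 2 * 2)  # trait x adjusted x analysis
  expect_setequal(unique(tab$analysis), c("observational", "genetic"))

  # pure-noise control: no analysis finds an association at alpha = 0.001
  noise <- tab[tab$trait == "control_noise", ]
  expect_true(all(noise$p > 0.001))

  # confounder-driven control with a valid instrument: the observational
  # association is strong, the genetic one is not
  cc <- tab[tab$trait == "control_cont" & !tab$adjusted, ]
  expect_lt(cc$p[cc$analysis == "observational"], 1e-6)
  expect_gt(cc$p[cc$analysis == "genetic"], 0.001)

  expect_error(negative_control_battery(co, controls = "missing_trait",
                                        score = score), "not present")
})

test_that("stratum p-values are uniform under the sex-homogeneous null", {
  # Fisher z across sexes under a null causal effect: p approximately uniform
  ps <- vapply(1:40, function(r) {
    co <- simulate_cohort(sim_config(n_samples = 4000L, causal_effect = 0,
                                     seed = 8000 + r))
    s <- weighted_grs(co$genotypes, true_instruments(co))
    res <- sexstratified_run(co, s)
    fisher_z_diff(res[[1]]$tsls, res[[2]]$tsls)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
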