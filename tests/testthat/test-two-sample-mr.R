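test_that("Wald ratio follows the delta-method formula", {
  p <- make_pairs(bx = 0.1, by = 0.05, se_y = 0.01)
  est <- wald_ratio(p)
  expect_equal(est$estimate, 0.5)
  expect_equal(est$se, 0.1)

  expect_equal(wald_ratio(make_pairs(0.1, 0, se_y = 0.01))$estimate, 0)

  neg <- wald_ratio(make_pairs(-0.1, -0.05, se_y = 0.01))
  expect_equal(neg$estimate, 0.5)
  expect_equal(neg$se, 0.1)

  expect_error(wald_ratio(make_pairs(0, 0.05)), "bx = 0")
})

test_that("IVW matches its closed-form normal equations", {
  # exact proportionality: slope recovered, zero heterogeneity
  col <- make_pairs(bx = c(0.1, 0.2, 0.4), by = c(0.05, 0.10, 0.20),
                    se_y = rep(0.03, 3))
  est <- mr_ivw(col)
  expect_equal(est$estimate, 0.5, tolerance = 1e-12)
  expect_equal(est$Q, 0, tolerance = 1e-20)

  # frozen hand-computed example
  two <- make_pairs(bx = c(0.1, 0.2), by = c(0.08, 0.12),
                    se_y = c(0.05, 0.04))
  est2 <- mr_ivw(two)
  expect_equal(est2$estimate, 18.2 / 29, tolerance = 1e-12)
  expect_equal(est2$se, 1 / sqrt(29), tolerance = 1e-12)
  expect_equal(est2$Q, 0.137931034, tolerance = 1e-8)

  # linearity: negating outcomes negates the estimate, SE unchanged
  neg <- two; neg$by <- -neg$by
  est3 <- mr_ivw(neg)
  expect_equal(est3$estimate, -est2$estimate)
  expect_equal(est3$se, est2$se)

  # random-effects model never shrinks the SE
  set.seed(61)
  noisy <- make_pairs(bx = runif(20, 0.05, 0.3),
                      by = rnorm(20, 0, 0.2), se_y = runif(20, 0.02, 0.1))
  expect_gte(mr_ivw(noisy, "random")$se, mr_ivw(noisy, "fixed")$se)

  expect_error(mr_ivw(two[1, ]), "wald_ratio")

  # closed-form weighted-least-squares oracle on random instances
  set.seed(63)
  for (i in 1:100) {
    k <- sample(3:30, 1)
    d <- make_pairs(bx = runif(k, -0.3, 0.3) + 0.05,
                    by = rnorm(k, 0, 0.1), se_y = runif(k, 0.01, 0.2))
    oracle <- unname(coef(lm(by ~ 0 + bx, data = d, weights = 1 / d$se_y^2)))
    expect_equal(mr_ivw(d)$estimate, oracle, tolerance = 1e-10)
  }
})

test_that("MR-Egger separates slope from directional pleiotropy", {
  # exact affine data: intercept and slope recovered exactly
  ex <- make_pairs(bx = c(0.1, 0.2, 0.3), by = 0.1 + 0.5 * c(0.1, 0.2, 0.3),
                   se_y = rep(0.05, 3))
  eg <- suppressWarnings(mr_egger(ex))  # exact fit: summary.lm warns
  expect_equal(eg$intercept$estimate, 0.1, tolerance = 1e-10)
  expect_equal(eg$slope$estimate, 0.5, tolerance = 1e-10)

  # frozen unweighted least-squares example
  d <- make_pairs(bx = c(0.1, 0.2, 0.3), by = c(0.12, 0.24, 0.30),
                  se_y = rep(1, 3))
  eg2 <- mr_egger(d)
  expect_equal(eg2$slope$estimate, 0.9, tolerance = 1e-10)
  expect_equal(eg2$intercept$estimate, 0.04, tolerance = 1e-10)

  # data through the origin: intercept 0, slope equals IVW
  o <- make_pairs(bx = c(0.1, 0.25, 0.4), by = 0.5 * c(0.1, 0.25, 0.4),
                  se_y = rep(0.04, 3))
  eg3 <- mr_egger(o)
  expect_equal(eg3$intercept$estimate, 0, tolerance = 1e-10)
  expect_equal(eg3$slope$estimate, mr_ivw(o)$estimate, tolerance = 1e-10)

  # orientation rule: joint sign flips of any pair leave the fit unchanged
  set.seed(65)
  r <- make_pairs(bx = runif(10, 0.05, 0.3), by = rnorm(10, 0.1, 0.05),
                  se_y = runif(10, 0.02, 0.08))
  flipped <- r
  flipped$bx[c(2, 5)] <- -flipped$bx[c(2, 5)]
  flipped$by[c(2, 5)] <- -flipped$by[c(2, 5)]
  ega <- mr_egger(r); egb <- mr_egger(flipped)
  expect_equal(egb$slope$estimate, ega$slope$estimate)
  expect_equal(egb$intercept$estimate, ega$intercept$estimate)

  expect_error(mr_egger(d[1:2, ]), ">= 3")
  expect_error(mr_egger(make_pairs(rep(0.2, 4), rnorm(4))), "rank-deficient")
})

test_that("weighted median interpolates standardized cumulative weights", {
  # middle ratio lands exactly on probability 0.5 under equal weights
  eq <- make_pairs(bx = c(1, 1, 1), by = c(0.2, 0.5, 0.9))
  expect_equal(mr_weighted_median(eq, seed = 2)$estimate, 0.5)

  # frozen hand-interpolated example: ratios (.1,.4,.6), weights (1,1,2)
  hw <- make_pairs(bx = c(1, 1, 1), by = c(0.1, 0.4, 0.6),
                   se_y = 1 / sqrt(c(1, 1, 2)))
  expect_equal(mr_weighted_median(hw, seed = 2)$estimate,
               0.4 + 0.2 * (0.125 / 0.375), tolerance = 1e-12)

  # degenerate: identical ratios collapse to that ratio with tiny SE
  cc <- make_pairs(bx = c(0.1, 0.2, 0.4), by = 0.7 * c(0.1, 0.2, 0.4),
                   se_y = rep(0.001, 3), se_x = rep(1e-6, 3))
  wm <- mr_weighted_median(cc, bootstrap_reps = 200, seed = 3)
  expect_equal(wm$estimate, 0.7, tolerance = 1e-9)
  expect_lt(wm$se, 0.05)

  # bootstrap SE is deterministic under a fixed seed
  set.seed(67)
  r <- make_pairs(bx = runif(12, 0.05, 0.3), by = rnorm(12, 0.05, 0.04),
                  se_y = runif(12, 0.02, 0.08), se_x = rep(0.01, 12))
  a <- mr_weighted_median(r, bootstrap_reps = 200, seed = 11)
  b <- mr_weighted_median(r, bootstrap_reps = 200, seed = 11)
  expect_identical(a$se, b$se)

  # penalization leaves homogeneous data essentially unchanged
  pen <- mr_weighted_median(cc, penalized = TRUE, bootstrap_reps = 200,
                            seed = 3)
  expect_equal(pen$estimate, 0.7, tolerance = 1e-9)

  # orientation invariance of the median
  fl <- r
  fl$bx[3] <- -fl$bx[3]; fl$by[3] <- -fl$by[3]
  expect_equal(mr_weighted_median(fl, seed = 5)$estimate,
               mr_weighted_median(r, seed = 5)$estimate)

  expect_error(mr_weighted_median(r[1:2, ]), ">= 3")
})

test_that("the two-sample battery returns one tidy row per estimator", {
  co <- get_cohort()
  tab <- mr_two_sample_battery(cohort_pairs(co), bootstrap_reps = 100,
                               seed = 5)
  expect_setequal(tab$method,
                  c("ivw_fixed", "ivw_random", "egger_slope",
                    "egger_intercept", "weighted_median",
                    "penalized_weighted_median"))
  expect_true(all(tab$se > 0))
  expect_true(all(tab$ci_low <= tab$estimate & tab$estimate <= tab$ci_high))
})
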