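# independent generic WLS oracles used to cross-check the estimators
wls_no_intercept <- function(p) {
  unname(coef(lm(beta_y ~ 0 + beta_x, data = p, weights = 1 / p$se_y^2)))
}
wls_with_intercept <- function(p) {
  unname(coef(lm(beta_y ~ beta_x, data = p, weights = 1 / p$se_y^2)))
}

test_that("IVW reduces to the ratio for one SNP and the weighted mean in general", {
  expect_equal(estimate(mrIVW(make_pairs(0.5, 1))), 2)
  expect_equal(estimate(mrIVW(make_pairs(c(1, 1), c(1, 3)))), 2)
  est <- mrIVW(make_pairs(c(1, 1), c(1, 3), se_y = 0.5))
  expect_equal(stdError(est), 1 / sqrt(sum(c(1, 1) / 0.25)))
  expect_equal(pValue(est),
               2 * pnorm(-abs(estimate(est) / stdError(est))))
  expect_error(mrIVW(make_pairs(numeric(0), numeric(0))), "empty")
  expect_error(mrIVW(make_pairs(c(0, 0), c(1, 1))), "undefined")
})

test_that("IVW and MR-Egger match generic WLS oracles on random instances", {
  set.seed(101)
  for (i in 1:20) {
    p <- sim_summary_instance(J = sample(5:40, 1), theta = rnorm(1),
                              se_y = runif(1, 0.01, 0.2))
    expect_equal(estimate(mrIVW(p)), wls_no_intercept(p), tolerance = 1e-10)
    po <- p
    s <- sign(po$beta_x)
    po$beta_x <- abs(po$beta_x); po$beta_y <- po$beta_y * s
    cf <- wls_with_intercept(po)
    eg <- mrEgger(p)
    expect_equal(eg@intercept, cf[1], tolerance = 1e-10)
    expect_equal(estimate(eg), cf[2], tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers slope and intercept from exact affine data", {
  p <- make_pairs(c(1, 2, 3, 4), 0.5 * c(1, 2, 3, 4))
  eg <- suppressWarnings(mrEgger(p))  # exact fit warns in summary.lm
  expect_equal(estimate(eg), 0.5, tolerance = 1e-12)
  expect_equal(eg@intercept, 0, tolerance = 1e-12)
  p2 <- make_pairs(c(1, 2, 3, 4), 0.5 * c(1, 2, 3, 4) + 0.1)
  expect_equal(suppressWarnings(mrEgger(p2))@intercept, 0.1, tolerance = 1e-12)
  expect_error(mrEgger(make_pairs(c(1, 2), c(1, 2))), "at least 3")
})

test_that("the weighted median interpolates the weighted ratio distribution", {
  p <- make_pairs(c(1, 1, 1), c(1, 2, 3))
  expect_equal(estimate(mrWeightedMedian(p, n_boot = 50, seed = 1)), 2)
  # dominant-weight SNP pulls the median onto itself
  pw <- make_pairs(c(1, 1, 1), c(1, 2, 3), se_y = 1 / sqrt(c(0.98, 0.01, 0.01)))
  est <- estimate(mrWeightedMedian(pw, n_boot = 50, seed = 1))
  expect_equal(est, 1, tolerance = 0.05)
  # equal weights equal the unweighted median of ratios (odd J)
  set.seed(33)
  for (i in 1:10) {
    r <- rnorm(11)
    p <- make_pairs(rep(1, 11), r)
    expect_equal(estimate(mrWeightedMedian(p, n_boot = 10, seed = 1)),
                 median(r))
  }
  expect_error(mrWeightedMedian(make_pairs(1, 1), seed = 1), "at least 3")
  expect_error(mrWeightedMedian(make_pairs(c(1, 1, 1), c(1, 2, 3))),
               "seed")
})

test_that("penalization leaves concordant sets untouched and shrinks outliers", {
  set.seed(55)
  # concordant ratios: penalty inactive, estimates identical
  p <- make_pairs(runif(9, 0.5, 1.5), NA)
  p$beta_y <- p$beta_x * 0.5 + rnorm(9, 0, 0.01)
  wm <- mrWeightedMedian(p, n_boot = 50, seed = 2)
  pwm <- mrPenalizedWeightedMedian(p, n_boot = 50, seed = 2)
  expect_equal(estimate(pwm), estimate(wm))

  # one gross outlier is down-weighted towards the concordant median
  out <- rbind(p, make_pairs(1, 25, rsid = "rs_outlier"))
  wm_all <- estimate(mrWeightedMedian(out, n_boot = 50, seed = 2))
  pwm_all <- estimate(mrPenalizedWeightedMedian(out, n_boot = 50, seed = 2))
  wm_clean <- estimate(mrWeightedMedian(p, n_boot = 50, seed = 2))
  expect_lt(abs(pwm_all - wm_clean), abs(wm_all - wm_clean) + 1e-9)
  expect_lt(abs(pwm_all - wm_clean), 0.1)

  # penalty_scale -> 0 leaves the estimate to the most concordant SNPs
  ps <- estimate(mrPenalizedWeightedMedian(out, n_boot = 10, seed = 2,
                                           penalty_scale = 1e-8))
  expect_lt(abs(ps - wm_clean), 0.2)
})

test_that("estimators are invariant to allele re-orientation of any SNP subset", {
  set.seed(77)
  p <- sim_summary_instance(15, theta = -0.4)
  flip <- sample(c(1, -1), 15, replace = TRUE)
  pf <- p
  pf$beta_x <- p$beta_x * flip
  pf$beta_y <- p$beta_y * flip
  expect_equal(estimate(mrIVW(pf)), estimate(mrIVW(p)), tolerance = 1e-12)
  expect_equal(estimate(mrEgger(pf)), estimate(mrEgger(p)), tolerance = 1e-12)
  expect_equal(estimate(mrWeightedMedian(pf, 50, seed = 3)),
               estimate(mrWeightedMedian(p, 50, seed = 3)), tolerance = 1e-12)
  expect_equal(estimate(mrPenalizedWeightedMedian(pf, 50, seed = 3)),
               estimate(mrPenalizedWeightedMedian(p, 50, seed = 3)),
               tolerance = 1e-12)
})

test_that("leave-one-out exposes influential instruments", {
  p2 <- make_pairs(c(1, 2), c(2, 6))
  loo <- mrLeaveOneOut(p2)
  expect_equal(loo$beta, c(3, 2))  # each fold is the surviving ratio
  expect_error(mrLeaveOneOut(make_pairs(1, 1)), "at least 2")

  set.seed(9)
  p <- sim_summary_instance(12, theta = 0.5, se_y = 0.02)
  # homogeneous instruments: every fold inside every other fold's CI
  loo <- mrLeaveOneOut(p)
  expect_true(all(loo$beta >= min(loo$ci_low) & loo$beta <= max(loo$ci_high)))

  out <- rbind(p, make_pairs(0.15, 0.4, se_y = 0.02, rsid = "rs_outlier"))
  loo2 <- mrLeaveOneOut(out)
  shifts <- abs(loo2$beta - estimate(mrIVW(out)))
  expect_equal(loo2$omitted[which.max(shifts)], "rs_outlier")
  expect_gt(max(shifts), 3 * sort(shifts, decreasing = TRUE)[2])
})

test_that("exclusion re-estimation honours the complement", {
  set.seed(14)
  p <- sim_summary_instance(10, theta = 0.2)
  expect_equal(estimate(mrExclude(p, character(0))), estimate(mrIVW(p)))
  keep_one <- mrExclude(p, p$rsid[-3])
  expect_equal(estimate(keep_one), p$beta_y[3] / p$beta_x[3])
  expect_message(mrExclude(p, c(p$rsid[1], "rs_not_there")), "not in the")
  expect_error(mrExclude(p, p$rsid), "every instrument")
})

test_that("2SLS recovers exact effects and flags weak instruments", {
  set.seed(6)
  z <- rnorm(200)
  x <- z + rnorm(200)
  expect_equal(estimate(tsls(x, 2 * x, z)), 2, tolerance = 1e-12)
  expect_error(tsls(rnorm(50), rnorm(50), rep(1, 50)), "weak instrument")
  # first-stage F matches the squared first-stage t statistic
  y <- x + rnorm(200)
  iv <- tsls(x, y, z)
  f1 <- summary(lm(x ~ z))$coefficients["z", "t value"]^2
  expect_equal(iv@f_first_stage, f1, tolerance = 1e-10)
})

test_that("SD-unit conversion and the mediation product behave as arithmetic", {
  expect_equal(sdUnits(0, 24.23), 0)
  expect_equal(sdUnits(24.23, 24.23), 1)
  expect_error(sdUnits(1, 0), "sd_outcome")

  expect_equal(estimate(mediationExpectation(0, b = 123)), 0)
  m <- mediationExpectation(2, 3)
  expect_equal(estimate(m), 6)
  expect_equal(stdError(m), 0)
  m2 <- mediationExpectation(a = 0.5, b = -2, se_a = 0.1, se_b = 0.2)
  expect_equal(stdError(m2), sqrt(0.5^2 * 0.2^2 + 2^2 * 0.1^2))
})
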