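test_that("variance explained follows beta^2 2p(1-p)/var_y", {
  expect_equal(varianceExplained(1, 0.5, 1.767), 0.5 / 1.767)
  expect_equal(varianceExplained(0, 0.3, 1.767), 0)
  expect_equal(varianceExplained(c(0.2, -0.2), c(0.1, 0.9), 2),
               rep(0.2^2 * 2 * 0.1 * 0.9 / 2, 2))
  # invariant under allele relabelling
  b <- rnorm(10); p <- runif(10, 0.05, 0.95)
  expect_equal(varianceExplained(b, p, 1.767),
               varianceExplained(-b, 1 - p, 1.767))
  expect_error(varianceExplained(1, 0, 1.767), "degenerate")
  expect_error(varianceExplained(1, 0.5, -1), "var_y")
})

test_that("the genetic score is the weighted dosage sum, standardized", {
  G <- matrix(c(0, 1, 2,
                2, 1, 0,
                1, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("rs1", "rs2", "rs3"), NULL))
  gs <- buildScore(G, c(1, 1, 1))
  expect_equal(rawScore(gs), c(3, 3, 3))
  # degenerate: zero variance gives NaN standardization, flagged by scale()
  gs2 <- buildScore(G, c(1, 2, 0.5))
  expect_equal(rawScore(gs2), as.numeric(crossprod(G, c(1, 2, 0.5))))
  expect_equal(mean(standardizedScore(gs2)), 0, tolerance = 1e-12)
  expect_equal(sd(standardizedScore(gs2)), 1, tolerance = 1e-12)
})

test_that("missing dosages are mean-imputed and all-missing SNPs excluded", {
  G <- matrix(c(0, NA, 2, 1,
                NA, NA, NA, NA,
                1, 1, 0, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("rs1", "rs2", "rs3"), NULL))
  expect_warning(gs <- buildScore(G, c(1, 5, 1)), "rs2")
  expect_equal(gs@excluded, "rs2")
  # rs1 mean dosage 1 imputed into position 2
  expect_equal(rawScore(gs), c(0 + 1, 1 + 1, 2 + 0, 1 + 2))
})

test_that("regressing the simulated exposure on the standardized score recovers sqrt(r2)", {
  co <- simulateDuos(duoSimConfig(n_snps = 60, n_duos = 15000,
                                  confounder_on_exposure = 0, seed = 8))
  gs <- buildScore(maternalGenotypes(co),
                   SummarizedExperiment::rowData(co)$w_exposure)
  slope <- coef(lm(phenotypes(co)$urate_sd ~ standardizedScore(gs)))[2]
  # per 1 SD of GS the exposure (variance 1) moves by sqrt(target r2)
  expect_equal(unname(slope), sqrt(0.064), tolerance = 0.05 * 4)
})

test_that("per-SNP F statistics and their mean follow (beta/se)^2", {
  p <- make_pairs(beta_x = c(0.5, 0.5), beta_y = c(0, 0),
                  se_x = c(0.05, 0.5 / sqrt(150)))
  fs <- fStatistics(p)
  expect_equal(unname(fs$f[1]), 100)
  expect_equal(fs$mean_f, mean(c(100, 150)))
  expect_error(fStatistics(make_pairs(numeric(0), numeric(0))), "empty")
})

test_that("mean F grows with GWAS sample size as 1 + n r2/(1-r2)", {
  pred_mean_f <- function(co, n) {
    r2 <- SummarizedExperiment::rowData(co)$w_exposure^2 * 2 *
      SummarizedExperiment::rowData(co)$maf *
      (1 - SummarizedExperiment::rowData(co)$maf)
    mean(1 + n * r2 / (1 - r2))
  }
  obs_mean_f <- function(n, seed) {
    co <- simulateDuos(duoSimConfig(n_snps = 114, n_duos = n, seed = seed))
    ss <- cohortSummaryStats(co)
    rec <- snpRecords(ss$exposure)
    p <- make_pairs(rec$beta, rec$beta * 0, se_x = rec$se)
    c(obs = fStatistics(p)$mean_f, pred = pred_mean_f(co, n))
  }
  a <- obs_mean_f(3000, seed = 41)
  b <- obs_mean_f(12000, seed = 42)
  expect_equal(unname(a["obs"]), unname(a["pred"]), tolerance = 0.2)
  expect_equal(unname(b["obs"]), unname(b["pred"]), tolerance = 0.2)
  # fourfold sample size roughly quadruples the excess over 1
  expect_equal((b["obs"] - 1) / (a["obs"] - 1), 4, tolerance = 0.3,
               ignore_attr = TRUE)
})

test_that("Cochran's Q measures heterogeneity about the IVW fit", {
  # exact line -> Q = 0
  p <- make_pairs(c(1, 2, 3), c(0.5, 1, 1.5), se_y = 0.1)
  expect_equal(cochranQ(p, 0.5)$q, 0)
  # arithmetic: residual/se of (1, 2) -> Q = 1 + 4 = 5 on 1 df
  p2 <- make_pairs(c(1, 1), c(1, 2), se_y = 1)
  q2 <- cochranQ(p2, 0)
  expect_equal(q2$q, 5)
  expect_equal(q2$df, 1)
  expect_equal(q2$pval, pchisq(5, 1, lower.tail = FALSE))
  expect_error(cochranQ(make_pairs(1, 1), 1), "at least 2")
  # invariant under simultaneous sign flips
  set.seed(2)
  p3 <- sim_summary_instance(20, theta = 0.3)
  flip <- sample(c(1, -1), 20, replace = TRUE)
  p4 <- p3; p4$beta_x <- p3$beta_x * flip; p4$beta_y <- p3$beta_y * flip
  b <- estimate(mrIVW(p3))
  expect_equal(cochranQ(p4, b)$q, cochranQ(p3, b)$q)
})

test_that("Bonferroni threshold is alpha/m", {
  expect_equal(signif(bonferroniThreshold(0.05, 114), 2), 4.4e-4)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.05, 5), 0.01)
  expect_error(bonferroniThreshold(1.5, 10), "alpha")
  expect_error(bonferroniThreshold(0.05, 0), "m must")
})

test_that("combined diagnostics aggregate r2, F and Q coherently", {
  set.seed(4)
  p <- sim_summary_instance(30, theta = 0.2)
  p$eaf <- runif(30, 0.1, 0.9)
  d <- instrumentDiagnostics(p, var_y = 1)
  expect_equal(totalR2(d), sum(varianceExplained(p$beta_x, p$eaf, 1)))
  expect_equal(meanF(d), fStatistics(p)$mean_f)
  expect_equal(unname(cochranQValue(d)["Q"]),
               cochranQ(p, estimate(mrIVW(p)))$q)
  expect_equal(unname(cochranQValue(d)["df"]), 29)
})
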