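mr_estimate <- function(method, beta, se, pval, n_snps, units = "outcome per SD exposure",
                        reference = "normal", ci_mult = 1.96,
                        intercept = NA_real_, intercept_se = NA_real_,
                        intercept_ci = c(NA_real_, NA_real_),
                        intercept_pval = NA_real_,
                        n_boot = NA_real_, boot_seed = NA_real_,
                        n = NA_real_) {
  new("MrEstimate", method = method, beta = beta, se = se,
      ci_low = beta - ci_mult * se, ci_high = beta + ci_mult * se,
      pval = pval, n = n, units = units, n_snps = n_snps,
      intercept = intercept, intercept_se = intercept_se,
      intercept_ci_low = intercept_ci[1], intercept_ci_high = intercept_ci[2],
      intercept_pval = intercept_pval, reference = reference,
      n_boot = n_boot, boot_seed = boot_seed)
}

#' Inverse-variance weighted (fixed-effects) MR estimate
#'
#' Zero-intercept weighted regression of outcome betas on exposure betas
#' with first-order weights w_j = 1/se_y_j^2:
#' beta = sum(w bx by) / sum(w bx^2), se = (sum(w bx^2))^(-1/2), two-sided
#' normal p. With a single SNP this reduces to the ratio estimate by/bx.
#'
#' @param pairs a [HarmonizedPairs] or a data.frame with `beta_x`, `se_x`,
#'   `beta_y`, `se_y` (and optionally `rsid`).
#' @return An [MrEstimate].
#' @export
mrIVW <- function(pairs) {
  p <- as_pairs_df(pairs)
  if (!nrow(p)) stop("empty instrument set")
  if (all(p$beta_x == 0)) stop("all exposure betas are zero: estimate undefined")
  w <- 1 / p$se_y^2
  denom <- sum(w * p$beta_x^2)
  beta <- sum(w * p$beta_x * p$beta_y) / denom
  se <- 1 / sqrt(denom)
  pval <- 2 * pnorm(-abs(beta / se))
  mr_estimate("IVW (fixed effects)", beta, se, pval, n_snps = nrow(p))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept (weights 1/se_y^2). The slope is the pleiotropy-corrected
#' causal estimate under InSIDE; a non-null intercept is evidence that the
#' IVW estimate is biased by unbalanced horizontal pleiotropy. Instruments
#' are first oriented so all exposure betas are non-negative (outcome betas
#' flipped in tandem); SNPs with `beta_x == 0` are excluded with a warning.
#' Inference uses a t reference with J - 2 df and a residual dispersion
#' factor bounded below at 1.
#'
#' @param pairs a [HarmonizedPairs] or pairs data.frame; needs >= 3 SNPs.
#' @return An [MrEstimate] with intercept slots filled.
#' @export
mrEgger <- function(pairs) {
  p <- as_pairs_df(pairs)
  zero <- p$beta_x == 0
  if (any(zero)) {
    warning(sum(zero), " SNP(s) with beta_x = 0 excluded from MR-Egger")
    p <- p[!zero, , drop = FALSE]
  }
  if (nrow(p) < 3) stop("MR-Egger needs at least 3 SNPs")
  s <- sign(p$beta_x)
  bx <- abs(p$beta_x)
  by <- p$beta_y * s
  w <- 1 / p$se_y^2

  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  disp <- max(sm$sigma, 1)          # multiplicative dispersion, floored at 1
  cf <- coef(sm)
  se_slope <- cf["bx", "Std. Error"] / sm$sigma * disp
  se_int <- cf["(Intercept)", "Std. Error"] / sm$sigma * disp
  df <- nrow(p) - 2
  tq <- qt(0.975, df)
  slope <- cf["bx", "Estimate"]
  inter <- cf["(Intercept)", "Estimate"]
  mr_estimate("MR-Egger", slope, se_slope,
              pval = 2 * pt(-abs(slope / se_slope), df),
              n_snps = nrow(p), reference = "t", ci_mult = tq,
              intercept = inter, intercept_se = se_int,
              intercept_ci = inter + c(-1, 1) * tq * se_int,
              intercept_pval = 2 * pt(-abs(inter / se_int), df))
}

# weighted median of ratio estimates by interpolation of the weighted ECDF
weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  cum <- cumsum(w) - w / 2
  if (0.5 <= cum[1]) return(r[1])
  if (0.5 >= cum[length(cum)]) return(r[length(r)])
  approx(cum, r, xout = 0.5, ties = "ordered")$y
}

wm_ratios <- function(pairs, caller) {
  p <- as_pairs_df(pairs)
  zero <- p$beta_x == 0
  if (any(zero)) {
    warning(sum(zero), " SNP(s) with beta_x = 0 excluded from ", caller)
    p <- p[!zero, , drop = FALSE]
  }
  if (nrow(p) < 3) stop(caller, " needs at least 3 SNPs")
  p
}

wm_boot_se <- function(p, n_boot, seed, point_fun) {
  with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(nrow(p), p$beta_x, p$se_x)
      by <- rnorm(nrow(p), p$beta_y, p$se_y)
      point_fun(by / bx, bx^2 / p$se_y^2)
    }, numeric(1))
    sd(est)
  })
}

#' Weighted median MR estimate
#'
#' Weighted median of the per-SNP ratio estimates r_j = beta_y_j/beta_x_j
#' with first-order inverse-ratio-variance weights w_j = beta_x_j^2 /
#' se_y_j^2, consistent when at least half of the instrument weight comes
#' from valid instruments. The SE is a parametric bootstrap: exposure and
#' outcome betas are resampled from normal(beta, se) and the median
#' recomputed, with a mandatory explicit seed.
#'
#' @param pairs a [HarmonizedPairs] or pairs data.frame; needs >= 3 usable
#'   SNPs (SNPs with `beta_x == 0` are excluded with a warning).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return An [MrEstimate].
#' @export
mrWeightedMedian <- function(pairs, n_boot = 1000, seed) {
  if (missing(seed)) stop("an explicit bootstrap seed is required")
  p <- wm_ratios(pairs, "weighted median")
  w <- p$beta_x^2 / p$se_y^2
  beta <- weighted_median_point(p$beta_y / p$beta_x, w)
  se <- wm_boot_se(p, n_boot, seed, weighted_median_point)
  mr_estimate("Weighted median", beta, se,
              pval = 2 * pnorm(-abs(beta / se)), n_snps = nrow(p),
              n_boot = n_boot, boot_seed = seed)
}

penalized_point <- function(r, w, penalty_scale) {
  b0 <- weighted_median_point(r, w)
  qj <- w * (r - b0)^2
  pj <- pchisq(qj, df = 1, lower.tail = FALSE)
  weighted_median_point(r, w * pmin(1, penalty_scale * pj))
}

#' Penalized weighted median MR estimate
#'
#' Weighted median with outlier down-weighting: each SNP's heterogeneity
#' contribution Q_j = w_j (r_j - beta_WM)^2 is referred to a one-df
#' chi-square, and the weight is multiplied by min(1, penalty_scale * p_j),
#' shrinking the influence of SNPs whose ratio sits far from the bulk. With
#' no outliers (all p_j large) it equals the plain weighted median exactly.
#'
#' @inheritParams mrWeightedMedian
#' @param penalty_scale multiplier on the heterogeneity p-value before
#'   capping at 1 (default 20, the published convention).
#' @return An [MrEstimate].
#' @export
mrPenalizedWeightedMedian <- function(pairs, n_boot = 1000, seed,
                                      penalty_scale = 20) {
  if (missing(seed)) stop("an explicit bootstrap seed is required")
  p <- wm_ratios(pairs, "penalized weighted median")
  w <- p$beta_x^2 / p$se_y^2
  beta <- penalized_point(p$beta_y / p$beta_x, w, penalty_scale)
  se <- wm_boot_se(p, n_boot, seed,
                   function(r, w) penalized_point(r, w, penalty_scale))
  mr_estimate("Penalized weighted median", beta, se,
              pval = 2 * pnorm(-abs(beta / se)), n_snps = nrow(p),
              n_boot = n_boot, boot_seed = seed)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-runs an estimator J times, omitting one SNP each time; a single fold
#' that shifts materially flags an influential instrument.
#'
#' @param pairs a [HarmonizedPairs] or pairs data.frame with >= 2 SNPs.
#' @param estimator an estimator taking a pairs data.frame (default
#'   [mrIVW]).
#' @param ... passed to `estimator`.
#' @return `data.frame` with one row per omitted rsid: `omitted`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `pval`.
#' @export
mrLeaveOneOut <- function(pairs, estimator = mrIVW, ...) {
  p <- as_pairs_df(pairs)
  if (nrow(p) < 2) stop("leave-one-out needs at least 2 SNPs")
  res <- lapply(seq_len(nrow(p)), function(j) {
    est <- estimator(p[-j, , drop = FALSE], ...)
    data.frame(omitted = p$rsid[j], beta = estimate(est), se = stdError(est),
               ci_low = ci95(est)[["low"]], ci_high = ci95(est)[["high"]],
               pval = pValue(est), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Re-estimate after excluding a SNP set
#'
#' Applies an estimator to the instruments remaining after removing an
#' exclusion set (e.g. SNPs flagged as associated with a candidate
#' pleiotropic trait). Exclusion rsids not in the instrument set are
#' reported and ignored.
#'
#' @param pairs a [HarmonizedPairs] or pairs data.frame.
#' @param exclude character vector of rsids to drop.
#' @param estimator estimator function (default [mrIVW]).
#' @param ... passed to `estimator`.
#' @return The estimator's result on the complement.
#' @export
mrExclude <- function(pairs, exclude, estimator = mrIVW, ...) {
  p <- as_pairs_df(pairs)
  unknown <- setdiff(exclude, p$rsid)
  if (length(unknown))
    message("ignoring ", length(unknown),
            " exclusion rsid(s) not in the instrument set")
  keep <- !(p$rsid %in% exclude)
  if (!any(keep)) stop("exclusion removes every instrument")
  estimator(p[keep, , drop = FALSE], ...)
}

#' One-sample MR by two-stage least squares
#'
#' Stage 1 regresses the exposure on the (typically standardized genetic
#' score) instrument; stage 2 regresses the outcome on the stage-1 fitted
#' values. The SE uses the standard IV variance with stage-2 residuals
#' formed against the observed (not fitted) exposure. The first-stage F
#' statistic is reported; an instrument with no first-stage association is
#' an error.
#'
#' @param exposure,outcome,instrument aligned per-individual numeric
#'   vectors, n >= 3.
#' @param units label for the reported effect.
#' @return A [TslsEstimate].
#' @export
tsls <- function(exposure, outcome, instrument,
                 units = "outcome per unit exposure") {
  n <- length(exposure)
  stopifnot(length(outcome) == n, length(instrument) == n, n >= 3)
  zc <- instrument - mean(instrument)
  xc <- exposure - mean(exposure)
  yc <- outcome - mean(outcome)
  szx <- sum(zc * xc)
  szz <- sum(zc^2)
  if (szz == 0 || abs(szx) < .Machine$double.eps * n)
    stop("weak instrument: no first-stage association with the exposure")
  # first stage
  b1 <- szx / szz
  r1 <- xc - b1 * zc
  se_b1 <- sqrt(sum(r1^2) / (n - 2) / szz)
  f1 <- (b1 / se_b1)^2
  # IV estimate and variance with observed-exposure residuals
  beta <- sum(zc * yc) / szx
  e <- yc - beta * xc
  sigma2 <- sum(e^2) / (n - 2)
  se <- sqrt(sigma2 * szz / szx^2)
  pval <- 2 * pnorm(-abs(beta / se))
  new("TslsEstimate", method = "2SLS", beta = beta, se = se,
      ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
      pval = pval, n = n, units = units, f_first_stage = f1)
}

#' Convert an effect to outcome-SD units
#'
#' @param beta effect in raw outcome units.
#' @param sd_outcome outcome SD in the same units, > 0.
#' @return `beta / sd_outcome`.
#' @export
#' @examples
#' sdUnits(1.7, 24.23)  # 0.07 SD
sdUnits <- function(beta, sd_outcome) {
  if (!is.numeric(sd_outcome) || any(sd_outcome <= 0))
    stop("sd_outcome must be > 0")
  beta / sd_outcome
}

#' Expected outcome effect under full mediation
#'
#' Product-of-paths expectation: if the entire effect of the exposure on the
#' outcome ran through the mediator, the total effect would be a * b, where
#' a is the exposure -> mediator path and b the mediator -> outcome path.
#' The SE is first-order delta method, sqrt(a^2 se_b^2 + b^2 se_a^2).
#' Units must chain: b's denominator is a's numerator.
#'
#' @param a exposure -> mediator effect (e.g. SD SBP per SD urate).
#' @param b mediator -> outcome effect (e.g. g birthweight per SD SBP).
#' @param se_a,se_b standard errors (default 0: plug-in arithmetic).
#' @param units label for the product.
#' @return A [MediationExpectation].
#' @export
#' @examples
#' mediationExpectation(a = 0.07, b = -171.4)
mediationExpectation <- function(a, b, se_a = 0, se_b = 0,
                                 units = "outcome per SD exposure") {
  est <- a * b
  se <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  pval <- if (se > 0) 2 * pnorm(-abs(est / se)) else NA_real_
  new("MediationExpectation", method = "Full-mediation expectation (a*b)",
      beta = est, se = se, ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
      pval = pval, n = NA_real_, units = units,
      a = a, se_a = se_a, b = b, se_b = se_b)
}
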