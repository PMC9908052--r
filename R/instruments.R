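#' Per-SNP variance explained
#'
#' Proportion of phenotypic variance explained by a SNP under Hardy-Weinberg:
#' `beta^2 * 2p(1-p) / var_y`. For independent SNPs the per-SNP values sum
#' to the total instrument r-squared. Invariant under allele relabelling
#' (beta -> -beta, p -> 1-p).
#'
#' @param beta per-allele effect size(s).
#' @param p effect-allele frequency(ies), strictly inside (0,1).
#' @param var_y phenotypic variance of the trait, same units as `beta^2`.
#' @return Numeric vector of per-SNP variance proportions.
#' @export
#' @examples
#' varianceExplained(1, 0.5, 1.767)  # 0.28297
varianceExplained <- function(beta, p, var_y) {
  if (var_y <= 0) stop("var_y must be > 0")
  if (any(is.na(p)) || any(p <= 0 | p >= 1))
    stop("degenerate SNP: allele frequency must lie strictly in (0,1)")
  beta^2 * 2 * p * (1 - p) / var_y
}

#' Build a weighted standardized genetic score
#'
#' GS = sum_i w_i g_i over instrument SNPs (g_i the effect-allele dosage
#' 0-2), then z-scored against the sample. Missing dosages are mean-imputed
#' per SNP; SNPs with all dosages missing are excluded with a warning.
#'
#' @param genotypes dosage matrix, SNPs in rows, individuals in columns
#'   (values in \[0,2\], `NA` allowed).
#' @param weights per-SNP weights, exposure units per effect allele.
#' @param rsids optional SNP identifiers (defaults to rownames).
#' @return A [GeneticScore].
#' @export
buildScore <- function(genotypes, weights, rsids = rownames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != length(weights))
    stop("weight vector must match the SNP dimension of the dosage matrix")
  if (is.null(rsids)) rsids <- sprintf("snp%d", seq_len(nrow(genotypes)))
  rng <- range(genotypes, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")

  all_missing <- apply(genotypes, 1, function(g) all(is.na(g)))
  if (any(all_missing)) {
    warning(sum(all_missing), " SNP(s) with all dosages missing excluded: ",
            paste(rsids[all_missing], collapse = ", "))
  }
  keep <- !all_missing
  G <- genotypes[keep, , drop = FALSE]
  if (anyNA(G)) {
    mu <- rowMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 1]]
  }
  raw <- as.numeric(crossprod(G, weights[keep]))
  std <- as.numeric(scale(raw))
  new("GeneticScore", rsids = rsids[keep], weights = weights[keep],
      raw = raw, standardized = std,
      excluded = rsids[all_missing])
}

as_pairs_df <- function(pairs) {
  if (is(pairs, "HarmonizedPairs")) pairs@pairs
  else if (is.data.frame(pairs)) pairs
  else stop("expected a HarmonizedPairs object or a pairs data.frame")
}

#' Per-SNP and mean F statistics
#'
#' Instrument strength from summary data: per-SNP F_j = (beta_x_j/se_x_j)^2,
#' summarised by the arithmetic mean. This is the standard summary-data
#' approximation; for a single SNP it equals the squared exposure-GWAS
#' z-score, and in expectation grows as 1 + n r2 / (1 - r2).
#'
#' @param pairs a [HarmonizedPairs] or a data.frame with `beta_x`, `se_x`.
#' @return list with `f` (per-SNP vector, named by rsid when available) and
#'   `mean_f`.
#' @export
fStatistics <- function(pairs) {
  p <- as_pairs_df(pairs)
  if (!nrow(p)) stop("empty instrument set")
  if (any(p$se_x <= 0)) stop("se_x must be > 0")
  f <- (p$beta_x / p$se_x)^2
  if (!is.null(p$rsid)) names(f) <- p$rsid
  list(f = f, mean_f = mean(f))
}

#' Cochran's Q heterogeneity statistic
#'
#' Heterogeneity of per-SNP effects about the fixed-effects IVW fit, using
#' first-order (outcome-only) weights:
#' Q = sum_j (beta_y_j - beta_ivw * beta_x_j)^2 / se_y_j^2, referred to a
#' chi-square with J - 1 degrees of freedom. Invariant under simultaneous
#' sign flips of (beta_x, beta_y).
#'
#' @param pairs a [HarmonizedPairs] or pairs data.frame.
#' @param beta_ivw the pooled IVW slope the residuals are taken about
#'   (see [mrIVW()]).
#' @return list with `q`, `df`, `pval`.
#' @export
cochranQ <- function(pairs, beta_ivw) {
  p <- as_pairs_df(pairs)
  if (nrow(p) < 2) stop("Cochran's Q needs at least 2 SNPs")
  q <- sum((p$beta_y - beta_ivw * p$beta_x)^2 / p$se_y^2)
  df <- nrow(p) - 1
  list(q = q, df = df, pval = pchisq(q, df, lower.tail = FALSE))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0,1).
#' @param m number of tests, >= 1.
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroniThreshold(0.05, 114)  # 4.4e-4 at two significant digits
bonferroniThreshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0,1)")
  if (!is.numeric(m) || m < 1) stop("m must be >= 1")
  alpha / m
}

#' Combined instrument diagnostics
#'
#' Convenience wrapper computing per-SNP variance explained (requires `eaf`),
#' per-SNP and mean F, and Cochran's Q about the internally computed
#' fixed-effects IVW slope.
#'
#' @param pairs a [HarmonizedPairs] or pairs data.frame.
#' @param var_y phenotypic variance of the exposure used for the r-squared
#'   column (default 1: exposure already in SD units).
#' @return An [InstrumentDiagnostics].
#' @export
instrumentDiagnostics <- function(pairs, var_y = 1) {
  p <- as_pairs_df(pairs)
  fs <- fStatistics(p)
  r2 <- if (all(!is.na(p$eaf)) && all(p$eaf > 0 & p$eaf < 1))
    varianceExplained(p$beta_x, p$eaf, var_y)
  else rep(NA_real_, nrow(p))
  if (nrow(p) >= 2) {
    qq <- cochranQ(p, estimate(mrIVW(p)))
  } else {
    qq <- list(q = NA_real_, df = NA_real_, pval = NA_real_)
  }
  new("InstrumentDiagnostics",
      per_snp = data.frame(rsid = p$rsid, f_stat = unname(fs$f), r2 = r2,
                           stringsAsFactors = FALSE),
      mean_f = fs$mean_f, total_r2 = sum(r2),
      q = qq$q, q_df = qq$df, q_pval = qq$pval,
      weighting = "first-order (outcome-only) inverse variance")
}
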