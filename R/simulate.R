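#' Configure a mother-offspring duo simulation
#'
#' Defaults describe the study conditions the package is designed around:
#' 114 independent biallelic SNPs jointly explaining 6.4% of the variance in
#' maternal serum urate (phenotypic variance 1.767 on the measurement scale),
#' a urate -> SBP path of 0.07 SD SBP per SD urate with SD(SBP) = 24.23 mmHg,
#' an SBP -> birthweight path sized so that the full-mediation expectation is
#' about -12 g per SD urate, no direct (non-mediated) urate effect, and a
#' shared latent confounder loading on both urate and birthweight so the
#' observational association is biased away from the causal effect.
#'
#' @param n_snps number of independent instrument SNPs.
#' @param n_duos number of mother-offspring duos.
#' @param maf_range uniform range of minor-allele frequencies.
#' @param target_r2_exposure total exposure variance explained by the SNPs.
#' @param var_y_exposure exposure phenotypic variance on the measurement
#'   scale (used only to rescale the SD-unit exposure for display).
#' @param a_urate_to_sbp mediator path, SD SBP per SD urate.
#' @param sd_sbp_mmHg SD of SBP in mmHg (display scale).
#' @param b_sbp_to_bw outcome path, g birthweight per SD SBP.
#' @param direct_urate_to_bw g birthweight per SD urate not via SBP.
#' @param fetal_effect_sd SD of per-SNP fetal (offspring-genotype) effects on
#'   birthweight, g per allele.
#' @param confounder_on_exposure,confounder_on_bw loadings of the standard
#'   Gaussian confounder on urate (SD per SD) and birthweight (g per SD).
#' @param pleiotropy_mean,pleiotropy_sd,pleiotropy_frac distribution of
#'   per-SNP direct maternal-genotype-to-birthweight effects (g per allele)
#'   and the fraction of SNPs carrying one. Effects are oriented to the
#'   exposure-raising allele, so `mean = 0` gives balanced
#'   (InSIDE-satisfying) and `mean != 0` directional pleiotropy;
#'   `frac = 0` disables it.
#' @param bw_mean,bw_resid_sd birthweight mean and residual SD, g.
#' @param sbp_mean_mmHg,urate_mean_umol display-scale means.
#' @param seed mandatory integer seed; a fixed seed makes the cohort and all
#'   derived summary tables byte-identical.
#' @return A validated [DuoSimConfig].
#' @export
duoSimConfig <- function(n_snps = 114L, n_duos = 10000L,
                         maf_range = c(0.05, 0.5),
                         target_r2_exposure = 0.064,
                         var_y_exposure = 1.767,
                         a_urate_to_sbp = 0.07,
                         sd_sbp_mmHg = 24.23,
                         b_sbp_to_bw = -12 / 0.07,
                         direct_urate_to_bw = 0,
                         fetal_effect_sd = 5,
                         confounder_on_exposure = 0.3,
                         confounder_on_bw = -55,
                         pleiotropy_mean = 0, pleiotropy_sd = 0,
                         pleiotropy_frac = 0,
                         bw_mean = 3500, bw_resid_sd = 440,
                         sbp_mean_mmHg = 115, urate_mean_umol = 270.8,
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  new("DuoSimConfig",
      n_snps = as.integer(n_snps), n_duos = as.integer(n_duos),
      maf_range = maf_range, target_r2_exposure = target_r2_exposure,
      var_y_exposure = var_y_exposure, a_urate_to_sbp = a_urate_to_sbp,
      sd_sbp_mmHg = sd_sbp_mmHg, b_sbp_to_bw = b_sbp_to_bw,
      direct_urate_to_bw = direct_urate_to_bw,
      fetal_effect_sd = fetal_effect_sd,
      confounder_on_exposure = confounder_on_exposure,
      confounder_on_bw = confounder_on_bw,
      pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
      pleiotropy_frac = pleiotropy_frac,
      bw_mean = bw_mean, bw_resid_sd = bw_resid_sd,
      sbp_mean_mmHg = sbp_mean_mmHg, urate_mean_umol = urate_mean_umol,
      seed = as.integer(seed))
}

# non-palindromic and palindromic allele pairs; sampled per SNP
ALLELE_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"),
  c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate a mother-offspring duo cohort
#'
#' Generative model, per the configured causal chain:
#' \enumerate{
#'   \item per-SNP MAF ~ Uniform(`maf_range`); maternal dosages
#'     Binomial(2, maf).
#'   \item offspring dosage = one allele transmitted from the mother
#'     (Bernoulli(gM/2) per locus) + one paternal allele drawn from the
#'     population frequency, so corr(gM, gOff) -> 0.5 per locus.
#'   \item raw per-SNP exposure weights are rescaled so the genetic
#'     component's variance share equals `target_r2_exposure`; urate (SD
#'     units) = genetic score + confounder loading + Gaussian noise, total
#'     variance 1.
#'   \item SBP (SD units) = a * urate + noise, total variance 1.
#'   \item birthweight (g) = mean + b * SBP + direct * urate + fetal effects
#'     on gOff + pleiotropic effects on gM + confounder loading + noise.
#' }
#' The per-SNP truth (weights, maternal/fetal/pleiotropic effects) is stored
#' in `rowData()` so estimators can be checked against it.
#'
#' @param config a [DuoSimConfig].
#' @return A [DuoCohort].
#' @export
#' @examples
#' cohort <- simulateDuos(duoSimConfig(n_snps = 10, n_duos = 500, seed = 1))
#' cohort
simulateDuos <- function(config) {
  stopifnot(is(config, "DuoSimConfig"))
  validObject(config)
  with_seed(config@seed, {
    J <- config@n_snps; n <- config@n_duos
    maf <- runif(J, config@maf_range[1], config@maf_range[2])
    gM <- matrix(rbinom(J * n, 2L, rep(maf, n)), nrow = J)
    transmitted <- matrix(rbinom(J * n, 1L, as.vector(gM) / 2), nrow = J)
    paternal <- matrix(rbinom(J * n, 1L, rep(maf, n)), nrow = J)
    gOff <- transmitted + paternal

    het <- 2 * maf * (1 - maf)
    w_raw <- rnorm(J)
    w <- w_raw * sqrt(config@target_r2_exposure / sum(w_raw^2 * het))

    confounder <- rnorm(n)
    c_x <- config@confounder_on_exposure
    g_score <- as.numeric(crossprod(gM, w))
    urate_sd <- g_score - sum(w * 2 * maf) +  # centre the genetic component
      c_x * confounder +
      rnorm(n, 0, sqrt(1 - config@target_r2_exposure - c_x^2))

    a <- config@a_urate_to_sbp
    sbp_sd <- a * urate_sd + rnorm(n, 0, sqrt(1 - a^2))

    fetal <- rnorm(J, 0, config@fetal_effect_sd)
    pleio <- numeric(J)
    n_invalid <- round(config@pleiotropy_frac * J)
    if (n_invalid > 0) {
      # direct effects are expressed relative to the exposure-raising allele,
      # so a non-zero mean produces directional (IVW-biasing) pleiotropy
      # while the magnitudes stay independent of instrument strength (InSIDE)
      idx <- sample.int(J, n_invalid)
      pleio[idx] <- sign(w[idx]) * rnorm(n_invalid, config@pleiotropy_mean,
                                         config@pleiotropy_sd)
    }
    bw <- config@bw_mean +
      config@b_sbp_to_bw * sbp_sd +
      config@direct_urate_to_bw * urate_sd +
      as.numeric(crossprod(gOff, fetal)) - sum(fetal * 2 * maf) +
      as.numeric(crossprod(gM, pleio)) - sum(pleio * 2 * maf) +
      config@confounder_on_bw * confounder +
      rnorm(n, 0, config@bw_resid_sd)

    # mmol-scale displays and routine covariates (independent of the model)
    sd_raw <- sqrt(config@var_y_exposure)
    umol_per_mgdl <- 59.48
    pheno <- DataFrame(
      urate_sd = urate_sd,
      urate_umol = config@urate_mean_umol + urate_sd * sd_raw * umol_per_mgdl,
      sbp_sd = sbp_sd,
      sbp_mmHg = config@sbp_mean_mmHg + sbp_sd * config@sd_sbp_mmHg,
      birthweight_g = bw,
      confounder = confounder,
      age = rnorm(n, 30.5, 5.1),
      bmi = rnorm(n, 27.9, 4.6),
      smoking = rbinom(n, 1L, 0.14))

    pair_idx <- sample.int(nrow(ALLELE_PAIRS), J, replace = TRUE)
    tau_m <- config@a_urate_to_sbp * config@b_sbp_to_bw +
      config@direct_urate_to_bw
    rd <- DataFrame(
      rsid = sprintf("rs%06d", seq_len(J)),
      chrom = as.character(sample.int(22L, J, replace = TRUE)),
      pos = sample.int(2.5e8, J),
      effect_allele = ALLELE_PAIRS[pair_idx, 1],
      other_allele = ALLELE_PAIRS[pair_idx, 2],
      maf = maf,
      w_exposure = w,
      beta_fetal_true = fetal,
      beta_pleiotropy_true = pleio,
      beta_maternal_true = w * tau_m + pleio)
    rownames(rd) <- rd$rsid

    se <- SummarizedExperiment(
      assays = list(gM = gM, gOff = gOff),
      rowData = rd, colData = pheno)
    metadata(se)$config <- config
    new("DuoCohort", se)
  })
}

# vectorised per-SNP simple regressions of y on each row of G
snp_regressions <- function(G, y) {
  n <- length(y)
  yc <- y - mean(y)
  gm <- rowMeans(G)
  Sxx <- rowSums(G^2) - n * gm^2
  Sxy <- as.numeric(G %*% yc)
  beta <- ifelse(Sxx > 0, Sxy / Sxx, NA_real_)
  Syy <- sum(yc^2)
  rss <- pmax(Syy - beta^2 * Sxx, 0)
  se <- sqrt(rss / (n - 2) / Sxx)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = n - 2)
  list(beta = beta, se = se, pval = pmax(pval, .Machine$double.xmin),
       eaf = gm / 2, monomorphic = !(Sxx > 0))
}

#' Derive GWAS summary-statistic tables from a duo cohort
#'
#' Emulates the two samples of a two-sample maternal MR design by running
#' per-SNP simple regressions on the cohort: (i) maternal urate (SD units)
#' on maternal dosage (the exposure GWAS), (ii) offspring birthweight on
#' offspring dosage (the "own birthweight" GWAS), and (iii) offspring
#' birthweight on maternal dosage (the "offspring birthweight" GWAS).
#' Monomorphic SNPs are excluded from the tables and listed in
#' [rejectedRecords()].
#'
#' @param cohort a [DuoCohort].
#' @return Named list of three [SummaryStats]: `exposure`, `own_bw`,
#'   `offspring_bw`.
#' @export
cohortSummaryStats <- function(cohort) {
  stopifnot(is(cohort, "DuoCohort"), ncol(cohort) > 0)
  rd <- as.data.frame(rowData(cohort))
  ph <- phenotypes(cohort)
  n <- ncol(cohort)

  mk <- function(G, y, trait, unit) {
    fit <- snp_regressions(G, y)
    rec <- data.frame(
      rsid = rd$rsid, chrom = rd$chrom, pos = rd$pos,
      effect_allele = rd$effect_allele, other_allele = rd$other_allele,
      eaf = fit$eaf, beta = fit$beta, se = fit$se, pval = fit$pval,
      n = n, stringsAsFactors = FALSE)
    SummaryStats(rec, trait = trait, unit = unit)
  }
  list(
    exposure = mk(maternalGenotypes(cohort), ph$urate_sd,
                  "maternal urate", "SD urate"),
    own_bw = mk(offspringGenotypes(cohort), ph$birthweight_g,
                "own birthweight", "g birthweight"),
    offspring_bw = mk(maternalGenotypes(cohort), ph$birthweight_g,
                      "offspring birthweight", "g birthweight"))
}

#' Per-SNP sampling covariance of own- and offspring-birthweight betas
#'
#' When both birthweight GWAS come from the same duos (the same birthweight
#' regressed once on offspring and once on maternal dosage), the two
#' estimates share sampling noise. Conditional on the genotypes,
#' cov(b_own, b_off) = sigma^2 * S(gOff, gM) / (S(gOff) * S(gM)) with S the
#' centred sums of squares/products; sigma^2 is taken from the own-birthweight
#' regression residuals. Feed this into [wlmPartition()] for calibrated
#' maternal/fetal SEs; for GWAS from non-overlapping samples the covariance
#' is zero and can be omitted.
#'
#' @param cohort a [DuoCohort].
#' @return Named numeric vector of per-SNP covariances.
#' @export
duoEffectCovariance <- function(cohort) {
  G1 <- offspringGenotypes(cohort)
  G2 <- maternalGenotypes(cohort)
  y <- phenotypes(cohort)$birthweight_g
  n <- length(y)
  yc <- y - mean(y)
  S11 <- rowSums(G1^2) - n * rowMeans(G1)^2
  S22 <- rowSums(G2^2) - n * rowMeans(G2)^2
  S12 <- rowSums(G1 * G2) - n * rowMeans(G1) * rowMeans(G2)
  beta1 <- as.numeric(G1 %*% yc) / S11
  rss <- pmax(sum(yc^2) - beta1^2 * S11, 0)
  sigma2 <- rss / (n - 2)
  setNames(sigma2 * S12 / (S11 * S22), rowData(cohort)$rsid)
}
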