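#' GWAS summary statistics for one trait
#'
#' Per-SNP association records (effect/other allele, effect-allele frequency,
#' beta, SE, p, n) for a single trait, the common currency of two-sample MR.
#' Rows failing record-level invariants are kept out of the table and exposed
#' through [rejectedRecords()].
#'
#' @slot trait single character, trait label.
#' @slot unit single character, unit of the per-allele effect (e.g.
#'   `"SD urate"`, `"g birthweight"`).
#' @slot records `data.frame` with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @slot rejected `data.frame` of rejected input rows with a `reason` column.
#' @exportClass SummaryStats
setClass("SummaryStats",
  representation(trait = "character", unit = "character",
                 records = "data.frame", rejected = "data.frame"))

SUMSTAT_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")

setValidity("SummaryStats", function(object) {
  msg <- character()
  rec <- object@records
  missing_cols <- setdiff(SUMSTAT_COLS, names(rec))
  if (length(missing_cols))
    return(paste("records missing columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(rec$rsid)) msg <- c(msg, "duplicated rsids")
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  if (nrow(rec)) {
    if (!all(ok_allele(rec$effect_allele) & ok_allele(rec$other_allele)))
      msg <- c(msg, "alleles must be single characters in {A,C,G,T}")
    if (any(rec$effect_allele == rec$other_allele))
      msg <- c(msg, "effect and other allele must differ")
    if (any(!is.na(rec$se) & rec$se <= 0)) msg <- c(msg, "se must be > 0")
    if (any(!is.na(rec$eaf) & (rec$eaf < 0 | rec$eaf > 1)))
      msg <- c(msg, "eaf must lie in [0,1]")
    if (any(!is.na(rec$pval) & (rec$pval <= 0 | rec$pval > 1)))
      msg <- c(msg, "pval must lie in (0,1]")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Harmonized exposure-outcome instrument set
#'
#' The result of aligning an exposure and an outcome [SummaryStats] table to
#' a common effect allele per SNP: one row per retained instrument with the
#' exposure (`beta_x`, `se_x`) and outcome (`beta_y`, `se_y`) associations,
#' plus a log of SNPs dropped during harmonization and why.
#'
#' @slot pairs `data.frame` with columns `rsid`, `beta_x`, `se_x`, `beta_y`,
#'   `se_y`, `eaf`, `flipped`, `proxy_substituted`.
#' @slot dropped `data.frame` with columns `rsid`, `reason`.
#' @slot palindrome_eaf_limit numeric scalar used during harmonization.
#' @exportClass HarmonizedPairs
setClass("HarmonizedPairs",
  representation(pairs = "data.frame", dropped = "data.frame",
                 palindrome_eaf_limit = "numeric"))

setValidity("HarmonizedPairs", function(object) {
  p <- object@pairs
  need <- c("rsid", "beta_x", "se_x", "beta_y", "se_y")
  if (!all(need %in% names(p))) return("pairs missing mandatory columns")
  if (nrow(p) && any(p$se_x <= 0 | p$se_y <= 0)) return("SEs must be > 0")
  if (anyDuplicated(p$rsid)) return("duplicated rsids in pairs")
  TRUE
})

#' Mother-offspring duo cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] with SNPs as rows and duos
#' as columns. Assays `"gM"` and `"gOff"` hold maternal and offspring effect
#' allele dosages (0/1/2); `rowData` carries the per-SNP simulation truth
#' (allele labels, MAF, exposure weight, maternal/fetal birthweight effects);
#' `colData` the phenotypes (urate, SBP, birthweight, confounder, covariates).
#'
#' @exportClass DuoCohort
setClass("DuoCohort", contains = "SummarizedExperiment")

#' Duo-cohort simulation configuration
#'
#' Parameters of the generative model: independent biallelic SNPs, Mendelian
#' transmission from mother to offspring (paternal alleles drawn from the
#' population), an exposure -> mediator -> outcome chain (urate in SD units
#' -> SBP in SD units -> birthweight in grams) with maternal-specific and
#' fetal-specific genetic effects, optional per-SNP pleiotropic (direct
#' genotype-to-outcome) effects, and a shared latent confounder.
#'
#' @exportClass DuoSimConfig
setClass("DuoSimConfig",
  representation(
    n_snps = "integer", n_duos = "integer", maf_range = "numeric",
    target_r2_exposure = "numeric", var_y_exposure = "numeric",
    a_urate_to_sbp = "numeric", sd_sbp_mmHg = "numeric",
    b_sbp_to_bw = "numeric", direct_urate_to_bw = "numeric",
    fetal_effect_sd = "numeric",
    confounder_on_exposure = "numeric", confounder_on_bw = "numeric",
    pleiotropy_mean = "numeric", pleiotropy_sd = "numeric",
    pleiotropy_frac = "numeric",
    bw_mean = "numeric", bw_resid_sd = "numeric",
    sbp_mean_mmHg = "numeric", urate_mean_umol = "numeric",
    seed = "integer"))

setValidity("DuoSimConfig", function(object) {
  msg <- character()
  if (object@n_duos <= 0L) msg <- c(msg, "n_duos must be positive")
  if (object@n_snps <= 0L) msg <- c(msg, "n_snps must be positive")
  if (object@target_r2_exposure <= 0 || object@target_r2_exposure >= 1)
    msg <- c(msg, "target_r2_exposure must lie in (0,1)")
  mr <- object@maf_range
  if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    msg <- c(msg, "maf_range must be an increasing pair within (0, 0.5]")
  budget <- object@target_r2_exposure + object@confounder_on_exposure^2
  if (budget >= 1)
    msg <- c(msg, sprintf(
      "infeasible exposure variance budget: r2 + confounder loading^2 = %.3f >= 1",
      budget))
  if (abs(object@a_urate_to_sbp) >= 1)
    msg <- c(msg, "a_urate_to_sbp must have |a| < 1 (SD units)")
  if (object@var_y_exposure <= 0) msg <- c(msg, "var_y_exposure must be > 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Weighted standardized genetic score
#'
#' GS = sum_i w_i g_i over the instrument SNPs, z-scored against the sample.
#'
#' @slot rsids SNP identifiers, aligned 1:1 with `weights`.
#' @slot weights per-allele weights (exposure units per effect allele).
#' @slot raw per-individual weighted dosage sum.
#' @slot standardized per-individual z-scored score (mean 0, SD 1).
#' @slot excluded rsids excluded from scoring (e.g. all-missing dosages).
#' @exportClass GeneticScore
setClass("GeneticScore",
  representation(rsids = "character", weights = "numeric", raw = "numeric",
                 standardized = "numeric", excluded = "character"))

#' Instrument-strength and heterogeneity diagnostics
#'
#' @slot per_snp per-SNP `data.frame` (`rsid`, `f_stat`, `r2`).
#' @slot mean_f arithmetic mean of per-SNP F = (beta/se)^2.
#' @slot total_r2 summed per-SNP variance explained (independence assumed).
#' @slot q,q_df,q_pval Cochran's Q about the fixed-effects IVW fit.
#' @slot weighting label for the Q weighting scheme used.
#' @exportClass InstrumentDiagnostics
setClass("InstrumentDiagnostics",
  representation(per_snp = "data.frame", mean_f = "numeric",
                 total_r2 = "numeric", q = "numeric", q_df = "numeric",
                 q_pval = "numeric", weighting = "character"))

#' Maternal/fetal partition of birthweight GWAS effects
#'
#' Per-SNP maternal-specific and fetal-specific effects obtained by inverting
#' the structural system E[beta_own] = beta_F + beta_M/2 and
#' E[beta_offspring] = beta_M + beta_F/2.
#'
#' @slot effects `data.frame` with `rsid`, `beta_maternal`, `se_maternal`,
#'   `beta_fetal`, `se_fetal`, `cov_own_off`.
#' @slot excluded `data.frame` of SNPs present in only one input table.
#' @exportClass WlmEffects
setClass("WlmEffects",
  representation(effects = "data.frame", excluded = "data.frame"))

#' A single effect estimate
#'
#' Base container for any scalar effect with normal-theory or t-based
#' uncertainty: method label, point estimate, SE, 95% CI, p-value, sample
#' size and units.
#'
#' @exportClass EffectEstimate
setClass("EffectEstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ci_low = "numeric", ci_high = "numeric", pval = "numeric",
                 n = "numeric", units = "character"))

setValidity("EffectEstimate", function(object) {
  if (length(object@beta) != 1) return("beta must be scalar")
  if (!is.na(object@ci_low) && !is.na(object@ci_high) &&
      (object@ci_low > object@beta + 1e-8 || object@ci_high < object@beta - 1e-8))
    return("CI must bracket the point estimate")
  TRUE
})

#' Two-sample MR causal estimate
#'
#' @slot n_snps number of instruments used.
#' @slot intercept,intercept_se,intercept_ci_low,intercept_ci_high,intercept_pval
#'   MR-Egger intercept inference (NA for other methods).
#' @slot reference reference distribution used for inference
#'   (`"normal"` or `"t"`).
#' @slot n_boot,boot_seed parametric-bootstrap metadata (median methods).
#' @exportClass MrEstimate
setClass("MrEstimate", contains = "EffectEstimate",
  representation(n_snps = "numeric",
                 intercept = "numeric", intercept_se = "numeric",
                 intercept_ci_low = "numeric", intercept_ci_high = "numeric",
                 intercept_pval = "numeric",
                 reference = "character",
                 n_boot = "numeric", boot_seed = "numeric"))

#' One-sample two-stage least-squares estimate
#'
#' @slot f_first_stage first-stage F statistic of the instrument.
#' @exportClass TslsEstimate
setClass("TslsEstimate", contains = "EffectEstimate",
  representation(f_first_stage = "numeric"))

#' Expected outcome effect under full mediation
#'
#' Product-of-paths expectation a*b with delta-method SE
#' sqrt(a^2 se_b^2 + b^2 se_a^2).
#'
#' @slot a,se_a exposure -> mediator path and its SE.
#' @slot b,se_b mediator -> outcome path and its SE.
#' @exportClass MediationExpectation
setClass("MediationExpectation", contains = "EffectEstimate",
  representation(a = "numeric", se_a = "numeric",
                 b = "numeric", se_b = "numeric"))

#' End-to-end analysis configuration
#'
#' Inputs (file paths or in-memory objects), covariate list for the
#' observational stage, estimator list, lookup thresholds, harmonization and
#' bootstrap settings, the seed, and an optional output directory.
#'
#' @exportClass MrAnalysisConfig
setClass("MrAnalysisConfig",
  representation(
    exposure = "ANY", own_bw = "ANY", offspring_bw = "ANY",
    cohort = "ANY", pleiotropy_lookup = "ANY",
    covariates = "character", methods = "character",
    gw_threshold = "numeric", bonferroni_alpha = "numeric",
    palindrome_eaf_limit = "numeric",
    n_boot = "numeric", seed = "integer",
    var_y_exposure = "numeric", sd_sbp_mmHg = "numeric",
    mediation_b = "numeric", mediation_b_se = "numeric",
    out_dir = "character"))

#' Pipeline run report
#'
#' Per-stage estimates plus a provenance block (config hash, seed, input
#' checksums, package version) sufficient to reproduce every number.
#'
#' @slot stages named list of per-stage results.
#' @slot provenance named list (config_hash, seed, input_md5, version).
#' @exportClass RunReport
setClass("RunReport",
  representation(stages = "list", provenance = "list"))
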