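#' Confounder-adjusted observational effect per 1-SD exposure
#'
#' Ordinary least squares of the outcome on the within-sample standardized
#' exposure plus covariates, with listwise deletion of incomplete rows
#' (deletion count reported in the result's metadata via `n`).
#'
#' @param data `data.frame` (or [DuoCohort], whose phenotypes are used).
#' @param exposure,outcome column names.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param units label for the effect.
#' @return An [EffectEstimate]; `n` is the complete-case count used.
#' @export
observationalStage <- function(data, exposure, outcome,
                               covariates = character(),
                               units = "outcome per SD exposure") {
  if (is(data, "DuoCohort")) data <- phenotypes(data)
  cols <- c(exposure, outcome, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  d <- data[cols]
  cc <- complete.cases(d)
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  if (nrow(d) < length(covariates) + 2)
    stop("too few complete cases for the requested model")
  d$..exposure_sd <- as.numeric(scale(d[[exposure]]))
  rhs <- paste(c("..exposure_sd", covariates), collapse = " + ")
  fit <- lm(stats::reformulate(c("..exposure_sd", covariates),
                               response = outcome), data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  beta <- sm["..exposure_sd", "Estimate"]
  se <- sm["..exposure_sd", "Std. Error"]
  df <- fit$df.residual
  est <- new("EffectEstimate", method = "Observational OLS",
             beta = beta, se = se,
             ci_low = beta - qt(0.975, df) * se,
             ci_high = beta + qt(0.975, df) * se,
             pval = sm["..exposure_sd", "Pr(>|t|)"],
             n = nrow(d), units = units)
  attr(est, "n_dropped") <- n_dropped
  if (n_dropped > 0)
    message(n_dropped, " incomplete row(s) removed by listwise deletion")
  est
}

#' Flag instruments associated with a candidate pleiotropic trait
#'
#' Looks instrument rsids up in an external trait GWAS and returns the
#' nested sets significant at genome-wide and at Bonferroni-corrected
#' thresholds; SNPs absent from the lookup are reported unevaluable.
#'
#' @param rsids instrument rsids.
#' @param lookup `data.frame` with columns `rsid` and `pval`.
#' @param gw_threshold genome-wide threshold (default 5e-8).
#' @param bonferroni_threshold Bonferroni threshold (e.g.
#'   `bonferroniThreshold(0.05, length(rsids))`).
#' @return list with `genome_wide`, `bonferroni` (a superset of
#'   `genome_wide`) and `unevaluable` rsid vectors.
#' @export
pleiotropyLookup <- function(rsids, lookup, gw_threshold = 5e-8,
                             bonferroni_threshold) {
  if (!all(c("rsid", "pval") %in% names(lookup)))
    stop("lookup must have columns rsid, pval")
  idx <- match(rsids, lookup$rsid)
  p <- lookup$pval[idx]
  list(genome_wide = rsids[!is.na(p) & p <= gw_threshold],
       bonferroni = rsids[!is.na(p) & p <= bonferroni_threshold],
       unevaluable = rsids[is.na(p)])
}

#' Association between a standardized genetic score and a binary covariate
#'
#' Difference in mean standardized GS between the two covariate groups
#' (equivalently OLS of the GS on the indicator), a check that the
#' instrument set is not systematically related to a candidate confounder or
#' pleiotropic behaviour.
#'
#' @param gs standardized genetic score vector (or a [GeneticScore]).
#' @param covariate 0/1 vector aligned with `gs`.
#' @return An [EffectEstimate] (SD of GS per unit covariate).
#' @export
scoreCovariateAssociation <- function(gs, covariate) {
  if (is(gs, "GeneticScore")) gs <- standardizedScore(gs)
  if (length(unique(covariate[!is.na(covariate)])) < 2)
    stop("covariate has a single class")
  if (!all(covariate[!is.na(covariate)] %in% 0:1))
    stop("covariate must be coded 0/1")
  fit <- summary(lm(gs ~ covariate))$coefficients
  beta <- fit["covariate", "Estimate"]
  se <- fit["covariate", "Std. Error"]
  df <- sum(!is.na(gs) & !is.na(covariate)) - 2
  new("EffectEstimate", method = "GS-covariate association",
      beta = beta, se = se,
      ci_low = beta - qt(0.975, df) * se,
      ci_high = beta + qt(0.975, df) * se,
      pval = fit["covariate", "Pr(>|t|)"],
      n = df + 2, units = "SD of GS")
}

#' Configure an end-to-end analysis
#'
#' Inputs may be file paths (canonical TSV, read with [readSummaryStats()])
#' or in-memory objects ([SummaryStats], [DuoCohort], `data.frame`).
#'
#' @param exposure,own_bw,offspring_bw exposure and the two birthweight
#'   summary-statistic inputs.
#' @param cohort optional individual-level [DuoCohort] (or path to an RDS
#'   file) enabling the observational, one-sample 2SLS and GS-covariate
#'   stages.
#' @param pleiotropy_lookup optional `data.frame`/path with `rsid`, `pval`
#'   for the SNP-exclusion sensitivity stage.
#' @param covariates observational-stage covariates present in the cohort
#'   phenotypes.
#' @param methods subset of `c("ivw", "egger", "wm", "pwm")`.
#' @param gw_threshold,bonferroni_alpha lookup thresholds (the Bonferroni
#'   threshold is `bonferroni_alpha / n_instruments`).
#' @param palindrome_eaf_limit passed to [harmonize()].
#' @param n_boot bootstrap replicates for median methods.
#' @param seed mandatory seed governing every stochastic step.
#' @param var_y_exposure exposure phenotypic variance for the r2 diagnostic.
#' @param sd_sbp_mmHg mediator SD used to express the 2SLS effect per SD.
#' @param mediation_b,mediation_b_se mediator -> outcome path (g per SD SBP)
#'   for the mediation expectation.
#' @param out_dir optional directory; when set, [runPipeline()] writes
#'   `report.json` and `report.txt` there.
#' @return An [MrAnalysisConfig].
#' @export
mrAnalysisConfig <- function(exposure, own_bw, offspring_bw,
                             cohort = NULL, pleiotropy_lookup = NULL,
                             covariates = c("age", "bmi", "smoking"),
                             methods = c("ivw", "egger", "wm", "pwm"),
                             gw_threshold = 5e-8, bonferroni_alpha = 0.05,
                             palindrome_eaf_limit = 0.42,
                             n_boot = 1000, seed,
                             var_y_exposure = 1,
                             sd_sbp_mmHg = 24.23,
                             mediation_b = -12 / 0.07, mediation_b_se = 0,
                             out_dir = NA_character_) {
  if (missing(seed)) stop("seed is mandatory")
  methods <- match.arg(methods, c("ivw", "egger", "wm", "pwm"),
                       several.ok = TRUE)
  new("MrAnalysisConfig", exposure = exposure, own_bw = own_bw,
      offspring_bw = offspring_bw, cohort = cohort,
      pleiotropy_lookup = pleiotropy_lookup, covariates = covariates,
      methods = methods, gw_threshold = gw_threshold,
      bonferroni_alpha = bonferroni_alpha,
      palindrome_eaf_limit = palindrome_eaf_limit,
      n_boot = n_boot, seed = as.integer(seed),
      var_y_exposure = var_y_exposure, sd_sbp_mmHg = sd_sbp_mmHg,
      mediation_b = mediation_b, mediation_b_se = mediation_b_se,
      out_dir = out_dir)
}

resolve_sumstats <- function(x, trait, unit) {
  if (is(x, "SummaryStats")) x
  else if (is.character(x) && length(x) == 1)
    readSummaryStats(x, trait = trait, unit = unit)
  else if (is.data.frame(x)) SummaryStats(x, trait = trait, unit = unit)
  else stop("cannot interpret input for ", trait)
}

resolve_table <- function(x) {
  if (is.null(x) || is.data.frame(x)) x
  else if (is.character(x) && length(x) == 1)
    read.delim(x, stringsAsFactors = FALSE)
  else stop("cannot interpret lookup input")
}

input_md5 <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(unname(tools::md5sum(x)))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp)
  unname(tools::md5sum(tmp))
}

estimate_block <- function(est) {
  out <- list(method = est@method, beta = est@beta, se = est@se,
              ci_low = est@ci_low, ci_high = est@ci_high, pval = est@pval,
              n = est@n, units = est@units)
  if (is(est, "MrEstimate")) {
    out$n_snps <- est@n_snps
    if (!is.na(est@intercept)) {
      out$intercept <- est@intercept
      out$intercept_se <- est@intercept_se
      out$intercept_ci_low <- est@intercept_ci_low
      out$intercept_ci_high <- est@intercept_ci_high
      out$intercept_pval <- est@intercept_pval
    }
  }
  if (is(est, "TslsEstimate")) out$f_first_stage <- est@f_first_stage
  out
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: harmonization of the two birthweight
#' tables to the exposure's effect alleles; the maternal/fetal partition;
#' instrument diagnostics (total r2, mean F, Cochran's Q); the requested MR
#' estimators on the exposure -> maternal-specific-birthweight pairs;
#' sensitivity analyses (pleiotropy lookup with SNP-exclusion re-estimation,
#' leave-one-out IVW); and, when an individual-level cohort is supplied, the
#' observational OLS stage, one-sample 2SLS of the mediator on the exposure
#' with a genetic-score instrument, the GS-covariate association, and the
#' full-mediation expectation. Re-running with the same config and seed
#' reproduces the report bit for bit.
#'
#' @param config an [MrAnalysisConfig].
#' @return A [RunReport]; if `out_dir` is set, `report.json` and
#'   `report.txt` are written there as a side effect.
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "MrAnalysisConfig"))
  stages <- list()
  inputs_md5 <- list()

  exposure <- resolve_sumstats(config@exposure, "exposure", "SD exposure")
  own <- resolve_sumstats(config@own_bw, "own birthweight", "g birthweight")
  off <- resolve_sumstats(config@offspring_bw, "offspring birthweight",
                          "g birthweight")
  for (nm in c("exposure", "own_bw", "offspring_bw"))
    inputs_md5[[nm]] <- input_md5(slot(config, nm))

  # harmonize both outcome tables to the exposure's effect alleles, then
  # partition; the partition requires a common allele per SNP across tables
  h_own <- harmonize(exposure, own, config@palindrome_eaf_limit)
  h_off <- harmonize(exposure, off, config@palindrome_eaf_limit)
  align <- function(h, template) {
    p <- instrumentPairs(h)
    tr <- template@records[match(p$rsid, template@records$rsid), ]
    rec <- data.frame(rsid = p$rsid, chrom = tr$chrom, pos = tr$pos,
                      effect_allele = tr$effect_allele,
                      other_allele = tr$other_allele,
                      eaf = p$eaf, beta = p$beta_y, se = p$se_y,
                      pval = NA_real_, n = NA_real_,
                      stringsAsFactors = FALSE)
    SummaryStats(rec, trait = "aligned outcome", unit = "g birthweight")
  }
  own_al <- align(h_own, exposure)
  off_al <- align(h_off, exposure)
  wlm <- wlmPartition(own_al, off_al)
  maternal <- wlmToSummaryStats(wlm, "maternal")
  stages$wlm <- list(n_snps = nrow(wlmEffects(wlm)),
                     n_excluded = nrow(wlm@excluded))

  pairs_mat <- harmonize(exposure, maternal, config@palindrome_eaf_limit)
  p <- instrumentPairs(pairs_mat)
  p$se_x <- exposure@records$se[match(p$rsid, exposure@records$rsid)]
  stages$harmonization <- list(
    n_instruments = nrow(p),
    n_dropped_own = nrow(droppedSnps(h_own)),
    n_dropped_offspring = nrow(droppedSnps(h_off)))

  diag <- instrumentDiagnostics(p, var_y = config@var_y_exposure)
  stages$diagnostics <- list(mean_f = meanF(diag), total_r2 = totalR2(diag),
                             q = diag@q, q_df = diag@q_df,
                             q_pval = diag@q_pval,
                             weighting = diag@weighting)

  run_method <- function(m) {
    switch(m,
      ivw = mrIVW(p),
      egger = mrEgger(p),
      wm = mrWeightedMedian(p, config@n_boot, seed = config@seed),
      pwm = mrPenalizedWeightedMedian(p, config@n_boot, seed = config@seed))
  }
  stages$mr <- lapply(setNames(config@methods, config@methods), function(m)
    estimate_block(run_method(m)))

  lookup <- resolve_table(config@pleiotropy_lookup)
  if (!is.null(lookup)) {
    inputs_md5$pleiotropy_lookup <- input_md5(config@pleiotropy_lookup)
    bonf <- bonferroniThreshold(config@bonferroni_alpha, nrow(p))
    flags <- pleiotropyLookup(p$rsid, lookup, config@gw_threshold, bonf)
    excl <- mrExclude(p, flags$bonferroni, mrIVW)
    stages$pleiotropy <- list(
      bonferroni_threshold = bonf,
      n_genome_wide = length(flags$genome_wide),
      n_bonferroni = length(flags$bonferroni),
      n_unevaluable = length(flags$unevaluable),
      flagged = flags$bonferroni,
      ivw_after_exclusion = estimate_block(excl))
  }
  loo <- mrLeaveOneOut(p, mrIVW)
  full_ivw <- mrIVW(p)
  stages$leave_one_out <- list(
    max_abs_shift = max(abs(loo$beta - estimate(full_ivw))),
    most_influential = loo$omitted[which.max(abs(loo$beta - estimate(full_ivw)))])

  cohort <- config@cohort
  if (is.character(cohort) && length(cohort) == 1) cohort <- readRDS(cohort)
  if (!is.null(cohort)) {
    inputs_md5$cohort <- input_md5(cohort)
    ph <- phenotypes(cohort)
    obs <- observationalStage(ph, "urate_sd", "birthweight_g",
                              config@covariates,
                              units = "g birthweight per SD exposure")
    stages$observational <- c(estimate_block(obs),
                              n_dropped = attr(obs, "n_dropped"))

    wts <- exposure@records$beta
    names(wts) <- exposure@records$rsid
    keep <- intersect(rowData(cohort)$rsid, names(wts))
    gs <- buildScore(maternalGenotypes(cohort)[keep, , drop = FALSE],
                     wts[keep], rsids = keep)
    iv <- tsls(as.numeric(scale(ph$urate_sd)), ph$sbp_mmHg,
               standardizedScore(gs),
               units = "mmHg SBP per SD exposure")
    stages$tsls_exposure_to_mediator <- c(
      estimate_block(iv),
      list(beta_sd_units = sdUnits(estimate(iv), config@sd_sbp_mmHg),
           se_sd_units = sdUnits(stdError(iv), config@sd_sbp_mmHg)))

    if ("smoking" %in% names(ph)) {
      gsa <- scoreCovariateAssociation(gs, ph$smoking)
      stages$gs_covariate <- estimate_block(gsa)
    }

    med <- mediationExpectation(
      a = sdUnits(estimate(iv), config@sd_sbp_mmHg),
      b = config@mediation_b,
      se_a = sdUnits(stdError(iv), config@sd_sbp_mmHg),
      se_b = config@mediation_b_se,
      units = "g birthweight per SD exposure")
    stages$mediation <- c(estimate_block(med),
                          list(a = med@a, b = med@b))
  }

  provenance <- list(
    config_hash = input_md5(config),
    seed = config@seed,
    input_md5 = inputs_md5,
    version = as.character(packageVersion("duoMR")))
  report <- new("RunReport", stages = stages, provenance = provenance)
  if (!is.na(config@out_dir)) writeRunReport(report, config@out_dir)
  report
}

#' Write a run report to disk
#'
#' Writes `report.json` (full precision) and a human-readable `report.txt`
#' (estimates rounded to 1 g / 0.01 SD for display).
#'
#' @param report a [RunReport].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(stages = report@stages, provenance = report@provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  txt <- c("duoMR pipeline report",
           sprintf("seed %d, config %s, duoMR %s",
                   report@provenance$seed, report@provenance$config_hash,
                   report@provenance$version), "")
  for (nm in names(report@stages)) {
    s <- report@stages[[nm]]
    txt <- c(txt, sprintf("[%s]", nm))
    flat <- unlist(s)
    txt <- c(txt, paste0("  ", names(flat), " = ",
                         vapply(flat, function(v) {
                           vn <- suppressWarnings(as.numeric(v))
                           if (is.na(vn)) as.character(v)
                           else format(signif(vn, 4))
                         }, character(1))), "")
  }
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
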