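#' Partition birthweight GWAS effects into maternal and fetal components
#'
#' An individual's birthweight associates with their own genotype through
#' both a fetal effect and (because mother and child share half their
#' alleles) half the maternal effect, and with their mother's genotype
#' through the maternal effect plus half the fetal effect:
#' \deqn{E[\beta_{own}] = \beta_F + \tfrac12\beta_M, \qquad
#'       E[\beta_{offspring}] = \beta_M + \tfrac12\beta_F.}
#' Inverting this linear system per SNP gives
#' \deqn{\beta_M = (4\beta_{offspring} - 2\beta_{own})/3, \qquad
#'       \beta_F = (4\beta_{own} - 2\beta_{offspring})/3,}
#' with variances from the same linear combination, e.g.
#' var(beta_M) = (16 var(beta_offspring) + 4 var(beta_own) - 16 cov)/9.
#' Using the maternal-specific effects as the MR outcome keeps the fetal
#' genome from violating the exclusion restriction.
#'
#' @param own [SummaryStats] of own-birthweight effects (trait regressed on
#'   the individual's own genotype), harmonized to the same effect allele as
#'   `offspring`.
#' @param offspring [SummaryStats] of offspring-birthweight effects (child's
#'   birthweight regressed on the mother's genotype).
#' @param cov_own_off per-SNP sampling covariance between the two input
#'   betas: a single number recycled to all SNPs, or a vector named by rsid.
#'   Defaults to 0 (non-overlapping GWAS samples); see
#'   [duoEffectCovariance()] for fully overlapping duo samples.
#' @return A [WlmEffects]. SNPs present in only one table are excluded and
#'   listed in the `excluded` slot.
#' @export
#' @examples
#' own <- data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
#'                   beta = 0.5, se = 0.1)
#' off <- transform(own, beta = 1.0)
#' wlmEffects(wlmPartition(SummaryStats(own, "own bw", "g"),
#'                         SummaryStats(off, "offspring bw", "g")))
wlmPartition <- function(own, offspring, cov_own_off = 0) {
  stopifnot(is(own, "SummaryStats"), is(offspring, "SummaryStats"))
  o <- own@records
  f <- offspring@records
  shared <- intersect(o$rsid, f$rsid)
  only <- c(setdiff(o$rsid, f$rsid), setdiff(f$rsid, o$rsid))
  excluded <- data.frame(
    rsid = only,
    reason = rep(c("absent from offspring table", "absent from own table"),
                 c(length(setdiff(o$rsid, f$rsid)),
                   length(setdiff(f$rsid, o$rsid)))),
    stringsAsFactors = FALSE)
  o <- o[match(shared, o$rsid), , drop = FALSE]
  f <- f[match(shared, f$rsid), , drop = FALSE]
  if (!all(o$effect_allele == f$effect_allele &
           o$other_allele == f$other_allele))
    stop("tables must be harmonized to a common effect allele per SNP")

  cov_vec <- if (length(cov_own_off) == 1) rep(cov_own_off, length(shared))
             else unname(cov_own_off[shared])
  if (anyNA(cov_vec)) stop("cov_own_off missing for some shared rsids")

  b_own <- o$beta; v_own <- o$se^2
  b_off <- f$beta; v_off <- f$se^2
  beta_m <- (4 * b_off - 2 * b_own) / 3
  beta_f <- (4 * b_own - 2 * b_off) / 3
  var_m <- (16 * v_off + 4 * v_own - 16 * cov_vec) / 9
  var_f <- (16 * v_own + 4 * v_off - 16 * cov_vec) / 9
  if (any(var_m <= 0) || any(var_f <= 0))
    stop("non-positive partitioned variance; check cov_own_off")

  new("WlmEffects",
      effects = data.frame(
        rsid = shared,
        effect_allele = o$effect_allele, other_allele = o$other_allele,
        eaf = o$eaf, n = pmin(o$n, f$n),
        beta_maternal = beta_m, se_maternal = sqrt(var_m),
        beta_fetal = beta_f, se_fetal = sqrt(var_f),
        cov_own_off = cov_vec, stringsAsFactors = FALSE),
      excluded = excluded)
}

#' Recompose own/offspring betas from a partition
#'
#' Applies the forward structural equations to partitioned effects; on the
#' output of [wlmPartition()] this reproduces the input betas exactly (the
#' partition is a linear bijection).
#'
#' @param wlm a [WlmEffects].
#' @return `data.frame` with `rsid`, `beta_own`, `beta_offspring`.
#' @export
wlmRecompose <- function(wlm) {
  e <- wlmEffects(wlm)
  data.frame(rsid = e$rsid,
             beta_own = e$beta_fetal + 0.5 * e$beta_maternal,
             beta_offspring = e$beta_maternal + 0.5 * e$beta_fetal,
             stringsAsFactors = FALSE)
}

#' Export a partition as an MR-ready outcome table
#'
#' Wraps the maternal-specific (or fetal-specific) effects as a
#' [SummaryStats] directly consumable by [harmonize()] as the MR outcome.
#'
#' @param wlm a [WlmEffects].
#' @param which `"maternal"` or `"fetal"`.
#' @param trait,unit labels for the resulting table.
#' @return A [SummaryStats].
#' @export
wlmToSummaryStats <- function(wlm, which = c("maternal", "fetal"),
                              trait = NULL, unit = "g birthweight") {
  which <- match.arg(which)
  e <- wlmEffects(wlm)
  beta <- e[[paste0("beta_", which)]]
  se <- e[[paste0("se_", which)]]
  rec <- data.frame(
    rsid = e$rsid, effect_allele = e$effect_allele,
    other_allele = e$other_allele, eaf = e$eaf,
    beta = beta, se = se,
    pval = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = e$n, stringsAsFactors = FALSE)
  if (is.null(trait)) trait <- sprintf("%s-specific birthweight effect", which)
  SummaryStats(rec, trait = trait, unit = unit)
}
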