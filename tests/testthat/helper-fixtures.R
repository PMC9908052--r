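# small construction helpers shared across test files

make_records <- function(n = 3, seed = 1) {
  set.seed(seed)
  pairs <- rbind(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  idx <- sample.int(nrow(pairs), n, replace = TRUE)
  data.frame(
    rsid = sprintf("rs%03d", seq_len(n)),
    chrom = as.character(sample.int(22, n, replace = TRUE)),
    pos = sample.int(1e8, n),
    effect_allele = pairs[idx, 1], other_allele = pairs[idx, 2],
    eaf = round(runif(n, 0.05, 0.95), 3),
    beta = round(rnorm(n, 0, 0.1), 4),
    se = round(runif(n, 0.01, 0.05), 4),
    pval = round(runif(n, 1e-10, 0.9), 6),
    n = 10000L, stringsAsFactors = FALSE)
}

make_pairs <- function(beta_x, beta_y, se_x = 0.01, se_y = 0.05,
                       eaf = 0.3, rsid = sprintf("rs%03d", seq_along(beta_x))) {
  J <- length(beta_x)
  data.frame(rsid = rsid, beta_x = beta_x, se_x = rep_len(se_x, J),
             beta_y = beta_y, se_y = rep_len(se_y, J),
             eaf = rep_len(eaf, J),
             flipped = rep_len(FALSE, J),
             proxy_substituted = rep_len(FALSE, J),
             stringsAsFactors = FALSE)
}

# summary-level two-sample instrument generator: J SNPs with true exposure
# weights w, causal slope theta, optional per-SNP direct (pleiotropic)
# outcome effects; sampling noise at the given SE scales
sim_summary_instance <- function(J = 50, theta = 0, se_x = 0.005,
                                 se_y = 0.05, w_sd = 0.05,
                                 pleio = rep(0, J)) {
  w <- rnorm(J, 0, w_sd)
  bx <- rnorm(J, w, se_x)
  by <- rnorm(J, theta * w + pleio, se_y)
  make_pairs(bx, by, se_x = se_x, se_y = se_y)
}

# convert a HarmonizedPairs back into exposure/outcome SummaryStats sharing
# the exposure's allele coding (used for idempotence checks)
pairs_to_tables <- function(h, exposure) {
  p <- instrumentPairs(h)
  ex <- snpRecords(exposure)
  ex <- ex[match(p$rsid, ex$rsid), ]
  out <- ex
  out$beta <- p$beta_y
  out$se <- p$se_y
  list(exposure = SummaryStats(ex, "x", "u"),
       outcome = SummaryStats(out, "y", "u"))
}

# synthetic stand-in for a published instrument table, generated at the
# stated study conditions: J independent SNPs jointly explaining r2_total of
# an exposure with phenotypic variance var_y, association SEs at GWAS
# sample size n
make_instrument_table <- function(J = 114, n = 288649, var_y = 1.767,
                                  r2_total = 0.064, seed = 2023) {
  set.seed(seed)
  maf <- runif(J, 0.05, 0.5)
  het <- 2 * maf * (1 - maf)
  w <- rnorm(J)
  w <- w * sqrt(r2_total * var_y / sum(w^2 * het))
  r2j <- w^2 * het / var_y
  se <- sqrt(var_y * (1 - r2j) / (n * het))
  data.frame(rsid = sprintf("rs%04d", seq_len(J)),
             effect_allele = "A", other_allele = "G",
             eaf = maf, beta = w, se = se,
             pval = pmax(2 * pnorm(-abs(w / se)), 1e-300),
             n = n, stringsAsFactors = FALSE)
}

# run the full two-sample chain on a simulated super-cohort split into a
# non-overlapping exposure sample and outcome (duo) sample
two_sample_chain <- function(n_per_sample, seed, ...) {
  cfg <- duoSimConfig(n_duos = 2L * n_per_sample, seed = seed, ...)
  co <- simulateDuos(cfg)
  s1 <- co[, seq_len(n_per_sample)]
  s2 <- co[, n_per_sample + seq_len(n_per_sample)]
  exposure <- cohortSummaryStats(s1)$exposure
  ss2 <- cohortSummaryStats(s2)
  wlm <- wlmPartition(ss2$own_bw, ss2$offspring_bw,
                      cov_own_off = duoEffectCovariance(s2))
  maternal <- wlmToSummaryStats(wlm, "maternal")
  pairs <- harmonize(exposure, maternal)
  tau <- cfg@a_urate_to_sbp * cfg@b_sbp_to_bw + cfg@direct_urate_to_bw
  list(cohort = co, sample2 = s2, exposure = exposure, wlm = wlm,
       pairs = pairs, tau = tau)
}
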