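#' Construct a summary-statistics table
#'
#' Validates per-SNP records and builds a [SummaryStats] object. Rows that
#' violate record-level invariants (non-ACGT or identical alleles,
#' non-positive SE, frequency outside \[0,1\], p outside (0,1\], missing
#' beta) are removed and reported via [rejectedRecords()] rather than
#' failing the whole table.
#'
#' @param records `data.frame` with (a superset of) the canonical columns
#'   `rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pval`, `n`. Missing optional columns (`chrom`, `pos`, `eaf`,
#'   `pval`, `n`) are filled with `NA`.
#' @param trait trait label.
#' @param unit unit of `beta` (per effect allele).
#' @return A [SummaryStats] object; row order of valid records is preserved.
#' @export
#' @examples
#' rec <- data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
#'                   eaf = 0.3, beta = 0.1, se = 0.02, pval = 1e-6, n = 1000)
#' SummaryStats(rec, trait = "urate", unit = "SD urate")
SummaryStats <- function(records, trait = "trait", unit = NA_character_) {
  stopifnot(is.data.frame(records))
  mandatory <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(mandatory, names(records))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  for (col in setdiff(SUMSTAT_COLS, names(records))) records[[col]] <- NA
  records <- records[SUMSTAT_COLS]
  records$rsid <- as.character(records$rsid)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n", "pos"))
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))

  reason <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  acgt <- c("A", "C", "G", "T")
  reason <- flag(!(records$effect_allele %in% acgt) |
                 !(records$other_allele %in% acgt), "non-ACGT allele")
  reason <- flag(records$effect_allele == records$other_allele,
                 "identical alleles")
  reason <- flag(is.na(records$beta), "missing beta")
  reason <- flag(is.na(records$se) | records$se <= 0, "se not > 0")
  reason <- flag(!is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1),
                 "eaf outside [0,1]")
  reason <- flag(!is.na(records$pval) & (records$pval <= 0 | records$pval > 1),
                 "pval outside (0,1]")
  reason <- flag(!is.na(records$n) & records$n <= 0, "n not positive")
  reason <- flag(duplicated(records$rsid), "duplicated rsid")

  bad <- !is.na(reason)
  rejected <- records[bad, , drop = FALSE]
  rejected$reason <- reason[bad]
  rownames(rejected) <- NULL
  kept <- records[!bad, , drop = FALSE]
  rownames(kept) <- NULL
  new("SummaryStats", trait = trait, unit = unit,
      records = kept, rejected = rejected)
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab-separated association file into a [SummaryStats] object. A
#' `dialect` maps consortium-specific headers (e.g. `A1`, `freq`) onto the
#' canonical column names, so differently headed consortium files read
#' identically to canonically headed ones.
#'
#' @param path path to a TSV file.
#' @param dialect `NULL` for canonical headers; a named character vector
#'   `c(canonical = "file_column", ...)`; or a path to a YAML/JSON file
#'   containing such a mapping.
#' @param trait,unit passed to [SummaryStats()].
#' @return A validated [SummaryStats]; rejected rows are available through
#'   [rejectedRecords()].
#' @export
readSummaryStats <- function(path, dialect = NULL, trait = "trait",
                             unit = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    if (is.character(dialect) && length(dialect) == 1 && file.exists(dialect)) {
      dialect <- if (grepl("\\.ya?ml$", dialect))
        unlist(yaml::read_yaml(dialect))
      else unlist(jsonlite::read_json(dialect, simplifyVector = TRUE))
    }
    missing_src <- setdiff(unname(dialect), names(raw))
    if (length(missing_src))
      stop("dialect names absent from file: ",
           paste(missing_src, collapse = ", "))
    idx <- match(unname(dialect), names(raw))
    names(raw)[idx] <- names(dialect)
  }
  mandatory <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  SummaryStats(raw, trait = trait, unit = unit)
}

#' Write a summary-statistics table as canonical TSV
#'
#' @param x a [SummaryStats].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(x, path) {
  stopifnot(is(x, "SummaryStats"))
  write.table(x@records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "G" & a2 == "C") | (a1 == "C" & a2 == "G")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome table to the exposure table's effect allele at every
#' shared rsid so that `beta_x` and `beta_y` refer to the same allele. Where
#' the outcome's effect allele equals the exposure's other allele the outcome
#' beta is sign-flipped and its frequency complemented; alleles reported on
#' the opposite strand are complemented first. Strand-ambiguous (A/T, G/C)
#' SNPs whose minor-allele frequency is too close to 0.5 to resolve strand
#' are dropped. Every exclusion is logged with its reason.
#'
#' @param exposure,outcome [SummaryStats] tables.
#' @param palindrome_eaf_limit drop a palindromic SNP when
#'   `min(eaf, 1 - eaf) > palindrome_eaf_limit` (default 0.42). The exposure
#'   frequency is used; if the outcome frequency is present it is screened
#'   too, and used to orient retained palindromic SNPs.
#' @return A [HarmonizedPairs] object. `|pairs| + |dropped|` equals the size
#'   of the rsid intersection.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  stopifnot(is(exposure, "SummaryStats"), is(outcome, "SummaryStats"))
  ex <- exposure@records
  ou <- outcome@records
  shared <- intersect(ex$rsid, ou$rsid)
  ex <- ex[match(shared, ex$rsid), , drop = FALSE]
  ou <- ou[match(shared, ou$rsid), , drop = FALSE]

  n <- length(shared)
  keep <- logical(n); flipped <- logical(n); reason <- character(n)
  beta_y <- ou$beta; eaf_y <- ou$eaf

  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    pal <- is_palindromic(ea_x, oa_x)
    if (pal) {
      maf_x <- min(ex$eaf[i], 1 - ex$eaf[i])
      maf_y <- if (is.na(ou$eaf[i])) NA else min(ou$eaf[i], 1 - ou$eaf[i])
      ambiguous <- (!is.na(maf_x) && maf_x > palindrome_eaf_limit) ||
        (!is.na(maf_y) && maf_y > palindrome_eaf_limit)
      if (ambiguous) { reason[i] <- "palindromic_dropped"; next }
      same_set <- (ea_y %in% c(ea_x, oa_x)) && (oa_y %in% c(ea_x, oa_x)) &&
        ea_y != oa_y
      if (!same_set) { reason[i] <- "allele_mismatch"; next }
      # orient by frequency when available, else by reported allele labels
      if (!is.na(ex$eaf[i]) && !is.na(ou$eaf[i])) {
        same_allele <- (ex$eaf[i] > 0.5) == (ou$eaf[i] > 0.5)
      } else {
        same_allele <- ea_y == ea_x
      }
      keep[i] <- TRUE
      if (!same_allele) {
        flipped[i] <- TRUE
        beta_y[i] <- -beta_y[i]
        if (!is.na(eaf_y[i])) eaf_y[i] <- 1 - eaf_y[i]
      }
      next
    }
    cea_y <- ALLELE_COMPLEMENT[[ea_y]]; coa_y <- ALLELE_COMPLEMENT[[oa_y]]
    if (ea_y == ea_x && oa_y == oa_x) {
      keep[i] <- TRUE
    } else if (ea_y == oa_x && oa_y == ea_x) {
      keep[i] <- TRUE; flipped[i] <- TRUE
    } else if (cea_y == ea_x && coa_y == oa_x) {
      keep[i] <- TRUE
    } else if (cea_y == oa_x && coa_y == ea_x) {
      keep[i] <- TRUE; flipped[i] <- TRUE
    } else {
      reason[i] <- "allele_mismatch"
    }
    if (keep[i] && flipped[i]) {
      beta_y[i] <- -beta_y[i]
      if (!is.na(eaf_y[i])) eaf_y[i] <- 1 - eaf_y[i]
    }
  }

  pairs <- data.frame(
    rsid = shared[keep],
    beta_x = ex$beta[keep], se_x = ex$se[keep],
    beta_y = beta_y[keep], se_y = ou$se[keep],
    eaf = ex$eaf[keep],
    flipped = flipped[keep],
    proxy_substituted = FALSE,
    stringsAsFactors = FALSE)
  dropped <- data.frame(rsid = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  new("HarmonizedPairs", pairs = pairs, dropped = dropped,
      palindrome_eaf_limit = palindrome_eaf_limit)
}

#' Substitute LD proxies for missing instrument SNPs
#'
#' For each wanted rsid absent from the table, substitutes the available
#' proxy with the highest r-squared at or above `r2_min`; targets with no
#' qualifying proxy are excluded and reported. Mirrors proxy search within a
#' fixed window in a reference panel (the proxy table is a file/table input,
#' not a live LD lookup). Ties at equal r-squared break lexicographically by
#' proxy rsid.
#'
#' @param table a [SummaryStats] holding the SNPs actually available.
#' @param wanted character vector of instrument rsids.
#' @param proxies `data.frame` with columns `target`, `proxy`, `r2`.
#' @param r2_min minimum acceptable r-squared (default 0.8).
#' @return list with `table` (a [SummaryStats] restricted to usable SNPs,
#'   proxies included) and `report` (`data.frame`: `target`, `status`,
#'   `proxy`, `r2`, `reason`).
#' @export
substituteProxies <- function(table, wanted, proxies, r2_min = 0.8) {
  stopifnot(is(table, "SummaryStats"))
  if (!all(c("target", "proxy", "r2") %in% names(proxies)))
    stop("proxy table must have columns target, proxy, r2")
  if (!is.numeric(r2_min) || r2_min <= 0 || r2_min > 1)
    stop("r2_min must lie in (0, 1]")
  rec <- table@records
  have <- wanted %in% rec$rsid
  report <- data.frame(target = wanted, status = NA_character_,
                       proxy = NA_character_, r2 = NA_real_,
                       reason = NA_character_, stringsAsFactors = FALSE)
  report$status[have] <- "present"
  used <- rec[rec$rsid %in% wanted, , drop = FALSE]

  for (i in which(!have)) {
    t <- wanted[i]
    cand <- proxies[proxies$target == t & proxies$r2 >= r2_min, , drop = FALSE]
    cand <- cand[cand$proxy %in% rec$rsid, , drop = FALSE]
    if (!nrow(cand)) {
      report$status[i] <- "excluded"
      report$reason[i] <- sprintf("no proxy with r2 >= %g in table", r2_min)
      next
    }
    cand <- cand[order(-cand$r2, cand$proxy), , drop = FALSE]
    best <- cand[1, ]
    report$status[i] <- "proxied"
    report$proxy[i] <- best$proxy
    report$r2[i] <- best$r2
    used <- rbind(used, rec[rec$rsid == best$proxy, , drop = FALSE])
  }
  used <- used[!duplicated(used$rsid), , drop = FALSE]
  rownames(used) <- NULL
  out <- new("SummaryStats", trait = table@trait, unit = table@unit,
             records = used, rejected = table@rejected)
  list(table = out, report = report)
}
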