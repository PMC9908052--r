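#' @name duoMR-accessors
#' @title Accessors for duoMR classes
#' @description Accessor generics for the S4 containers: summary-statistic
#'   records, harmonized instrument pairs, drop logs, genotype dosages,
#'   phenotypes, effect estimates and their uncertainty.
#' @param x an object of the documented class.
#' @return The slot contents described for each method.
NULL

#' @rdname duoMR-accessors
#' @export
setGeneric("snpRecords", function(x) standardGeneric("snpRecords"))
#' @rdname duoMR-accessors
#' @export
setGeneric("rejectedRecords", function(x) standardGeneric("rejectedRecords"))
#' @rdname duoMR-accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))
#' @rdname duoMR-accessors
#' @export
setGeneric("traitUnit", function(x) standardGeneric("traitUnit"))
#' @rdname duoMR-accessors
#' @export
setGeneric("instrumentPairs", function(x) standardGeneric("instrumentPairs"))
#' @rdname duoMR-accessors
#' @export
setGeneric("droppedSnps", function(x) standardGeneric("droppedSnps"))
#' @rdname duoMR-accessors
#' @export
setGeneric("maternalGenotypes", function(x) standardGeneric("maternalGenotypes"))
#' @rdname duoMR-accessors
#' @export
setGeneric("offspringGenotypes", function(x) standardGeneric("offspringGenotypes"))
#' @rdname duoMR-accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
#' @rdname duoMR-accessors
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))
#' @rdname duoMR-accessors
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))
#' @rdname duoMR-accessors
#' @export
setGeneric("ci95", function(x) standardGeneric("ci95"))
#' @rdname duoMR-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname duoMR-accessors
#' @export
setGeneric("scoreWeights", function(x) standardGeneric("scoreWeights"))
#' @rdname duoMR-accessors
#' @export
setGeneric("rawScore", function(x) standardGeneric("rawScore"))
#' @rdname duoMR-accessors
#' @export
setGeneric("standardizedScore", function(x) standardGeneric("standardizedScore"))
#' @rdname duoMR-accessors
#' @export
setGeneric("meanF", function(x) standardGeneric("meanF"))
#' @rdname duoMR-accessors
#' @export
setGeneric("totalR2", function(x) standardGeneric("totalR2"))
#' @rdname duoMR-accessors
#' @export
setGeneric("cochranQValue", function(x) standardGeneric("cochranQValue"))
#' @rdname duoMR-accessors
#' @export
setGeneric("wlmEffects", function(x) standardGeneric("wlmEffects"))

#' @rdname duoMR-accessors
setMethod("snpRecords", "SummaryStats", function(x) x@records)
#' @rdname duoMR-accessors
setMethod("rejectedRecords", "SummaryStats", function(x) x@rejected)
#' @rdname duoMR-accessors
setMethod("traitName", "SummaryStats", function(x) x@trait)
#' @rdname duoMR-accessors
setMethod("traitUnit", "SummaryStats", function(x) x@unit)

#' @rdname duoMR-accessors
setMethod("instrumentPairs", "HarmonizedPairs", function(x) x@pairs)
#' @rdname duoMR-accessors
setMethod("droppedSnps", "HarmonizedPairs", function(x) x@dropped)

#' @rdname duoMR-accessors
setMethod("maternalGenotypes", "DuoCohort", function(x) assay(x, "gM"))
#' @rdname duoMR-accessors
setMethod("offspringGenotypes", "DuoCohort", function(x) assay(x, "gOff"))
#' @rdname duoMR-accessors
setMethod("phenotypes", "DuoCohort",
          function(x) as.data.frame(colData(x)))

#' @rdname duoMR-accessors
setMethod("estimate", "EffectEstimate", function(x) x@beta)
#' @rdname duoMR-accessors
setMethod("stdError", "EffectEstimate", function(x) x@se)
#' @rdname duoMR-accessors
setMethod("ci95", "EffectEstimate",
          function(x) c(low = x@ci_low, high = x@ci_high))
#' @rdname duoMR-accessors
setMethod("pValue", "EffectEstimate", function(x) x@pval)

#' @rdname duoMR-accessors
setMethod("scoreWeights", "GeneticScore",
          function(x) setNames(x@weights, x@rsids))
#' @rdname duoMR-accessors
setMethod("rawScore", "GeneticScore", function(x) x@raw)
#' @rdname duoMR-accessors
setMethod("standardizedScore", "GeneticScore", function(x) x@standardized)

#' @rdname duoMR-accessors
setMethod("meanF", "InstrumentDiagnostics", function(x) x@mean_f)
#' @rdname duoMR-accessors
setMethod("totalR2", "InstrumentDiagnostics", function(x) x@total_r2)
#' @rdname duoMR-accessors
setMethod("cochranQValue", "InstrumentDiagnostics",
          function(x) c(Q = x@q, df = x@q_df, pval = x@q_pval))

#' @rdname duoMR-accessors
setMethod("wlmEffects", "WlmEffects", function(x) x@effects)

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats: %s [%s]\n", object@trait, object@unit))
  cat(sprintf("  %d SNP records (%d rejected on read)\n",
              nrow(object@records), nrow(object@rejected)))
})

setMethod("show", "HarmonizedPairs", function(object) {
  cat(sprintf("HarmonizedPairs: %d instruments, %d dropped\n",
              nrow(object@pairs), nrow(object@dropped)))
  if (nrow(object@dropped)) {
    tab <- table(object@dropped$reason)
    for (r in names(tab)) cat(sprintf("  dropped (%s): %d\n", r, tab[[r]]))
  }
})

setMethod("show", "DuoCohort", function(object) {
  cat(sprintf("DuoCohort: %d SNPs x %d mother-offspring duos\n",
              nrow(object), ncol(object)))
  cat("  assays: ", paste(names(assays(object)), collapse = ", "), "\n")
  cat("  phenotypes: ", paste(names(colData(object)), collapse = ", "), "\n")
})

setMethod("show", "EffectEstimate", function(object) {
  cat(sprintf("%s: %.4g (95%% CI %.4g, %.4g), SE %.4g, p = %.3g [%s]\n",
              object@method, object@beta, object@ci_low, object@ci_high,
              object@se, object@pval, object@units))
})

setMethod("show", "MrEstimate", function(object) {
  callNextMethod()
  cat(sprintf("  %d SNPs", object@n_snps))
  if (!is.na(object@intercept))
    cat(sprintf("; intercept %.4g (95%% CI %.4g, %.4g), p = %.3g",
                object@intercept, object@intercept_ci_low,
                object@intercept_ci_high, object@intercept_pval))
  cat("\n")
})

setMethod("show", "TslsEstimate", function(object) {
  callNextMethod()
  cat(sprintf("  first-stage F = %.1f\n", object@f_first_stage))
})

setMethod("show", "InstrumentDiagnostics", function(object) {
  cat(sprintf(
    "InstrumentDiagnostics: %d SNPs, mean F = %.1f, total r2 = %.4f\n",
    nrow(object@per_snp), object@mean_f, object@total_r2))
  if (!is.na(object@q))
    cat(sprintf("  Cochran's Q = %.1f on %d df (p = %.3g; %s weights)\n",
                object@q, object@q_df, object@q_pval, object@weighting))
})

setMethod("show", "WlmEffects", function(object) {
  cat(sprintf("WlmEffects: maternal/fetal partition for %d SNPs (%d excluded)\n",
              nrow(object@effects), nrow(object@excluded)))
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport with stages:", paste(names(object@stages), collapse = ", "), "\n")
  cat(sprintf("  seed %s, config %s\n",
              object@provenance$seed, object@provenance$config_hash))
})
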