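#' PooledVariants: called variant sites with per-sample pooled read support
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] subclass holding one
#' row per called site and one column per pooled sample.  Assays:
#' `DP` (total read depth), `ADref`/`ADalt` (reads supporting the reference
#' and alternate alleles; `ADalt` sums alternates at multiallelic sites),
#' `GQ` (Phred-scaled genotype quality, capped at 127) and `called`
#' (logical; `FALSE` where the genotype is missing).  Row metadata carries
#' `ref`, `alt` (comma-separated when multiallelic), `qual` and
#' `variant_id` (`<contig>_<pos>`).  Column metadata must contain a
#' `species` label per sample, so replicate pools of one species can be
#' grouped by the diagnostic rules.
#'
#' @aliases PooledVariants-class
#' @exportClass PooledVariants
setClass("PooledVariants", contains = "RangedSummarizedExperiment")

setValidity("PooledVariants", function(object) {
  msg <- character()
  need <- c("DP", "ADref", "ADalt", "GQ", "called")
  have <- names(SummarizedExperiment::assays(object))
  if (!all(need %in% have))
    msg <- c(msg, paste("missing assays:", paste(setdiff(need, have), collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("ref", "alt", "variant_id") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'ref', 'alt', 'variant_id'")
  if (!"species" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'species' column")
  if (all(need %in% have)) {
    dp <- SummarizedExperiment::assay(object, "DP")
    adr <- SummarizedExperiment::assay(object, "ADref")
    ada <- SummarizedExperiment::assay(object, "ADalt")
    if (any(dp < 0, na.rm = TRUE) || any(adr < 0, na.rm = TRUE) ||
        any(ada < 0, na.rm = TRUE))
      msg <- c(msg, "depths must be non-negative")
    gq <- SummarizedExperiment::assay(object, "GQ")
    if (any(gq < 0, na.rm = TRUE))
      msg <- c(msg, "GQ must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' DosageMatrix: variants-by-samples allele proportions
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass with a single
#' `dosage` assay of alternate-allele proportions in \[0, 1\] (NA where a
#' sample has no informative reads or a missing genotype).  Rows are
#' variants, columns samples; `colData` carries `species` (and, for
#' simulated samples, `parent_a`, `parent_b` and `proportion`).  The
#' stored proportion is the alternate-allele dosage; every downstream
#' result is invariant (or label-swapped) under the complement
#' `1 - dosage`, so the orientation is a bookkeeping convention recorded
#' here rather than a modelling choice.
#'
#' @aliases DosageMatrix-class
#' @exportClass DosageMatrix
setClass("DosageMatrix", contains = "SummarizedExperiment")

setValidity("DosageMatrix", function(object) {
  msg <- character()
  if (!"dosage" %in% names(SummarizedExperiment::assays(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    if (any(d < 0 | d > 1, na.rm = TRUE))
      msg <- c(msg, "dosage values must lie in [0, 1]")
  }
  if (!"species" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'species' column")
  if (length(msg)) msg else TRUE
})

#' PCAResult: principal components of a scaled dosage matrix
#'
#' Scores are samples-by-components, loadings variants-by-components.
#' `varExplained` holds each component's share of total variance (sums
#' to 1 over the non-null components).  `center` and `scale` are the
#' per-variant training statistics needed to project new samples into
#' the same space; `dropped` lists zero-variance variants excluded
#' before decomposition.
#'
#' @aliases PCAResult-class
#' @exportClass PCAResult
setClass("PCAResult", representation(
  scores       = "matrix",
  loadings     = "matrix",
  sdev         = "numeric",
  varExplained = "numeric",
  center       = "numeric",
  scale        = "numeric",
  dropped      = "character"
))

setValidity("PCAResult", function(object) {
  msg <- character()
  if (ncol(object@scores) != ncol(object@loadings))
    msg <- c(msg, "scores and loadings disagree on component count")
  if (length(object@varExplained) != ncol(object@scores))
    msg <- c(msg, "varExplained length must match component count")
  ve <- object@varExplained
  if (length(ve) && (any(ve < -1e-12) || abs(sum(ve) - 1) > 1e-6))
    msg <- c(msg, "varExplained must be non-negative and sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PooledVariants", function(object) {
  cat(sprintf("PooledVariants: %d sites x %d samples (%d species)\n",
              nrow(object), ncol(object),
              length(unique(object$species))))
  cls <- table(classifySite(object))
  cat("  site classes:",
      paste(sprintf("%s=%d", names(cls), as.integer(cls)), collapse = ", "),
      "\n")
  methods::callNextMethod()
})

setMethod("show", "DosageMatrix", function(object) {
  cat(sprintf("DosageMatrix: %d variants x %d samples (%d species); %d missing values\n",
              nrow(object), ncol(object), length(unique(object$species)),
              sum(is.na(SummarizedExperiment::assay(object, "dosage")))))
  methods::callNextMethod()
})

setMethod("show", "PCAResult", function(object) {
  cat(sprintf("PCAResult: %d samples, %d variants, %d components\n",
              nrow(object@scores), nrow(object@loadings), ncol(object@scores)))
  ve <- round(100 * object@varExplained, 2)
  cat("  variance explained (%):", paste(ve, collapse = ", "), "\n")
  if (length(object@dropped))
    cat("  dropped zero-variance variants:", length(object@dropped), "\n")
  invisible(NULL)
})
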