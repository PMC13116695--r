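#' Accessors for diagSNP classes
#'
#' `dosage()` returns the variants-by-samples allele-proportion matrix;
#' `speciesLabels()` the per-sample species assignment; `pcaScores()`,
#' `pcaLoadings()` and `varianceExplained()` the components of a
#' [PCAResult-class].
#'
#' @param x a diagSNP object
#' @return `dosage()` a numeric matrix; `speciesLabels()` a character
#'   vector; `pcaScores()`/`pcaLoadings()` numeric matrices;
#'   `varianceExplained()` a numeric vector summing to 1.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname accessors
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' @rdname accessors
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))

#' @rdname accessors
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))

#' @rdname accessors
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @rdname accessors
#' @export
setMethod("dosage", "DosageMatrix", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
#' @export
setMethod("speciesLabels", "SummarizedExperiment", function(x)
  as.character(SummarizedExperiment::colData(x)$species))

#' @rdname accessors
#' @export
setMethod("pcaScores", "PCAResult", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("pcaLoadings", "PCAResult", function(x) x@loadings)

#' @rdname accessors
#' @export
setMethod("varianceExplained", "PCAResult", function(x) x@varExplained)
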