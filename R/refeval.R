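#' Intersect per-sample coverage into shared regions
#'
#' Maximal intervals covered in every input set.  Overlaps as short as
#' 1 bp are legal and retained.  Associative and commutative.
#'
#' @param coverage list of [GenomicRanges::GRanges] (length >= 2), or a
#'   single GRanges (returned reduced).
#' @return a reduced [GenomicRanges::GRanges] of shared intervals.
#' @export
#' @examples
#' a <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("c1", IRanges::IRanges(51, 150))
#' intersectCoverage(list(a, b))
intersectCoverage <- function(coverage) {
  if (methods::is(coverage, "GRanges"))
    return(GenomicRanges::reduce(coverage))
  stopifnot(length(coverage) >= 1L)
  Reduce(function(a, b)
    GenomicRanges::intersect(GenomicRanges::reduce(a),
                             GenomicRanges::reduce(b),
                             ignore.strand = TRUE),
    coverage)
}

#' Length statistics of shared regions
#'
#' @param shared a [GenomicRanges::GRanges] of (normalized) intervals.
#' @return list: `n_regions`, `min_length`, `median_length`,
#'   `mean_length`, `max_length` (lengths NULL when the set is empty).
#' @export
overlapStats <- function(shared) {
  w <- GenomicRanges::width(GenomicRanges::reduce(shared))
  if (!length(w))
    return(list(n_regions = 0L, min_length = NULL, median_length = NULL,
                mean_length = NULL, max_length = NULL))
  list(n_regions = length(w), min_length = min(w),
       median_length = stats::median(w), mean_length = mean(w),
       max_length = max(w))
}

#' Evaluate a reference genome's variant yield
#'
#' Computes, over the full variant set, the per-category counts used to
#' compare candidate reference genomes: site-class failures, low-depth
#' sites, a configurable site-quality predicate, fixed sites, variants
#' in regions shared by all species with complete calls, call-rate
#' passes, and the top-loading concordance between the two marker
#' filtering strategies (call-rate pass vs complete-case).  Categories
#' are each evaluated against the full set, not sequentially.
#'
#' @param pv a [PooledVariants-class] object.
#' @param coverage named list of per-sample [GenomicRanges::GRanges].
#' @param referenceId label for the report.
#' @param minDepth,tLow,tHigh,minCr cascade thresholds (see
#'   [runCascade()]).
#' @param qualityMin site-quality predicate threshold: sites with QUAL
#'   below it are counted as quality failures (an operational definition;
#'   default 20).
#' @param topK,components top-loading concordance parameters.
#' @return list of class `ReferenceEvalReport`.
#' @export
evaluateReference <- function(pv, coverage, referenceId = "reference",
                              minDepth = 10L, tLow = 0.1, tHigh = 0.9,
                              minCr = 0.5, qualityMin = 20,
                              topK = 100L, components = 1:2) {
  n <- nrow(pv)
  cls <- classifySite(pv)
  dp <- SummarizedExperiment::assay(pv, "DP")
  lowDepth <- rowSums(dp <= minDepth) > 0L
  q <- SummarizedExperiment::rowData(pv)$qual
  qualityFail <- !is.na(q) & q < qualityMin
  fixed <- !passFixed(pv, tLow, tHigh) & cls == "biallelic_snv"
  shared <- intersectCoverage(coverage)
  gr <- SummarizedExperiment::rowRanges(pv)
  inShared <- IRanges::overlapsAny(gr, shared, type = "within",
                                   ignore.strand = TRUE)
  complete <- rowSums(SummarizedExperiment::assay(pv, "called")) == ncol(pv)
  common <- inShared & complete
  crPass <- callRate(pv) >= minCr
  top <- topConcordance(pv, strategyA = crPass, strategyB = common,
                        topK = topK, components = components)
  pct <- function(k) if (n) round(100 * k / n, 2) else NA_real_
  structure(list(
    reference_id = referenceId, total_variants = n,
    indel_multiallelic = sum(cls != "biallelic_snv"),
    indel_multiallelic_pct = pct(sum(cls != "biallelic_snv")),
    low_depth = sum(lowDepth), low_depth_pct = pct(sum(lowDepth)),
    quality_fail = sum(qualityFail), quality_fail_pct = pct(sum(qualityFail)),
    fixed = sum(fixed), common_among_species = sum(common),
    cr_pass = sum(crPass),
    top_concordance = top,
    overlap_stats = overlapStats(shared)), class = "ReferenceEvalReport")
}

# Concordance of top-loading variants between two filtering strategies:
# per component, |top-k by absolute PC loading under A  intersect  same
# under B|; reported per component plus the total.
topConcordance <- function(pv, strategyA, strategyB, topK = 100L,
                           components = 1:2) {
  perPC <- stats::setNames(rep(0L, length(components)),
                           paste0("PC", components))
  topOf <- function(keep) {
    if (sum(keep) < 1L || ncol(pv) < 2L) return(NULL)
    dm <- buildDosage(pv[keep, ])
    sc <- scaleCenter(dm)
    if (!ncol(sc$matrix)) return(NULL)
    pca <- pcaDosage(sc)
    rankInformative(pca, components = components, k = topK)
  }
  ta <- topOf(strategyA); tb <- topOf(strategyB)
  if (!is.null(ta) && !is.null(tb)) {
    for (pc in names(perPC)) {
      if (!is.null(ta[[pc]]) && !is.null(tb[[pc]]))
        perPC[pc] <- length(intersect(ta[[pc]], tb[[pc]]))
    }
  }
  c(as.list(perPC), list(total = sum(perPC)))
}

#' Rank candidate reference genomes across evaluation criteria
#'
#' Criteria: fewer fixed variants is better; more variants common among
#' the species is better; longer mean shared-region length is better;
#' higher top-loading concordance is better.  Reports the per-criterion
#' rank matrix and a mean-rank ordering; no single scalar winner is
#' forced.
#'
#' @param reports list of `ReferenceEvalReport`s (length >= 1).
#' @return list with `ranks` (criteria x references matrix), `mean_rank`
#'   and `ordering` (reference ids, best mean rank first).
#' @export
rankReferences <- function(reports) {
  if (!length(reports)) stop("at least one report is required")
  ids <- vapply(reports, `[[`, character(1), "reference_id")
  crit <- rbind(
    fixed = rank(vapply(reports, `[[`, numeric(1), "fixed"),
                 ties.method = "min"),
    common_among_species = rank(-vapply(reports, `[[`, numeric(1),
                                        "common_among_species"),
                                ties.method = "min"),
    mean_overlap_length = rank(-vapply(reports, function(r)
      r$overlap_stats$mean_length %||% 0, numeric(1)), ties.method = "min"),
    top_concordance = rank(-vapply(reports, function(r)
      r$top_concordance$total, numeric(1)), ties.method = "min"))
  colnames(crit) <- ids
  mr <- colMeans(crit)
  list(ranks = crit, mean_rank = mr, ordering = ids[order(mr)])
}
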