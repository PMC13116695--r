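#' Read a multi-sample VCF into a PooledVariants object
#'
#' Parses with [VariantAnnotation::readVcf()] and restructures the
#' per-sample `GT`, `DP`, `AD` and `GQ` fields into depth matrices.
#' `ADalt` sums all alternate alleles at multiallelic sites.
#'
#' @param path VCF file (plain or gzip).
#' @param species named character vector mapping sample id to species
#'   label; every name must be a sample in the VCF.
#' @return a [PooledVariants-class] object.
#' @export
readPooledVariants <- function(path, species) {
  vcf <- VariantAnnotation::readVcf(path)
  samples <- colnames(vcf)
  if (is.null(names(species)) || !all(names(species) %in% samples))
    stop("species must be named by VCF sample ids; unknown: ",
         paste(setdiff(names(species), samples), collapse = ", "))
  vcf <- vcf[, names(species)]
  gt <- VariantAnnotation::geno(vcf)$GT
  dp <- VariantAnnotation::geno(vcf)$DP
  gq <- VariantAnnotation::geno(vcf)$GQ
  adList <- VariantAnnotation::geno(vcf)$AD
  adRef <- apply(adList, c(1, 2), function(x) as.integer(x[[1]][1]))
  adAlt <- apply(adList, c(1, 2), function(x) {
    v <- x[[1]]
    if (length(v) < 2) NA_integer_ else as.integer(sum(v[-1]))
  })
  gr <- SummarizedExperiment::rowRanges(vcf)
  refA <- as.character(VariantAnnotation::ref(vcf))
  altA <- vapply(as(VariantAnnotation::alt(vcf), "CharacterList"),
                 paste, character(1), collapse = ",")
  q <- VariantAnnotation::qual(vcf)
  ids <- paste0(as.character(GenomicRanges::seqnames(gr)), "_",
                GenomicRanges::start(gr))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    ref = refA, alt = altA, qual = q, variant_id = ids)
  names(gr) <- ids
  fix <- function(m) {
    m[is.na(m)] <- 0L
    storage.mode(m) <- "integer"
    dimnames(m) <- list(ids, names(species)); m
  }
  newPooledVariants(gr, DP = fix(dp), ADref = fix(adRef),
                    ADalt = fix(adAlt), GQ = fix(gq),
                    called = matrix(!(is.na(gt) | gt %in% c("./.", ".|.", ".")),
                                    nrow(gt), ncol(gt),
                                    dimnames = list(ids, names(species))),
                    species = unname(species))
}

#' Classify variant sites
#'
#' A site is a biallelic SNV iff it has exactly one alternate allele and
#' both alleles are single bases; more than one alternate makes it
#' multiallelic; unequal allele lengths make it an indel.
#'
#' @param x a [PooledVariants-class] object, or a character vector of
#'   reference alleles (with `alt` supplied).
#' @param alt alternate alleles, comma-separated where multiallelic.
#' @return factor with levels `biallelic_snv`, `indel`, `multiallelic`.
#' @export
classifySite <- function(x, alt = NULL) {
  if (methods::is(x, "PooledVariants")) {
    rd <- SummarizedExperiment::rowData(x)
    return(classifySite(as.character(rd$ref), as.character(rd$alt)))
  }
  refA <- x
  if (any(!nzchar(refA)) || any(!nzchar(alt)))
    stop("empty allele string")
  nAlt <- lengths(strsplit(alt, ",", fixed = TRUE))
  altLen <- nchar(alt)
  cls <- ifelse(nAlt > 1, "multiallelic",
         ifelse(nchar(refA) == 1 & altLen == 1, "biallelic_snv", "indel"))
  factor(cls, levels = c("biallelic_snv", "indel", "multiallelic"))
}

# Stage predicates: each returns a logical keep vector over rows.

passSiteClass <- function(pv) classifySite(pv) == "biallelic_snv"

passDepth <- function(pv, minDepth = 10L) {
  dp <- SummarizedExperiment::assay(pv, "DP")
  called <- SummarizedExperiment::assay(pv, "called")
  ok <- !called | (!is.na(dp) & dp > minDepth)
  rowSums(!ok) == 0L & rowSums(called) > 0L
}

passFixed <- function(pv, tLow = 0.1, tHigh = 0.9) {
  f <- altFrequencies(pv)
  apply(f, 1L, function(row) {
    row <- row[!is.na(row)]
    if (!length(row)) return(FALSE)          # no data: removed
    !(all(row >= tHigh) || all(row <= tLow))
  })
}

passCallRate <- function(pv, minCr = 0.5) {
  if (ncol(pv) == 0L) stop("call rate undefined with zero samples")
  callRate(pv) >= minCr
}

passFlank <- function(pv, coverage, window = 20L, ref = NULL) {
  gr <- SummarizedExperiment::rowRanges(pv)
  contig <- as.character(GenomicRanges::seqnames(gr))
  pos <- GenomicRanges::start(gr)
  if (methods::is(coverage, "GRanges"))
    coverage <- stats::setNames(rep(list(coverage), ncol(pv)), colnames(pv))
  keep <- rep(TRUE, length(pos))
  # coverage clause: closed window inside one covered interval, all samples
  win <- GenomicRanges::GRanges(contig,
                                IRanges::IRanges(pmax(1L, pos - window),
                                                 pos + window))
  for (cov in coverage) {
    covR <- GenomicRanges::reduce(cov)
    hit <- GenomicRanges::findOverlaps(win, covR, type = "within")
    keep <- keep & seq_along(pos) %in% S4Vectors::queryHits(hit)
  }
  # neighbor clause: no other variant site within `window` bp
  ord <- order(contig, pos)
  for (k in seq_along(ord)[-1]) {
    i <- ord[k - 1L]; j <- ord[k]
    if (contig[i] == contig[j] && pos[j] - pos[i] <= window) {
      keep[i] <- FALSE; keep[j] <- FALSE
    }
  }
  # N clause: no N in the reference window
  if (!is.null(ref)) {
    for (i in which(keep)) {
      ci <- which(names(ref) == contig[i])
      if (!length(ci)) { keep[i] <- FALSE; next }
      refSeq <- ref[[ci[1]]]
      s <- max(1L, pos[i] - window)
      e <- min(length(refSeq), pos[i] + window)
      wseq <- Biostrings::subseq(refSeq, s, e)
      if (Biostrings::letterFrequency(wseq, "N")[1] > 0) keep[i] <- FALSE
    }
  }
  keep
}

#' Per-variant call rate and the call-rate filter
#'
#' Call rate is the fraction of samples with a non-missing genotype.
#' The filter retains variants with call rate at or above `minCr`
#' (inclusive, so that 0.5 keeps variants genotyped in two of four
#' samples).
#'
#' @param pv a [PooledVariants-class] object.
#' @param minCr minimum call rate (default 0.5).
#' @return `callRate()` a numeric vector in \[0, 1\];
#'   `callRateFilter()` the retained subset.
#' @export
callRate <- function(pv) {
  if (ncol(pv) == 0L) stop("call rate undefined with zero samples")
  rowMeans(SummarizedExperiment::assay(pv, "called"))
}

#' @rdname callRate
#' @export
callRateFilter <- function(pv, minCr = 0.5) pv[passCallRate(pv, minCr), ]

#' Depth filter
#'
#' Retains variants whose depth exceeds `minDepth` (strictly) in every
#' sample with a non-missing genotype; a missing DP in a called sample
#' counts as failing.
#'
#' @inheritParams callRate
#' @param minDepth exclusive minimum depth (default 10: DP > 10).
#' @return the retained subset.
#' @export
depthFilter <- function(pv, minDepth = 10L) pv[passDepth(pv, minDepth), ]

#' Fixed-site filter
#'
#' Removes variants whose pooled alternate-allele frequencies are on the
#' same side in every species sample (all at or above `tHigh`, or all at
#' or below `tLow`): such sites cannot distinguish the species.  Sites
#' with no informative reads anywhere are removed too.
#'
#' @inheritParams callRate
#' @param tLow,tHigh frequency thresholds (defaults 0.1 / 0.9), shared
#'   with the diagnostic calling rules.
#' @return the retained subset.
#' @export
fixedFilter <- function(pv, tLow = 0.1, tHigh = 0.9)
  pv[passFixed(pv, tLow, tHigh), ]

#' Flanking-sequence filter
#'
#' Retains variants whose closed window of `window` bp on each side is
#' (i) fully inside a covered interval in every sample, (ii) free of any
#' other variant site in the table, and (iii) free of N in the reference
#' (when `ref` is supplied).  Variants on contigs absent from a sample's
#' coverage are removed.
#'
#' @inheritParams callRate
#' @param coverage a [GenomicRanges::GRanges] or a named list of them
#'   (one per sample) of covered intervals.
#' @param window flank width in bp (default 20).
#' @param ref optional reference [Biostrings::DNAStringSet] for the N
#'   clause.
#' @return the retained subset.
#' @export
flankFilter <- function(pv, coverage, window = 20L, ref = NULL)
  pv[passFlank(pv, coverage, window, ref), ]

#' Per-sample alternate-allele frequencies
#'
#' `ADalt / (ADref + ADalt)`, with NA where the genotype is missing or
#' the sample has no informative reads at the site.
#'
#' @inheritParams callRate
#' @return numeric matrix, variants x samples.
#' @export
altFrequencies <- function(pv) {
  f <- altFrequency(SummarizedExperiment::assay(pv, "ADref"),
                    SummarizedExperiment::assay(pv, "ADalt"),
                    SummarizedExperiment::assay(pv, "called"))
  dimnames(f) <- dimnames(SummarizedExperiment::assay(pv, "DP"))
  f
}

#' Run the variant-retention cascade
#'
#' Applies, in order: site-class (biallelic SNV only), depth, fixed-site,
#' flanking-sequence and call-rate filters, with per-stage accounting.
#'
#' @inheritParams flankFilter
#' @param minDepth exclusive depth minimum (default 10).
#' @param tLow,tHigh fixed-site frequency thresholds.
#' @param minCr minimum call rate (inclusive).
#' @return list with `retained` (a [PooledVariants-class]) and `report`
#'   (data.frame: stage, n_in, n_removed, n_out).
#' @export
#' @examples
#' sc <- simulateScenario(scenarioConfig(genomeLength = 20000, seed = 5))
#' res <- runCascade(asPooledVariants(sc), sc$coverage, ref = sc$ref)
#' res$report
runCascade <- function(pv, coverage, ref = NULL, minDepth = 10L,
                       tLow = 0.1, tHigh = 0.9, window = 20L,
                       minCr = 0.5) {
  stages <- list(
    site_class = function(x) passSiteClass(x),
    depth      = function(x) passDepth(x, minDepth),
    fixed      = function(x) passFixed(x, tLow, tHigh),
    flank      = function(x) passFlank(x, coverage, window, ref),
    call_rate  = function(x) passCallRate(x, minCr))
  report <- data.frame(stage = names(stages), n_in = NA_integer_,
                       n_removed = NA_integer_, n_out = NA_integer_)
  cur <- pv
  for (k in seq_along(stages)) {
    keep <- if (nrow(cur)) stages[[k]](cur) else logical(0)
    report$n_in[k] <- nrow(cur)
    report$n_removed[k] <- sum(!keep)
    report$n_out[k] <- sum(keep)
    cur <- cur[keep, ]
  }
  list(retained = cur, report = report)
}
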