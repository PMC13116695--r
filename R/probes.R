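#' Extract probe flanks around diagnostic SNPs
#'
#' For each diagnostic call, takes `flank` bp of reference sequence on
#' each side of the SNP (truncated and flagged at contig ends), flags
#' candidates whose flanks contain another variant site or an N, and
#' reports the longest variant-free stretch adjacent to the SNP on each
#' side against `minClear` (primer-binding regions of 18-25 bp free of
#' variation are the usual design requirement; the default 25 is the
#' conservative end).
#'
#' @param calls data.frame of diagnostic calls with a `variant_id`
#'   column (`<contig>_<pos>`), as returned by [callSpeciesSpecific()] /
#'   [callPairwise()].
#' @param ref reference [Biostrings::DNAStringSet].
#' @param allVariants every known variant site, as a
#'   [PooledVariants-class] or a character vector of `<contig>_<pos>`
#'   ids; used for the clean-flank check.
#' @param flank flank length in bp (default 50).
#' @param minClear required variant-free stretch in bp (default 25).
#' @return data.frame: one row per candidate with flank sequences,
#'   lengths, truncation/clean flags and per-side clear runs.
#' @export
extractFlanks <- function(calls, ref, allVariants = NULL, flank = 50L,
                          minClear = 25L) {
  ids <- calls$variant_id
  contig <- sub("_[0-9]+$", "", ids)
  pos <- as.integer(sub(".*_", "", ids))
  allIds <- if (is.null(allVariants)) ids
            else if (methods::is(allVariants, "PooledVariants"))
              SummarizedExperiment::rowData(allVariants)$variant_id
            else as.character(allVariants)
  allContig <- sub("_[0-9]+$", "", allIds)
  allPos <- as.integer(sub(".*_", "", allIds))
  out <- lapply(seq_along(ids), function(i) {
    ci <- which(names(ref) == contig[i])
    if (!length(ci))
      stop(sprintf("contig '%s' not found in the reference", contig[i]))
    refSeq <- ref[[ci[1]]]
    L <- length(refSeq)
    ls <- max(1L, pos[i] - flank); le <- pos[i] - 1L
    rs <- pos[i] + 1L; re <- min(L, pos[i] + flank)
    left <- if (le >= ls) as.character(Biostrings::subseq(refSeq, ls, le)) else ""
    right <- if (re >= rs) as.character(Biostrings::subseq(refSeq, rs, re)) else ""
    d <- allPos[allContig == contig[i]] - pos[i]
    d <- d[d != 0L]
    leftClear <- min(c(-d[d < 0L] - 1L, flank))
    rightClear <- min(c(d[d > 0L] - 1L, flank))
    hasN <- grepl("N", left, fixed = TRUE) || grepl("N", right, fixed = TRUE)
    neighborIn <- any(abs(d) <= flank)
    data.frame(
      variant_id = ids[i], contig = contig[i], position = pos[i],
      ref_base = as.character(Biostrings::subseq(refSeq, pos[i], pos[i])),
      left_flank = left, right_flank = right,
      left_length = nchar(left), right_length = nchar(right),
      truncated = nchar(left) < flank || nchar(right) < flank,
      clean = !neighborIn && !hasN,
      left_clear = min(leftClear, nchar(left)),
      right_clear = min(rightClear, nchar(right)),
      meets_min_clear = min(leftClear, nchar(left)) >= minClear &&
                        min(rightClear, nchar(right)) >= minClear)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write probe candidates as FASTA
#'
#' One record per candidate: `left_flank + ref_base + right_flank`, with
#' the SNP position and flank lengths encoded in the header.
#'
#' @param probes output of [extractFlanks()].
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
writeProbesFasta <- function(probes, path) {
  seqs <- Biostrings::DNAStringSet(paste0(probes$left_flank, probes$ref_base,
                                          probes$right_flank))
  names(seqs) <- sprintf("%s|pos=%d|snp_offset=%d|clean=%s",
                         probes$variant_id, probes$position,
                         probes$left_length + 1L, probes$clean)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
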