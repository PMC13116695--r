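#' Read trimming and length filtering
#'
#' Applies the two parameterized pre-alignment rules: remove the first
#' `headTrim` bases from the 5' end of every read, then discard reads
#' whose remaining length is below `minLength`.  The trim is applied
#' before the length test, so a 55 bp read trimmed by 10 is discarded at
#' the default 50 bp minimum.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param headTrim bases removed from the 5' end (default 10).
#' @param minLength minimum surviving read length (default 50).
#' @return list with `reads` (the surviving, trimmed set) and `report`
#'   (read counts and mean lengths before and after).
#' @export
#' @examples
#' r <- generateReads(generateReference(5000, 1), 50, 150, seed = 2)
#' trimAndFilter(r)$report
trimAndFilter <- function(reads, headTrim = 10L, minLength = 50L) {
  stopifnot(headTrim >= 0, minLength >= 0)
  nIn <- length(reads)
  lenIn <- if (nIn) Biostrings::width(reads) else integer(0)
  if (nIn) {
    keepAfterTrim <- pmax(lenIn - headTrim, 0L)
    trimmed <- Biostrings::subseq(reads, start = pmin(headTrim + 1L,
                                                      lenIn + 1L))
    keep <- keepAfterTrim >= minLength & keepAfterTrim > 0L
    out <- trimmed[keep]
  } else out <- reads
  lenOut <- if (length(out)) Biostrings::width(out) else integer(0)
  report <- list(
    reads_in = nIn, reads_out = length(out),
    reads_discarded = nIn - length(out),
    mean_length_in = if (nIn) mean(lenIn) else NA_real_,
    mean_length_out = if (length(out)) mean(lenOut) else NA_real_,
    head_trim = as.integer(headTrim), min_length = as.integer(minLength))
  list(reads = out, report = report)
}

#' Read a FASTQ file as quality-scaled reads
#'
#' Thin wrapper over [Biostrings::readQualityScaledDNAStringSet()] (Sanger
#' encoding) that, on failure, locates and names the first malformed
#' record.
#'
#' @param path FASTQ file (plain or gzip).
#' @return a [Biostrings::QualityScaledDNAStringSet].
#' @export
readFastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("malformed FASTQ record %d in '%s': truncated record",
                 length(lines) %/% 4L + 1L, path), call. = FALSE)
  for (i in seq_len(length(lines) %/% 4L)) {
    block <- lines[(i - 1L) * 4L + 1:4]
    bad <- !startsWith(block[1], "@") || !startsWith(block[3], "+") ||
      nchar(block[2]) != nchar(block[4])
    if (bad)
      stop(sprintf("malformed FASTQ record %d in '%s'", i, path),
           call. = FALSE)
  }
  # Biostrings warns about dropping its own internal metadata columns
  suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
}

#' Write quality-scaled reads as FASTQ
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path output file; `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}
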