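# Shared helpers: small scenario builder and brute-force oracles.

smallConfig <- function(seed, noise = "noiseless", ...) {
  args <- list(genomeLength = 20000L, nSpecificPerSpecies = 2L,
               nPairwisePerPair = 1L, nFixed = 3L, nLowDepth = 2L,
               nIndel = 2L, nMultiallelic = 2L, nEdgeProximal = 2L,
               nMissingCall = 2L, noise = noise, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(scenarioConfig, args)
}

# Construct a PooledVariants object from explicit per-sample frequencies
# at a fixed depth, for rule-level tests.
pvFromFreq <- function(freq, species, depth = 30L, contig = "chrT",
                       positions = NULL, refAllele = NULL, altAllele = NULL,
                       called = NULL, gapBp = 1000L) {
  freq <- as.matrix(freq)
  n <- nrow(freq); m <- ncol(freq)
  if (is.null(positions)) positions <- seq(gapBp, by = gapBp, length.out = n)
  if (is.null(refAllele)) refAllele <- rep("A", n)
  if (is.null(altAllele)) altAllele <- rep("G", n)
  if (is.null(called)) called <- matrix(TRUE, n, m)
  alt <- matrix(as.integer(round(freq * depth)), n, m)
  dp <- matrix(as.integer(depth), n, m)
  ids <- paste0(contig, "_", positions)
  dimnames(alt) <- dimnames(dp) <- list(ids, colnames(freq))
  gr <- GenomicRanges::GRanges(contig,
          IRanges::IRanges(positions, width = nchar(refAllele)))
  names(gr) <- ids
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    ref = refAllele, alt = altAllele, qual = rep(100, n), variant_id = ids)
  diagSNP:::newPooledVariants(gr, DP = dp, ADref = dp - alt, ADalt = alt,
                              GQ = matrix(99L, n, m, dimnames = dimnames(dp)),
                              called = matrix(called, n, m,
                                              dimnames = dimnames(dp)),
                              species = species)
}

# Per-base brute-force intersection of coverage sets on one contig.
bruteIntersect <- function(covList, genomeLength) {
  covered <- rep(TRUE, genomeLength)
  for (gr in covList) {
    mask <- rep(FALSE, genomeLength)
    for (i in seq_along(gr)) {
      s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
      mask[seq(s, min(e, genomeLength))] <- TRUE
    }
    covered <- covered & mask
  }
  covered
}

# Per-base brute-force flank predicate (coverage + neighbor + N clauses).
bruteFlank <- function(pv, coverage, window, ref) {
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(pv))
  L <- length(ref[[1]])
  refChars <- strsplit(as.character(ref[[1]]), "")[[1]]
  vapply(seq_along(pos), function(i) {
    lo <- pos[i] - window; hi <- pos[i] + window
    if (lo < 1) lo <- 1
    if (hi > L) return(FALSE)
    for (cov in coverage) {
      mask <- rep(FALSE, L)
      for (k in seq_along(cov))
        mask[seq(GenomicRanges::start(cov)[k],
                 min(GenomicRanges::end(cov)[k], L))] <- TRUE
      if (!all(mask[lo:hi])) return(FALSE)
      # the closed window must also sit inside ONE interval: contiguity
      # is implied by all bases covered after reduce()
    }
    if (any(abs(pos[-i] - pos[i]) <= window)) return(FALSE)
    if (any(refChars[lo:hi] == "N")) return(FALSE)
    TRUE
  }, logical(1))
}

# Eigendecomposition PCA oracle: variance proportions of X'X / (n-1).
pcaOracle <- function(xs) {
  ev <- eigen(stats::cov(xs), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  ev / sum(ev)
}
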