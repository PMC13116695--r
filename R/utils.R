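# Internal helpers shared across modules.

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All stochastic operations in the
# package take explicit seeds and route through here: no hidden global
# state.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stage tag, kept inside the
# 32-bit integer range.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% .Machine$integer.max)
}

# VCF positions are 1-based; BED intervals 0-based half-open.  These two
# converters are the only place the conversion happens.
posToBed <- function(pos) c(start = pos - 1L, end = pos)
bedToGRanges <- function(df) {
  GenomicRanges::GRanges(df[[1]], IRanges::IRanges(start = df[[2]] + 1L,
                                                   end = df[[3]]))
}
grangesToBed <- function(gr) {
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

# Phred-scaled genotype quality for a pooled sample: posterior error of
# the best of three genotype classes (hom-ref, het, hom-alt) under a
# binomial read model, capped at 127 as emitted by common callers.
phredGQ <- function(altReads, depth, cap = 127L) {
  stopifnot(length(altReads) == length(depth))
  out <- integer(length(depth))
  fClass <- c(0.001, 0.5, 0.999)
  for (i in seq_along(depth)) {
    if (is.na(depth[i]) || depth[i] == 0) { out[i] <- 0L; next }
    lik <- dbinom(altReads[i], depth[i], fClass)
    err <- 1 - max(lik) / sum(lik)
    out[i] <- as.integer(min(cap, round(-10 * log10(max(err, 1e-13)))))
  }
  out
}

# Per-sample alternate-allele proportion from allele depths; NA where the
# genotype is missing or the site has no informative reads in that sample.
altFrequency <- function(adRef, adAlt, called = NULL) {
  tot <- adRef + adAlt
  f <- ifelse(tot > 0, adAlt / tot, NA_real_)
  if (!is.null(called)) f[!called] <- NA_real_
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a
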