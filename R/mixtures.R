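#' Simulate pure replicate samples
#'
#' Replicates each species' dosage profile `nPerSpecies` times.  In
#' noiseless mode the profile is copied exactly; in binomial mode each
#' dosage is resampled as a read pool of the given depth.
#'
#' @param profiles variants x species dosage matrix (see
#'   [speciesProfiles()]).
#' @param nPerSpecies replicates per species (default 15, giving 60 pure
#'   samples for four species).
#' @param noise `"noiseless"` or `"binomial"`.
#' @param depth read depth for binomial resampling (default 30).
#' @param seed integer seed.
#' @return a [DosageMatrix-class] with `parent_a`, `parent_b` (NA) and
#'   `proportion` (1) in its column metadata.
#' @export
#' @examples
#' fx <- diagFixture()
#' prof <- speciesProfiles(fx$dosage)
#' ncol(simulatePure(prof))  # 60
simulatePure <- function(profiles, nPerSpecies = 15L,
                         noise = c("noiseless", "binomial"),
                         depth = 30L, seed = 1L) {
  noise <- match.arg(noise)
  if (nPerSpecies < 0) stop("nPerSpecies must be non-negative")
  if (!ncol(profiles)) stop("profiles are empty")
  species <- rep(colnames(profiles), each = nPerSpecies)
  vals <- profiles[, species, drop = FALSE]
  colnames(vals) <- sprintf("%s_pure%02d", species,
                            rep(seq_len(nPerSpecies), ncol(profiles)))
  if (noise == "binomial" && length(vals))
    vals <- withSeed(seed, resampleDosage(vals, depth))
  dm <- DosageMatrix(vals, species = species)
  SummarizedExperiment::colData(dm)$parent_a <- species
  SummarizedExperiment::colData(dm)$parent_b <- NA_character_
  SummarizedExperiment::colData(dm)$proportion <- 1
  dm
}

#' Simulate pairwise species mixtures
#'
#' For each unordered species pair and mixing proportion `p`, the mixture
#' dosage is the convex combination `p * A + (1 - p) * B`, optionally
#' followed by binomial resampling.  Four species and the default
#' proportions give 6 pairs x 3 proportions = 18 mixed samples.
#'
#' @inheritParams simulatePure
#' @param proportions proportions of the first parent (default
#'   `c(0.25, 0.5, 0.75)`), each in \[0, 1\].
#' @param pairs optional 2-row character matrix of parent pairs
#'   (default: all unordered pairs).
#' @return a [DosageMatrix-class] with `parent_a`, `parent_b` and
#'   `proportion` column metadata (`species` is NA for mixtures).
#' @export
simulateMixtures <- function(profiles, proportions = c(0.25, 0.5, 0.75),
                             pairs = NULL,
                             noise = c("noiseless", "binomial"),
                             depth = 30L, seed = 1L) {
  noise <- match.arg(noise)
  if (any(proportions < 0 | proportions > 1))
    stop("proportions must lie in [0, 1]")
  if (ncol(profiles) < 2L) stop("mixtures require at least two species")
  if (is.null(pairs)) pairs <- utils::combn(colnames(profiles), 2)
  cols <- list(); pa <- pb <- character(0); pp <- numeric(0)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    for (p in proportions) {
      cols[[length(cols) + 1L]] <- p * profiles[, a] + (1 - p) * profiles[, b]
      pa <- c(pa, a); pb <- c(pb, b); pp <- c(pp, p)
    }
  }
  vals <- do.call(cbind, cols)
  colnames(vals) <- sprintf("%s_%s_p%02d", pa, pb, round(100 * pp))
  rownames(vals) <- rownames(profiles)
  if (noise == "binomial")
    vals <- withSeed(seed, resampleDosage(vals, depth))
  dm <- DosageMatrix(vals, species = rep(NA_character_, ncol(vals)))
  SummarizedExperiment::colData(dm)$parent_a <- pa
  SummarizedExperiment::colData(dm)$parent_b <- pb
  SummarizedExperiment::colData(dm)$proportion <- pp
  dm
}

# Resample each dosage value as alt reads / depth ~ Binomial(depth, f)/depth.
resampleDosage <- function(vals, depth) {
  out <- vals
  ok <- !is.na(vals)
  out[ok] <- rbinom(sum(ok), depth, vals[ok]) / depth
  out
}
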