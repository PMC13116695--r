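#' Build the dosage matrix from filtered variants
#'
#' Dosage is the per-sample alternate-allele proportion
#' `ADalt / (ADref + ADalt)`, NA where the genotype is missing or no
#' informative reads cover the site.
#'
#' @param pv a non-empty [PooledVariants-class] object.
#' @return a [DosageMatrix-class] (variants x samples).
#' @export
buildDosage <- function(pv) {
  if (nrow(pv) == 0L) stop("filtered variant table is empty")
  d <- altFrequencies(pv)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = d),
    rowRanges = SummarizedExperiment::rowRanges(pv),
    colData = SummarizedExperiment::colData(pv))
  methods::new("DosageMatrix", se)
}

#' Construct a DosageMatrix from a plain frequency matrix
#'
#' Convenience constructor for matrices that do not originate from a
#' VCF, e.g. transcribed published allele-frequency tables or simulated
#' profiles.
#'
#' @param values numeric matrix in \[0, 1\], variants x samples.
#' @param species character vector of per-sample species labels.
#' @param variantIds optional row ids (default from rownames).
#' @return a [DosageMatrix-class].
#' @export
DosageMatrix <- function(values, species, variantIds = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(variantIds)) variantIds <- paste0("v", seq_len(nrow(values)))
  rownames(values) <- variantIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = values),
    colData = S4Vectors::DataFrame(species = species,
                                   row.names = colnames(values)))
  methods::new("DosageMatrix", se)
}

#' Center and scale the dosage matrix for PCA and distances
#'
#' Transposes to samples x variants, centers and unit-scales each
#' variant column (sample standard deviation), drops zero-variance
#' columns, and imputes missing values to 0 after centering (the column
#' mean).  Missing values are excluded from the moments.
#'
#' @param dm a [DosageMatrix-class] or a samples-x-variants numeric
#'   matrix.
#' @param collapseReplicates average replicate samples of one species
#'   into a single row per species before scaling (used for the
#'   species-level PCA and distance analyses).
#' @return list with `matrix` (scaled samples x variants), `center`,
#'   `scale` (per retained variant), `dropped` (zero-variance variant
#'   ids) and `species` (per-row labels).
#' @export
scaleCenter <- function(dm, collapseReplicates = FALSE) {
  if (methods::is(dm, "DosageMatrix")) {
    x <- t(dosage(dm))
    species <- speciesLabels(dm)
  } else {
    x <- as.matrix(dm)
    species <- rownames(x) %||% paste0("s", seq_len(nrow(x)))
  }
  if (collapseReplicates && anyDuplicated(species)) {
    x <- do.call(rbind, lapply(split(seq_len(nrow(x)), species)[unique(species)],
                               function(i) colMeans(x[i, , drop = FALSE],
                                                    na.rm = TRUE)))
    species <- rownames(x)
  }
  if (!nrow(x) || !ncol(x))
    return(list(matrix = x, center = numeric(0), scale = numeric(0),
                dropped = character(0), species = species))
  ctr <- apply(x, 2L, mean, na.rm = TRUE)
  sdv <- apply(x, 2L, stats::sd, na.rm = TRUE)
  keep <- !is.na(sdv) & sdv > 0
  dropped <- colnames(x)[!keep] %||% character(0)
  x <- x[, keep, drop = FALSE]
  ctr2 <- ctr[keep]; sdv2 <- sdv[keep]
  xs <- sweep(sweep(x, 2L, ctr2, "-"), 2L, sdv2, "/")
  xs[is.na(xs)] <- 0
  rownames(xs) <- species
  list(matrix = xs, center = ctr2, scale = sdv2, dropped = dropped,
       species = species)
}

#' Principal component analysis of the scaled dosage matrix
#'
#' Singular value decomposition of the samples-by-variants matrix (via
#' [stats::prcomp()] on the pre-scaled input).  Component signs are
#' fixed so each loading vector's largest-magnitude entry is positive.
#' Variance proportions are computed over all components and sum to 1;
#' with n samples at most n - 1 are nonzero.
#'
#' @param scaled output of [scaleCenter()] (or a plain pre-scaled
#'   samples x variants matrix).
#' @return a [PCAResult-class].
#' @export
#' @examples
#' fx <- diagFixture()
#' pca <- pcaDosage(scaleCenter(fx$dosage, collapseReplicates = TRUE))
#' round(100 * varianceExplained(pca), 2)
pcaDosage <- function(scaled) {
  if (is.matrix(scaled))
    scaled <- list(matrix = scaled, center = rep(0, ncol(scaled)),
                   scale = rep(1, ncol(scaled)), dropped = character(0),
                   species = rownames(scaled))
  x <- scaled$matrix
  if (nrow(x) < 2L) stop("PCA requires at least two samples")
  if (ncol(x) < 1L) stop("PCA requires at least one variant")
  p <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  # sign convention: largest |loading| entry positive per component
  for (k in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, k]))
    if (p$rotation[i, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  methods::new("PCAResult", scores = p$x, loadings = p$rotation,
               sdev = p$sdev, varExplained = ve,
               center = scaled$center, scale = scaled$scale,
               dropped = scaled$dropped)
}

#' Rank variants by absolute PCA loading
#'
#' Per requested component, variants sorted by absolute loading
#' descending; ties broken by variant id (contig, position) ascending.
#'
#' @param pca a [PCAResult-class].
#' @param components component indices (default 1:3).
#' @param k list length cap (default 100); larger than the variant count
#'   returns the full list.
#' @return named list (`PC1`, ...) of ranked variant-id vectors.
#' @export
rankInformative <- function(pca, components = 1:3, k = 100L) {
  if (k <= 0) stop("k must be positive")
  ld <- pcaLoadings(pca)
  components <- components[components <= ncol(ld)]
  out <- lapply(components, function(pc) {
    ids <- rownames(ld) %||% as.character(seq_len(nrow(ld)))
    ord <- order(-abs(ld[, pc]), ids)
    utils::head(ids[ord], k)
  })
  stats::setNames(out, paste0("PC", components))
}

# Label each species side at one variant: LOW if every replicate
# frequency <= tLow, HIGH if every replicate >= tHigh, else AMBIGUOUS
# (NA frequencies are ambiguous).
sideLabels <- function(freqRow, species, tLow, tHigh) {
  vapply(unique(species), function(sp) {
    f <- freqRow[species == sp]
    if (anyNA(f)) return("AMBIGUOUS")
    if (all(f <= tLow)) "LOW"
    else if (all(f >= tHigh)) "HIGH"
    else "AMBIGUOUS"
  }, character(1))
}

diagnosticInput <- function(freqs) {
  if (methods::is(freqs, "DosageMatrix"))
    list(values = dosage(freqs), species = speciesLabels(freqs))
  else if (methods::is(freqs, "PooledVariants"))
    list(values = altFrequencies(freqs), species = speciesLabels(freqs))
  else {
    m <- as.matrix(freqs)
    list(values = m, species = colnames(m))
  }
}

#' Species-specific diagnostic calls
#'
#' A variant is diagnostic for one species when every species can be
#' labeled LOW (all replicates at or below `tLow`) or HIGH (all at or
#' above `tHigh`) and exactly one species sits alone on its side — the
#' variant allele fixed or highly frequent in one species and absent or
#' rare in the others, or the mirror image.
#'
#' @param freqs a [DosageMatrix-class], a [PooledVariants-class], or a
#'   variants-x-samples numeric matrix with per-column species labels in
#'   `species`.
#' @param species per-sample species labels (ignored when `freqs`
#'   carries its own).
#' @param tLow,tHigh frequency thresholds (defaults 0.1 / 0.9).
#' @return data.frame: `variant_id`, `call_type`, `target`, per-species
#'   side labels, `t_low`, `t_high`.  Zero rows when nothing is called.
#' @export
#' @examples
#' fx <- diagFixture("table4")
#' calls <- callSpeciesSpecific(fx$dosage)
#' table(calls$target)
callSpeciesSpecific <- function(freqs, species = NULL, tLow = 0.1,
                                tHigh = 0.9) {
  inp <- diagnosticInput(freqs)
  if (!is.null(species)) inp$species <- species
  diagnosticCalls(inp$values, inp$species, tLow, tHigh,
                  type = "species_specific")
}

#' Pairwise diagnostic calls
#'
#' A variant differentiates two species pairs when every species is
#' unambiguously LOW or HIGH and exactly two species sit on each side.
#' Pair labels are joined with a multiplication sign in canonical
#' species order.
#'
#' @inheritParams callSpeciesSpecific
#' @return data.frame: `variant_id`, `call_type`, `low_pair`,
#'   `high_pair`, per-species side labels, `t_low`, `t_high`.
#' @export
#' @examples
#' fx <- diagFixture("table5")
#' callPairwise(fx$dosage)[, c("variant_id", "low_pair", "high_pair")]
callPairwise <- function(freqs, species = NULL, tLow = 0.1, tHigh = 0.9) {
  inp <- diagnosticInput(freqs)
  if (!is.null(species)) inp$species <- species
  diagnosticCalls(inp$values, inp$species, tLow, tHigh, type = "pairwise")
}

diagnosticCalls <- function(values, species, tLow, tHigh, type) {
  stopifnot(length(species) == ncol(values))
  usp <- unique(species)
  if (length(usp) < 2L) stop("at least two species are required")
  ids <- rownames(values) %||% paste0("v", seq_len(nrow(values)))
  rows <- lapply(seq_len(nrow(values)), function(i) {
    lab <- sideLabels(values[i, ], species, tLow, tHigh)
    if (any(lab == "AMBIGUOUS")) return(NULL)
    nLow <- sum(lab == "LOW"); nHigh <- sum(lab == "HIGH")
    if (type == "species_specific") {
      if (!(nLow == 1L || nHigh == 1L) || nLow == 0L || nHigh == 0L)
        return(NULL)
      target <- usp[lab == if (nLow == 1L) "LOW" else "HIGH"]
      base <- data.frame(variant_id = ids[i], call_type = "species_specific",
                         target = target)
    } else {
      if (!(nLow == 2L && nHigh == 2L)) return(NULL)
      base <- data.frame(variant_id = ids[i], call_type = "pairwise",
                         low_pair = paste(usp[lab == "LOW"],
                                          collapse = " × "),
                         high_pair = paste(usp[lab == "HIGH"],
                                           collapse = " × "))
    }
    cbind(base, as.data.frame(as.list(lab)), t_low = tLow, t_high = tHigh)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    cols <- if (type == "species_specific")
      c("variant_id", "call_type", "target") else
      c("variant_id", "call_type", "low_pair", "high_pair")
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Euclidean distances and clustering order
#'
#' Pairwise Euclidean distances over the scaled matrix via
#' [stats::dist()], with complete-linkage hierarchical clustering
#' supplying the leaf order.
#'
#' @param scaled output of [scaleCenter()] or a pre-scaled samples x
#'   variants matrix.
#' @return list with `distances` (symmetric matrix, zero diagonal),
#'   `order` (leaf order labels) and `hclust`.
#' @export
euclideanMatrix <- function(scaled) {
  x <- if (is.matrix(scaled)) scaled else scaled$matrix
  if (nrow(x) < 2L) stop("distances require at least two samples")
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = "complete")
  list(distances = as.matrix(d), order = rownames(x)[hc$order] %||% hc$order,
       hclust = hc)
}

#' Per-species mean dosage profiles
#'
#' Averages replicate samples of each species; the substrate for the
#' mixture simulator and the species-level PCA.
#'
#' @param dm a [DosageMatrix-class].
#' @return numeric matrix, variants x species.
#' @export
speciesProfiles <- function(dm) {
  d <- dosage(dm)
  sp <- speciesLabels(dm)
  out <- vapply(unique(sp), function(s)
    rowMeans(d[, sp == s, drop = FALSE], na.rm = TRUE), numeric(nrow(d)))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(unique(sp)),
                                       dimnames = list(rownames(d),
                                                       unique(sp)))
  out
}
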