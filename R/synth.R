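#' Scenario configuration for the synthetic pooled-sequencing generator
#'
#' Describes a complete multi-species pooled-sequencing scenario: how many
#' diagnostic and nuisance variants to plant, the genome size, the
#' sequencing depth and read length, and the noise model.  Defaults mirror
#' the study design the package was built around: four pooled species
#' samples sequenced PE150 at ~30x mean depth, with allele-frequency
#' profiles in which most planted frequencies are fixed (0 or 1) and a
#' minority are near-fixed, as observed in real pooled panels.
#'
#' @param species character vector of species labels (>= 1).
#' @param replicates named integer vector: pooled replicate count per
#'   species (default 1 each; a duplicated pool, as for the TH04 sample in
#'   the motivating study, is expressed as `2`).
#' @param genomeLength genome size in bp.
#' @param nSpecificPerSpecies species-specific diagnostic variants planted
#'   per species.
#' @param nPairwisePerPair pairwise diagnostic variants planted per
#'   unordered species pair.
#' @param nFixed,nLowDepth,nIndel,nMultiallelic,nEdgeProximal,nMissingCall
#'   nuisance variants per category; each is designed to be removed by a
#'   specific stage of the filtering cascade.
#' @param meanDepth simulated read depth per sample (default 30).
#' @param readLength simulated read length in bp (default 150).
#' @param noise `"noiseless"` (allele depths are the rounded expectation)
#'   or `"binomial"` (alternate reads ~ Binomial(depth, frequency)).
#' @param seed integer seed controlling every random draw in the scenario.
#' @return a validated list of class `ScenarioConfig`.
#' @export
#' @examples
#' cfg <- scenarioConfig(genomeLength = 20000, seed = 7)
#' cfg$meanDepth
scenarioConfig <- function(species = c("PA03", "TD01", "TP02", "TH04"),
                           replicates = NULL,
                           genomeLength = 50000L,
                           nSpecificPerSpecies = 3L,
                           nPairwisePerPair = 1L,
                           nFixed = 6L,
                           nLowDepth = 4L,
                           nIndel = 4L,
                           nMultiallelic = 4L,
                           nEdgeProximal = 4L,
                           nMissingCall = 4L,
                           meanDepth = 30L,
                           readLength = 150L,
                           noise = c("noiseless", "binomial"),
                           seed = 1L) {
  noise <- match.arg(noise)
  if (length(species) < 1L || anyDuplicated(species))
    stop("species labels must be non-empty and unique")
  if (is.null(replicates))
    replicates <- stats::setNames(rep(1L, length(species)), species)
  if (is.null(names(replicates)) || !setequal(names(replicates), species))
    stop("replicates must be named by species")
  replicates <- replicates[species]
  counts <- c(nSpecificPerSpecies, nPairwisePerPair, nFixed, nLowDepth,
              nIndel, nMultiallelic, nEdgeProximal, nMissingCall)
  if (any(counts < 0)) stop("variant counts must be non-negative")
  if (meanDepth < 1) stop("meanDepth must be >= 1")
  if (readLength < 1) stop("readLength must be >= 1")
  if (genomeLength < 1) stop("genomeLength must be >= 1")
  if (nPairwisePerPair > 0 && length(species) < 2)
    stop("pairwise variants require at least two species")
  structure(list(
    species = species, replicates = as.integer(replicates),
    genomeLength = as.integer(genomeLength),
    nSpecificPerSpecies = as.integer(nSpecificPerSpecies),
    nPairwisePerPair = as.integer(nPairwisePerPair),
    nFixed = as.integer(nFixed), nLowDepth = as.integer(nLowDepth),
    nIndel = as.integer(nIndel), nMultiallelic = as.integer(nMultiallelic),
    nEdgeProximal = as.integer(nEdgeProximal),
    nMissingCall = as.integer(nMissingCall),
    meanDepth = as.integer(meanDepth), readLength = as.integer(readLength),
    noise = noise, seed = as.integer(seed)),
    class = "ScenarioConfig")
}

#' Generate a random reference contig
#'
#' Uniform base composition over A/C/G/T; deterministic for a fixed seed.
#' `nRuns` optionally places runs of N (as `IRanges`-style start/width
#' pairs) to exercise the N-aware flank logic.
#'
#' @param length contig length in bp (>= 1).
#' @param seed integer seed.
#' @param contigId contig name.
#' @param nRuns optional two-column matrix `(start, width)` of N runs.
#' @return a [Biostrings::DNAStringSet] of length 1.
#' @export
generateReference <- function(length, seed, contigId = "ctg1", nRuns = NULL) {
  if (length(length) != 1L || is.na(length) || length < 1)
    stop("reference length must be a positive integer")
  bases <- withSeed(seed,
    sample(c("A", "C", "G", "T"), length, replace = TRUE))
  if (!is.null(nRuns)) {
    nRuns <- as.matrix(nRuns)
    for (i in seq_len(nrow(nRuns))) {
      idx <- seq(nRuns[i, 1], length.out = nRuns[i, 2])
      idx <- idx[idx >= 1 & idx <= length]
      bases[idx] <- "N"
    }
  }
  ref <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(ref) <- contigId
  ref
}

# Draw a "low"-side (near 0) or "high"-side (near 1) pooled allele
# frequency.  Most planted frequencies are exactly fixed; a minority are
# near-fixed with offsets concentrated near the boundary, matching the
# profile of real pooled diagnostic panels (lows <= ~0.05, highs >= ~0.91).
drawFreq <- function(n, side, pExact = 0.8, maxOff = 0.1) {
  off <- ifelse(runif(n) < pExact, 0, maxOff * rbeta(n, 1, 3))
  if (side == "low") off else 1 - off
}

# Nominal coverage-gap layout for a genome: evenly spaced gaps of fixed
# width, used both to carve per-sample coverage and to site edge-proximal
# variants.
gapLayout <- function(genomeLength, nGaps, gapWidth = 60L) {
  if (nGaps == 0L) return(cbind(start = integer(0), end = integer(0)))
  centers <- round(genomeLength * seq_len(nGaps) / (nGaps + 1))
  start <- pmax(2L, as.integer(centers - gapWidth %/% 2))
  cbind(start = start, end = pmin(genomeLength - 1L,
                                  start + gapWidth - 1L))
}

#' Plant diagnostic and nuisance variants on a reference
#'
#' Chooses positions (with clean margins where the category requires
#' them), alleles and true per-species pooled allele frequencies for
#' every requested variant category, and records them in a truth table.
#' Species-specific variants put exactly one species on the minority side
#' (<= 0.1 vs >= 0.9); pairwise variants split the species two against
#' two; fixed variants are high in all species; edge-proximal variants
#' sit within 20 bp of a coverage-gap boundary.
#'
#' @param ref reference from [generateReference()].
#' @param cfg a [scenarioConfig()].
#' @return list with `truth` (a [S4Vectors::DataFrame]: variant_id,
#'   contig, position, ref, alt, category, target_species, low_pair,
#'   high_pair, low_depth_sample, missing_samples), `profiles`
#'   (variants x species true-frequency matrix) and `gaps` (nominal
#'   coverage gaps).
#' @export
plantVariants <- function(ref, cfg) {
  stopifnot(inherits(cfg, "ScenarioConfig"))
  L <- Biostrings::width(ref)[1]
  contig <- names(ref)[1]
  sp <- cfg$species
  nsp <- length(sp)
  pairs <- if (nsp >= 2) utils::combn(sp, 2) else matrix(character(0), 2, 0)
  cats <- c(rep("specific", nsp * cfg$nSpecificPerSpecies),
            rep("pairwise", ncol(pairs) * cfg$nPairwisePerPair),
            rep("fixed", cfg$nFixed),
            rep("low_depth", cfg$nLowDepth),
            rep("indel", cfg$nIndel),
            rep("multiallelic", cfg$nMultiallelic),
            rep("edge", cfg$nEdgeProximal),
            rep("missing", cfg$nMissingCall))
  n <- length(cats)
  if (n == 0L) {
    truth <- S4Vectors::DataFrame(
      variant_id = character(0), contig = character(0),
      position = integer(0), ref = character(0), alt = character(0),
      category = character(0), target_species = character(0),
      low_pair = character(0), high_pair = character(0),
      low_depth_sample = character(0), missing_samples = character(0))
    return(list(truth = truth,
                profiles = matrix(numeric(0), 0, nsp,
                                  dimnames = list(NULL, sp)),
                gaps = gapLayout(L, 0L)))
  }
  nEdge <- cfg$nEdgeProximal
  gaps <- gapLayout(L, max(if (nEdge > 0) ceiling(nEdge / 2) else 0L, 0L))

  withSeed(childSeed(cfg$seed, 11L), {
    # positions: regular grid away from genome ends and gap boundaries
    margin <- 60L; spacing <- 60L
    grid <- seq(margin, L - margin, by = spacing)
    if (nrow(gaps)) {
      nearGap <- vapply(grid, function(p)
        any(p >= gaps[, "start"] - 40L & p <= gaps[, "end"] + 40L), logical(1))
      grid <- grid[!nearGap]
    }
    nNonEdge <- sum(cats != "edge")
    if (length(grid) < nNonEdge)
      stop("genome too small for the requested variant counts")
    posMain <- sort(sample(grid, nNonEdge))
    # edge-proximal positions: 6-15 bp left of a nominal gap start
    posEdge <- integer(0)
    if (nEdge > 0) {
      gi <- rep(seq_len(nrow(gaps)), length.out = nEdge)
      offs <- sample(6:15, nEdge, replace = TRUE)
      posEdge <- as.integer(gaps[gi, "start"] - offs)
      if (anyDuplicated(posEdge))
        posEdge <- posEdge + seq_along(posEdge) %% 3L  # de-clash within 20bp zone
    }
    pos <- integer(n)
    pos[cats != "edge"] <- posMain
    pos[cats == "edge"] <- posEdge

    refBase <- vapply(pos, function(p)
      as.character(Biostrings::subseq(ref[[1]], p, p)), character(1))
    otherBases <- function(b) setdiff(c("A", "C", "G", "T"), b)
    altAllele <- vapply(refBase, function(b) sample(otherBases(b), 1), character(1))

    profiles <- matrix(NA_real_, n, nsp, dimnames = list(NULL, sp))
    targetSpecies <- rep(NA_character_, n)
    lowPair <- rep(NA_character_, n)
    highPair <- rep(NA_character_, n)

    specificLike <- function(target) {
      row <- numeric(nsp)
      if (runif(1) < 0.5) {  # target on the low side
        row[sp == target] <- drawFreq(1, "low")
        row[sp != target] <- drawFreq(nsp - 1, "high")
      } else {
        row[sp == target] <- drawFreq(1, "high")
        row[sp != target] <- drawFreq(nsp - 1, "low")
      }
      row
    }
    iSpec <- which(cats == "specific")
    specTargets <- rep(sp, each = cfg$nSpecificPerSpecies)
    for (k in seq_along(iSpec)) {
      targetSpecies[iSpec[k]] <- specTargets[k]
      profiles[iSpec[k], ] <- specificLike(specTargets[k])
    }
    iPair <- which(cats == "pairwise")
    pairIdx <- rep(seq_len(ncol(pairs)), each = cfg$nPairwisePerPair)
    for (k in seq_along(iPair)) {
      pr <- pairs[, pairIdx[k]]
      row <- numeric(nsp)
      lowSide <- sp %in% pr
      if (runif(1) < 0.5) lowSide <- !lowSide
      row[lowSide] <- drawFreq(sum(lowSide), "low")
      row[!lowSide] <- drawFreq(sum(!lowSide), "high")
      profiles[iPair[k], ] <- row
      lowPair[iPair[k]] <- paste(sp[lowSide], collapse = " × ")
      highPair[iPair[k]] <- paste(sp[!lowSide], collapse = " × ")
    }
    for (i in which(cats == "fixed"))
      profiles[i, ] <- drawFreq(nsp, "high")
    for (i in which(cats %in% c("low_depth", "indel", "multiallelic",
                                "edge"))) {
      t <- sample(sp, 1)
      targetSpecies[i] <- t
      profiles[i, ] <- specificLike(t)
    }
    # missing-call variants carry intermediate frequencies so that only
    # the call-rate stage (not the fixed-site filter acting on the few
    # visible samples) removes them
    for (i in which(cats == "missing"))
      profiles[i, ] <- runif(nsp, 0.3, 0.7)

    # category-specific allele edits
    alt <- altAllele
    refOut <- refBase
    for (i in which(cats == "indel")) {
      refOut[i] <- as.character(Biostrings::subseq(ref[[1]], pos[i], pos[i] + 1))
      alt[i] <- refBase[i]                       # 2 bp -> 1 bp deletion
    }
    for (i in which(cats == "multiallelic"))
      alt[i] <- paste(sample(otherBases(refBase[i]), 2), collapse = ",")

    lowDepthSample <- rep(NA_character_, n)
    sampleIds <- scenarioSampleIds(cfg)
    for (i in which(cats == "low_depth"))
      lowDepthSample[i] <- sample(sampleIds, 1)
    missingSamples <- rep(NA_character_, n)
    nMiss <- floor(length(sampleIds) / 2) + 1L    # enough to fail call rate
    for (i in which(cats == "missing"))
      missingSamples[i] <- paste(sample(sampleIds, min(nMiss, length(sampleIds))),
                                 collapse = ",")

    ord <- order(pos)
    truth <- S4Vectors::DataFrame(
      variant_id = paste0(contig, "_", pos),
      contig = contig, position = pos, ref = refOut, alt = alt,
      category = cats, target_species = targetSpecies,
      low_pair = lowPair, high_pair = highPair,
      low_depth_sample = lowDepthSample, missing_samples = missingSamples)[ord, ]
    profiles <- profiles[ord, , drop = FALSE]
    rownames(profiles) <- truth$variant_id
    list(truth = truth, profiles = profiles, gaps = gaps)
  })
}

# Sample identifiers implied by a config: species name, suffixed _r1, _r2
# where a species has replicate pools.
scenarioSampleIds <- function(cfg) {
  unlist(mapply(function(s, r) {
    if (r == 1L) s else paste0(s, "_r", seq_len(r))
  }, cfg$species, cfg$replicates, SIMPLIFY = FALSE), use.names = FALSE)
}

scenarioSampleSpecies <- function(cfg) {
  rep(cfg$species, cfg$replicates)
}

#' Simulate a complete pooled-sequencing scenario
#'
#' Generates a reference, plants variants, simulates per-sample read
#' support under the configured noise model, and derives per-sample
#' coverage intervals (the genome minus jittered gaps).  With `dir` set,
#' writes FASTA, multi-sample VCF v4.2, per-sample BED3 and the truth
#' table (TSV and JSON); identical config and seed give byte-identical
#' files.
#'
#' @param cfg a [scenarioConfig()].
#' @param dir optional output directory.
#' @return list with `ref`, `truth`, `profiles`, `calls` (internal
#'   per-sample record table), `coverage` (named list of
#'   [GenomicRanges::GRanges]), `config`, and `paths` when `dir` is given.
#' @export
#' @examples
#' sc <- simulateScenario(scenarioConfig(genomeLength = 20000, seed = 3))
#' table(sc$truth$category)
simulateScenario <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "ScenarioConfig"))
  ref <- generateReference(cfg$genomeLength, childSeed(cfg$seed, 1L))
  planted <- plantVariants(ref, cfg)
  calls <- simulateCalls(planted$truth, planted$profiles, cfg)
  coverage <- simulateCoverage(cfg, planted$gaps)
  out <- list(ref = ref, truth = planted$truth, profiles = planted$profiles,
              calls = calls, coverage = coverage, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(dir, "reference.fa"),
      vcf = file.path(dir, "variants.vcf"),
      truth_tsv = file.path(dir, "truth.tsv"),
      truth_json = file.path(dir, "truth.json"),
      bed = stats::setNames(file.path(dir, paste0(calls$samples, ".bed")),
                            calls$samples))
    Biostrings::writeXStringSet(ref, paths$fasta)
    writeScenarioVcf(out, paths$vcf)
    writeTruth(planted$truth, paths$truth_tsv, paths$truth_json)
    for (s in calls$samples) {
      bed <- grangesToBed(coverage[[s]])
      utils::write.table(bed, paths$bed[[s]], sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    out$paths <- paths
  }
  out
}

# Per-sample read support for every planted variant.  Depth is the
# configured mean depth (overridden to <= 10 at designated low-depth
# sites); alternate read counts are the rounded expectation (noiseless)
# or a binomial draw.  GQ is a Phred-scaled posterior error over three
# genotype classes, capped at 127.
simulateCalls <- function(truth, profiles, cfg) {
  samples <- scenarioSampleIds(cfg)
  speciesOf <- scenarioSampleSpecies(cfg)
  n <- nrow(truth); m <- length(samples)
  dm <- function() matrix(0L, n, m, dimnames = list(truth$variant_id, samples))
  DP <- dm(); ADref <- dm(); ADalt <- dm(); ADalt2 <- dm(); GQ <- dm()
  GT <- matrix("./.", n, m, dimnames = list(truth$variant_id, samples))
  withSeed(childSeed(cfg$seed, 23L), {
    qual <- round(runif(n, 50, 228), 1)
    for (j in seq_len(m)) {
      f <- profiles[, speciesOf[j]]
      depth <- rep(cfg$meanDepth, n)
      iLow <- which(truth$category == "low_depth" &
                    truth$low_depth_sample == samples[j])
      if (length(iLow)) depth[iLow] <- sample(1:10, length(iLow), replace = TRUE)
      altN <- if (cfg$noise == "noiseless") as.integer(round(f * depth))
              else rbinom(n, depth, f)
      isMulti <- truth$category == "multiallelic"
      a2 <- integer(n)
      a2[isMulti] <- as.integer(round(altN[isMulti] * 0.4))
      a1 <- altN - a2
      DP[, j] <- as.integer(depth)
      ADref[, j] <- as.integer(depth - altN)
      ADalt[, j] <- as.integer(a1)
      ADalt2[, j] <- a2
      GQ[, j] <- phredGQ(altN, depth)
      fhat <- ifelse(depth > 0, altN / depth, NA_real_)
      GT[, j] <- ifelse(is.na(fhat), "./.",
                 ifelse(fhat < 0.25, "0/0",
                 ifelse(fhat > 0.75, "1/1", "0/1")))
      miss <- which(!is.na(truth$missing_samples) &
                    vapply(strsplit(truth$missing_samples, ","), function(x)
                      samples[j] %in% x, logical(1)))
      if (length(miss)) GT[miss, j] <- "./."
    }
    list(samples = samples, species = speciesOf, qual = qual,
         DP = DP, ADref = ADref, ADalt = ADalt, ADalt2 = ADalt2,
         GQ = GQ, GT = GT)
  })
}

# Per-sample coverage: the full genome minus gaps whose boundaries are
# jittered by up to +/-5 bp per sample, so samples share most but not all
# covered bases (>= 95% of the genome is covered).
simulateCoverage <- function(cfg, gaps) {
  samples <- scenarioSampleIds(cfg)
  L <- cfg$genomeLength
  withSeed(childSeed(cfg$seed, 37L), {
    out <- lapply(samples, function(s) {
      if (nrow(gaps) == 0)
        return(GenomicRanges::GRanges("ctg1", IRanges::IRanges(1, L)))
      gs <- pmax(2L, gaps[, "start"] + sample(-5:5, nrow(gaps), replace = TRUE))
      ge <- pmin(L - 1L, gaps[, "end"] + sample(-5:5, nrow(gaps), replace = TRUE))
      ge <- pmax(ge, gs)
      gapGr <- GenomicRanges::GRanges("ctg1", IRanges::IRanges(gs, ge))
      GenomicRanges::setdiff(GenomicRanges::GRanges("ctg1",
                                                    IRanges::IRanges(1, L)),
                             gapGr)
    })
    stats::setNames(out, samples)
  })
}

#' Build a [PooledVariants-class] object directly from a scenario
#'
#' Bypasses the VCF round-trip; useful for in-memory property tests.
#' `ADalt` sums both alternate alleles at multiallelic sites.
#'
#' @param scenario result of [simulateScenario()].
#' @return a [PooledVariants-class] object.
#' @export
asPooledVariants <- function(scenario) {
  truth <- scenario$truth; calls <- scenario$calls
  gr <- GenomicRanges::GRanges(truth$contig,
                               IRanges::IRanges(truth$position,
                                                width = nchar(truth$ref)))
  names(gr) <- truth$variant_id
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    ref = truth$ref, alt = truth$alt, qual = calls$qual,
    variant_id = truth$variant_id)
  newPooledVariants(gr,
                    DP = calls$DP, ADref = calls$ADref,
                    ADalt = calls$ADalt + calls$ADalt2, GQ = calls$GQ,
                    called = calls$GT != "./.",
                    species = calls$species)
}

newPooledVariants <- function(rowRanges, DP, ADref, ADalt, GQ, called,
                              species) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(DP = DP, ADref = ADref, ADalt = ADalt, GQ = GQ,
                  called = called),
    rowRanges = rowRanges,
    colData = S4Vectors::DataFrame(species = species,
                                   row.names = colnames(DP)))
  methods::new("PooledVariants", se)
}

# Serialize a scenario's calls as VCF v4.2 text with GT:DP:AD:GQ fields.
writeScenarioVcf <- function(scenario, path) {
  truth <- scenario$truth; calls <- scenario$calls
  cfg <- scenario$config
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=diagSNPsimulateScenario",
    sprintf("##contig=<ID=%s,length=%d>", names(scenario$ref)[1],
            cfg$genomeLength),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", calls$samples), collapse = "\t")), con)
  isMulti <- truth$category == "multiallelic"
  for (i in seq_len(nrow(truth))) {
    fields <- vapply(seq_along(calls$samples), function(j) {
      ad <- if (isMulti[i])
        paste(calls$ADref[i, j], calls$ADalt[i, j], calls$ADalt2[i, j], sep = ",")
      else paste(calls$ADref[i, j], calls$ADalt[i, j], sep = ",")
      paste(calls$GT[i, j], calls$DP[i, j], ad, calls$GQ[i, j], sep = ":")
    }, character(1))
    writeLines(paste(c(truth$contig[i], truth$position[i],
                       truth$variant_id[i], truth$ref[i], truth$alt[i],
                       calls$qual[i], "PASS", ".", "GT:DP:AD:GQ", fields),
                     collapse = "\t"), con)
  }
  invisible(path)
}

writeTruth <- function(truth, tsvPath, jsonPath) {
  df <- as.data.frame(truth)
  utils::write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(df, jsonPath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(tsvPath)
}

#' Simulate fixed-length reads from a reference
#'
#' Uniform start positions, random strand, Sanger-encoded qualities.
#' Deterministic for a fixed seed.
#'
#' @param ref a [Biostrings::DNAStringSet] (first contig is used).
#' @param nReads number of reads (>= 0).
#' @param readLength read length in bp (<= contig length).
#' @param seed integer seed.
#' @return a [Biostrings::QualityScaledDNAStringSet].
#' @export
generateReads <- function(ref, nReads, readLength = 150L, seed = 1L) {
  if (nReads < 0) stop("nReads must be non-negative")
  L <- Biostrings::width(ref)[1]
  if (readLength > L) stop("readLength exceeds the reference length")
  if (nReads == 0)
    return(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(), Biostrings::PhredQuality(character(0))))
  withSeed(seed, {
    starts <- sample.int(L - readLength + 1L, nReads, replace = TRUE)
    seqs <- Biostrings::DNAStringSet(ref[[1]],
                                     start = starts, width = readLength)
    rev <- runif(nReads) < 0.5
    seqs[rev] <- Biostrings::reverseComplement(seqs[rev])
    q <- vapply(seq_len(nReads), function(i)
      paste(rawToChar(as.raw(33L + pmin(40L, pmax(2L,
        rnorm(readLength, 36, 3))))), collapse = ""), character(1))
    names(seqs) <- sprintf("read%06d", seq_len(nReads))
    Biostrings::QualityScaledDNAStringSet(seqs, Biostrings::PhredQuality(q))
  })
}
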