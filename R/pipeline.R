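#' Pipeline configuration
#'
#' Collects every tunable threshold of the stage pipeline in one
#' validated object.  Defaults are the study parameters: head trim 10 bp
#' and minimum read length 50 bp; depth filter DP > 10; 20 bp clean
#' flanks; diagnostic frequency thresholds 0.1 / 0.9; call rate >= 0.5;
#' 50 bp probe flanks; mixture proportions 25/50/75%; 15 pure replicates
#' per species at depth 30.
#'
#' @param scenario a [scenarioConfig()] describing the synthetic input
#'   scenario.
#' @param headTrim,minLength read QC parameters.
#' @param minDepth,window,tLow,tHigh,minCr cascade thresholds.
#' @param flank,minClear probe extraction parameters.
#' @param proportions,nPurePerSpecies,mixDepth,mixNoise simulation
#'   parameters.
#' @param nReads reads to simulate for the QC stage (0 skips it).
#' @param seed global seed; stage seeds are derived from it.
#' @return a validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(scenario = scenarioConfig(),
                           headTrim = 10L, minLength = 50L,
                           minDepth = 10L, window = 20L,
                           tLow = 0.1, tHigh = 0.9, minCr = 0.5,
                           flank = 50L, minClear = 25L,
                           proportions = c(0.25, 0.5, 0.75),
                           nPurePerSpecies = 15L,
                           mixDepth = 30L,
                           mixNoise = c("noiseless", "binomial"),
                           nReads = 200L, seed = 1L) {
  mixNoise <- match.arg(mixNoise)
  if (tLow >= tHigh) stop("tLow must be below tHigh")
  if (tLow < 0 || tHigh > 1) stop("tLow/tHigh must lie in [0, 1]")
  if (minCr < 0 || minCr > 1) stop("minCr must lie in [0, 1]")
  if (any(proportions < 0 | proportions > 1))
    stop("proportions must lie in [0, 1]")
  if (window < 0 || flank < 0 || headTrim < 0 || minLength < 0 ||
      nPurePerSpecies < 0 || nReads < 0)
    stop("lengths and counts must be non-negative")
  structure(list(scenario = scenario, headTrim = as.integer(headTrim),
                 minLength = as.integer(minLength),
                 minDepth = as.integer(minDepth), window = as.integer(window),
                 tLow = tLow, tHigh = tHigh, minCr = minCr,
                 flank = as.integer(flank), minClear = as.integer(minClear),
                 proportions = proportions,
                 nPurePerSpecies = as.integer(nPurePerSpecies),
                 mixDepth = as.integer(mixDepth), mixNoise = mixNoise,
                 nReads = as.integer(nReads), seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the stage pipeline end to end
#'
#' Simulate -> QC -> filter cascade -> reference evaluation -> markers
#' (dosage, PCA, diagnostic calls, distances) -> mixture simulation ->
#' classification -> probe extraction, with every stage's report
#' collected into one structure that echoes all consumed parameters and
#' seeds.  Reruns with the same config are identical.
#'
#' @param config a [pipelineConfig()].
#' @param dir optional output directory; when given, scenario files and
#'   a consolidated JSON report are written.
#' @return list of class `PipelineReport` with one element per stage.
#' @export
#' @examples
#' cfg <- pipelineConfig(scenarioConfig(genomeLength = 20000, seed = 2),
#'                       nReads = 50, seed = 2)
#' rep <- runPipeline(cfg)
#' names(rep)
runPipeline <- function(config, dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  sc <- simulateScenario(config$scenario, dir = dir)
  pv <- asPooledVariants(sc)

  qcStage <- NULL
  if (config$nReads > 0) {
    reads <- generateReads(sc$ref, config$nReads,
                           config$scenario$readLength,
                           seed = childSeed(config$seed, 101L))
    qcStage <- trimAndFilter(reads, config$headTrim, config$minLength)$report
  }

  cascade <- runCascade(pv, sc$coverage, ref = sc$ref,
                        minDepth = config$minDepth, tLow = config$tLow,
                        tHigh = config$tHigh, window = config$window,
                        minCr = config$minCr)
  refReport <- evaluateReference(pv, sc$coverage,
                                 referenceId = "synthetic",
                                 minDepth = config$minDepth,
                                 tLow = config$tLow, tHigh = config$tHigh,
                                 minCr = config$minCr)

  retained <- cascade$retained
  markers <- NULL; mixtures <- NULL; classification <- NULL; probes <- NULL
  if (nrow(retained) >= 1L) {
    dm <- buildDosage(retained)
    specific <- callSpeciesSpecific(dm, tLow = config$tLow,
                                    tHigh = config$tHigh)
    pairwise <- callPairwise(dm, tLow = config$tLow, tHigh = config$tHigh)
    sc2 <- scaleCenter(dm, collapseReplicates = TRUE)
    pca <- if (nrow(sc2$matrix) >= 2 && ncol(sc2$matrix) >= 1)
      pcaDosage(sc2) else NULL
    distances <- if (nrow(sc2$matrix) >= 2) euclideanMatrix(sc2) else NULL
    markers <- list(n_retained = nrow(retained),
                    specific = specific, pairwise = pairwise,
                    variance_explained = if (!is.null(pca))
                      varianceExplained(pca),
                    distances = distances$distances)

    prof <- speciesProfiles(dm)
    pure <- simulatePure(prof, config$nPurePerSpecies,
                         noise = config$mixNoise, depth = config$mixDepth,
                         seed = childSeed(config$seed, 211L))
    mixed <- simulateMixtures(prof, config$proportions,
                              noise = config$mixNoise,
                              depth = config$mixDepth,
                              seed = childSeed(config$seed, 223L))
    mixtures <- list(n_pure = ncol(pure), n_mixed = ncol(mixed))
    model <- trainClassifier(pure, seed = childSeed(config$seed, 307L))
    evalPure <- evaluateClassifier(model, pure)
    evalMixed <- evaluateClassifier(model, mixed)
    classification <- list(accuracy_pure = evalPure$accuracy_pure,
                           mixture_majority_rate =
                             evalMixed$mixture_majority_rate,
                           by_proportion = evalMixed$by_proportion)

    allCalls <- rbind(specific["variant_id"], pairwise["variant_id"])
    if (nrow(allCalls))
      probes <- extractFlanks(allCalls, sc$ref, allVariants = pv,
                              flank = config$flank,
                              minClear = config$minClear)
  }

  report <- structure(list(
    config = config[setdiff(names(config), "scenario")],
    scenario = list(seed = config$scenario$seed,
                    genome_length = config$scenario$genomeLength,
                    categories = as.list(table(sc$truth$category))),
    qc = qcStage,
    filter = list(report = cascade$report,
                  n_retained = nrow(cascade$retained)),
    refeval = unclass(refReport),
    markers = markers,
    mixtures = mixtures,
    classification = classification,
    probes = if (!is.null(probes)) list(n_candidates = nrow(probes),
                                        n_clean = sum(probes$clean))),
    class = "PipelineReport")
  if (!is.null(dir)) {
    jsonlite::write_json(reportToJson(report),
                         file.path(dir, "pipeline_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
  }
  report
}

# Strip non-serializable pieces (matrices keep their dimnames via force).
reportToJson <- function(report) {
  rapply(unclass(report), function(x) {
    if (is.matrix(x)) as.data.frame(x) else x
  }, how = "replace")
}
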