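sp4 <- c("PA03", "TD01", "TP02", "TH04")

test_that("site classification separates biallelic SNVs, indels and multiallelic sites", {
  expect_equal(as.character(classifySite("A", "G")), "biallelic_snv")
  expect_equal(as.character(classifySite("A", "G,T")), "multiallelic")
  expect_equal(as.character(classifySite("AT", "A")), "indel")
  expect_equal(as.character(classifySite("A", "AT")), "indel")
  expect_error(classifySite("", "G"), "empty allele")
})

test_that("depth filter requires DP strictly above the threshold in every called sample", {
  pv <- pvFromFreq(rbind(rep(0.5, 4), rep(0.5, 4)), sp4)
  SummarizedExperiment::assay(pv, "DP")[2, 2] <- 10L   # not > 10
  out <- depthFilter(pv)
  expect_equal(nrow(out), 1L)
  expect_equal(nrow(depthFilter(pv[integer(0), ])), 0L)
  # a sample with a missing genotype is not evaluated
  pv2 <- pvFromFreq(rbind(rep(0.5, 4)), sp4)
  SummarizedExperiment::assay(pv2, "DP")[1, 3] <- 5L
  SummarizedExperiment::assay(pv2, "called")[1, 3] <- FALSE
  expect_equal(nrow(depthFilter(pv2)), 1L)
})

test_that("call rate is inclusive at the threshold (two of four samples kept)", {
  pv <- pvFromFreq(rbind(rep(0.5, 4), rep(0.5, 4), rep(0.5, 4)), sp4)
  called <- SummarizedExperiment::assay(pv, "called")
  called[2, c(1, 2)] <- FALSE          # CR = 0.5
  called[3, c(1, 2, 3)] <- FALSE       # CR = 0.25
  SummarizedExperiment::assay(pv, "called") <- called
  expect_equal(unname(callRate(pv)), c(1, 0.5, 0.25))
  out <- callRateFilter(pv, minCr = 0.5)
  expect_equal(nrow(out), 2L)
})

test_that("fixed-site filter removes one-sided variants and keeps contrasting ones", {
  freq <- rbind(c(1, 1, 1, 1),
                c(1, 0, 1, 1),
                c(0.05, 0.02, 0, 0.08),
                c(0, 0, 0, 0))
  pv <- pvFromFreq(freq, sp4, depth = 100L)
  out <- fixedFilter(pv)
  expect_equal(nrow(out), 1L)
  expect_equal(unname(altFrequencies(out)[1, ]), c(1, 0, 1, 1))
  # a site with zero informative depth everywhere is removed
  pv0 <- pvFromFreq(rbind(rep(0.5, 4)), sp4, depth = 0L)
  expect_equal(nrow(fixedFilter(pv0)), 0L)
})

test_that("flank filter enforces coverage windows, neighbor spacing and N-free sequence", {
  cov <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 500))
  ref <- generateReference(600, 1, contigId = "chrT")
  # variant 5 bp from the coverage end: window protrudes
  pv <- pvFromFreq(rbind(rep(0.5, 4)), sp4, positions = 495L)
  expect_equal(nrow(flankFilter(pv, cov, ref = ref)), 0L)
  # well inside coverage: retained
  pv <- pvFromFreq(rbind(rep(0.5, 4)), sp4, positions = 250L)
  expect_equal(nrow(flankFilter(pv, cov, ref = ref)), 1L)
  # two variants 10 bp apart: both removed by the neighbor clause
  pv <- pvFromFreq(rbind(rep(0.5, 4), rep(0.5, 4)), sp4,
                   positions = c(200L, 210L))
  expect_equal(nrow(flankFilter(pv, cov, ref = ref)), 0L)
  # N inside the window: removed
  refN <- generateReference(600, 1, contigId = "chrT",
                            nRuns = cbind(255, 2))
  pv <- pvFromFreq(rbind(rep(0.5, 4)), sp4, positions = 250L)
  expect_equal(nrow(flankFilter(pv, cov, ref = refN)), 0L)
  # contig absent from coverage: removed
  covOther <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 500))
  expect_equal(nrow(suppressWarnings(flankFilter(pv, covOther, ref = ref))), 0L)
})

test_that("flank filter agrees with the per-base brute-force oracle", {
  for (seed in 1:5) {
    cfg <- smallConfig(seed = seed, genomeLength = 8000L,
                       nSpecificPerSpecies = 1L, nFixed = 2L,
                       nLowDepth = 1L, nIndel = 1L, nMultiallelic = 1L,
                       nEdgeProximal = 2L, nMissingCall = 1L)
    sc <- simulateScenario(cfg)
    pv <- asPooledVariants(sc)
    got <- diagSNP:::passFlank(pv, sc$coverage, 20L, sc$ref)
    want <- bruteFlank(pv, sc$coverage, 20L, sc$ref)
    expect_equal(got, want)
  }
})

test_that("the cascade is monotone, reconciles its report, and recovers planted markers exactly", {
  sc <- simulateScenario(smallConfig(seed = 21))
  res <- runCascade(asPooledVariants(sc), sc$coverage, ref = sc$ref)
  rep <- res$report
  expect_equal(rep$n_out, rep$n_in - rep$n_removed)
  expect_equal(rep$n_in[-1], rep$n_out[-nrow(rep)])
  expect_equal(rep$stage,
               c("site_class", "depth", "fixed", "flank", "call_rate"))
  truthDiag <- sc$truth$variant_id[sc$truth$category %in%
                                   c("specific", "pairwise")]
  expect_setequal(SummarizedExperiment::rowData(res$retained)$variant_id,
                  truthDiag)
})

test_that("depth and site-class stages commute", {
  sc <- simulateScenario(smallConfig(seed = 8))
  pv <- asPooledVariants(sc)
  a <- depthFilter(pv[diagSNP:::passSiteClass(pv), ])
  dOnly <- depthFilter(pv)
  b <- dOnly[diagSNP:::passSiteClass(dOnly), ]
  expect_identical(SummarizedExperiment::rowData(a)$variant_id,
                   SummarizedExperiment::rowData(b)$variant_id)
})

test_that("with thresholds relaxed to extremes only the site-class stage binds", {
  sc <- simulateScenario(smallConfig(seed = 13))
  pv <- asPooledVariants(sc)
  cov <- list(GenomicRanges::GRanges("ctg1",
    IRanges::IRanges(1, sc$config$genomeLength)))
  res <- runCascade(pv, cov, ref = NULL, minDepth = -1L, tLow = -0.01,
                    tHigh = 1.01, window = 0L, minCr = 0)
  expect_equal(nrow(res$retained), sum(classifySite(pv) == "biallelic_snv"))
  expect_equal(sum(res$report$n_removed[-1]), 0L)
})

test_that("an all-indel table empties at the first stage", {
  pv <- pvFromFreq(rbind(rep(0.5, 4), rep(1, 4)), sp4,
                   refAllele = c("AT", "GC"), altAllele = c("A", "G"))
  cov <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 5000))
  res <- runCascade(pv, cov)
  expect_equal(nrow(res$retained), 0L)
  expect_equal(res$report$n_removed, c(2L, 0L, 0L, 0L, 0L))
})

test_that("a VCF round trip preserves depths, genotypes and cascade output", {
  d <- withr::local_tempdir()
  sc <- simulateScenario(smallConfig(seed = 31), dir = d)
  pv <- asPooledVariants(sc)
  sp <- stats::setNames(sc$calls$species, sc$calls$samples)
  pv2 <- readPooledVariants(sc$paths$vcf, sp)
  expect_equal(SummarizedExperiment::assay(pv2, "DP"),
               SummarizedExperiment::assay(pv, "DP"))
  expect_equal(SummarizedExperiment::assay(pv2, "ADalt"),
               SummarizedExperiment::assay(pv, "ADalt"))
  expect_equal(SummarizedExperiment::assay(pv2, "called"),
               SummarizedExperiment::assay(pv, "called"))
  expect_error(readPooledVariants(sc$paths$vcf,
                                  c(NOSUCH = "PA03")), "NOSUCH")
  r1 <- runCascade(pv, sc$coverage, ref = sc$ref)
  r2 <- runCascade(pv2, sc$coverage, ref = sc$ref)
  expect_identical(SummarizedExperiment::rowData(r1$retained)$variant_id,
                   SummarizedExperiment::rowData(r2$retained)$variant_id)
})
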