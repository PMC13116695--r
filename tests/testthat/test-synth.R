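test_that("reference generation is seeded, uniform and rejects bad input", {
  expect_error(generateReference(0, 1), "positive")
  r1 <- generateReference(1000, seed = 1)
  r2 <- generateReference(1000, seed = 1)
  expect_identical(as.character(r1), as.character(r2))
  # base composition inside exact binomial 99% bounds for p = 1/4
  counts <- Biostrings::letterFrequency(r1[[1]], c("A", "C", "G", "T"))
  lo <- qbinom(0.005, 1000, 0.25); hi <- qbinom(0.995, 1000, 0.25)
  expect_true(all(counts >= lo & counts <= hi))
  # requested N runs appear; none otherwise
  expect_equal(Biostrings::letterFrequency(r1[[1]], "N")[[1]], 0)
  rn <- generateReference(1000, 1, nRuns = cbind(100, 5))
  expect_equal(Biostrings::letterFrequency(rn[[1]], "N")[[1]], 5)
})

test_that("planted variants follow their category's frequency pattern", {
  cfg <- smallConfig(seed = 42)
  sc <- simulateScenario(cfg)
  truth <- sc$truth; prof <- sc$profiles
  expect_equal(unname(table(truth$category)[c("specific", "pairwise", "fixed")]),
               c(8L, 6L, 3L), ignore_attr = TRUE)
  for (i in which(truth$category == "specific")) {
    t <- truth$target_species[i]
    tf <- prof[i, t]; others <- prof[i, setdiff(colnames(prof), t)]
    expect_true((tf <= 0.1 && all(others >= 0.9)) ||
                (tf >= 0.9 && all(others <= 0.1)))
  }
  for (i in which(truth$category == "pairwise")) {
    low <- strsplit(truth$low_pair[i], " × ")[[1]]
    expect_length(low, 2)
    expect_true(all(prof[i, low] <= 0.1))
    expect_true(all(prof[i, setdiff(colnames(prof), low)] >= 0.9))
  }
  for (i in which(truth$category == "fixed"))
    expect_true(all(prof[i, ] >= 0.9))
  # every planted variant appears exactly once
  expect_false(anyDuplicated(truth$variant_id) > 0)
  expect_true(all(prof >= 0 & prof <= 1))
})

test_that("all-zero configs give empty truth tables", {
  cfg <- scenarioConfig(genomeLength = 5000, nSpecificPerSpecies = 0,
                        nPairwisePerPair = 0, nFixed = 0, nLowDepth = 0,
                        nIndel = 0, nMultiallelic = 0, nEdgeProximal = 0,
                        nMissingCall = 0, seed = 1)
  sc <- simulateScenario(cfg)
  expect_equal(nrow(sc$truth), 0L)
  expect_equal(nrow(sc$profiles), 0L)
})

test_that("a genome too small for the requested counts is a capacity error", {
  expect_error(simulateScenario(smallConfig(seed = 1,
                                            genomeLength = 500L)),
               "too small")
})

test_that("noiseless mode emits exact allele depths; indel and multiallelic records are well-formed", {
  sc <- simulateScenario(smallConfig(seed = 7))
  truth <- sc$truth; calls <- sc$calls
  i1 <- which(truth$category == "specific" &
              apply(sc$profiles, 1, function(x) any(x == 1)))[1]
  spHigh <- colnames(sc$profiles)[sc$profiles[i1, ] == 1][1]
  j <- which(calls$species == spHigh)[1]
  expect_equal(calls$ADalt[i1, j], 30L)
  expect_equal(calls$ADref[i1, j], 0L)
  for (i in which(truth$category == "indel"))
    expect_true(nchar(truth$ref[i]) != nchar(truth$alt[i]))
  for (i in which(truth$category == "multiallelic"))
    expect_length(strsplit(truth$alt[i], ",")[[1]], 2)
  # low-depth sites really are shallow in their designated sample
  for (i in which(truth$category == "low_depth")) {
    s <- truth$low_depth_sample[i]
    expect_lte(calls$DP[i, s], 10L)
  }
  # GQ obeys the Phred cap
  expect_true(all(calls$GQ <= 127L & calls$GQ >= 0L))
})

test_that("binomial mode is unbiased: mean alt fraction within 3 SE of truth", {
  cfg <- smallConfig(seed = 3, noise = "binomial",
                     nSpecificPerSpecies = 40L, genomeLength = 150000L)
  sc <- simulateScenario(cfg)
  keep <- sc$truth$category == "specific"
  f <- sc$profiles[keep, ]
  fhat <- sc$calls$ADalt[keep, ] /
    pmax(sc$calls$DP[keep, ], 1L)
  sp <- sc$calls$species
  fTrue <- f[, sp]
  err <- mean(fhat - fTrue)
  se <- sqrt(sum(fTrue * (1 - fTrue) / 30) / length(fTrue)^2)
  expect_lt(abs(err), 3 * max(se, 1e-12))
})

test_that("scenario emission is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateScenario(smallConfig(seed = 11), dir = d1)
  simulateScenario(smallConfig(seed = 11), dir = d2)
  for (f in c("variants.vcf", "truth.tsv", "reference.fa", "PA03.bed"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("read simulation honors count, length and seed", {
  ref <- generateReference(5000, 1)
  expect_length(generateReads(ref, 0, 150, 1), 0)
  expect_error(generateReads(ref, -1, 150, 1), "non-negative")
  expect_error(generateReads(ref, 10, 6000, 1), "exceeds")
  r <- generateReads(ref, 100, 150, seed = 4)
  expect_length(r, 100)
  expect_true(all(Biostrings::width(r) == 150))
  expect_equal(Biostrings::width(Biostrings::quality(r)),
               Biostrings::width(r))
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  writeFastq(generateReads(ref, 50, 150, seed = 9), f1)
  writeFastq(generateReads(ref, 50, 150, seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("replicate pools share their species' frequency profile", {
  cfg <- smallConfig(seed = 5, replicates = c(PA03 = 1L, TD01 = 1L,
                                              TP02 = 1L, TH04 = 2L))
  sc <- simulateScenario(cfg)
  expect_equal(sum(sc$calls$species == "TH04"), 2L)
  r1 <- which(sc$calls$samples == "TH04_r1")
  r2 <- which(sc$calls$samples == "TH04_r2")
  expect_equal(sc$calls$ADalt[, r1], sc$calls$ADalt[, r2],
               ignore_attr = TRUE)  # noiseless replicates agree exactly
})
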