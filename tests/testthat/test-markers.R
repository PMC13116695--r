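sp4 <- c("PA03", "TD01", "TP02", "TH04")

test_that("dosage is the alternate-allele read proportion", {
  pv <- pvFromFreq(rbind(c(0, 0.5, 1, 0.25)), sp4, depth = 1000L)
  dm <- buildDosage(pv)
  expect_equal(unname(dosage(dm)[1, ]), c(0, 0.5, 1, 0.25))
  # a published-style row reconstructed from allele depths
  pv2 <- pvFromFreq(rbind(c(0.05, 0.016, 1, 0, 0)),
                    c(sp4, "TH04"), depth = 1000L)
  expect_equal(unname(dosage(buildDosage(pv2))[1, ]),
               c(0.05, 0.016, 1, 0, 0))
  expect_error(buildDosage(pv[integer(0), ]), "empty")
})

test_that("scaling centers retained columns, drops constants and imputes missing to the mean", {
  m <- rbind(PA03 = c(1, 1, 0.2), TD01 = c(0, 1, NA),
             TP02 = c(1, 1, 0.6), TH04 = c(1, 1, 0.4))
  colnames(m) <- c("v1", "v2", "v3")
  sc <- scaleCenter(m)
  expect_equal(sc$dropped, "v2")
  expect_equal(ncol(sc$matrix), 2L)
  expect_equal(unname(colMeans(sc$matrix[, 1, drop = FALSE])), 0)
  expect_equal(unname(apply(sc$matrix, 2, stats::sd)[1]), 1)
  expect_equal(sc$matrix[2, 2], 0)    # NA imputed to the column mean
  empty <- scaleCenter(matrix(numeric(0), 0, 0))
  expect_equal(dim(empty$matrix), c(0L, 0L))
})

test_that("replicate collapsing averages replicate pools per species", {
  fx <- diagFixture()
  sc <- scaleCenter(fx$dosage, collapseReplicates = TRUE)
  expect_equal(rownames(sc$matrix), c("PA03", "TD01", "TP02", "TH04"))
  d <- dosage(fx$dosage)
  raw <- (d[, 4] + d[, 5]) / 2
  keep <- setdiff(rownames(d), sc$dropped)
  expect_equal(unname(sc$matrix["TH04", keep[1]]),
               unname((raw[keep[1]] - sc$center[keep[1]]) / sc$scale[keep[1]]))
})

test_that("PCA satisfies the rank bound and matches the eigendecomposition oracle", {
  set.seed(42)
  for (rep in 1:5) {
    x <- matrix(runif(8 * 10), 8, 10,
                dimnames = list(paste0("s", 1:8), paste0("v", 1:10)))
    xs <- scale(x)
    attr(xs, "scaled:center") <- NULL
    pca <- pcaDosage(list(matrix = unclass(xs)[, ], center = rep(0, 10),
                          scale = rep(1, 10), dropped = character(0),
                          species = rownames(x)))
    want <- pcaOracle(unclass(xs)[, ])
    k <- length(varianceExplained(pca))
    expect_equal(varianceExplained(pca), want[seq_len(k)],
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_true(all(want[-seq_len(k)] < 1e-10))
    # orthogonality: score covariance is diagonal
    cv <- stats::cov(pcaScores(pca))
    expect_equal(cv - diag(diag(cv)), matrix(0, ncol(cv), ncol(cv)),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("with four samples at most three components are nonzero and proportions sum to 1", {
  fx <- diagFixture()
  pca <- pcaDosage(scaleCenter(fx$dosage, collapseReplicates = TRUE))
  ve <- varianceExplained(pca)
  expect_equal(sum(ve), 1)
  expect_lte(sum(ve > 1e-10), 3L)
})

test_that("duplicating sample rows leaves variance proportions unchanged", {
  fx <- diagFixture()
  sc <- scaleCenter(fx$dosage, collapseReplicates = TRUE)
  x <- sc$matrix
  xd <- rbind(x, x)
  # re-scale the duplicated matrix (moments identical after duplication)
  ve1 <- varianceExplained(pcaDosage(sc))
  ve2 <- varianceExplained(pcaDosage(list(matrix = xd,
                                          center = sc$center,
                                          scale = sc$scale,
                                          dropped = character(0),
                                          species = rownames(xd))))
  nz <- ve1 > 1e-10
  expect_equal(ve2[seq_len(sum(nz))], ve1[nz], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("loading ranks respect magnitude, ties and k", {
  ld <- matrix(c(0.9, 0, 0.5, -0.7), 4, 1,
               dimnames = list(c("c1_10", "c1_20", "c1_30", "c1_40"), NULL))
  pca <- methods::new("PCAResult", scores = matrix(0, 2, 1),
                      loadings = ld, sdev = 1, varExplained = 1,
                      center = 0, scale = 1, dropped = character(0))
  rk <- rankInformative(pca, components = 1, k = 10)
  expect_equal(rk$PC1, c("c1_10", "c1_40", "c1_30", "c1_20"))
  expect_equal(rankInformative(pca, 1, k = 2)$PC1, c("c1_10", "c1_40"))
  expect_error(rankInformative(pca, 1, k = 0), "positive")
})

test_that("planted discriminating variants dominate PC1 on a one-axis matrix", {
  set.seed(9)
  # 10 samples; 5 planted variants share one separating axis, 40 noise
  # variants vary independently of it
  axis <- c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  planted <- matrix(rep(axis, 5), 10, 5)
  noise <- matrix(runif(10 * 40, 0.4, 0.6), 10, 40)
  x <- cbind(planted, noise)
  rownames(x) <- paste0("s", 1:10)
  colnames(x) <- paste0("c1_", seq_len(ncol(x)) * 100)
  pca <- pcaDosage(scaleCenter(x))
  top5 <- rankInformative(pca, 1, k = 5)$PC1
  expect_setequal(top5, colnames(x)[1:5])
})

test_that("species-specific rule calls exactly one species opposite all others", {
  f <- rbind(c(1, 0, 1, 1, 1),
             c(0.05, 0.016, 1, 0, 0),
             c(0.5, 0, 1, 1, 1),
             c(1, 1, 0, 0, 1))
  rownames(f) <- paste0("v", 1:4)
  sp5 <- c(sp4[1:3], "TH04", "TH04")[c(1, 2, 3, 4, 5)]
  species <- c("PA03", "TD01", "TP02", "TH04", "TH04")
  calls <- callSpeciesSpecific(f, species = species)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$target[calls$variant_id == "v1"], "TD01")
  expect_equal(calls$target[calls$variant_id == "v2"], "TP02")
  # v3: PA03 at 0.5 is ambiguous; v4: 2-2 split is not species-specific
  expect_false(any(calls$variant_id %in% c("v3", "v4")))
  # replicate disagreement blocks a call
  f5 <- rbind(v9 = c(1, 0, 1, 1, 0))
  expect_equal(nrow(callSpeciesSpecific(f5, species = species)), 0L)
})

test_that("pairwise rule requires a clean two-against-two split", {
  species <- c("PA03", "TD01", "TP02", "TH04", "TH04")
  f <- rbind(v1 = c(0.991, 0.992, 0, 0, 0),
             v2 = c(1, 0, 0, 1, 0.987),
             v3 = c(1, 1, 1, 0, 0))
  calls <- callPairwise(f, species = species)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$low_pair[calls$variant_id == "v1"], "TP02 × TH04")
  expect_equal(calls$high_pair[calls$variant_id == "v1"], "PA03 × TD01")
  expect_equal(calls$low_pair[calls$variant_id == "v2"], "TD01 × TP02")
  expect_equal(calls$high_pair[calls$variant_id == "v2"], "PA03 × TH04")
  expect_false("v3" %in% calls$variant_id)   # 3-1 split
})

test_that("complement invariance: 1 - f preserves targets and swaps pair sides", {
  set.seed(5)
  species <- c("PA03", "TD01", "TP02", "TH04", "TH04")
  for (rep in 1:20) {
    f <- matrix(sample(c(0, 1, runif(2)), 5 * 6, replace = TRUE), 6, 5)
    rownames(f) <- paste0("v", 1:6)
    s1 <- callSpeciesSpecific(f, species = species)
    s2 <- callSpeciesSpecific(1 - f, species = species)
    expect_equal(s1[c("variant_id", "target")],
                 s2[c("variant_id", "target")])
    p1 <- callPairwise(f, species = species)
    p2 <- callPairwise(1 - f, species = species)
    expect_equal(p1$variant_id, p2$variant_id)
    expect_equal(p1$low_pair, p2$high_pair)
    expect_equal(p1$high_pair, p2$low_pair)
    # PCA variance proportions unchanged under complement
    if (rep == 1) {
      x <- t(f[, 1:4]); colnames(x) <- rownames(f); rownames(x) <- sp4
      v1 <- varianceExplained(pcaDosage(scaleCenter(x)))
      v2 <- varianceExplained(pcaDosage(scaleCenter(1 - x)))
      expect_equal(v1, v2, tolerance = 1e-10)
    }
  }
})

test_that("species-specific and pairwise call sets are disjoint", {
  fx <- diagFixture()
  cs <- callSpeciesSpecific(fx$dosage)
  cp <- callPairwise(fx$dosage)
  expect_length(intersect(cs$variant_id, cp$variant_id), 0)
})

test_that("euclidean distances are symmetric with zero diagonal; identical rows at distance 0", {
  x <- rbind(a = c(1, 0, 1), b = c(1, 0, 1), c = c(0, 1, 0))
  em <- euclideanMatrix(x)
  expect_equal(em$distances["a", "b"], 0)
  expect_equal(em$distances, t(em$distances))
  expect_true(all(diag(em$distances) == 0))
  expect_error(euclideanMatrix(x[1, , drop = FALSE]), "two samples")
})
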