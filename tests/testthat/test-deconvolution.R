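test_that("expression filter and max-normalization follow the 20-TPM rule", {
  m <- rbind(low = c(5, 19), mid = c(10, 50), high = c(100, 40))
  colnames(m) <- c("s1", "s2")
  fn <- filterAndNormalize(m, minTpm = 20)
  expect_setequal(fn$retainedGenes, c("mid", "high"))
  expect_equal(unname(fn$normalized["mid", ]), c(0.2, 1))
  expect_equal(unname(apply(fn$normalized, 1, max)), c(1, 1))
  expect_error(filterAndNormalize(m, minTpm = 1000), "all genes fall below")
})

test_that("retained-gene count matches an independent re-scan", {
  mix <- generateMixture(generateReference(studyConfig(seed = 14)),
                         NULL, studyConfig(seed = 14), nSamples = 8)
  m <- SummarizedExperiment::assay(mix)
  fn <- filterAndNormalize(m, minTpm = 20)
  oracle <- rownames(m)[vapply(seq_len(nrow(m)),
                               function(i) max(m[i, ]) >= 20, logical(1))]
  expect_identical(fn$retainedGenes, oracle)
})

test_that("NMF factorizes exact low-rank structure with a monotone objective", {
  withr::with_seed(41, {
    u <- runif(40, 0.5, 2); v <- runif(9, 0.5, 2)
  })
  X1 <- u %o% v
  dimnames(X1) <- list(sprintf("g%02d", 1:40), sprintf("s%d", 1:9))
  d1 <- nmfDecompose(X1, 1, seed = 1)
  expect_lt(reconstructionError(d1), 1e-8)
  expect_true(all(diff(d1@objective) <= 1e-10))
  # rank-6 synthetic mixtures, noiseless: near-exact reconstruction
  cfg <- studyConfig(seed = 42)
  mix <- generateMixture(generateReference(cfg), NULL, cfg, nSamples = 24)
  fn <- filterAndNormalize(mix)
  d6 <- nmfDecompose(fn$normalized, 6, seed = 1)
  expect_lt(reconstructionError(d6) / sqrt(sum(fn$normalized^2)), 1e-6)
  expect_true(all(diff(d6@objective) <= 1e-10 * max(d6@objective[1], 1)))
})

test_that("NMF is deterministic given a seed and equivariant to sample order", {
  cfg <- simulationConfig(nGenes = 150, nCelltypes = 3, markersPerType = 8,
                          seed = 4)
  mix <- generateMixture(generateReference(cfg), NULL, cfg, nSamples = 8)
  X <- filterAndNormalize(mix)$normalized
  d1 <- nmfDecompose(X, 3, seed = 7)
  d2 <- nmfDecompose(X, 3, seed = 7)
  expect_identical(loadings(d1), loadings(d2))
  expect_identical(activities(d1), activities(d2))
  perm <- c(3, 1, 4, 2, 8, 7, 5, 6)
  dP <- nmfDecompose(X[, perm], 3, seed = 7)
  fitted <- loadings(d1) %*% activities(d1)
  fittedP <- loadings(dP) %*% activities(dP)
  expect_equal(fittedP, fitted[, perm], tolerance = 1e-6)
})

test_that("held-out rank selection prefers the true rank region", {
  cfg <- studyConfig(seed = 77)
  mix <- generateMixture(generateReference(cfg), NULL, cfg, nSamples = 24)
  X <- filterAndNormalize(mix)$normalized
  sel <- nmfSelectRank(X, ranks = c(2, 4, 6), seed = 5, maxIter = 150)
  expect_equal(sel$rank, 6)
  expect_lt(sel$heldOutError[["6"]], sel$heldOutError[["2"]])
})

test_that("components are annotated by marker plurality", {
  cfg <- simulationConfig(nGenes = 300, nCelltypes = 4, markersPerType = 10,
                          seed = 3)
  ref <- generateReference(cfg)
  calls <- callSpecificGenes(ref)
  mix <- generateMixture(ref, NULL, cfg, nSamples = 12)
  X <- filterAndNormalize(mix)$normalized
  dec <- nmfDecompose(X, 4, seed = 1)
  ann <- annotations(annotateComponents(dec, calls, topN = 8))
  expect_setequal(ann, rownames(refValues(ref)))
  # with no specificity calls every component stays unannotated
  empty <- calls[0, ]
  ann0 <- annotations(annotateComponents(dec, empty, topN = 8))
  expect_true(all(ann0 == "unannotated"))
  expect_error(annotateComponents(dec, calls, topN = 1e5), "topN exceeds")
})

test_that("constrained least squares recovers vertices and mixtures exactly", {
  cfg <- simulationConfig(nGenes = 300, nCelltypes = 3, markersPerType = 10,
                          seed = 6)
  ref <- generateReference(cfg)
  sig <- signatureMatrix(ref)
  # vertex: a pure rescaled profile
  x <- refValues(ref)[2, ] * 3.7
  fe <- estimateFractions(x, sig)
  expect_equal(unname(fractions(fe)[, 1]), c(0, 1, 0), tolerance = 1e-9)
  # interior mixture, noiseless
  p <- c(0.6, 0.3, 0.1)
  mix <- generateMixture(ref, p, cfg)
  feM <- estimateFractions(SummarizedExperiment::assay(mix), sig)
  expect_equal(unname(fractions(feM)[, 1]), p, tolerance = 1e-6)
  # oracle: closed-form least squares on the noiseless linear system
  # (interior solution, so the bound is inactive)
  xr <- SummarizedExperiment::assay(mix)[colnames(sig), 1]
  oracle <- closedFormFractions(sig, xr)
  expect_equal(unname(fractions(feM)[, 1]), unname(oracle),
               tolerance = 1e-6)
})

test_that("fraction estimates are scale-invariant and flag rank deficiency", {
  cfg <- simulationConfig(nGenes = 300, nCelltypes = 3, markersPerType = 10,
                          seed = 16)
  ref <- generateReference(cfg)
  sig <- signatureMatrix(ref)
  mix <- SummarizedExperiment::assay(
    generateMixture(ref, c(0.2, 0.5, 0.3), cfg))
  f1 <- fractions(estimateFractions(mix, sig))
  f2 <- fractions(estimateFractions(mix * 250, sig * 250))
  expect_equal(f1, f2, tolerance = 1e-9)
  # an entity duplicated into the signature makes it rank-deficient
  sigDup <- rbind(sig, dup = sig[1, ])
  expect_warning(estimateFractions(mix, sigDup), "rank-deficient")
})

test_that("fractions stay accurate under multinomial counting noise", {
  cfg0 <- studyConfig(seed = 52)
  ref <- generateReference(cfg0)
  sig <- signatureMatrix(ref)
  p <- c(0.30, 0.25, 0.20, 0.15, 0.07, 0.03)
  errs <- vapply(1:10, function(i) {
    cfgI <- studyConfig(seed = 52 + i * 1000, noiseModel = "multinomial",
                        readDepth = 1e6)
    m <- SummarizedExperiment::assay(generateMixture(ref, p, cfgI))
    mean(abs(fractions(estimateFractions(m, sig))[, 1] - p))
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("NMF contributions rank-correlate with truth across seeds", {
  rhos <- vapply(1:20, function(s) {
    cfg <- simulationConfig(nGenes = 300, nCelltypes = 4,
                            markersPerType = 10, seed = 100 + s)
    ref <- generateReference(cfg)
    mix <- generateMixture(ref, NULL, cfg, nSamples = 10)
    X <- filterAndNormalize(mix)$normalized
    dec <- annotateComponents(nmfDecompose(X, 4, seed = 1, maxIter = 2000),
                              callSpecificGenes(ref), topN = 8,
                              minFraction = 0.3)
    cf <- fractions(componentFractions(dec))
    P <- groundTruth(mix)$true_proportions
    shared <- intersect(rownames(cf), rownames(P))
    cor(as.vector(cf[shared, ]), as.vector(P[shared, ]),
        method = "spearman")
  }, numeric(1))
  expect_true(all(rhos > 0.8))
})

test_that("component fractions aggregate annotated activity shares", {
  cfg <- simulationConfig(nGenes = 300, nCelltypes = 4, markersPerType = 10,
                          seed = 3)
  ref <- generateReference(cfg)
  mix <- generateMixture(ref, NULL, cfg, nSamples = 12)
  X <- filterAndNormalize(mix)$normalized
  dec <- annotateComponents(nmfDecompose(X, 4, seed = 1),
                            callSpecificGenes(ref), topN = 8)
  cf <- componentFractions(dec)
  expect_true(all(abs(colSums(fractions(cf)) - 1) < 1e-9))
  P <- groundTruth(mix)$true_proportions
  rs <- vapply(rownames(P), function(t) cor(fractions(cf)[t, ], P[t, ]),
               numeric(1))
  expect_true(all(rs > 0.9))
  # unannotated decomposition cannot be aggregated
  expect_error(componentFractions(nmfDecompose(X, 4, seed = 1)),
               "no component is annotated")
})
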