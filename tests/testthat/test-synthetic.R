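test_that("simulation config enforces its invariants", {
  expect_error(simulationConfig(nGenes = 10, nCelltypes = 4,
                                markersPerType = 3),
               "exceeds nGenes")
  expect_error(simulationConfig(markerFold = 1), "markerFold")
  expect_error(simulationConfig(timeGrid = c(0, 2, 2)), "strictly increasing")
  expect_error(simulationConfig(noiseModel = "gaussian"), "noiseModel")
  expect_s4_class(simulationConfig(), "SimulationConfig")
})

test_that("reference generator plants exact-fold markers and is seed-deterministic", {
  cfg <- simulationConfig(nGenes = 120, nCelltypes = 3, markersPerType = 4,
                          markerFold = 50, seed = 11)
  ref <- generateReference(cfg)
  v <- refValues(ref)
  gt <- groundTruth(ref)$marker_assignment
  expect_length(gt, 12)
  for (g in names(gt)) {
    own <- v[gt[[g]], g]
    others <- v[setdiff(rownames(v), gt[[g]]), g]
    expect_equal(own, 50 * max(others))
  }
  # determinism: same seed bitwise identical, different seed differs
  expect_identical(v, refValues(generateReference(cfg)))
  cfg2 <- simulationConfig(nGenes = 120, nCelltypes = 3, markersPerType = 4,
                           markerFold = 50, seed = 12)
  expect_false(identical(v, refValues(generateReference(cfg2))))
})

test_that("markers below the 20-fold rule yield no specificity call", {
  cfg <- simulationConfig(nGenes = 120, nCelltypes = 3, markersPerType = 4,
                          markerFold = 10, seed = 5)
  ref <- generateReference(cfg)
  calls <- callSpecificGenes(ref)
  expect_false(any(names(groundTruth(ref)$marker_assignment) %in% calls$gene))
})

test_that("noiseless mixtures are exact TPM-scale weighted sums", {
  cfg <- simulationConfig(nGenes = 200, nCelltypes = 4, markersPerType = 8,
                          seed = 2)
  ref <- generateReference(cfg)
  # pure sample equals the rescaled profile of its cell type
  pure <- generateMixture(ref, c(1, 0, 0, 0), cfg)
  prof <- refValues(ref)[1, ]
  expect_equal(unname(SummarizedExperiment::assay(pure)[, 1]),
               unname(prof / sum(prof) * 1e6), tolerance = 1e-12)
  # column sums are 1e6
  mix <- generateMixture(ref, NULL, cfg, nSamples = 6)
  expect_true(all(abs(colSums(SummarizedExperiment::assay(mix)) - 1e6) < 1e-3))
  # invalid proportions are rejected
  expect_error(generateMixture(ref, c(0.5, 0.2, 0.2, 0.2), cfg), "sum to 1")
  expect_error(generateMixture(ref, c(0.5, 0.5), cfg), "one entry per")
})

test_that("noiseless mode is the expectation of the multinomial mode", {
  cfg0 <- simulationConfig(nGenes = 150, nCelltypes = 3, markersPerType = 5,
                           seed = 9, noiseModel = "none")
  ref <- generateReference(cfg0)
  p <- c(0.5, 0.3, 0.2)
  expected <- SummarizedExperiment::assay(generateMixture(ref, p, cfg0))[, 1]
  depth <- 5e4
  nRep <- 200
  draws <- vapply(seq_len(nRep), function(i) {
    cfgI <- simulationConfig(nGenes = 150, nCelltypes = 3, markersPerType = 5,
                             seed = 9 + 1000 * i, noiseModel = "multinomial",
                             readDepth = depth)
    SummarizedExperiment::assay(generateMixture(ref, p, cfgI))[, 1]
  }, numeric(150))
  avg <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(nRep)
  ok <- abs(avg - expected) <= 3 * pmax(se, 1e-9)
  expect_gt(mean(ok), 0.99)
})

test_that("timecourse generator follows the planted lineage trajectories", {
  cfg <- simulationConfig(nGenes = 200, nCelltypes = 4, markersPerType = 8,
                          seed = 3, timeGrid = -6:14)
  ref <- generateReference(cfg)
  # flat trajectories give identical columns, so nothing is time-varying
  flat <- data.frame(lineage = "celltype1", preLevel = 1, ablationDay = -2,
                     nadirLevel = 1, recoveryStartDay = 9, recoveryRate = 0)
  tcFlat <- generateTimecourse(ref, flat, cfg)
  expect_length(selectTimeVarying(tcFlat), 0)
  # nadir 0: lineage contributes nothing, markers fall to the background
  # share computed from the other entities alone
  zero <- data.frame(lineage = "celltype1", preLevel = 1, ablationDay = -2,
                     nadirLevel = 0, recoveryStartDay = 5, recoveryRate = 0)
  tcZero <- generateTimecourse(ref, zero, cfg)
  gt <- groundTruth(ref)$marker_assignment
  m1 <- names(gt)[gt == "celltype1"]
  nadirDay <- which(-6:14 == 6)
  S <- refValues(ref)
  bgMix <- colSums(S[-1, ])
  bgTpm <- bgMix / sum(bgMix) * 1e6
  expect_equal(unname(SummarizedExperiment::assay(tcZero)[m1, nadirDay]),
               unname(bgTpm[m1]), tolerance = 1e-9)
  expect_error(generateTimecourse(ref, transform(zero, nadirLevel = -1), cfg),
               "non-negative")
})

test_that("Ig generator honors the symmetric-share clone model", {
  # clone fraction 1: every read lands on a clone segment
  ig1 <- generateIgCounts(c("IGHV3-15", "IGKV2-24"), c(1, 1), 20, 5000,
                          seed = 4, days = 1:2)
  cts <- igCounts(ig1)
  expect_true(all(colSums(cts) == 5000))
  expect_true(all(colSums(cts[c("IGHV3-15", "IGKV2-24"), ]) == 5000))
  # clone fraction 0: clone segments behave like background (uniform null)
  ig0 <- generateIgCounts("IGHV3-15", rep(0, 40), 10, 2e4, seed = 4,
                          days = 1:40)
  frac <- rowMeans(igCounts(ig0)) / 2e4
  expect_true(all(abs(frac - 1 / 11) < 0.01))
  expect_error(generateIgCounts(character(), c(0.5), 10, 100, 1),
               "clone segment")
  # determinism
  again <- generateIgCounts("IGHV3-15", rep(0, 40), 10, 2e4, seed = 4,
                            days = 1:40)
  expect_identical(igCounts(ig0), igCounts(again))
})

test_that("SNP generator reproduces genotype arithmetic", {
  geno <- data.frame(snp = "s1", host = "hom-ref", donor = "het")
  # m = 0, no error: all reads are reference
  t0 <- generateSnpCounts(geno, 0, depth = 50, errorRate = 0, seed = 1,
                          days = 0)
  expect_equal(unname(refCounts(t0)[1, 1]), 50)
  expect_equal(unname(alleleFrequency(t0)[1, 1]), 1)
  # m = 1, donor het: expected frequency 0.5
  t1 <- generateSnpCounts(geno, 1, depth = 50, errorRate = 0, seed = 1,
                          days = 0)
  expect_equal(unname(groundTruth(t1)$expected_frequency[1, 1]), 0.5)
  expect_error(
    generateSnpCounts(data.frame(snp = "s", host = "??", donor = "het"),
                      0, 10, 0, 1, days = 0),
    "unknown genotype")
  expect_error(generateSnpCounts(geno, 0, depth = 10, errorRate = 0.7,
                                 seed = 1, days = 0), "errorRate")
})
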