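test_that("time-varying selection applies the 50-TPM / 5-fold rules", {
  m <- rbind(sel = c(10, 60), lowmax = c(5, 40), flat = c(100, 300))
  colnames(m) <- c("day0", "day5")
  # pc = 0: (10,60) max 60 > 50 and ratio 6 > 5; (100,300) ratio only 3
  got <- selectTimeVarying(m, ratioPseudocount = 0)
  expect_identical(got, "sel")
  expect_error(selectTimeVarying(m[, 1, drop = FALSE]), "two time points")
})

test_that("selection matches a brute-force re-scan on 1000 synthetic genes", {
  withr::with_seed(61, {
    m <- matrix(rlnorm(1000 * 8, log(40), 1.2), nrow = 1000,
                dimnames = list(sprintf("g%04d", 1:1000), paste0("day", 1:8)))
  })
  got <- selectTimeVarying(m, 50, 5, ratioPseudocount = 1)
  oracle <- rownames(m)[vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    max(v) > 50 && (max(v) + 1) / (min(v) + 1) > 5
  }, logical(1))]
  expect_identical(got, oracle)
})

test_that("max-normalization preserves shape and attains 1 in every row", {
  m <- rbind(a = c(10, 60, 30), b = c(7, 7, 7), z = c(0, 0, 0))
  colnames(m) <- paste0("day", 0:2)
  nm <- maxNormalize(m[c("a", "b"), ])
  expect_equal(unname(nm["a", ]), c(1 / 6, 1, 0.5))
  expect_equal(unname(nm["b", ]), c(1, 1, 1))
  expect_true(all(apply(nm, 1, max) == 1))
  expect_equal(apply(nm, 1, which.max)[["a"]],
               unname(which.max(m["a", ])))
  expect_error(maxNormalize(m), "all-zero")
})

test_that("clustering separates planted temporal archetypes perfectly", {
  days <- 0:9
  early <- exp(-days / 2)
  late <- pmin(1, 0.05 * exp(pmax(days - 5, 0)))
  profiles <- rbind(
    matrix(rep(early, each = 50), nrow = 50,
           dimnames = list(sprintf("early%02d", 1:50), NULL)),
    matrix(rep(late, each = 50), nrow = 50,
           dimnames = list(sprintf("late%02d", 1:50), NULL)))
  truth <- rep(1:2, each = 50)
  for (method in c("kmeans", "hierarchical")) {
    cl <- clusterGenes(profiles, method = method, k = 2, seed = 1)
    expect_equal(length(unique(cl$membership[truth == 1])), 1)
    expect_equal(length(unique(cl$membership[truth == 2])), 1)
    expect_false(cl$membership[1] == cl$membership[51])
  }
  # k = number of genes gives singletons
  sub <- profiles[c(1, 51, 60), ] + matrix(seq_len(30) / 100, nrow = 3)
  singles <- clusterGenes(sub, "kmeans", k = 3, seed = 1)
  expect_equal(sort(unname(singles$membership)), 1:3)
  expect_error(clusterGenes(sub, "kmeans", k = 10), "k exceeds")
})

test_that("duplicating genes leaves converged k-means centroids unchanged", {
  withr::with_seed(71, {
    profiles <- matrix(runif(40 * 6), nrow = 40,
                       dimnames = list(sprintf("g%02d", 1:40), NULL))
  })
  base <- clusterGenes(profiles, "kmeans", k = 3, seed = 2)
  dup <- rbind(profiles, profiles)
  rownames(dup) <- make.unique(rownames(dup))
  again <- clusterGenes(dup, "kmeans", k = 3, centers = base$centers)
  expect_equal(unname(again$centers), unname(base$centers), tolerance = 1e-12)
  # each duplicate lands with its original
  expect_identical(unname(again$membership[1:40]),
                   unname(again$membership[41:80]))
})

test_that("lineage trajectories are exact at the reference day and planted steps", {
  m <- rbind(g1 = c(100, 300, 50), g2 = c(20, 60, 10), g3 = c(4, 12, 2))
  colnames(m) <- c("day0", "day3", "day6")
  tr <- lineageTrajectory(m, c("g1", "g2", "g3"), referenceDay = 0)
  expect_equal(tr$mean[tr$day == 0], 1)
  expect_equal(tr$mean[tr$day == 3], 3, tolerance = 1e-9)  # planted 3x step
  expect_equal(tr$mean[tr$day == 6], 0.5, tolerance = 1e-9)
  pc <- lineageTrajectory(m, c("g1", "g2"), mode = "percent_change",
                          referenceDay = 0)
  expect_equal(pc$mean[pc$day == 0], 0)
  expect_equal(pc$mean[pc$day == 3], 200)
  # invariant to gene order; adding a gene equal to the average changes
  # nothing
  trRev <- lineageTrajectory(m, c("g3", "g1", "g2"), referenceDay = 0)
  expect_equal(tr$mean, trRev$mean)
  avgGene <- colMeans(m / m[, 1])
  m4 <- rbind(m, gAvg = avgGene * 10)
  tr4 <- lineageTrajectory(m4, rownames(m4), referenceDay = 0)
  expect_equal(tr4$mean, tr$mean, tolerance = 1e-12)
  # zero at the reference day: excluded and reported
  m5 <- rbind(m, gZero = c(0, 5, 5))
  tr5 <- lineageTrajectory(m5, rownames(m5), referenceDay = 0)
  expect_equal(attr(tr5, "excluded"), "gZero")
  expect_equal(tr5$mean, tr$mean)
  expect_error(lineageTrajectory(m, "g1", referenceDay = 99), "referenceDay")
})

test_that("the TPM cap excludes very abundant genes", {
  m <- rbind(g1 = c(100, 300), g2 = c(6000, 9000))
  colnames(m) <- c("day0", "day1")
  tr <- lineageTrajectory(m, c("g1", "g2"), referenceDay = 0,
                          maxTpmCap = 5000)
  expect_equal(attr(tr, "excluded"), "g2")
  expect_equal(tr$mean[2], 3)
})

test_that("planted ablation/recovery timing is recovered from the trajectory", {
  cfg <- simulationConfig(nGenes = 400, nCelltypes = 4, markersPerType = 12,
                          seed = 19, timeGrid = -6:14)
  ref <- generateReference(cfg)
  spec <- data.frame(lineage = "celltype2", preLevel = 1, ablationDay = -2,
                     nadirLevel = 0.02, recoveryStartDay = 9,
                     recoveryRate = 0.8)
  tc <- generateTimecourse(ref, spec, cfg)
  gt <- groundTruth(ref)$marker_assignment
  lineageGenes <- names(gt)[gt == "celltype2"]
  tr <- lineageTrajectory(tc, lineageGenes, referenceDay = -6)
  # minimum in the planted nadir window (just before recovery start)
  expect_true(tr$day[which.min(tr$mean)] %in% 7:9)
  nadirVal <- min(tr$mean)
  expect_true(all(tr$mean[tr$day >= 12] > 2 * nadirVal))
  # analytic oracle: recompute the expected TPM trajectory from the
  # generator's mixing weights and compare the average fold change
  W <- groundTruth(tc)$lineage_trajectories
  S <- refValues(ref)
  P <- sweep(W, 2, colSums(W), "/")
  expectedTpm <- cfmarrow:::.tpmNormalize(t(S) %*% P)
  oracle <- colMeans(expectedTpm[lineageGenes, ] /
                     expectedTpm[lineageGenes, 1])
  expect_equal(unname(tr$mean), unname(oracle), tolerance = 1e-9)
})

test_that("marker trajectories dissociate from flat cell counts after ablation", {
  cfg <- simulationConfig(nGenes = 400, nCelltypes = 4, markersPerType = 12,
                          seed = 23, timeGrid = -6:14)
  ref <- generateReference(cfg)
  spec <- data.frame(lineage = "celltype1", preLevel = 1, ablationDay = -2,
                     nadirLevel = 0.02, recoveryStartDay = 10,
                     recoveryRate = 0.5)
  tc <- generateTimecourse(ref, spec, cfg)
  gt <- groundTruth(ref)$marker_assignment
  tr <- lineageTrajectory(tc, names(gt)[gt == "celltype1"],
                          referenceDay = -6)
  # the transcript signal collapses by more than 5x post-ablation ...
  expect_lt(min(tr$mean), 1 / 5)
  # ... while a flat circulating-cell count series stays within 10%
  rbcCount <- rep(4.8, length(tr$day))
  expect_true(all(abs(rbcCount / rbcCount[1] - 1) < 0.10))
})
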