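# Shared fixture builders and analytic oracles used across the suite.

# Small deterministic entity x gene reference built by hand.
tinyReference <- function() {
  v <- rbind(
    celltypeA = c(g1 = 210, g2 = 10, g3 = 100, g4 = 3, g5 = 8),
    celltypeB = c(g1 = 10, g2 = 300, g3 = 5, g4 = 2, g5 = 8),
    celltypeC = c(g1 = 4, g2 = 2, g3 = 5, g4 = 90, g5 = 8)
  )
  ReferenceMatrix(v)
}

# Default synthetic study configuration (the acceptance-scale conditions).
studyConfig <- function(seed = 1L, markerFold = 50, ...) {
  simulationConfig(nGenes = 1000L, nCelltypes = 6L, markersPerType = 30L,
                   markerFold = markerFold, seed = seed, ...)
}

# Brute-force re-implementation of the 20-fold specificity rule, used as an
# independent oracle against callSpecificGenes().
bruteForceSpecific <- function(values, fold = 20, floor = 1) {
  hits <- list()
  for (g in colnames(values)) {
    col <- values[, g]
    top <- which(col == max(col))
    if (length(top) > 1L) next
    if (col[top] < floor) next
    if (all(col[top] > fold * col[-top])) {
      hits[[g]] <- rownames(values)[top]
    }
  }
  unlist(hits)
}

# Expected Ig composition under the symmetric-share clone model with two
# clone segments in two classes and `rep` background segments split evenly:
# per-class clone fraction and per-class background fraction.
igClassComposition <- function(cf, nClone = 2L, rep = 50L) {
  nSeg <- nClone + rep
  bgPerClass <- rep / nClone
  cloneShare <- cf / nClone + (1 - cf) / nSeg
  bgShare <- (1 - cf) / nSeg
  classTotal <- cloneShare + bgPerClass * bgShare
  list(cloneFrac = cloneShare / classTotal,
       bgFrac = bgShare / classTotal)
}

# Planted loss-of-dominance day: the dual dominance rule applied to the
# noiseless expected composition.
plantedLossDay <- function(cfs, days, nClone = 2L, rep = 50L,
                           threshold = 0.5, fold = 5) {
  dom <- vapply(cfs, function(cf) {
    comp <- igClassComposition(cf, nClone, rep)
    comp$cloneFrac > threshold ||
      (comp$bgFrac > 0 && comp$cloneFrac > fold * comp$bgFrac)
  }, logical(1))
  if (!any(dom) || dom[length(dom)]) return(NA_real_)
  min(days[days > days[max(which(dom))]])
}

# Deterministic IgCountTable from exact per-day clone fractions (expected
# counts, rounded), for example-style tests without sampling noise.
exactIgTable <- function(cfs, days, nClone = 2L, rep = 50L,
                         totalReads = 1e4) {
  cloneSegs <- c("IGHV3-15", "IGKV2-24")[seq_len(nClone)]
  prefix <- c("IGHV", "IGKV")
  bgNames <- paste0(rep(prefix[seq_len(nClone)], length.out = rep), "-bg",
                    formatC(seq_len(rep), width = 3, flag = "0"))
  nSeg <- nClone + rep
  counts <- vapply(cfs, function(cf) {
    p <- rep((1 - cf) / nSeg, nSeg)
    p[seq_len(nClone)] <- p[seq_len(nClone)] + cf / nClone
    round(p * totalReads)
  }, numeric(nSeg))
  rownames(counts) <- c(cloneSegs, bgNames)
  colnames(counts) <- as.character(days)
  IgCountTable(counts, days = days)
}

# Closed-form oracle for estimateFractions() on interior noiseless
# mixtures: the TPM rescale makes the sample's scale arbitrary, so the
# constrained solution's direction is the ordinary least-squares direction,
# renormalized onto the simplex (exact when the system is consistent and
# the non-negativity bound inactive).
closedFormFractions <- function(signature, x) {
  A <- t(signature)                    # gene x entity
  u <- drop(solve(crossprod(A), crossprod(A, x)))
  u / sum(u)
}

# Brute-force exact two-sided rank-sum p-value by enumeration.
bruteForceRankSumP <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  muW <- n1 * (N + 1) / 2
  dev <- abs(sum(r[seq_len(n1)]) - muW)
  sums <- combn(N, n1, function(idx) sum(r[idx]))
  mean(abs(sums - muW) >= dev - 1e-9)
}

# Host/donor genotype panel covering every ordered genotype pair.
genotypePanel <- function(nSnps = 50L, seed = 1L) {
  codes <- c("hom-ref", "het", "hom-alt")
  pairs <- expand.grid(host = codes, donor = codes,
                       stringsAsFactors = FALSE)
  idx <- withr::with_seed(seed, sample(nrow(pairs), nSnps, replace = TRUE))
  data.frame(snp = sprintf("snp%03d", seq_len(nSnps)),
             host = pairs$host[idx], donor = pairs$donor[idx])
}

# Donor-fraction ramp: 0 before transplant, linear 0 -> 1 over days 0..8,
# then 1.
donorRamp <- function(days) pmin(1, pmax(0, days / 8))
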