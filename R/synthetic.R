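#' Synthetic cf-mRNA data generators
#'
#' Every input the pipeline consumes can be generated with known ground
#' truth: a cell-type reference with planted marker genes, TPM mixtures with
#' known proportions, ablation/reconstitution time courses, clonal Ig count
#' tables, and host/donor SNP allele-count series. Ground truth travels with
#' each object (see [groundTruth()]).
#'
#' @name synthetic
NULL

#' Generate a synthetic cell-type reference with planted markers
#'
#' Draws a log-normal expression background for every entity x gene cell and
#' then plants `markersPerType` marker genes per cell type: a marker's
#' expression in its own type is set to exactly `markerFold` times its
#' maximum over all other types. With `markerFold > 20` every planted marker
#' passes the 20-fold specificity rule of [callSpecificGenes()]; with
#' `markerFold <= 20` none does (the rule is a strict inequality).
#'
#' @param config a [SimulationConfig-class].
#' @return A [ReferenceMatrix-class]; `groundTruth(x)$marker_assignment` maps
#'   each planted marker gene to its cell type.
#' @examples
#' ref <- generateReference(simulationConfig(nGenes = 60, nCelltypes = 3,
#'                                           markersPerType = 5, seed = 7))
#' table(groundTruth(ref)$marker_assignment)
#' @export
generateReference <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  nG <- config@nGenes; nT <- config@nCelltypes; nM <- config@markersPerType
  genes <- sprintf("gene%04d", seq_len(nG))
  types <- sprintf("celltype%d", seq_len(nT))
  withr::with_seed(.substream(config@seed, 1L), {
    mu <- log(config@backgroundLevel) - config@logSigma^2 / 2
    vals <- matrix(stats::rlnorm(nT * nG, meanlog = mu,
                                 sdlog = config@logSigma),
                   nrow = nT, ncol = nG, dimnames = list(types, genes))
    markerGenes <- sample(genes, nM * nT)
  })
  assignment <- stats::setNames(rep(types, each = nM), markerGenes)
  for (i in seq_along(markerGenes)) {
    g <- markerGenes[i]; t <- assignment[[i]]
    others <- vals[setdiff(types, t), g]
    vals[t, g] <- config@markerFold * max(others)
  }
  ReferenceMatrix(vals, metadata = list(groundTruth = list(
    marker_assignment = assignment)))
}

# Dirichlet(alpha = 1) draw on the k-simplex.
.rdirichlet <- function(k) { g <- stats::rgamma(k, 1); g / sum(g) }

# Apply the configured noise model to an expected TPM matrix and return a
# TPM-renormalized matrix. Noiseless mode is the exact expectation of every
# stochastic mode.
.applyNoise <- function(expected, config) {
  out <- switch(config@noiseModel,
    none = expected,
    multinomial = apply(expected, 2L, function(col)
      stats::rmultinom(1L, size = round(config@readDepth),
                       prob = col / sum(col))[, 1L]),
    lognormal = expected * matrix(
      stats::rlnorm(length(expected),
                    meanlog = -config@logSigma^2 / 2,
                    sdlog = config@logSigma),
      nrow = nrow(expected))
  )
  dimnames(out) <- dimnames(expected)
  .tpmNormalize(out)
}

#' Generate TPM mixtures of cell-type profiles with known proportions
#'
#' The expected expression of each sample is the proportion-weighted sum of
#' the reference cell-type profiles, rescaled so every column sums to 1e6
#' (TPM). `noiseModel = "none"` returns the exact expectation;
#' `"multinomial"` draws `readDepth` reads from it and renormalizes;
#' `"lognormal"` applies mean-one multiplicative noise.
#'
#' @param reference a [ReferenceMatrix-class].
#' @param proportions mixture weights: a vector of length `nCelltypes` (one
#'   sample), an entity x sample matrix, or `NULL` to draw `nSamples`
#'   Dirichlet(1) proportion vectors.
#' @param config a [SimulationConfig-class] (noise model, read depth, seed).
#' @param nSamples number of samples when `proportions` is `NULL`.
#' @return A `SummarizedExperiment` (assay `"tpm"`, genes x samples) with
#'   `groundTruth(x)$true_proportions` (entity x sample).
#' @export
generateMixture <- function(reference, proportions = NULL, config,
                            nSamples = 12L) {
  stopifnot(is(reference, "ReferenceMatrix"), is(config, "SimulationConfig"))
  S <- refValues(reference)
  nT <- nrow(S)
  seed <- .substream(config@seed, 2L)
  withr::with_seed(seed, {
    if (is.null(proportions)) {
      P <- replicate(nSamples, .rdirichlet(nT))
    } else if (is.matrix(proportions)) {
      P <- proportions
    } else {
      P <- matrix(proportions, ncol = 1L)
    }
    if (nrow(P) != nT)
      stop("proportions must have one entry per reference entity")
    apply(P, 2L, .checkProportions, n = nT)
    rownames(P) <- rownames(S)
    if (is.null(colnames(P)))
      colnames(P) <- sprintf("sample%02d", seq_len(ncol(P)))
    expected <- .tpmNormalize(t(S) %*% P)
    tpm <- .applyNoise(expected, config)
  })
  .makeSE(tpm,
          colData = S4Vectors::DataFrame(sample = colnames(P),
                                         row.names = colnames(P)),
          groundTruth = list(true_proportions = P))
}

# Piecewise lineage activity: plateau at preLevel up to ablationDay,
# log-linear decay to nadirLevel at recoveryStartDay, then exponential
# recovery at recoveryRate per day, capped at preLevel. nadirLevel = 0 is
# absorbing (activity stays 0 from recoveryStartDay on).
.lineageActivity <- function(day, preLevel, ablationDay, nadirLevel,
                             recoveryStartDay, recoveryRate) {
  vapply(day, function(d) {
    if (d <= ablationDay) return(preLevel)
    if (d < recoveryStartDay) {
      if (nadirLevel <= 0) {
        # linear-in-value descent to exactly 0
        frac <- (d - ablationDay) / (recoveryStartDay - ablationDay)
        return(preLevel * (1 - frac))
      }
      lf <- (d - ablationDay) / (recoveryStartDay - ablationDay)
      return(exp((1 - lf) * log(preLevel) + lf * log(nadirLevel)))
    }
    if (nadirLevel <= 0) return(0)
    min(preLevel, nadirLevel * exp(recoveryRate * (d - recoveryStartDay)))
  }, numeric(1))
}

#' Generate an ablation/reconstitution time course
#'
#' Builds one mixture per day of `config@timeGrid`, with each lineage's
#' mixture weight following a piecewise trajectory: a pre-ablation plateau,
#' log-linear decay from the ablation day to a nadir at the recovery start
#' day, then exponential recovery (rate per day) capped at the pre-ablation
#' level. Lineage markers scale with their lineage's activity; entities not
#' listed in `trajectorySpec` keep constant weight 1.
#'
#' @param reference a [ReferenceMatrix-class].
#' @param trajectorySpec data.frame with columns `lineage` (entity name),
#'   `preLevel`, `ablationDay`, `nadirLevel`, `recoveryStartDay`,
#'   `recoveryRate`; all levels must be >= 0.
#' @param config a [SimulationConfig-class] whose `timeGrid` covers the
#'   ablation day.
#' @return A `SummarizedExperiment` (assay `"tpm"`, genes x days, `colData`
#'   column `day`) with ground truth `lineage_trajectories` (entity x day
#'   activity) and `true_proportions` (entity x day mixture weights).
#' @export
generateTimecourse <- function(reference, trajectorySpec, config) {
  stopifnot(is(reference, "ReferenceMatrix"), is(config, "SimulationConfig"))
  need <- c("lineage", "preLevel", "ablationDay", "nadirLevel",
            "recoveryStartDay", "recoveryRate")
  if (!all(need %in% names(trajectorySpec)))
    stop("trajectorySpec must have columns: ", paste(need, collapse = ", "))
  if (any(trajectorySpec$preLevel < 0) || any(trajectorySpec$nadirLevel < 0))
    stop("trajectory levels must be non-negative")
  days <- config@timeGrid
  if (!length(days)) stop("config@timeGrid must be non-empty")
  if (any(trajectorySpec$ablationDay < min(days) |
          trajectorySpec$ablationDay > max(days)))
    stop("timeGrid must cover every ablation day")
  S <- refValues(reference)
  missing <- setdiff(trajectorySpec$lineage, rownames(S))
  if (length(missing))
    stop("unknown lineage entity: ", paste(missing, collapse = ", "))
  W <- matrix(1, nrow = nrow(S), ncol = length(days),
              dimnames = list(rownames(S), paste0("day", days)))
  for (i in seq_len(nrow(trajectorySpec))) {
    r <- trajectorySpec[i, ]
    W[r$lineage, ] <- .lineageActivity(days, r$preLevel, r$ablationDay,
                                       r$nadirLevel, r$recoveryStartDay,
                                       r$recoveryRate)
  }
  P <- sweep(W, 2L, colSums(W), "/")
  expected <- .tpmNormalize(t(S) %*% P)
  withr::with_seed(.substream(config@seed, 3L), {
    tpm <- .applyNoise(expected, config)
  })
  .makeSE(tpm,
          colData = S4Vectors::DataFrame(day = days,
                                         row.names = colnames(W)),
          groundTruth = list(lineage_trajectories = W,
                             true_proportions = P,
                             days = days))
}

#' Generate an immunoglobulin segment count table with a planted clone
#'
#' At each day, reads are drawn multinomially over `length(cloneSegments) +
#' repertoireSize` segments. The planted clone receives a fraction
#' `cloneFraction` of the expected reads (split equally over its segments);
#' the remainder is shared symmetrically by *all* segments, so at
#' `cloneFraction = 0` every segment — clone included — has expected relative
#' abundance `1 / nSegments`.
#'
#' @param cloneSegments character vector of IMGT-style clone segment names
#'   (for example `c("IGHV3-15", "IGKV2-24")`).
#' @param cloneFractionSeries per-day expected clone read fraction, each in
#'   `[0, 1]`.
#' @param repertoireSize number of background segments (spread round-robin
#'   over the clone segments' Ig classes).
#' @param totalReads reads per day (every column of the result sums to this).
#' @param seed integer random seed.
#' @param days day labels, defaulting to `seq_along(cloneFractionSeries)`.
#' @return An [IgCountTable-class]; `groundTruth(x)$clone_fractions` records
#'   the *effective* expected clone fraction per day,
#'   `cloneFraction + (1 - cloneFraction) * nClone / nSegments`.
#' @export
generateIgCounts <- function(cloneSegments, cloneFractionSeries,
                             repertoireSize = 50L, totalReads = 1e4,
                             seed = 1L, days = NULL) {
  if (any(cloneFractionSeries < 0 | cloneFractionSeries > 1))
    stop("clone fractions must lie in [0, 1]")
  if (!length(cloneSegments) && any(cloneFractionSeries > 0))
    stop("non-zero clone fraction requires at least one clone segment")
  if (is.null(days)) days <- seq_along(cloneFractionSeries)
  stopifnot(length(days) == length(cloneFractionSeries))
  nClone <- length(cloneSegments)
  cloneClasses <- if (nClone) inferIgClass(cloneSegments) else "heavy-variable"
  bgClasses <- rep_len(unique(cloneClasses), repertoireSize)
  prefix <- c("heavy-variable" = "IGHV", "heavy-constant" = "IGHG",
              "kappa-variable" = "IGKV", "kappa-constant" = "IGKC",
              "lambda-variable" = "IGLV", "lambda-constant" = "IGLC")
  bgNames <- paste0(prefix[bgClasses], "-bg",
                    formatC(seq_len(repertoireSize), width = 3, flag = "0"))
  segments <- c(cloneSegments, bgNames)
  nSeg <- length(segments)
  counts <- matrix(0, nrow = nSeg, ncol = length(days),
                   dimnames = list(segments, as.character(days)))
  withr::with_seed(.substream(seed, 4L), {
    for (j in seq_along(days)) {
      cf <- cloneFractionSeries[j]
      p <- rep((1 - cf) / nSeg, nSeg)
      if (nClone) p[seq_len(nClone)] <- p[seq_len(nClone)] + cf / nClone
      counts[, j] <- stats::rmultinom(1L, size = round(totalReads), p)[, 1L]
    }
  })
  effective <- cloneFractionSeries +
    (1 - cloneFractionSeries) * nClone / nSeg
  IgCountTable(counts,
               segmentClass = c(if (nClone) cloneClasses, bgClasses),
               days = days,
               metadata = list(groundTruth = list(
                 clone_segments = cloneSegments,
                 clone_fractions = stats::setNames(effective,
                                                   as.character(days)),
                 planted_fractions = cloneFractionSeries,
                 days = days)))
}

.GENOTYPE_FREQ <- c("hom-ref" = 1, "het" = 0.5, "hom-alt" = 0)

#' Generate host/donor SNP allele counts under a mixing ramp
#'
#' The expected reference-allele frequency at each SNP and day is
#' `(1 - m) * f_host + m * f_donor`, where `m` is the donor fraction of
#' marrow output that day and `f` maps hom-ref to 1, het to 0.5, hom-alt
#' to 0, adjusted for a symmetric per-read miscall probability
#' (`p' = p (1 - e) + (1 - p) e`). Reference counts are binomial at the
#' stated depth.
#'
#' @param genotypes data.frame with columns `snp`, `host`, `donor`; genotype
#'   codes are `"hom-ref"`, `"het"`, `"hom-alt"`.
#' @param mixingFraction per-day donor fraction, each in `[0, 1]`.
#' @param depth reads per SNP per day (>= 1).
#' @param errorRate per-read miscall probability in `[0, 0.5)`.
#' @param seed integer random seed.
#' @param days integer day labels, same length as `mixingFraction`.
#' @param transplantDay transplant day (default 0).
#' @return A [SnpCountTable-class] with ground truth `genotypes`,
#'   `mixing_fraction` and the analytic `expected_frequency` matrix.
#' @export
generateSnpCounts <- function(genotypes, mixingFraction, depth = 200L,
                              errorRate = 0.01, seed = 1L, days,
                              transplantDay = 0L) {
  stopifnot(all(c("snp", "host", "donor") %in% names(genotypes)))
  codes <- unique(c(genotypes$host, genotypes$donor))
  bad <- setdiff(codes, names(.GENOTYPE_FREQ))
  if (length(bad))
    stop("unknown genotype code: ", paste(bad, collapse = ", "))
  if (depth < 1) stop("depth must be >= 1")
  if (errorRate < 0 || errorRate >= 0.5)
    stop("errorRate must lie in [0, 0.5)")
  if (any(mixingFraction < 0 | mixingFraction > 1))
    stop("mixingFraction must lie in [0, 1]")
  stopifnot(length(days) == length(mixingFraction))
  fHost <- .GENOTYPE_FREQ[genotypes$host]
  fDonor <- .GENOTYPE_FREQ[genotypes$donor]
  pRef <- outer(fHost, 1 - mixingFraction) + outer(fDonor, mixingFraction)
  pObs <- pRef * (1 - errorRate) + (1 - pRef) * errorRate
  dimnames(pObs) <- list(genotypes$snp, as.character(days))
  withr::with_seed(.substream(seed, 5L), {
    ref <- matrix(stats::rbinom(length(pObs), size = round(depth),
                                prob = pObs),
                  nrow = nrow(pObs), dimnames = dimnames(pObs))
  })
  alt <- round(depth) - ref
  SnpCountTable(ref, alt, days = days, transplantDay = transplantDay,
                metadata = list(groundTruth = list(
                  genotypes = genotypes,
                  mixing_fraction = stats::setNames(mixingFraction,
                                                    as.character(days)),
                  expected_frequency = pObs)))
}
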