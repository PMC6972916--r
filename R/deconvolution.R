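#' Filter lowly expressed genes and max-normalize rows
#'
#' Genes whose expression is below `minTpm` in all samples are excluded;
#' each retained gene's row is divided by its own maximum over samples, so
#' every row attains exactly 1. This brings all genes to a comparable scale
#' before factorization, focusing the decomposition on co-expression
#' patterns rather than absolute levels.
#'
#' @param x a `SummarizedExperiment` (assay `"tpm"`) or gene x sample matrix.
#' @param minTpm retention threshold on the per-gene maximum (default 20).
#' @return A list with `normalized` (gene x sample matrix, row maxima 1) and
#'   `retainedGenes` (character).
#' @export
filterAndNormalize <- function(x, minTpm = 20) {
  m <- .tpm(x)
  if (!nrow(m) || !ncol(m)) stop("empty expression matrix")
  mx <- .rowMax(m)
  keep <- mx >= minTpm
  if (!any(keep)) stop("all genes fall below ", minTpm, " TPM in all samples")
  norm <- m[keep, , drop = FALSE] / mx[keep]
  list(normalized = norm, retainedGenes = rownames(m)[keep])
}

#' Decompose a normalized expression matrix by NMF
#'
#' Factorizes a non-negative gene x sample matrix into gene x component
#' loadings and component x sample activities using HALS updates (with
#' objective-guarded extrapolation) from a deterministic NNDSVD
#' initialization (seeded random fill of its zeros). The Frobenius
#' objective is non-increasing across iterations and the result is
#' deterministic given `seed`. Non-convergence within `maxIter` is reported
#' through the convergence flag, not an error.
#'
#' @param x gene x sample non-negative matrix (typically the `normalized`
#'   element of [filterAndNormalize()]).
#' @param nComponents factorization rank, in `[2, min(dim(x))]` (transcriptome
#'   decompositions conventionally use 8-12).
#' @param seed integer seed.
#' @param maxIter maximum HALS sweeps (default 30000; sweeps are cheap and
#'   near-exact factorizations of low-rank data need many of them).
#' @param tol relative objective-decrease tolerance declaring convergence
#'   (default 1e-12).
#' @param relTol relative-residual floor: iteration stops once
#'   `||X - WH||_F / ||X||_F` falls below it (default 1e-7).
#' @return An [NmfDecomposition-class] (annotations all `"unannotated"`).
#' @export
nmfDecompose <- function(x, nComponents, seed = 1L, maxIter = 30000L,
                         tol = 1e-12, relTol = 1e-7) {
  m <- .tpm(x)
  if (nComponents < 1L || nComponents > min(dim(m)))
    stop("nComponents must lie in [1, min(genes, samples)]")
  if (any(m < 0)) stop("NMF requires a non-negative matrix")
  init <- .nndsvdInit(m, nComponents, seed = .substream(seed, 11L))
  fit <- .halsFit(m, init$W, init$H, maxIter = maxIter, tol = tol,
                  relTol = relTol)
  dimnames(fit$W) <- list(rownames(m),
                          sprintf("component%d", seq_len(nComponents)))
  dimnames(fit$H) <- list(colnames(fit$W), colnames(m))
  new("NmfDecomposition", loadings = fit$W, activities = fit$H,
      annotations = rep("unannotated", nComponents),
      objective = fit$objective, converged = fit$converged,
      seed = as.integer(seed))
}

#' Select an NMF rank by held-out reconstruction error
#'
#' Masks a random fraction of matrix entries, fits a masked NMF at each
#' candidate rank on the observed entries only, and returns the rank with
#' the smallest squared error on the held-out entries.
#'
#' @param x gene x sample non-negative matrix.
#' @param ranks candidate ranks (default `8:12`).
#' @param holdout fraction of entries held out (default 0.1).
#' @param seed integer seed (mask and initialization).
#' @param maxIter masked-fit iterations per rank (default 300).
#' @return A list with `rank` (the selected rank) and `heldOutError`
#'   (named numeric, one entry per candidate).
#' @export
nmfSelectRank <- function(x, ranks = 8:12, holdout = 0.1, seed = 1L,
                          maxIter = 300L) {
  m <- .tpm(x)
  withr::with_seed(.substream(seed, 12L), {
    M <- matrix(stats::rbinom(length(m), 1L, 1 - holdout), nrow = nrow(m))
  })
  err <- vapply(ranks, function(k) {
    fit <- .maskedMuFit(m, M, k, seed = .substream(seed, 12L + k),
                        maxIter = maxIter)
    R <- m - fit$W %*% fit$H
    sum(((1 - M) * R)^2)
  }, numeric(1))
  names(err) <- as.character(ranks)
  list(rank = ranks[which.min(err)], heldOutError = err)
}

#' Annotate NMF components with cell types via specificity calls
#'
#' For each component, its `topN` highest-loading genes are looked up in a
#' set of specificity calls; the component is labelled with the entity
#' holding a plurality of those genes' calls, provided that plurality
#' exceeds `minFraction` of `topN`. Otherwise it stays `"unannotated"`.
#' The per-component evidence (how many top genes voted for each entity) is
#' kept for review.
#'
#' @param decomposition an [NmfDecomposition-class].
#' @param calls result of [callSpecificGenes()] on a reference sharing the
#'   decomposition's gene universe.
#' @param topN number of top-loading genes examined per component
#'   (default 25).
#' @param minFraction minimum vote fraction of `topN` needed to annotate
#'   (default 0.5).
#' @return The decomposition with its `annotations` slot filled; the vote
#'   tables are attached as attribute `"evidence"` of the annotations.
#' @export
annotateComponents <- function(decomposition, calls, topN = 25L,
                               minFraction = 0.5) {
  W <- loadings(decomposition)
  if (topN > nrow(W)) stop("topN exceeds the number of genes")
  lookup <- stats::setNames(calls$topEntity, calls$gene)
  evidence <- vector("list", ncol(W))
  ann <- rep("unannotated", ncol(W))
  for (j in seq_len(ncol(W))) {
    top <- rownames(W)[order(W[, j], decreasing = TRUE)[seq_len(topN)]]
    votes <- table(lookup[top], useNA = "no")
    evidence[[j]] <- votes
    if (length(votes)) {
      best <- which.max(votes)
      if (votes[best] / topN > minFraction) ann[j] <- names(votes)[best]
    }
  }
  names(evidence) <- colnames(W)
  attr(ann, "evidence") <- evidence
  decomposition@annotations <- ann
  validObject(decomposition)
  decomposition
}

#' Estimate tissue fractions by simplex-constrained non-negative least squares
#'
#' Solves `min || x - t(S) p ||^2` subject to `p >= 0`, `sum(p) = 1` for
#' each sample, where `S` is an entity x gene signature matrix restricted to
#' cell-type-specific genes. Because TPM renormalization makes the sample's
#' overall scale arbitrary, the solve is scale-free: an unconstrained
#' non-negative least-squares pass (Lawson-Hanson) first puts the sample on
#' the signature's scale, then the simplex constraint is enforced through an
#' augmented all-ones row with a large weight, and the result is
#' renormalized to sum exactly 1. By default only signature genes detected
#' in the sample (> 0 TPM) enter the fit.
#'
#' @param x named TPM vector (one sample) or gene x sample matrix /
#'   `SummarizedExperiment`.
#' @param signature entity x gene matrix over specific genes (see
#'   [signatureMatrix()]), at least two entities.
#' @param constraintWeight weight of the sum-to-one row, as a multiple of
#'   the mean signature magnitude (default 1e3).
#' @param detectedOnly drop signature genes with 0 TPM in the sample before
#'   fitting (default TRUE).
#' @return A [FractionEstimate-class]. A numerically rank-deficient
#'   signature triggers a warning and sets the `rankDeficient` flag; the
#'   estimate is still returned.
#' @export
estimateFractions <- function(x, signature, constraintWeight = 1e3,
                              detectedOnly = TRUE) {
  if (nrow(signature) < 2L) stop("signature needs at least 2 entities")
  m <- if (is.matrix(x) || methods::is(x, "SummarizedExperiment")) .tpm(x)
       else matrix(x, ncol = 1L, dimnames = list(names(x), "sample1"))
  shared <- intersect(colnames(signature), rownames(m))
  if (!length(shared)) stop("sample and signature share no genes")
  Ct <- t(signature[, shared, drop = FALSE])      # gene x entity
  rankDef <- qr(Ct)$rank < ncol(Ct)
  if (rankDef)
    warning("signature matrix is rank-deficient; fractions are not unique")
  k <- ncol(Ct)
  w <- constraintWeight * mean(abs(Ct))
  # a tiny ridge keeps the active-set solver away from singular subproblems
  # when entities are collinear; the returned estimate is then one of the
  # non-unique minimizers
  ridge <- if (rankDef) sqrt(1e-10) * mean(abs(Ct)) * diag(k) else NULL
  frac <- matrix(NA_real_, nrow = k, ncol = ncol(m),
                 dimnames = list(rownames(signature), colnames(m)))
  res <- numeric(ncol(m))
  for (s in seq_len(ncol(m))) {
    xs <- m[shared, s]
    use <- if (detectedOnly) xs > 0 else rep(TRUE, length(xs))
    if (!any(use)) stop("no detected signature genes in sample ",
                        colnames(m)[s])
    C <- Ct[use, , drop = FALSE]; d <- xs[use]
    if (!is.null(ridge)) { C <- rbind(C, ridge); d <- c(d, rep(0, k)) }
    u <- pracma::lsqnonneg(C, d)$x
    sc <- sum(u)
    if (sc <= 0) sc <- 1
    dS <- d / sc
    Caug <- rbind(C, rep(w, k))
    p <- pracma::lsqnonneg(Caug, c(dS, w))$x
    if (sum(p) <= 0) p <- rep(1 / k, k)
    p <- p / sum(p)
    frac[, s] <- p
    res[s] <- sqrt(sum((C %*% (sc * p) - d)^2))
  }
  new("FractionEstimate", fractions = frac, residualNorm = res,
      rankDeficient = rankDef)
}

#' Per-sample contributions of annotated NMF components
#'
#' Turns component activities into per-sample contribution shares: loadings
#' columns are L1-normalized (pushing their mass into the activities), each
#' sample's activities are divided by their total, and shares are summed by
#' annotation label. Shares sum to 1 for every sample.
#'
#' @param decomposition an annotated [NmfDecomposition-class].
#' @return A [FractionEstimate-class] over annotation labels (including
#'   `"unannotated"` when present).
#' @export
componentFractions <- function(decomposition) {
  W <- loadings(decomposition); H <- activities(decomposition)
  ann <- annotations(decomposition)
  if (all(ann == "unannotated"))
    stop("no component is annotated; run annotateComponents() first")
  mass <- colSums(W)
  Ht <- H * mass                       # recycles mass down rows
  tot <- colSums(Ht)
  if (any(tot <= 0)) stop("a sample has zero total component activity")
  shares <- sweep(Ht, 2L, tot, "/")
  labels <- sort(unique(ann))
  agg <- matrix(0, nrow = length(labels), ncol = ncol(H),
                dimnames = list(labels, colnames(H)))
  for (i in seq_along(ann))
    agg[ann[i], ] <- agg[ann[i], ] + shares[i, ]
  new("FractionEstimate", fractions = agg,
      residualNorm = rep(NA_real_, ncol(agg)),
      rankDeficient = FALSE)
}
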