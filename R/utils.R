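# Internal helpers shared across modules.

# Coerce an expression container (SummarizedExperiment with a "tpm" assay,
# or a plain gene x sample matrix) to a base matrix.
.tpm <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    nm <- SummarizedExperiment::assayNames(x)
    a <- if (!is.null(nm) && "tpm" %in% nm) "tpm" else 1L
    return(SummarizedExperiment::assay(x, a))
  }
  if (is.matrix(x)) return(x)
  stop("expected a SummarizedExperiment or a gene x sample matrix")
}

# Rescale each column to sum to 1e6 (TPM convention).
.tpmNormalize <- function(m) {
  cs <- colSums(m)
  if (any(cs <= 0)) stop("cannot TPM-normalize a column with zero total")
  sweep(m, 2L, cs / 1e6, "/")
}

# Derive a per-operation substream seed from one global seed. Knuth-style
# multiplicative hash folded into [0, 2^31 - 2] so the result is a valid
# 32-bit R seed.
.substream <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) + 1
  h <- (s * 48271 + stream * 1664525 + 1013904223) %% 2147483647
  as.integer(h)
}

# Row maxima / minima without matrixStats.
.rowMax <- function(m) apply(m, 1L, max)
.rowMin <- function(m) apply(m, 1L, min)

# Wrap a gene x sample TPM matrix as a SummarizedExperiment with optional
# column data and ground truth in metadata.
.makeSE <- function(tpm, colData = NULL, groundTruth = NULL) {
  args <- list(assays = list(tpm = tpm))
  if (!is.null(colData)) args$colData <- colData
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  if (!is.null(groundTruth))
    S4Vectors::metadata(se)$groundTruth <- groundTruth
  se
}

# Validate a proportion vector (non-negative, sums to 1 within tol).
.checkProportions <- function(p, n = NULL, tol = 1e-9) {
  if (!is.null(n) && length(p) != n)
    stop("proportions must have length ", n)
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > tol)
    stop("proportions must sum to 1 (got ", format(sum(p), digits = 12), ")")
  invisible(p)
}
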