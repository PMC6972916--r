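#' Select time-varying genes
#'
#' A gene is time-varying when (1) its maximum expression across time points
#' exceeds `minMaxTpm` and (2) the ratio of its highest to lowest expression
#' exceeds `minRatio`. The ratio is computed as
#' `(max + pc) / (min + pc)`; the default pseudocount of 1 TPM keeps it
#' finite when the minimum is 0 (set `ratioPseudocount = 0` for the strict
#' ratio, which is infinite at zero minima).
#'
#' @param x a `SummarizedExperiment` or gene x day TPM matrix with at least
#'   two time points.
#' @param minMaxTpm expression floor on the per-gene maximum (default 50).
#' @param minRatio max/min ratio threshold, strict `>` (default 5).
#' @param ratioPseudocount TPM added to numerator and denominator
#'   (default 1).
#' @return Character vector of selected gene identifiers.
#' @export
selectTimeVarying <- function(x, minMaxTpm = 50, minRatio = 5,
                              ratioPseudocount = 1) {
  m <- .tpm(x)
  if (ncol(m) < 2L) stop("need at least two time points")
  mx <- .rowMax(m); mn <- .rowMin(m)
  rownames(m)[mx > minMaxTpm &
              (mx + ratioPseudocount) > minRatio * (mn + ratioPseudocount)]
}

#' Max-normalize temporal profiles
#'
#' Divides each gene's values by its maximum across time points, so every
#' row attains exactly 1; relative shape (and each row's argmax) is
#' preserved. This brings genes to a comparable scale so clustering sees
#' temporal pattern, not absolute level.
#'
#' @param x `SummarizedExperiment` or gene x day matrix; every row must have
#'   a positive maximum.
#' @param genes optional subset of genes (typically from
#'   [selectTimeVarying()]).
#' @return Gene x day matrix with row maxima exactly 1.
#' @export
maxNormalize <- function(x, genes = NULL) {
  m <- .tpm(x)
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  mx <- .rowMax(m)
  if (any(mx <= 0)) stop("cannot max-normalize all-zero rows: ",
                         paste(rownames(m)[mx <= 0], collapse = ", "))
  m / mx
}

#' Cluster temporal gene profiles
#'
#' Partitions max-normalized gene profiles into `k` clusters by k-means
#' (seeded, best of `nstart` restarts) or hierarchical clustering (Euclidean
#' distance, configurable linkage, tree cut at `k`).
#'
#' @param profiles gene x day matrix of normalized profiles (rows in
#'   `[0, 1]`, maxima 1).
#' @param method `"kmeans"` or `"hierarchical"`.
#' @param k number of clusters, `2 <= k <= nrow(profiles)` (default 8).
#' @param seed integer seed for k-means restarts.
#' @param nstart k-means restarts (default 10).
#' @param linkage hierarchical linkage (default `"average"`).
#' @param centers optional matrix of initial k-means centers (overrides the
#'   seeded restarts).
#' @return A list with `membership` (named integer vector), `method`, `k`,
#'   and `centers` (cluster x day mean profiles).
#' @export
clusterGenes <- function(profiles, method = c("kmeans", "hierarchical"),
                         k = 8L, seed = 1L, nstart = 10L,
                         linkage = "average", centers = NULL) {
  method <- match.arg(method)
  if (k > nrow(profiles)) stop("k exceeds the number of genes")
  if (k < 1L) stop("k must be >= 1")
  if (method == "kmeans") {
    if (k == nrow(profiles)) {
      membership <- stats::setNames(seq_len(nrow(profiles)),
                                    rownames(profiles))
      ctr <- profiles
    } else if (!is.null(centers)) {
      km <- stats::kmeans(profiles, centers = centers)
      membership <- stats::setNames(km$cluster, rownames(profiles))
      ctr <- km$centers
    } else {
      km <- withr::with_seed(.substream(seed, 21L),
        stats::kmeans(profiles, centers = k, nstart = nstart))
      membership <- stats::setNames(km$cluster, rownames(profiles))
      ctr <- km$centers
    }
  } else {
    hc <- stats::hclust(stats::dist(profiles), method = linkage)
    membership <- stats::setNames(stats::cutree(hc, k = k),
                                  rownames(profiles))
    ctr <- do.call(rbind, lapply(split(seq_along(membership), membership),
      function(i) colMeans(profiles[i, , drop = FALSE])))
  }
  list(membership = membership, method = method, k = as.integer(k),
       centers = ctr)
}

#' Summarize a lineage's temporal trajectory
#'
#' Computes, per gene of a lineage gene set, the fold change (or percent
#' change) relative to the gene's value at a reference day, then averages
#' across genes per day. Genes exceeding `maxTpmCap` at any day are excluded
#' when the cap is set (the figure-style convention is 5000 TPM); genes with
#' value 0 at the reference day are excluded in fold-change mode (or given
#' pseudocount 1 with `zeroReference = "pseudocount"`).
#'
#' @param x `SummarizedExperiment` (with a `day` column in `colData`) or
#'   gene x day matrix with days as column names or given via `days`.
#' @param lineageGenes character vector of lineage gene identifiers.
#' @param mode `"fold_change"` or `"percent_change"`.
#' @param referenceDay day used as denominator; must be in the series.
#' @param maxTpmCap optional TPM cap excluding very abundant genes
#'   (default `Inf`, i.e. off).
#' @param average `"arithmetic"` (mean of per-gene ratios, default) or
#'   `"geometric"`.
#' @param zeroReference `"exclude"` (default) or `"pseudocount"`.
#' @param days optional numeric day per column when `x` is a matrix without
#'   parseable column names.
#' @return A data.frame with `day`, `mean`, `se`, `nGenes`; per-gene traces
#'   are attached as attribute `"traces"`, excluded genes as `"excluded"`.
#' @export
lineageTrajectory <- function(x, lineageGenes,
                              mode = c("fold_change", "percent_change"),
                              referenceDay, maxTpmCap = Inf,
                              average = c("arithmetic", "geometric"),
                              zeroReference = c("exclude", "pseudocount"),
                              days = NULL) {
  mode <- match.arg(mode)
  average <- match.arg(average)
  zeroReference <- match.arg(zeroReference)
  m <- .tpm(x)
  if (is.null(days)) {
    if (methods::is(x, "SummarizedExperiment") &&
        "day" %in% names(SummarizedExperiment::colData(x)))
      days <- SummarizedExperiment::colData(x)$day
    else
      days <- suppressWarnings(as.numeric(sub("^day", "", colnames(m))))
  }
  if (anyNA(days)) stop("cannot determine day for every column")
  if (!referenceDay %in% days) stop("referenceDay not present in the series")
  present <- intersect(lineageGenes, rownames(m))
  if (!length(present)) stop("no lineage gene present in the matrix")
  sub <- m[present, , drop = FALSE]
  excluded <- character()
  if (is.finite(maxTpmCap)) {
    over <- .rowMax(sub) >= maxTpmCap
    excluded <- c(excluded, rownames(sub)[over])
    sub <- sub[!over, , drop = FALSE]
  }
  refCol <- which(days == referenceDay)[1L]
  refVal <- sub[, refCol]
  if (zeroReference == "exclude") {
    zero <- refVal == 0
    excluded <- c(excluded, rownames(sub)[zero])
    sub <- sub[!zero, , drop = FALSE]
    refVal <- refVal[!zero]
  } else {
    refVal[refVal == 0] <- 1
  }
  if (!nrow(sub)) stop("no lineage gene left after filtering")
  ratios <- sub / refVal
  mu <- if (average == "arithmetic") colMeans(ratios)
        else exp(colMeans(log(ratios)))
  if (mode == "percent_change") {
    ratios <- 100 * (ratios - 1)
    mu <- 100 * (mu - 1)
  }
  se <- apply(ratios, 2L, stats::sd) / sqrt(nrow(ratios))
  out <- data.frame(day = days, mean = unname(mu), se = unname(se),
                    nGenes = nrow(ratios))
  attr(out, "traces") <- ratios
  attr(out, "excluded") <- excluded
  out
}
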