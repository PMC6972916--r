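#' Relative abundance of Ig gene segments
#'
#' The relative abundance of a segment is its read count divided by the
#' total reads in scope — either within its own Ig class (heavy-variable
#' normalized separately from kappa-variable, and so on; the default,
#' matching per-panel repertoire plots) or over all Ig segments. A sample
#' with zero reads in a scope gets `NA` fractions there (flagged, never
#' silently 0).
#'
#' @param table an [IgCountTable-class].
#' @param scope `"per-class"` (default) or `"all-Ig"`.
#' @return A segment x sample matrix of fractions; samples/scopes with zero
#'   totals are `NA` and listed in attribute `"zeroTotal"`.
#' @export
relativeAbundance <- function(table, scope = c("per-class", "all-Ig")) {
  scope <- match.arg(scope)
  cts <- igCounts(table)
  cls <- segmentClasses(table)
  frac <- matrix(NA_real_, nrow = nrow(cts), ncol = ncol(cts),
                 dimnames = dimnames(cts))
  zero <- character()
  groups <- if (scope == "per-class") split(seq_len(nrow(cts)), cls)
            else list(`all-Ig` = seq_len(nrow(cts)))
  for (g in names(groups)) {
    idx <- groups[[g]]
    tot <- colSums(cts[idx, , drop = FALSE])
    ok <- tot > 0
    frac[idx, ok] <- sweep(cts[idx, ok, drop = FALSE], 2L, tot[ok], "/")
    if (any(!ok))
      zero <- c(zero, paste(g, colnames(cts)[!ok], sep = "/"))
  }
  attr(frac, "zeroTotal") <- zero
  frac
}

#' Detect dominant (clonal) Ig segments
#'
#' A segment is called dominant in a sample when its within-class fraction
#' strictly exceeds `dominanceThreshold`, or when it exceeds
#' `minFoldOverSecond` times the second-ranked segment of its class — in
#' either case requiring at least `minTotalReads` reads in the class (which
#' guards against shot-noise calls). Both trigger conditions are recorded
#' per call.
#'
#' @param table an [IgCountTable-class].
#' @param dominanceThreshold absolute fraction trigger (default 0.5).
#' @param minFoldOverSecond fold-over-runner-up trigger (default 5).
#' @param minTotalReads minimum class reads for any call (default 100).
#' @param scope passed to [relativeAbundance()].
#' @return A data.frame of calls: `segment`, `class`, `day`, `sample`,
#'   `fraction`, `dominant`, `byFraction`, `byFold`.
#' @export
detectDominant <- function(table, dominanceThreshold = 0.5,
                           minFoldOverSecond = 5, minTotalReads = 100,
                           scope = "per-class") {
  cts <- igCounts(table)
  cls <- segmentClasses(table)
  frac <- relativeAbundance(table, scope = scope)
  days <- sampleDays(table)
  out <- list()
  groups <- if (scope == "per-class") split(seq_len(nrow(cts)), cls)
            else list(`all-Ig` = seq_len(nrow(cts)))
  for (g in names(groups)) {
    idx <- groups[[g]]
    for (s in seq_len(ncol(cts))) {
      tot <- sum(cts[idx, s])
      f <- frac[idx, s]
      if (tot <= 0) next
      ord <- order(f, decreasing = TRUE)
      second <- if (length(idx) > 1L) f[ord[2L]] else 0
      byFraction <- f > dominanceThreshold
      byFold <- if (second > 0) f > minFoldOverSecond * second
                else f > 0 & seq_along(f) == ord[1L]
      enough <- tot >= minTotalReads
      out[[length(out) + 1L]] <- data.frame(
        segment = rownames(cts)[idx],
        class = cls[idx],
        day = days[s],
        sample = colnames(cts)[s],
        fraction = unname(f),
        byFraction = unname(byFraction),
        byFold = unname(byFold),
        dominant = unname(enough & (byFraction | byFold)),
        row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Track a clone's summed fraction and its loss-of-dominance day
#'
#' Sums the within-scope fractions of the clone's segments per day and,
#' using the dominance rule of [detectDominant()], reports the
#' loss-of-dominance day: the first observed day after which the clone is
#' never dominant again within the series (`NA` when the clone is dominant
#' through the last day, or never dominant at all).
#'
#' @param table an [IgCountTable-class].
#' @param cloneSegments character vector of the clone's segment names; an
#'   absent segment is an error listing the missing names.
#' @param ... thresholds passed to [detectDominant()].
#' @return A list with `trajectory` (data.frame `day`, `fraction`,
#'   `dominant`) and `lossOfDominanceDay`.
#' @export
trackClone <- function(table, cloneSegments, ...) {
  cts <- igCounts(table)
  missing <- setdiff(cloneSegments, rownames(cts))
  if (length(missing))
    stop("clone segment(s) absent from table: ",
         paste(missing, collapse = ", "))
  frac <- relativeAbundance(table)
  days <- sampleDays(table)
  cloneFrac <- colSums(frac[cloneSegments, , drop = FALSE]) /
    length(unique(segmentClasses(table)[cloneSegments]))
  calls <- detectDominant(table, ...)
  cloneCalls <- calls[calls$segment %in% cloneSegments, , drop = FALSE]
  domDay <- vapply(seq_along(days), function(s)
    any(cloneCalls$dominant[cloneCalls$sample == colnames(cts)[s]]),
    logical(1))
  loss <- NA_real_
  if (any(domDay) && !domDay[length(domDay)]) {
    lastDom <- max(which(domDay))
    later <- days[days > days[lastDom]]
    if (length(later)) loss <- min(later)
  }
  list(trajectory = data.frame(day = days, fraction = unname(cloneFrac),
                               dominant = domDay),
       lossOfDominanceDay = loss)
}
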