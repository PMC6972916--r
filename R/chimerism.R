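#' Reference-allele frequencies from SNP allele counts
#'
#' Frequency is `ref / (ref + alt)` per SNP per day. Zero-depth entries are
#' `NA` (flagged, not imputed) and listed in attribute `"undefined"`.
#' Frequencies are invariant to uniform depth scaling.
#'
#' @param table a [SnpCountTable-class].
#' @return SNP x day matrix of frequencies in `[0, 1]` with attribute
#'   `"depth"` (SNP x day read depth).
#' @export
alleleFrequency <- function(table) {
  r <- refCounts(table); a <- altCounts(table)
  depth <- r + a
  freq <- ifelse(depth > 0, r / depth, NA_real_)
  dimnames(freq) <- dimnames(r)
  attr(freq, "depth") <- depth
  und <- which(depth == 0, arr.ind = TRUE)
  attr(freq, "undefined") <- if (nrow(und))
    paste(rownames(r)[und[, 1L]], colnames(r)[und[, 2L]], sep = "@")
    else character()
  freq
}

#' Classify a genotype from a reference-allele frequency
#'
#' Frequencies at or above `homThreshold` are hom-ref, at or below
#' `1 - homThreshold` hom-alt, otherwise het; any call at depth below
#' `minDepth` is `"ambiguous"` regardless of frequency. The 0.9 / 10-read
#' defaults give essentially error-free calls at typical cf-mRNA depths
#' (the miscall probability at depth 30 and 1% sequencing error is below
#' 1e-4 per draw).
#'
#' @param frequency reference-allele frequency in `[0, 1]` (vectorized).
#' @param depth read depth (vectorized, recycled).
#' @param homThreshold homozygosity threshold (default 0.9).
#' @param minDepth minimum informative depth (default 10).
#' @return Character vector of calls: `"hom-ref"`, `"het"`, `"hom-alt"` or
#'   `"ambiguous"` (also for `NA` frequencies).
#' @export
classifyGenotype <- function(frequency, depth, homThreshold = 0.9,
                             minDepth = 10) {
  # the 1e-9 slack keeps the two hom bands exact mirror images despite
  # floating-point rounding of 1 - homThreshold (swap symmetry)
  eps <- 1e-9
  call <- ifelse(is.na(frequency) | depth < minDepth, "ambiguous",
          ifelse(frequency >= homThreshold - eps, "hom-ref",
          ifelse(frequency <= 1 - homThreshold + eps, "hom-alt", "het")))
  if (is.matrix(frequency))
    call <- matrix(call, nrow = nrow(frequency),
                   dimnames = dimnames(frequency))
  call
}

# Majority call over a set of informative (non-ambiguous) calls; ties give
# "ambiguous".
.majorityCall <- function(calls) {
  calls <- calls[calls != "ambiguous"]
  if (!length(calls)) return("ambiguous")
  tab <- table(calls)
  top <- tab[tab == max(tab)]
  if (length(top) > 1L) "ambiguous" else names(top)
}

#' Detect host-to-donor genotype transitions after transplant
#'
#' For each SNP, the pre-transplant consensus is the majority genotype over
#' all informative pre-transplant days (ties are ambiguous). The
#' post-transplant consensus is the terminal stable call: the genotype held
#' from some day through the end of the series over at least
#' `minPersistence` consecutive informative days (this tolerates the
#' intermediate calls seen while the donor fraction ramps). The transition
#' day is the first day of that terminal run. SNPs whose consensus matches
#' pre and post are labelled `"none"`; SNPs without an informative pre
#' consensus or stable post consensus are `"indeterminate"`.
#'
#' @param table a [SnpCountTable-class].
#' @param homThreshold,minDepth passed to [classifyGenotype()].
#' @param minPersistence informative days the terminal call must persist
#'   (default 2).
#' @return A data.frame with one row per SNP: `snp`, `preCall`, `postCall`,
#'   `label` (for example `"hom-ref->het"`, `"none"`, `"indeterminate"`) and
#'   `transitionDay` (`NA` unless a genotype change was detected).
#' @export
detectTransitions <- function(table, homThreshold = 0.9, minDepth = 10,
                              minPersistence = 2L) {
  freq <- alleleFrequency(table)
  depth <- attr(freq, "depth")
  days <- sampleDays(table)
  calls <- classifyGenotype(freq, depth, homThreshold, minDepth)
  pre <- days < table@transplantDay
  post <- days >= table@transplantDay
  out <- data.frame(snp = rownames(freq), preCall = NA_character_,
                    postCall = NA_character_, label = "indeterminate",
                    transitionDay = NA_real_)
  for (i in seq_len(nrow(freq))) {
    preCall <- .majorityCall(calls[i, pre])
    out$preCall[i] <- preCall
    postCalls <- calls[i, post]
    postDays <- days[post]
    inf <- postCalls != "ambiguous"
    postCalls <- postCalls[inf]; postDays <- postDays[inf]
    if (preCall == "ambiguous" || !length(postCalls)) next
    # terminal stable run
    n <- length(postCalls)
    runStart <- n
    while (runStart > 1L && postCalls[runStart - 1L] == postCalls[n])
      runStart <- runStart - 1L
    runLen <- n - runStart + 1L
    if (runLen < minPersistence) next
    postCall <- postCalls[n]
    out$postCall[i] <- postCall
    if (postCall == preCall) {
      out$label[i] <- "none"
    } else {
      out$label[i] <- paste0(preCall, "->", postCall)
      out$transitionDay[i] <- postDays[runStart]
    }
  }
  out
}

#' Average reference-allele-frequency trajectory over a SNP set
#'
#' Arithmetic mean (with standard error) of the reference-allele frequency
#' at each day over a set of SNPs — typically SNPs sharing a transition
#' label. Days where no SNP has a defined frequency are `NA` and flagged.
#'
#' @param table a [SnpCountTable-class].
#' @param snpSet non-empty character vector of SNP identifiers.
#' @return A data.frame with `day`, `mean`, `se`, `nSnps`; days with no
#'   informative SNP are listed in attribute `"uninformativeDays"`.
#' @export
averageTrajectory <- function(table, snpSet) {
  if (!length(snpSet)) stop("snpSet must be non-empty")
  freq <- alleleFrequency(table)
  missing <- setdiff(snpSet, rownames(freq))
  if (length(missing))
    stop("SNP(s) absent from table: ", paste(missing, collapse = ", "))
  sub <- freq[snpSet, , drop = FALSE]
  n <- colSums(!is.na(sub))
  mu <- colMeans(sub, na.rm = TRUE)
  mu[n == 0] <- NA_real_
  se <- apply(sub, 2L, function(v) stats::sd(v, na.rm = TRUE)) / sqrt(pmax(n, 1))
  out <- data.frame(day = sampleDays(table), mean = unname(mu),
                    se = unname(se), nSnps = unname(n))
  attr(out, "uninformativeDays") <- sampleDays(table)[n == 0]
  out
}
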