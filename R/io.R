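#' Read a gene x sample expression matrix from a tab-separated file
#'
#' Expects a header line (`gene` followed by sample names) and one row per
#' gene. Parsing is strict: duplicated gene names, non-numeric cells and
#' ragged rows are errors naming the offending gene or line number.
#' TPM-completeness (every column summing to 1e6 within 1e-3) is recorded
#' as attribute `"tpmComplete"`, not enforced.
#'
#' @param path file path.
#' @param expectedUnit `"TPM"` or `"counts"` (recorded as attribute
#'   `"unit"`).
#' @return A gene x sample numeric matrix.
#' @export
readExpressionMatrix <- function(path, expectedUnit = c("TPM", "counts")) {
  expectedUnit <- match.arg(expectedUnit)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("file has no data rows: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  samples <- header[-1L]
  nc <- length(header)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  genes <- character(length(rows))
  vals <- matrix(NA_real_, nrow = length(rows), ncol = nc - 1L)
  for (i in seq_along(rows)) {
    row <- rows[[i]]
    if (length(row) != nc)
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1L, nc, length(row)))
    genes[i] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v) && any(row[-1L][is.na(v)] != "NA"))
      stop(sprintf("line %d: non-numeric value for gene %s",
                   i + 1L, row[1L]))
    vals[i, ] <- v
  }
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicated gene name(s): ", paste(unique(dup), collapse = ", "))
  dimnames(vals) <- list(genes, samples)
  cs <- colSums(vals)
  attr(vals, "tpmComplete") <- all(abs(cs - 1e6) < 1e-3)
  attr(vals, "unit") <- expectedUnit
  vals
}

# Format a numeric matrix as tab-separated lines at full double precision
# (17 significant digits round-trip losslessly).
.formatMatrixLines <- function(m, idHeader = "gene") {
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i],
            ifelse(is.na(m[i, ]), "NA", sprintf("%.17g", m[i, ]))),
          collapse = "\t"), character(1))
  c(paste(c(idHeader, colnames(m)), collapse = "\t"), body)
}

#' Write a gene x sample expression matrix as tab-separated text
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces the doubles exactly.
#'
#' @param x matrix or `SummarizedExperiment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  m <- .tpm(x)
  writeLines(.formatMatrixLines(m, "gene"), path)
  invisible(path)
}

#' Read / write Ig segment count tables
#'
#' Tab-separated with columns `segment`, `class`, then one column per
#' sample/day.
#'
#' @param path file path.
#' @return [readIgCountTable()]: an [IgCountTable-class];
#'   [writeIgCountTable()]: `path`, invisibly.
#' @export
readIgCountTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("segment", "class") %in% names(df)))
  cts <- as.matrix(df[, setdiff(names(df), c("segment", "class")),
                      drop = FALSE])
  rownames(cts) <- df$segment
  IgCountTable(cts, segmentClass = df$class)
}

#' @rdname readIgCountTable
#' @param table an [IgCountTable-class].
#' @export
writeIgCountTable <- function(table, path) {
  cts <- igCounts(table)
  df <- data.frame(segment = rownames(cts),
                   class = unname(segmentClasses(table)),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(cts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write SNP allele-count tables
#'
#' Long tab-separated format with columns `snp`, `day`, `ref_count`,
#' `alt_count` (an optional `gene` column is carried along).
#'
#' @param path file path.
#' @param transplantDay transplant day for the resulting table (default 0).
#' @return [readSnpCountTable()]: a [SnpCountTable-class];
#'   [writeSnpCountTable()]: `path`, invisibly.
#' @export
readSnpCountTable <- function(path, transplantDay = 0L) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("snp", "day", "ref_count", "alt_count") %in% names(df)))
  snps <- unique(df$snp)
  days <- sort(unique(df$day))
  ref <- matrix(0, length(snps), length(days),
                dimnames = list(snps, as.character(days)))
  alt <- ref
  idx <- cbind(match(df$snp, snps), match(df$day, days))
  ref[idx] <- df$ref_count
  alt[idx] <- df$alt_count
  SnpCountTable(ref, alt, days = days, transplantDay = transplantDay)
}

#' @rdname readSnpCountTable
#' @param table a [SnpCountTable-class].
#' @export
writeSnpCountTable <- function(table, path) {
  r <- refCounts(table); a <- altCounts(table)
  days <- sampleDays(table)
  df <- data.frame(
    snp = rep(rownames(r), times = ncol(r)),
    day = rep(days, each = nrow(r)),
    ref_count = as.vector(r),
    alt_count = as.vector(a))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a SNP allele-count table from a VCF with allelic depths
#'
#' Reads biallelic records carrying the per-sample `AD` (allelic depth)
#' genotype field and maps each sample to a study day. Multi-allelic
#' records are skipped with a count (attribute `"skippedMultiallelic"`).
#' Requires the VariantAnnotation package.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param dayMap named numeric vector mapping VCF sample names to days.
#' @param transplantDay transplant day (default 0).
#' @return A [SnpCountTable-class]; SNPs are keyed `chrom:pos`.
#' @export
vcfToSnpCounts <- function(path, dayMap, transplantDay = 0L) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("vcfToSnpCounts requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  geno <- VariantAnnotation::geno(vcf)
  if (!"AD" %in% names(geno))
    stop("VCF lacks the per-sample allelic-depth (AD) genotype field")
  nAlt <- lengths(VariantAnnotation::alt(vcf))
  biallelic <- nAlt == 1L
  skipped <- sum(!biallelic)
  vcf <- vcf[biallelic, ]
  ad <- VariantAnnotation::geno(vcf)$AD
  samples <- colnames(vcf)
  missing <- setdiff(samples, names(dayMap))
  if (length(missing))
    stop("dayMap lacks day(s) for sample(s): ",
         paste(missing, collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(vcf)
  snpIds <- paste0(as.character(GenomicRanges::seqnames(rr)), ":",
                   GenomicRanges::start(rr))
  ref <- matrix(0, nrow(vcf), length(samples),
                dimnames = list(snpIds, as.character(dayMap[samples])))
  alt <- ref
  for (j in seq_along(samples)) {
    for (i in seq_len(nrow(vcf))) {
      depths <- ad[i, j][[1L]]
      ref[i, j] <- depths[1L]
      alt[i, j] <- depths[2L]
    }
  }
  ord <- order(dayMap[samples])
  out <- SnpCountTable(ref[, ord, drop = FALSE], alt[, ord, drop = FALSE],
                       days = dayMap[samples][ord],
                       transplantDay = transplantDay)
  out@metadata$skippedMultiallelic <- skipped
  out
}

#' Serialize / load ground truth as YAML
#'
#' Matrices are stored as row-wise lists with dimnames so the YAML stays
#' human-readable alongside the generated tables.
#'
#' @param gt ground-truth list (see [groundTruth()]).
#' @param path YAML file path.
#' @return [writeGroundTruth()]: `path`, invisibly; [readGroundTruth()]:
#'   a nested list.
#' @export
writeGroundTruth <- function(gt, path) {
  yaml::write_yaml(lapply(gt, function(x) {
    if (is.matrix(x))
      list(.matrix = TRUE, rownames = rownames(x), colnames = colnames(x),
           rows = lapply(seq_len(nrow(x)), function(i) unname(x[i, ])))
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }), path)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) {
    if (is.list(x) && isTRUE(x$.matrix)) {
      m <- do.call(rbind, lapply(x$rows, unlist))
      dimnames(m) <- list(unlist(x$rownames), unlist(x$colnames))
      m
    } else x
  })
}

#' Write a reproducibility manifest for a run
#'
#' Records parameters, seeds, package version and MD5 checksums of the
#' input files — enough to reproduce a deterministic stage byte-identically.
#'
#' @param path YAML output path.
#' @param params named list of stage parameters (seeds included).
#' @param inputs character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(path, params, inputs = character()) {
  manifest <- list(
    package = "cfmarrow",
    version = as.character(utils::packageVersion("cfmarrow")),
    params = params,
    inputs = as.list(tools::md5sum(inputs)))
  yaml::write_yaml(manifest, path)
  invisible(path)
}
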