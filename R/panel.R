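#' SNP genotype panel
#'
#' Container coupling an accessions x SNPs allele-dosage matrix with its
#' physical map. Dosages count copies of the alternate allele (0, 1, 2);
#' missing calls are `NA`. The map carries one row per SNP: identifier,
#' chromosome label, 1-based bp position, and the ordered reference/alternate
#' allele pair on the reporting strand.
#'
#' @param dosage integer matrix, accessions in rows (rownames = accession
#'   ids), SNPs in columns (colnames = SNP ids); entries 0/1/2 or `NA`.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`;
#'   one row per column of `dosage`, in the same order.
#' @return An object of class `snp_panel` with elements `dosage` and `map`.
#' @examples
#' geno <- matrix(c(0, 1, 2, NA, 1, 0), nrow = 2,
#'                dimnames = list(c("acc1", "acc2"), c("s1", "s2", "s3")))
#' map <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "1",
#'                   pos = c(100, 200, 300), ref = "A", alt = "G")
#' snp_panel(geno, map)
#' @export
snp_panel <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop("map is missing columns: ", paste(miss, collapse = ", "))
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (nrow(map) != ncol(dosage))
    stop("map has ", nrow(map), " rows but dosage has ", ncol(dosage),
         " SNP columns")
  if (is.null(colnames(dosage))) colnames(dosage) <- map$snp_id
  if (ncol(dosage) > 0 && !identical(colnames(dosage), map$snp_id))
    stop("dosage column names do not match map$snp_id")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("acc", seq_len(nrow(dosage)))
  if (anyDuplicated(rownames(dosage)))
    stop("duplicate accession ids")
  if (anyDuplicated(map$snp_id))
    stop("duplicate SNP ids")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  if (any(!is.na(map$pos) & map$pos < 1L))
    stop("map positions must be positive (1-based)")
  rownames(map) <- NULL
  structure(list(dosage = dosage, map = map), class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  nm <- sum(is.na(x$dosage))
  cat("snp_panel:", nrow(x$dosage), "accessions x", ncol(x$dosage), "SNPs\n")
  cat("  chromosomes:", length(unique(x$map$chrom)),
      " missing calls:", sprintf("%.1f%%", 100 * nm / length(x$dosage)), "\n")
  invisible(x)
}

#' @export
summary.snp_panel <- function(object, ...) {
  p <- alt_freq(object)
  maf <- pmin(p, 1 - p)
  het <- heterozygosity(object)
  out <- list(
    n_accessions = nrow(object$dosage),
    n_snps = ncol(object$dosage),
    n_chromosomes = length(unique(object$map$chrom)),
    missing_rate = mean(is.na(object$dosage)),
    median_maf = stats::median(maf, na.rm = TRUE),
    mean_heterozygosity = mean(het, na.rm = TRUE))
  class(out) <- "summary.snp_panel"
  out
}

#' @export
print.summary.snp_panel <- function(x, ...) {
  cat("SNP panel summary\n")
  cat(sprintf("  accessions:          %d\n", x$n_accessions))
  cat(sprintf("  SNPs:                %d on %d chromosome(s)\n",
              x$n_snps, x$n_chromosomes))
  cat(sprintf("  missing call rate:   %.3f\n", x$missing_rate))
  cat(sprintf("  median MAF:          %.3f\n", x$median_maf))
  cat(sprintf("  mean heterozygosity: %.3f\n", x$mean_heterozygosity))
  invisible(x)
}

#' Subset a panel by accessions and/or SNPs
#'
#' @param x an `snp_panel`.
#' @param accessions,snps index vectors (logical, integer or character) over
#'   rows and SNP columns respectively; missing means keep all.
#' @param ... unused.
#' @return The subset `snp_panel`.
#' @export
`[.snp_panel` <- function(x, accessions, snps, ...) {
  d <- x$dosage
  m <- x$map
  if (!missing(accessions)) d <- d[accessions, , drop = FALSE]
  if (!missing(snps)) {
    if (is.character(snps)) snps <- match(snps, m$snp_id)
    d <- d[, snps, drop = FALSE]
    m <- m[snps, , drop = FALSE]
  }
  snp_panel(d, m)
}

#' Alternate-allele frequency per SNP
#'
#' Computed over non-missing calls only.
#'
#' @param panel an `snp_panel`.
#' @return Named numeric vector of alternate-allele frequencies; `NaN` for
#'   all-missing SNPs.
#' @export
alt_freq <- function(panel) {
  colMeans(panel$dosage, na.rm = TRUE) / 2
}

#' Per-SNP missing-call fraction
#'
#' @param panel an `snp_panel`.
#' @return Named numeric vector of missing fractions.
#' @export
missing_rate <- function(panel) {
  colMeans(is.na(panel$dosage))
}
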