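#' Read a SNP genotype panel
#'
#' Reads biallelic diploid genotypes from a VCF (v4.x, via the vcfR parser)
#' or from the package's tabular genotype format. Heterozygotes are coded
#' dosage 1 regardless of phase; unresolvable calls are masked as missing.
#'
#' The tabular format is a tab-separated file whose header row names the
#' accessions; each following row is `snp_id`, `chrom`, `pos`, `alleles`
#' (e.g. `A/G`, reference allele first) and one call per accession. Calls
#' may be two-letter genotypes (`AG`), slash pairs (`A/G`), or single
#' IUPAC codes (`A`,`C`,`G`,`T` homozygous; `R`,`Y`,`S`,`W`,`K`,`M`
#' heterozygous; `N` or `-` missing).
#'
#' @param path file path.
#' @param format `"vcf"` or `"tabular"`; `"auto"` guesses from the
#'   extension/content.
#' @return An [snp_panel()]. Non-biallelic VCF records are dropped with a
#'   warning; non-diploid calls are an error.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tabular")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
    else if (startsWith(readLines(path, n = 1), "##fileformat=VCF")) "vcf"
    else "tabular"
  }
  switch(format, vcf = read_vcf_panel(path), tabular = read_tabular_panel(path))
}

read_vcf_panel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  biallelic <- !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  if (any(!biallelic))
    warning(sum(!biallelic), " non-biallelic-SNP record(s) dropped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  core <- gsub("\\|", "/", gt)
  ploidy_bad <- !is.na(core) & !grepl("^[0-9.]+/[0-9.]+$", core)
  if (any(ploidy_bad)) {
    bad <- which(ploidy_bad, arr.ind = TRUE)[1, ]
    stop("non-diploid genotype '", gt[ploidy_bad][1], "' at record ",
         bad[1])
  }
  dos <- matrix(NA_integer_, nrow(core), ncol(core))
  dos[core %in% c("0/0")] <- 0L
  dos[core %in% c("0/1", "1/0")] <- 1L
  dos[core %in% c("1/1")] <- 2L
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  map <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                    alt = fix[, "ALT"], stringsAsFactors = FALSE)
  dos <- t(dos)
  dimnames(dos) <- list(colnames(gt), ids)
  snp_panel(dos, map)
}

iupac_het <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

decode_call <- function(call, ref, alt) {
  call <- toupper(call)
  if (call %in% c("N", "NN", "-", "--", "./.", "", NA)) return(NA_integer_)
  if (nchar(call) == 1) {
    if (call %in% names(iupac_het)) call <- iupac_het[[call]]
    else call <- paste0(call, call)
  }
  call <- gsub("/", "", call)
  if (nchar(call) != 2) return(NA_integer_)
  a <- substr(call, 1, 1); b <- substr(call, 2, 2)
  d <- sum(c(a, b) == alt)
  if (!all(c(a, b) %in% c(ref, alt))) return(NA_integer_)
  as.integer(d)
}

read_tabular_panel <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty genotype file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  acc <- header[-(1:4)]
  if (!length(acc)) stop("no accession columns in header")
  n <- length(lines) - 1
  map <- data.frame(snp_id = character(n), chrom = character(n),
                    pos = NA_integer_, ref = character(n),
                    alt = character(n), stringsAsFactors = FALSE)
  dos <- matrix(NA_integer_, length(acc), n,
                dimnames = list(acc, NULL))
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4 + length(acc))
      stop("malformed record at line ", i + 1, ": expected ",
           4 + length(acc), " fields, found ", length(f))
    al <- strsplit(f[4], "/", fixed = TRUE)[[1]]
    if (length(al) != 2)
      stop("malformed allele pair '", f[4], "' at line ", i + 1)
    map$snp_id[i] <- f[1]; map$chrom[i] <- f[2]
    map$pos[i] <- as.integer(f[3]); map$ref[i] <- al[1]; map$alt[i] <- al[2]
    dos[, i] <- vapply(f[-(1:4)], decode_call, integer(1),
                       ref = al[1], alt = al[2])
  }
  colnames(dos) <- map$snp_id
  snp_panel(dos, map)
}

#' Write a SNP genotype panel
#'
#' Writes an [snp_panel()] as a minimal VCF v4.2 (GT field only) or as the
#' tabular genotype format documented in [read_genotypes()] (two-letter
#' calls, `NN` for missing). `read_genotypes()` round-trips both.
#'
#' @param panel an [snp_panel()].
#' @param path output file path.
#' @param format `"vcf"` or `"tabular"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, format = c("vcf", "tabular")) {
  format <- match.arg(format)
  m <- panel$map
  d <- panel$dosage
  if (format == "vcf") {
    gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d))
    gt[is.na(d)] <- "./."
    body <- paste(m$chrom, m$pos, m$snp_id, m$ref, m$alt, ".", "PASS", ".",
                  "GT", apply(gt, 2, paste, collapse = "\t"), sep = "\t")
    header <- c("##fileformat=VCFv4.2",
                '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", rownames(d)),
                      collapse = "\t"))
    writeLines(c(header, body), path)
  } else {
    calls <- matrix("NN", nrow(d), ncol(d))
    for (g in 0:2) {
      idx <- which(!is.na(d) & d == g, arr.ind = TRUE)
      if (!nrow(idx)) next
      al <- switch(as.character(g),
                   "0" = paste0(m$ref, m$ref),
                   "1" = paste0(m$ref, m$alt),
                   "2" = paste0(m$alt, m$alt))
      calls[idx] <- al[idx[, 2]]
    }
    header <- paste(c("snp_id", "chrom", "pos", "alleles", rownames(d)),
                    collapse = "\t")
    body <- paste(m$snp_id, m$chrom, m$pos, paste0(m$ref, "/", m$alt),
                  apply(calls, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), path)
  }
  invisible(path)
}

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

#' Merge genotype panels by SNP name and physical position
#'
#' Panels are matched on the (SNP id, chromosome, position) triple; by
#' default only SNPs present in every panel are retained (intersection).
#' When a later panel reports the complementary-strand allele pair (e.g.
#' T/C where the first panel has A/G), its alleles are complemented onto the
#' first panel's strand; a swapped ref/alt order flips dosages (d -> 2 - d).
#' SNPs whose allele pairs cannot be reconciled are dropped and reported.
#' A/T and C/G SNPs are strand-ambiguous (their complement is themselves
#' reversed) and are dropped by default.
#'
#' @param panels list of two or more [snp_panel()] objects.
#' @param ambiguous `"drop"` (default) removes A/T and C/G SNPs; `"keep"`
#'   trusts marker names and reconciles them by letter match alone.
#' @return list of class `merge_result`: `panel` (accessions concatenated,
#'   reconciled SNP set) and `report` (counts and dropped SNP ids).
#' @export
merge_panels <- function(panels, ambiguous = c("drop", "keep")) {
  ambiguous <- match.arg(ambiguous)
  stopifnot(length(panels) >= 2)
  keys <- lapply(panels, function(p)
    paste(p$map$snp_id, p$map$chrom, p$map$pos, sep = ":"))
  acc <- unlist(lapply(panels, function(p) rownames(p$dosage)))
  if (anyDuplicated(acc))
    stop("duplicate accession ids across panels: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  common <- Reduce(intersect, keys)
  if (!length(common)) stop("no SNPs shared by all panels")
  ref_panel <- panels[[1]]
  i1 <- match(common, keys[[1]])
  map <- ref_panel$map[i1, , drop = FALSE]
  is_ambiguous <- paste0(map$ref, map$alt) %in% c("AT", "TA", "CG", "GC")
  dropped_ambiguous <- character(0)
  if (ambiguous == "drop" && any(is_ambiguous)) {
    dropped_ambiguous <- map$snp_id[is_ambiguous]
    common <- common[!is_ambiguous]
    i1 <- i1[!is_ambiguous]
    map <- map[!is_ambiguous, , drop = FALSE]
    if (!length(common))
      stop("no SNPs left after dropping strand-ambiguous markers")
  }
  blocks <- list(ref_panel$dosage[, i1, drop = FALSE])
  irreconcilable <- rep(FALSE, length(common))
  for (k in seq_along(panels)[-1]) {
    pk <- panels[[k]]
    ik <- match(common, keys[[k]])
    dk <- pk$dosage[, ik, drop = FALSE]
    ref_k <- pk$map$ref[ik]; alt_k <- pk$map$alt[ik]
    same <- ref_k == map$ref & alt_k == map$alt
    swap <- ref_k == map$alt & alt_k == map$ref
    csame <- complement_base(ref_k) == map$ref &
      complement_base(alt_k) == map$alt
    cswap <- complement_base(ref_k) == map$alt &
      complement_base(alt_k) == map$ref
    if (ambiguous == "keep") {
      # for palindromic SNPs the complement duplicates the letter match
      csame <- csame & !(same | swap)
      cswap <- cswap & !(same | swap)
    }
    flip <- (swap | cswap) & !(same | csame)
    ok <- same | swap | csame | cswap
    dk[, flip] <- 2L - dk[, flip]
    irreconcilable <- irreconcilable | !ok
    blocks[[k]] <- dk
  }
  dropped_alleles <- map$snp_id[irreconcilable]
  if (all(irreconcilable))
    stop("no SNPs could be reconciled across panels")
  keep <- !irreconcilable
  blocks <- lapply(blocks, function(b) b[, keep, drop = FALSE])
  map <- map[keep, , drop = FALSE]
  dosage <- do.call(rbind, blocks)
  colnames(dosage) <- map$snp_id
  report <- list(
    n_input = vapply(panels, function(p) ncol(p$dosage), integer(1)),
    n_common = length(common) + length(dropped_ambiguous),
    n_dropped_ambiguous = length(dropped_ambiguous),
    n_dropped_alleles = length(dropped_alleles),
    n_merged = nrow(map),
    dropped_ambiguous = dropped_ambiguous,
    dropped_alleles = dropped_alleles,
    snp_policy = "intersection", ambiguous_policy = ambiguous)
  structure(list(panel = snp_panel(dosage, map), report = report),
            class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  r <- x$report
  cat("merge_result:", length(r$n_input), "panels (",
      paste(r$n_input, collapse = " + "), "SNPs ) ->", r$n_merged,
      "merged SNPs\n")
  cat("  shared by all panels:", r$n_common,
      "| strand-ambiguous dropped:", r$n_dropped_ambiguous,
      "| irreconcilable alleles dropped:", r$n_dropped_alleles, "\n")
  invisible(x)
}

#' Screen SNPs on MAF, missingness and map position
#'
#' Keeps SNPs whose minor allele frequency (over non-missing calls) strictly
#' exceeds `maf_min`, whose missing-call fraction is strictly below
#' `missing_max`, and whose map position is present. An all-missing SNP
#' fails the missingness criterion.
#'
#' @param panel an [snp_panel()].
#' @param maf_min minor-allele-frequency threshold (strict >; default 0.05).
#' @param missing_max missing-rate threshold (strict <; default 0.2).
#' @return list of class `filter_result`: `panel` (screened) and `report`
#'   (`n_input`, `n_failed_maf`, `n_failed_missing`, `n_failed_position`,
#'   `n_passed`; failure counts overlap when a SNP fails several criteria).
#' @export
filter_snps <- function(panel, maf_min = 0.05, missing_max = 0.2) {
  stopifnot(maf_min >= 0, maf_min < 1, missing_max > 0, missing_max <= 1)
  p <- alt_freq(panel)
  maf <- pmin(p, 1 - p)
  miss <- missing_rate(panel)
  fail_missing <- miss >= missing_max           # all-missing fails here
  fail_maf <- !is.nan(maf) & !(maf > maf_min)   # criteria may overlap
  fail_pos <- is.na(panel$map$pos) | is.na(panel$map$chrom)
  keep <- !fail_missing & !fail_maf & !fail_pos
  report <- list(n_input = ncol(panel$dosage),
                 n_failed_maf = sum(fail_maf),
                 n_failed_missing = sum(fail_missing),
                 n_failed_position = sum(fail_pos),
                 n_passed = sum(keep))
  structure(list(panel = panel[, keep], report = report),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  r <- x$report
  cat("filter_result:", r$n_passed, "of", r$n_input, "SNPs pass",
      sprintf("(failed MAF: %d, missing: %d, unmapped: %d)\n",
              r$n_failed_maf, r$n_failed_missing, r$n_failed_position))
  invisible(x)
}
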