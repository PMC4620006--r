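#' Per-locus Jost's D between subpopulations
#'
#' For each SNP, computes the within-subpopulation gene diversity H_S
#' (small-sample corrected: the equal-weight mean of 1 - sum p^2 across the
#' included subpopulations, multiplied by n~/(n~ - 1) with n~ the harmonic
#' mean of the subpopulations' called sample sizes), the overall gene
#' diversity H_T at the equal-weight pooled allele frequencies, and
#'
#'   D = (H_T - H_S) / (1 - H_S) * n / (n - 1)
#'
#' with n the number of subpopulations compared. D is 0 for identical
#' frequencies and 1 at fixed alternative alleles. The sample-size
#' correction can make individual loci slightly negative. A variant that
#' divides by n/(n-1) instead (the literal form some sources print) is
#' available via `n_correction = "divide"`; under division a two-deme fixed
#' difference yields 0.5 rather than 1.
#'
#' Loci are masked (`NA`) when any included subpopulation has fewer than 2
#' called accessions or when H_S reaches 1.
#'
#' @param panel an [snp_panel()].
#' @param assignment factor of subpopulation labels, one per accession.
#' @param pair character vector of 2+ subpopulation labels to compare, or
#'   `NULL` for all K subpopulations.
#' @param n_correction `"multiply"` (default) or `"divide"`.
#' @return list: `d` (named per-SNP vector), `components` (data.frame
#'   `snp_id`, `h_s`, `h_t`), `n_subpops`.
#' @export
dest_per_locus <- function(panel, assignment, pair = NULL,
                           n_correction = c("multiply", "divide")) {
  n_correction <- match.arg(n_correction)
  assignment <- as.factor(assignment)
  stopifnot(length(assignment) == nrow(panel$dosage))
  groups <- if (is.null(pair)) levels(droplevels(assignment)) else
    as.character(pair)
  if (length(groups) < 2) stop("need at least 2 subpopulations")
  if (!all(groups %in% levels(assignment)))
    stop("unknown subpopulation label(s): ",
         paste(setdiff(groups, levels(assignment)), collapse = ", "))
  n <- length(groups)
  S <- ncol(panel$dosage)
  p_k <- matrix(NA_real_, n, S)
  n_k <- matrix(0L, n, S)
  for (i in seq_len(n)) {
    sub <- panel$dosage[assignment == groups[i], , drop = FALSE]
    n_k[i, ] <- colSums(!is.na(sub))
    p_k[i, ] <- colMeans(sub, na.rm = TRUE) / 2
  }
  ok <- colSums(n_k >= 2L) == n
  h_raw <- colMeans(2 * p_k * (1 - p_k))          # equal subpop weight
  n_harm <- n / colSums(1 / pmax(n_k, 1L))
  h_s <- n_harm / (n_harm - 1) * h_raw
  p_bar <- colMeans(p_k)
  h_t <- 2 * p_bar * (1 - p_bar)
  masked <- !ok | h_s >= 1
  d <- (h_t - h_s) / (1 - h_s)
  d <- if (n_correction == "multiply") d * n / (n - 1) else d / (n / (n - 1))
  d[masked] <- NA_real_
  h_s[!ok] <- NA_real_
  h_t[!ok] <- NA_real_
  names(d) <- panel$map$snp_id
  list(d = d,
       components = data.frame(snp_id = panel$map$snp_id, h_s = h_s,
                               h_t = h_t, stringsAsFactors = FALSE),
       n_subpops = n)
}

#' Pairwise genome-average Jost's D matrix
#'
#' Symmetric K x K matrix whose (i, j) entry is the mean per-SNP Jost's D
#' over unmasked loci for that subpopulation pair; the diagonal is exactly
#' 0 (a subpopulation is undifferentiated from itself).
#'
#' @inheritParams dest_per_locus
#' @return Numeric matrix with subpopulation labels as dimnames; `NA` where
#'   a pair shares no unmasked loci.
#' @export
pairwise_dest_matrix <- function(panel, assignment,
                                 n_correction = c("multiply", "divide")) {
  n_correction <- match.arg(n_correction)
  assignment <- droplevels(as.factor(assignment))
  groups <- levels(assignment)
  K <- length(groups)
  if (K < 2) stop("need at least 2 subpopulations")
  M <- matrix(0, K, K, dimnames = list(groups, groups))
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      d <- dest_per_locus(panel, assignment, pair = groups[c(i, j)],
                          n_correction = n_correction)$d
      M[i, j] <- M[j, i] <-
        if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
    }
  }
  M
}

#' Windowed mean of per-SNP values
#'
#' Tiles each chromosome with non-overlapping windows of `window_size_bp`
#' starting at position 1 and averages the per-SNP values of the unmasked
#' SNPs inside each; empty windows are omitted. The window size of a
#' differentiation scan is conventionally twice the panel's LD decay
#' distance, so that each window spans roughly one independent linkage
#' neighbourhood.
#'
#' @param d named per-SNP numeric vector (NA = masked), e.g. from
#'   [dest_per_locus()].
#' @param map SNP map aligned with `d` (`chrom`, `pos`).
#' @param window_size_bp window length in bp (> 0).
#' @return data.frame: `chrom`, `start`, `end` (1-based inclusive),
#'   `mean_dest`, `n_snps`.
#' @export
window_scan <- function(d, map, window_size_bp) {
  stopifnot(window_size_bp > 0, length(d) == nrow(map))
  keep <- !is.na(d)
  if (!any(keep)) return(data.frame(chrom = character(), start = integer(),
                                    end = integer(), mean_dest = numeric(),
                                    n_snps = integer()))
  chrom <- map$chrom[keep]
  wi <- (map$pos[keep] - 1L) %/% as.integer(window_size_bp)
  key <- paste(chrom, wi, sep = ":")
  mean_d <- tapply(d[keep], key, mean)
  n_s <- tapply(d[keep], key, length)
  parts <- strsplit(names(mean_d), ":", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    win = as.integer(vapply(parts, `[`, "", 2)),
                    mean_dest = as.numeric(mean_d),
                    n_snps = as.integer(n_s), stringsAsFactors = FALSE)
  out$start <- out$win * as.integer(window_size_bp) + 1L
  out$end <- out$start + as.integer(window_size_bp) - 1L
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "mean_dest", "n_snps")]
}

#' Windowed Jost's D genome scan for one subpopulation pair
#'
#' Convenience wrapper: per-SNP Jost's D, then the non-overlapping window
#' scan at twice the LD decay distance (or an explicit window size).
#'
#' @inheritParams dest_per_locus
#' @param window_size_bp window length in bp; `NULL` derives it as
#'   2 x the genome-wide LD decay distance of the panel.
#' @param ld_threshold r-squared threshold used when deriving the window
#'   size from LD decay (default 0.1).
#' @return list of class `dest_scan`: `pair`, `d` (per-SNP), `windows`,
#'   `window_size_bp`, `mean_d` (genome-wide mean per-SNP D), `map`.
#' @export
dest_scan <- function(panel, assignment, pair = NULL, window_size_bp = NULL,
                      ld_threshold = 0.1,
                      n_correction = c("multiply", "divide")) {
  if (is.null(window_size_bp)) {
    dec <- ld_decay(panel, threshold = ld_threshold)
    window_size_bp <- 2 * dec$decay_distance[["genome"]]
    if (is.na(window_size_bp))
      stop("LD decay distance undefined; pass window_size_bp explicitly")
  }
  pl <- dest_per_locus(panel, assignment, pair, n_correction)
  windows <- window_scan(pl$d, panel$map, window_size_bp)
  label <- if (is.null(pair))
    paste(levels(droplevels(as.factor(assignment))), collapse = "|")
  else paste(pair, collapse = "|")
  structure(list(pair = label, d = pl$d, windows = windows,
                 window_size_bp = window_size_bp,
                 mean_d = mean(pl$d, na.rm = TRUE), map = panel$map),
            class = "dest_scan")
}

#' @export
print.dest_scan <- function(x, ...) {
  cat("dest_scan:", x$pair, "\n")
  cat(sprintf("  %d SNPs (%d masked), window %.0f bp, %d non-empty windows\n",
              length(x$d), sum(is.na(x$d)), x$window_size_bp,
              nrow(x$windows)))
  cat(sprintf("  genome-wide mean per-SNP D = %.4f\n", x$mean_d))
  invisible(x)
}

#' @export
plot.dest_scan <- function(x, ...) {
  w <- x$windows
  chroms <- unique(x$map$chrom)
  offs <- c(0, cumsum(tapply(x$map$pos, x$map$chrom, max)[chroms]))
  names(offs) <- c(chroms, "end")
  xs <- offs[w$chrom] + (w$start + w$end) / 2
  graphics::plot(xs, w$mean_dest, col = 1 + match(w$chrom, chroms) %% 2,
                 pch = 16, cex = 0.6, xlab = "genome position (bp)",
                 ylab = "window mean D", ...)
  graphics::abline(h = 2 * x$mean_d, lty = 2)
  invisible(x)
}

#' Call highly differentiated regions from a window scan
#'
#' Windows whose mean D strictly exceeds the cutoff are retained and
#' adjacent qualifying windows are merged into single regions. The cutoff is
#' the genome-wide mean per-SNP D (`"mean"`), twice it (`"twice_mean"`), or
#' an absolute level (`"absolute"`, default 0.2). With
#' `cutoff_basis = "window"` the mean of window means is used instead of the
#' per-SNP mean.
#'
#' @param scan a `dest_scan` (or a list with elements `windows` and `d`).
#' @param cutoff_mode `"twice_mean"`, `"mean"` or `"absolute"`.
#' @param absolute_level cutoff for `"absolute"` mode (default 0.2).
#' @param cutoff_basis `"snp"` (default) or `"window"`: which average the
#'   mean/twice_mean cutoffs are taken over.
#' @return data.frame of class `dest_regions`: `chrom`, `start`, `end`,
#'   `mean_dest` (SNP-count-weighted), `n_snps`, `n_windows`; attributes
#'   `cutoff`, `cutoff_mode`, `cutoff_basis`.
#' @export
call_regions <- function(scan, cutoff_mode = c("twice_mean", "mean",
                                               "absolute"),
                         absolute_level = 0.2,
                         cutoff_basis = c("snp", "window")) {
  cutoff_mode <- match.arg(cutoff_mode)
  cutoff_basis <- match.arg(cutoff_basis)
  w <- scan$windows
  if (is.null(w) || nrow(w) == 0) stop("empty window table")
  base_mean <- if (cutoff_basis == "snp") mean(scan$d, na.rm = TRUE)
  else mean(w$mean_dest)
  cutoff <- switch(cutoff_mode, mean = base_mean,
                   twice_mean = 2 * base_mean, absolute = absolute_level)
  q <- w[w$mean_dest > cutoff, , drop = FALSE]
  out <- if (nrow(q) == 0) {
    data.frame(chrom = character(), start = integer(), end = integer(),
               mean_dest = numeric(), n_snps = integer(),
               n_windows = integer())
  } else {
    q <- q[order(q$chrom, q$start), ]
    new_run <- c(TRUE, !(q$chrom[-1] == q$chrom[-nrow(q)] &
                           q$start[-1] == q$end[-nrow(q)] + 1L))
    run <- cumsum(new_run)
    data.frame(
      chrom = tapply(q$chrom, run, `[`, 1),
      start = as.integer(tapply(q$start, run, min)),
      end = as.integer(tapply(q$end, run, max)),
      mean_dest = as.numeric(tapply(q$mean_dest * q$n_snps, run, sum) /
                               tapply(q$n_snps, run, sum)),
      n_snps = as.integer(tapply(q$n_snps, run, sum)),
      n_windows = as.integer(tapply(q$n_snps, run, length)),
      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "cutoff_mode") <- cutoff_mode
  attr(out, "cutoff_basis") <- cutoff_basis
  class(out) <- c("dest_regions", "data.frame")
  out
}

#' Read QTL intervals from a BED-like file
#'
#' BED conventions: 0-based half-open intervals, tab-separated columns
#' `chrom`, `start`, `end`, then optionally `trait_class` and `source`.
#' Coordinates are converted to the package's 1-based inclusive reporting
#' convention.
#'
#' @param path file path.
#' @return data.frame: `chrom`, `start`, `end` (1-based inclusive),
#'   `trait_class`, `source`.
#' @export
read_qtl_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("BED file needs at least 3 columns")
  out <- data.frame(chrom = as.character(raw[[1]]),
                    start = as.integer(raw[[2]]) + 1L,
                    end = as.integer(raw[[3]]),
                    trait_class = if (ncol(raw) >= 4) as.character(raw[[4]])
                    else NA_character_,
                    source = if (ncol(raw) >= 5) as.character(raw[[5]])
                    else NA_character_, stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("malformed interval(s): start > end")
  out
}

#' Write called regions as BED
#'
#' Converts the package's 1-based inclusive regions back to BED's 0-based
#' half-open coordinates.
#'
#' @param regions a `dest_regions` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  writeLines(paste(regions$chrom, regions$start - 1L, regions$end,
                   sprintf("region_%d", seq_len(nrow(regions))),
                   sep = "\t"), path)
  invisible(path)
}

#' Overlap called regions with QTL intervals
#'
#' A region is "contained" in a QTL when its interval lies fully inside the
#' QTL interval (the strict reading of a region being located within a QTL);
#' any positional overlap is counted separately.
#'
#' @param regions data.frame of regions (`chrom`, `start`, `end`, 1-based
#'   inclusive).
#' @param qtl data.frame of QTL intervals (same columns; see
#'   [read_qtl_bed()]).
#' @return list: `hits` (per-region: `contained`, `any_overlap`, and the
#'   matching QTL trait classes), `n_regions`, `n_contained`,
#'   `n_any_overlap`.
#' @export
overlap_qtl <- function(regions, qtl) {
  if (!any(regions$chrom %in% qtl$chrom) && nrow(regions) > 0)
    warning("no shared chromosome labels between regions and QTL table")
  n <- nrow(regions)
  contained <- logical(n)
  any_ov <- logical(n)
  classes <- character(n)
  for (i in seq_len(n)) {
    same <- qtl$chrom == regions$chrom[i]
    ov <- same & qtl$start <= regions$end[i] & qtl$end >= regions$start[i]
    co <- same & qtl$start <= regions$start[i] & qtl$end >= regions$end[i]
    any_ov[i] <- any(ov)
    contained[i] <- any(co)
    classes[i] <- paste(unique(stats::na.omit(qtl$trait_class[ov])),
                        collapse = ",")
  }
  hits <- cbind(as.data.frame(regions)[, c("chrom", "start", "end")],
                contained = contained, any_overlap = any_ov,
                trait_classes = classes)
  list(hits = hits, n_regions = n, n_contained = sum(contained),
       n_any_overlap = sum(any_ov))
}

#' Regions shared across subpopulation-pair scans
#'
#' Pools the region lists of several subpopulation pairs, merges the pooled
#' intervals into maximal overlapping blocks, and reports each block shared
#' (by any positional overlap) by at least `min_pairs` pairs.
#'
#' @param region_lists named list of `dest_regions` data.frames, one per
#'   subpopulation pair.
#' @param min_pairs minimum number of pair lists an interval must appear in
#'   (default 2).
#' @return data.frame: `chrom`, `start`, `end`, `n_pairs`, `pairs`
#'   (comma-separated pair labels).
#' @export
common_regions <- function(region_lists, min_pairs = 2) {
  stopifnot(length(region_lists) >= 2)
  if (is.null(names(region_lists)))
    names(region_lists) <- paste0("pair", seq_along(region_lists))
  pooled <- do.call(rbind, lapply(names(region_lists), function(nm) {
    r <- region_lists[[nm]]
    if (nrow(r) == 0) return(NULL)
    data.frame(chrom = r$chrom, start = r$start, end = r$end, pair = nm,
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_pairs = integer(),
                      pairs = character())
  if (is.null(pooled) || nrow(pooled) == 0) return(empty)
  pooled <- pooled[order(pooled$chrom, pooled$start), ]
  # merge pooled intervals into maximal overlapping blocks per chromosome
  blocks <- do.call(rbind, lapply(split(pooled, pooled$chrom), function(pp) {
    run <- cumsum(c(TRUE, pp$start[-1] > cummax(pp$end)[-nrow(pp)]))
    data.frame(chrom = pp$chrom[1],
               start = as.integer(tapply(pp$start, run, min)),
               end = as.integer(tapply(pp$end, run, max)))
  }))
  res <- lapply(seq_len(nrow(blocks)), function(i) {
    ov <- pooled$chrom == blocks$chrom[i] & pooled$start <= blocks$end[i] &
      pooled$end >= blocks$start[i]
    prs <- sort(unique(pooled$pair[ov]))
    data.frame(chrom = blocks$chrom[i], start = blocks$start[i],
               end = blocks$end[i], n_pairs = length(prs),
               pairs = paste(prs, collapse = ","), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[out$n_pairs >= min_pairs, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) empty else out
}
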