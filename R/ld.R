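#' LD between two SNPs as squared Pearson correlation
#'
#' r-squared between the two allele-dosage vectors over jointly non-missing
#' accessions (the standard unphased-panel reading of LD).
#'
#' @param a,b dosage vectors (0/1/2, `NA` missing) of equal length.
#' @return r-squared in \[0, 1\]; `NA` when fewer than two joint calls remain
#'   or either SNP is monomorphic on the joint set.
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' LD decay profile from a mapped panel
#'
#' Computes r-squared for every intra-chromosomal SNP pair separated by at
#' most `max_dist` bp, bins pairs by physical distance, and reports the mean
#' r-squared per bin, per chromosome and genome-wide. The decay distance is
#' the distance at which the mean r-squared first falls below `threshold`,
#' obtained by linear interpolation between the straddling bin midpoints
#' (0 if already below in the first bin).
#'
#' @param panel an [snp_panel()].
#' @param max_dist maximum pair separation in bp (default 200 kb).
#' @param bin_width distance bin width in bp (default 5 kb).
#' @param threshold r-squared level defining the decay distance
#'   (default 0.1).
#' @return list of class `ld_decay`: `bins` (data.frame: `chrom`,
#'   `bin_start`, `bin_end`, `mean_r2`, `n_pairs`; chromosome `"genome"` is
#'   the pooled profile) and `decay_distance` (named vector, bp, per
#'   chromosome and genome-wide).
#' @export
ld_decay <- function(panel, max_dist = 2e5, bin_width = 5e3,
                     threshold = 0.1) {
  stopifnot(max_dist > 0, bin_width > 0)
  chroms <- unique(panel$map$chrom)
  per <- list()
  for (ch in chroms) {
    idx <- which(panel$map$chrom == ch)
    if (length(idx) < 2) {
      warning("chromosome ", ch, " has fewer than 2 SNPs; skipped")
      next
    }
    idx <- idx[order(panel$map$pos[idx])]
    pos <- panel$map$pos[idx]
    R2 <- pairwise_r2(panel$dosage[, idx, drop = FALSE])
    dmat <- abs(outer(pos, pos, "-"))
    keep <- upper.tri(dmat) & dmat <= max_dist & !is.na(R2)
    if (!any(keep)) next
    per[[ch]] <- data.frame(chrom = ch, dist = dmat[keep], r2 = R2[keep],
                            stringsAsFactors = FALSE)
  }
  if (!length(per)) stop("no usable SNP pairs within max_dist")
  pairs <- do.call(rbind, per)
  bin_of <- function(d) pmin(d %/% bin_width, max_dist %/% bin_width - 1)
  profile <- function(df, label) {
    b <- bin_of(df$dist)
    agg <- stats::aggregate(df$r2, list(bin = b), mean)
    cnt <- as.vector(table(b)[as.character(agg$bin)])
    data.frame(chrom = label, bin_start = agg$bin * bin_width,
               bin_end = (agg$bin + 1) * bin_width,
               mean_r2 = agg$x, n_pairs = cnt, stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, c(lapply(split(pairs, pairs$chrom), function(df)
    profile(df, df$chrom[1])), list(profile(pairs, "genome"))))
  rownames(bins) <- NULL
  decay <- vapply(split(bins, bins$chrom), function(bb)
    decay_from_profile(bb, threshold), numeric(1))
  structure(list(bins = bins, decay_distance = decay,
                 threshold = threshold), class = "ld_decay")
}

# All-pairs pairwise-complete squared Pearson correlation of dosage columns,
# via masked cross-products (exact, BLAS-speed).
pairwise_r2 <- function(X) {
  M <- (!is.na(X)) * 1
  X0 <- X
  X0[is.na(X0)] <- 0
  storage.mode(X0) <- "double"
  n <- crossprod(M)
  Sx <- crossprod(X0, M)
  Sxx <- crossprod(X0^2, M)
  Sxy <- crossprod(X0)
  cv <- Sxy - Sx * t(Sx) / n
  vx <- Sxx - Sx^2 / n
  r2 <- cv^2 / (vx * t(vx))
  r2[!is.finite(r2)] <- NA_real_
  r2[n < 2] <- NA_real_
  r2
}

# First distance where the binned mean r2 crosses below `threshold`, linearly
# interpolated between the straddling bin midpoints.
decay_from_profile <- function(bins, threshold) {
  bins <- bins[order(bins$bin_start), ]
  mid <- (bins$bin_start + bins$bin_end) / 2
  r2 <- bins$mean_r2
  below <- which(r2 < threshold)
  if (!length(below)) return(NA_real_)
  j <- below[1]
  if (j == 1) {
    # anchor at (0, 1): two identical alleles are perfectly correlated
    if (r2[1] >= 1) return(mid[1])
    return(mid[1] * (1 - threshold) / (1 - r2[1]))
  }
  i <- j - 1
  mid[i] + (mid[j] - mid[i]) * (r2[i] - threshold) / (r2[i] - r2[j])
}

#' @export
print.ld_decay <- function(x, ...) {
  g <- x$decay_distance["genome"]
  cat("ld_decay: genome-wide decay distance",
      ifelse(is.na(g), "NA", sprintf("%.1f kb", g / 1000)),
      "at r2 threshold", x$threshold, "\n")
  invisible(x)
}

#' @export
plot.ld_decay <- function(x, ...) {
  bb <- x$bins[x$bins$chrom == "genome", ]
  mid <- (bb$bin_start + bb$bin_end) / 2
  graphics::plot(mid / 1000, bb$mean_r2, type = "b", pch = 16,
                 xlab = "distance (kb)", ylab = expression(mean ~ r^2), ...)
  graphics::abline(h = x$threshold, lty = 2)
  g <- x$decay_distance["genome"]
  if (!is.na(g)) graphics::abline(v = g / 1000, lty = 3)
  invisible(x)
}
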