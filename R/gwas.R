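#' Bonferroni -log10 significance threshold
#'
#' Returns -log10(alpha / n_markers), the genome-wide cutoff on the
#' -log10(p) scale for a family of `n_markers` tests; e.g. alpha 0.05 over
#' 43,252 markers gives 5.94.
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param n_markers number of tested markers (>= 1).
#' @return Numeric threshold on the -log10 p scale.
#' @examples
#' significance_threshold(0.05, 43252)  # 5.94
#' @export
significance_threshold <- function(alpha = 0.05, n_markers) {
  stopifnot(alpha > 0, alpha < 1, n_markers >= 1)
  -log10(alpha / n_markers)
}

# REML log-likelihood profile over delta = sigma_e^2 / sigma_g^2, on the
# eigenbasis of the kinship matrix (EMMA-style single variance component).
reml_delta <- function(y, X, lambda, U) {
  n <- length(y)
  p <- qr(X)$rank
  Uy <- crossprod(U, y)
  UX <- crossprod(U, X)
  negll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- lambda + delta
    XtWX <- crossprod(UX, UX / w)
    XtWy <- crossprod(UX, Uy / w)
    beta <- solve(XtWX, XtWy)
    r <- Uy - UX %*% beta
    rss <- sum(r^2 / w)
    0.5 * ((n - p) * log(rss / (n - p)) + sum(log(w)) +
             determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(negll, c(log(1e-5), log(1e5)))
  exp(opt$minimum)
}

#' Mixed linear model genome-wide association scan
#'
#' Tests each SNP for association with a quantitative trait under the
#' standard single-variance-component mixed model
#' y = mu + covariates + SNP dosage + g + e, where the polygenic effect g
#' has covariance proportional to the kinship matrix. The variance
#' components are estimated once by REML on the null (no-SNP) model and
#' reused for every SNP — the population-parameters-previously-determined
#' scheme — so each SNP test is a generalized least-squares fit with a
#' t-test on the dosage coefficient.
#'
#' Missing dosages are imputed to the SNP mean for testing; monomorphic
#' SNPs are skipped. With an identity kinship and no covariates the p-values
#' coincide with ordinary least-squares regression.
#'
#' @param panel an [snp_panel()].
#' @param phenotype named numeric vector (names = accession ids); accessions
#'   missing a phenotype are dropped.
#' @param kinship a [kinship_matrix()], or a plain symmetric matrix over the
#'   panel's accessions, or `NULL` for an identity matrix. Raw (unclamped)
#'   values are used when a `kinship_matrix` is supplied; any negative
#'   eigenvalues are raised to zero to repair positive semi-definiteness.
#' @param covariates optional numeric matrix of structure covariates
#'   (e.g. the first principal components), rows named by accession.
#'   Linearly dependent columns are dropped with a warning.
#' @param alpha family-wise error rate for the Bonferroni threshold
#'   (default 0.05).
#' @return data.frame of class `mlm_gwas`: `snp_id`, `chrom`, `pos`,
#'   `effect`, `se`, `p_value`, `neg_log10_p`, `significant`; attributes
#'   `threshold`, `delta` (residual/polygenic variance ratio), `n_used`.
#' @export
mlm_gwas <- function(panel, phenotype, kinship = NULL, covariates = NULL,
                     alpha = 0.05) {
  acc <- rownames(panel$dosage)
  if (is.null(names(phenotype)))
    names(phenotype) <- acc[seq_along(phenotype)]
  use <- intersect(acc, names(phenotype)[!is.na(phenotype)])
  if (length(use) < 30)
    stop("need at least 30 accessions with phenotype and genotype")
  D <- panel$dosage[use, , drop = FALSE]
  y <- phenotype[use]
  K <- if (is.null(kinship)) diag(length(use))
  else if (inherits(kinship, "kinship_matrix")) kinship$F_raw[use, use]
  else kinship[use, use]
  X <- matrix(1, length(use), 1, dimnames = list(use, "intercept"))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (!is.null(rownames(cv))) cv <- cv[use, , drop = FALSE]
    X <- cbind(X, cv)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      drop_cols <- qx$pivot[-seq_len(qx$rank)]
      warning("dropping ", length(drop_cols),
              " linearly dependent covariate column(s)")
      X <- X[, -drop_cols, drop = FALSE]
    }
  }
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  U <- eg$vectors
  delta <- reml_delta(y, X, lambda, U)
  w <- lambda + delta
  sw <- 1 / sqrt(w)
  yt <- crossprod(U, y) * sw
  Xt <- crossprod(U, X) * sw
  # residualize on covariates once, then scan SNP columns in bulk
  qX <- qr(Xt)
  ry <- qr.resid(qX, yt)
  p_cov <- ncol(Xt)
  n <- length(yt)
  df <- n - p_cov - 1
  pfreq <- colMeans(D, na.rm = TRUE)
  mono <- is.nan(pfreq) | apply(D, 2, function(col)
    length(unique(col[!is.na(col)]))) < 2
  G <- D
  for (j in which(apply(is.na(G), 2, any)))
    G[is.na(G[, j]), j] <- pfreq[j]
  Gt <- crossprod(U, G) * sw
  rG <- qr.resid(qX, Gt)
  gg <- colSums(rG^2)
  gy <- colSums(rG * drop(ry))
  beta <- gy / gg
  rss <- sum(ry^2) - beta * gy
  se <- sqrt(rss / df / gg)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  beta[mono] <- se[mono] <- p[mono] <- NA_real_
  thr <- significance_threshold(alpha, sum(!mono))
  out <- data.frame(snp_id = panel$map$snp_id, chrom = panel$map$chrom,
                    pos = panel$map$pos, effect = beta, se = se,
                    p_value = p, neg_log10_p = -log10(p),
                    significant = !is.na(p) & -log10(p) > thr,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  attr(out, "delta") <- delta
  attr(out, "n_used") <- length(use)
  class(out) <- c("mlm_gwas", "data.frame")
  out
}

#' @export
print.mlm_gwas <- function(x, ...) {
  if (is.null(attr(x, "threshold"))) return(NextMethod())  # plain subset
  cat("mlm_gwas:", nrow(x), "SNPs,", attr(x, "n_used"), "accessions\n")
  cat(sprintf("  Bonferroni -log10 threshold %.2f; %d significant SNP(s)\n",
              attr(x, "threshold"), sum(x$significant, na.rm = TRUE)))
  cat(sprintf("  residual/polygenic variance ratio delta = %.3g\n",
              attr(x, "delta")))
  invisible(x)
}

#' Manhattan plot of a GWAS scan
#'
#' @param x an `mlm_gwas` result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mlm_gwas <- function(x, ...) {
  chroms <- unique(x$chrom)
  offs <- c(0, cumsum(tapply(x$pos, x$chrom, max)[chroms]))
  xs <- offs[match(x$chrom, chroms)] + x$pos
  graphics::plot(xs, x$neg_log10_p, col = 1 + match(x$chrom, chroms) %% 2,
                 pch = 16, cex = 0.5, xlab = "genome position (bp)",
                 ylab = expression(-log[10](p)), ...)
  graphics::abline(h = attr(x, "threshold"), col = 2, lty = 2)
  invisible(x)
}

#' Call significant QTNs from a GWAS scan
#'
#' SNPs whose -log10(p) strictly exceeds the threshold, sorted by p-value.
#'
#' @param results an `mlm_gwas` data.frame.
#' @param threshold -log10 p cutoff; defaults to the scan's Bonferroni
#'   threshold.
#' @return The significant rows of `results`, best first.
#' @export
call_qtns <- function(results, threshold = attr(results, "threshold")) {
  stopifnot(nrow(results) > 0, !is.null(threshold))
  hit <- !is.na(results$neg_log10_p) & results$neg_log10_p > threshold
  out <- results[hit, , drop = FALSE]
  out[order(out$p_value), , drop = FALSE]
}

#' Colocalize QTNs with differentiated regions
#'
#' Assigns each QTN to any region whose interval contains its position;
#' proximity within `window_bp` of a region boundary is reported separately.
#'
#' @param qtns data.frame with `snp_id`, `chrom`, `pos` (e.g. from
#'   [call_qtns()]).
#' @param regions data.frame of regions (`chrom`, `start`, `end`, 1-based
#'   inclusive).
#' @param window_bp slack distance for the `near` call (default 0).
#' @return data.frame: one row per QTN with `in_region`, `near_region`
#'   (within `window_bp`), and the region coordinates hit (NA when none).
#' @export
colocalize <- function(qtns, regions, window_bp = 0) {
  n <- nrow(qtns)
  if (any(is.na(qtns$pos))) {
    warning(sum(is.na(qtns$pos)), " QTN(s) without map position skipped")
  }
  out <- data.frame(snp_id = qtns$snp_id, chrom = qtns$chrom,
                    pos = qtns$pos, in_region = FALSE, near_region = FALSE,
                    region = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (is.na(qtns$pos[i])) next
    same <- regions$chrom == qtns$chrom[i]
    inside <- same & regions$start <= qtns$pos[i] &
      regions$end >= qtns$pos[i]
    near <- same & regions$start - window_bp <= qtns$pos[i] &
      regions$end + window_bp >= qtns$pos[i]
    out$in_region[i] <- any(inside)
    out$near_region[i] <- any(near)
    if (any(near)) {
      j <- which(near)[1]
      out$region[i] <- paste0(regions$chrom[j], ":", regions$start[j], "-",
                              regions$end[j])
    }
  }
  out
}
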