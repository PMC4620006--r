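#' Pairwise identity-by-state distance matrix
#'
#' Per-locus IBS similarity between accessions i and j is the probability
#' that one allele drawn at random from each is identical: 1 for matching
#' homozygotes, 0 for opposite homozygotes, and 0.5 whenever either call is
#' heterozygous (including het vs het). In dosage terms
#' IBS = (d_i d_j + (2 - d_i)(2 - d_j)) / 4, which is averaged over the
#' jointly non-missing loci of each pair; distance = 1 - mean IBS.
#'
#' @param panel an [snp_panel()].
#' @param het_calls `"random-draw"` (default) scores loci involving a
#'   heterozygote as 0.5; `"skip"` drops them from a pair's average instead,
#'   the convention of some toolkits.
#' @return Symmetric accessions x accessions distance matrix; pairs sharing
#'   no called loci are `NA` (with a warning).
#' @export
ibs_distance <- function(panel, het_calls = c("random-draw", "skip")) {
  1 - ibs_similarity(panel, het_calls)
}

#' Pairwise IBS similarity matrix
#'
#' @inheritParams ibs_distance
#' @return Symmetric matrix of mean per-locus IBS similarities.
#' @export
ibs_similarity <- function(panel, het_calls = c("random-draw", "skip")) {
  het_calls <- match.arg(het_calls)
  D <- panel$dosage
  if (het_calls == "skip") D[D == 1L] <- NA_integer_
  M <- !is.na(D)
  A <- D
  A[!M] <- 0L
  storage.mode(A) <- "double"
  B <- (2 - A) * M
  shared <- tcrossprod(M * 1)
  Q <- (tcrossprod(A) + tcrossprod(B)) / (4 * shared)
  if (any(shared == 0)) {
    warning("some accession pairs share no called loci; IBS set to NA")
    Q[shared == 0] <- NA_real_
  }
  dimnames(Q) <- list(rownames(D), rownames(D))
  Q
}

#' Centered-IBS kinship matrix
#'
#' F_ij = (Q_ij - Q_m) / (1 - Q_m), where Q_ij is the pairwise probability of
#' identity by state and Q_m the mean IBS over all distinct accession pairs
#' (diagonal excluded). Raw values are returned in `F_raw`; `F` clamps
#' negatives to zero, the usual reporting convention of GWAS toolkits.
#'
#' @param panel an [snp_panel()].
#' @return list of class `kinship_matrix`: `F` (clamped), `F_raw`, `Q`
#'   (IBS similarities) and `Q_m`.
#' @export
kinship_matrix <- function(panel) {
  if (nrow(panel$dosage) < 2) stop("kinship needs at least 2 accessions")
  Q <- ibs_similarity(panel)
  off <- Q[lower.tri(Q)]
  Q_m <- mean(off, na.rm = TRUE)
  if (Q_m >= 1)
    stop("degenerate panel: all accessions identical (mean IBS = 1)")
  F_raw <- (Q - Q_m) / (1 - Q_m)
  structure(list(F = pmax(F_raw, 0), F_raw = F_raw, Q = Q, Q_m = Q_m),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix:", nrow(x$F), "accessions, background IBS Q_m =",
      sprintf("%.3f", x$Q_m), "\n")
  off <- x$F[lower.tri(x$F)]
  cat("  off-diagonal F (clamped): ",
      sprintf("min %.3f / median %.3f / max %.3f", min(off),
              stats::median(off), max(off)), "\n")
  invisible(x)
}
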