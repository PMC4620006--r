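#' Principal component analysis with Patterson normalisation
#'
#' Each SNP column is mean-centered and divided by the binomial standard
#' deviation sqrt(p(1-p)), p being the sample alternate-allele frequency —
#' the normalisation of the Patterson/EIGENSTRAT formulation. Missing calls
#' are imputed to the column mean before scaling (so they contribute zero
#' after centering). Monomorphic columns are dropped with a reported count.
#'
#' @param panel an [snp_panel()].
#' @param n_components number of components to return (capped at the matrix
#'   rank with a warning).
#' @return list of class `pca_result`: `scores` (accessions x components),
#'   `eigenvalues` (non-increasing), `n_snps_used`, `n_dropped`.
#' @export
pca_patterson <- function(panel, n_components = 10) {
  D <- panel$dosage
  if (nrow(D) < 2) stop("PCA needs at least 2 accessions")
  p <- colMeans(D, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  n_dropped <- sum(!poly)
  if (sum(poly) < 1) stop("no polymorphic SNPs")
  X <- D[, poly, drop = FALSE]
  p <- p[poly]
  mu <- 2 * p
  for (j in seq_len(ncol(X))) {
    m <- is.na(X[, j])
    if (any(m)) X[m, j] <- mu[j]
  }
  X <- sweep(X, 2, mu)
  X <- sweep(X, 2, sqrt(p * (1 - p)), "/")
  # covariance across accessions; eigen on the small side
  G <- tcrossprod(X) / ncol(X)
  eg <- eigen(G, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-9
  rank <- sum(pos)
  k <- min(n_components, rank, nrow(D) - 1)
  if (k < n_components)
    warning("only ", k, " component(s) recoverable (rank bound)")
  scores <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(k)], 0)), k)
  dimnames(scores) <- list(rownames(D), paste0("PC", seq_len(k)))
  structure(list(scores = scores, eigenvalues = eg$values[seq_len(k)],
                 n_snps_used = ncol(X), n_dropped = n_dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", ncol(x$scores), "components from", x$n_snps_used,
      "SNPs\n")
  pv <- x$eigenvalues / sum(x$eigenvalues)
  cat("  leading eigenvalue shares:",
      paste(sprintf("%.2f", utils::head(pv, 5)), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.pca_result <- function(x, components = c(1, 2), groups = NULL, ...) {
  s <- x$scores[, components, drop = FALSE]
  col <- if (is.null(groups)) 1 else as.integer(as.factor(groups))
  graphics::plot(s[, 1], s[, 2], col = col, pch = 16,
                 xlab = colnames(s)[1], ylab = colnames(s)[2], ...)
  invisible(x)
}

#' Evenly spread, diversity-maximising SNP subsample
#'
#' Divides the genome into windows of equal physical length (genome length /
#' m, tiled per chromosome) and keeps, in each window, the SNP with the
#' highest gene diversity; ties go to the lowest missing rate, then the
#' lowest position. Empty windows are skipped, so fewer than `m` SNPs may
#' return.
#'
#' @param panel an [snp_panel()].
#' @param m target number of SNPs (>= 1).
#' @param offset_frac window-offset fraction in \[0, 1): shifts all window
#'   starts by `offset_frac` x window length, used to vary replicate
#'   subsamples while keeping them evenly spread.
#' @return Integer vector of selected SNP column indices, with attribute
#'   `shortfall` = m - length(selection).
#' @export
subsample_snps <- function(panel, m, offset_frac = 0) {
  if (m < 1) stop("m must be >= 1")
  S <- ncol(panel$dosage)
  if (m >= S) {
    out <- seq_len(S)
    attr(out, "shortfall") <- 0L
    return(out)
  }
  map <- panel$map
  chrom_len <- tapply(map$pos, map$chrom, max)
  w <- sum(chrom_len) / m
  off <- offset_frac * w
  win <- paste(map$chrom, floor((map$pos - 1 + off) / w))
  p <- alt_freq(panel)
  gd <- 2 * p * (1 - p)
  miss <- missing_rate(panel)
  ord <- order(win, -gd, miss, map$pos)
  sel <- ord[!duplicated(win[ord])]
  sel <- sort(sel)
  attr(sel, "shortfall") <- as.integer(m - length(sel))
  sel
}

# Greedy matching of subset PCs to full-set PCs by maximal absolute
# correlation; returns the mean absolute correlation over the matched pairs.
match_pc_correlation <- function(full, sub, n_pcs = 5) {
  k <- min(n_pcs, ncol(full), ncol(sub))
  C <- abs(stats::cor(full[, seq_len(min(n_pcs, ncol(full))), drop = FALSE],
                      sub))
  taken_r <- rep(FALSE, nrow(C))
  taken_c <- rep(FALSE, ncol(C))
  vals <- numeric(k)
  for (i in seq_len(k)) {
    C2 <- C
    C2[taken_r, ] <- -Inf
    C2[, taken_c] <- -Inf
    ij <- arrayInd(which.max(C2), dim(C2))
    vals[i] <- C[ij[1], ij[2]]
    taken_r[ij[1]] <- TRUE
    taken_c[ij[2]] <- TRUE
  }
  mean(vals)
}

#' Marker-number sufficiency (ascertainment) curve
#'
#' For each requested marker count, repeatedly subsamples that many evenly
#' spread, diversity-maximising SNPs (replicates jitter the window offsets),
#' reruns the Patterson PCA, and measures agreement with the full-panel PCA
#' as the mean absolute Pearson correlation of the first five principal
#' components after greedy matching of components by maximal absolute
#' correlation (component order and sign are arbitrary). The curve value at
#' the full marker count is 1 by construction.
#'
#' @param panel an [snp_panel()].
#' @param marker_counts integer vector of subset sizes (each <= total SNPs).
#' @param n_replicates subsample replicates per count (default 20).
#' @param n_pcs number of leading components compared (default 5).
#' @param seed integer seed for the replicate offsets.
#' @return list of class `ascertainment_curve`: `curve` (data.frame
#'   `marker_count`, `mean_abs_correlation`, `sd`), `n_replicates`.
#' @export
ascertainment_curve <- function(panel, marker_counts, n_replicates = 20,
                                n_pcs = 5, seed = 1L) {
  S <- ncol(panel$dosage)
  if (any(marker_counts > S)) stop("marker count exceeds total SNPs")
  full <- pca_patterson(panel, n_components = n_pcs)
  if (ncol(full$scores) < n_pcs)
    warning("only ", ncol(full$scores), " full-panel components recoverable")
  set.seed(seed)
  res <- lapply(sort(marker_counts), function(m) {
    offs <- if (m >= S) rep(0, n_replicates)
    else stats::runif(n_replicates)
    vals <- vapply(offs, function(o) {
      sel <- subsample_snps(panel, m, offset_frac = o)
      sub <- pca_patterson(panel[, sel], n_components = n_pcs)
      match_pc_correlation(full$scores, sub$scores, n_pcs)
    }, numeric(1))
    c(mean = mean(vals), sd = stats::sd(vals))
  })
  curve <- data.frame(marker_count = sort(marker_counts),
                      mean_abs_correlation = vapply(res, `[[`, 0, "mean"),
                      sd = vapply(res, `[[`, 0, "sd"))
  structure(list(curve = curve, n_replicates = n_replicates, n_pcs = n_pcs),
            class = "ascertainment_curve")
}

#' @export
print.ascertainment_curve <- function(x, ...) {
  cat("ascertainment_curve (", x$n_replicates, "replicates, first",
      x$n_pcs, "PCs )\n")
  print(x$curve, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration (via \pkg{ape}): iteratively joins the
#' pair minimising the Q-criterion and computes branch lengths. Negative
#' branch lengths, permitted by the algorithm, are flagged via the
#' `n_negative_branches` attribute.
#'
#' @param d symmetric non-negative distance matrix (or `dist`) over at
#'   least 3 accessions.
#' @return An \pkg{ape} `phylo` tree whose tips are the accessions.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (nrow(d) < 3) stop("neighbor-joining needs at least 3 accessions")
  if (any(d < 0)) stop("distances must be non-negative")
  tr <- ape::nj(as.dist(d))
  attr(tr, "n_negative_branches") <- sum(tr$edge.length < 0)
  tr
}

#' Extract K clusters from a tree by cutting its longest branches
#'
#' Removes the K-1 longest internal branches (falling back to terminal
#' branches if the tree has fewer internal edges than needed); the connected
#' components of the remaining tree define the clusters. Ties are broken by
#' edge insertion order.
#'
#' @param tree a `phylo` tree (e.g. from [nj_tree()]).
#' @param K number of clusters (2 <= K <= number of tips).
#' @return factor of cluster labels (`"C1"` ... `"CK"`), named by tip label.
#' @export
assign_clusters <- function(tree, K) {
  n_tip <- length(tree$tip.label)
  if (K < 2) stop("K must be >= 2 for downstream differentiation use")
  if (K > n_tip) stop("K exceeds the number of tips")
  edges <- tree$edge
  internal <- edges[, 2] > n_tip
  ord <- order(!internal, -tree$edge.length, seq_len(nrow(edges)))
  tip_components <- function(cut) {
    # union-find over tree nodes using the remaining edges
    parent <- seq_len(max(edges))
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (e in setdiff(seq_len(nrow(edges)), cut)) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) parent[a] <- b
    }
    vapply(seq_len(n_tip), find, integer(1))
  }
  # cutting an edge adds at most one tip-bearing component (a cut can also
  # strand a tipless internal node), so keep cutting until K is reached
  n_cut <- K - 1
  repeat {
    comp <- tip_components(ord[seq_len(n_cut)])
    if (length(unique(comp)) >= K || n_cut >= nrow(edges)) break
    n_cut <- n_cut + 1
  }
  labels <- factor(comp, levels = unique(comp),
                   labels = paste0("C", seq_along(unique(comp))))
  names(labels) <- tree$tip.label
  labels
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same accessions;
#' 1 means identical partitions up to label permutation, 0 the chance level.
#'
#' @param a,b label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
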