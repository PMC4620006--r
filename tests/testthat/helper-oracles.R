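# Independent brute-force oracles, coded scalar/per-locus with explicit
# loops so they share no code path with the package implementations.

# Jost's D for one locus and two subpopulations from raw dosage vectors.
oracle_dest_pair <- function(d1, d2, multiply = TRUE) {
  stat <- function(d) {
    d <- d[!is.na(d)]
    list(n = length(d), p = if (length(d)) sum(d) / (2 * length(d)) else NaN)
  }
  a <- stat(d1)
  b <- stat(d2)
  if (a$n < 2 || b$n < 2) return(NA_real_)
  hs_raw <- ((1 - a$p^2 - (1 - a$p)^2) + (1 - b$p^2 - (1 - b$p)^2)) / 2
  nh <- 2 / (1 / a$n + 1 / b$n)
  hs <- nh / (nh - 1) * hs_raw
  if (hs >= 1) return(NA_real_)
  pb <- (a$p + b$p) / 2
  ht <- 1 - pb^2 - (1 - pb)^2
  dd <- (ht - hs) / (1 - hs)
  if (multiply) dd * 2 else dd / 2
}

# PIC by the double sum written out.
oracle_pic <- function(p) {
  k <- length(p)
  s <- 1 - sum(p^2)
  for (u in seq_len(k - 1)) {
    for (v in (u + 1):k) {
      s <- s - 2 * p[u]^2 * p[v]^2
    }
  }
  s
}

oracle_gd <- function(p) {
  tot <- 0
  for (u in seq_along(p)) tot <- tot + p[u]^2
  1 - tot
}

# IBS by enumerating random single-allele draws from each genotype.
oracle_ibs_pair <- function(g1, g2) {
  as_alleles <- function(d) switch(as.character(d), "0" = c(0L, 0L),
                                   "1" = c(0L, 1L), "2" = c(1L, 1L))
  vals <- c()
  for (l in seq_along(g1)) {
    if (is.na(g1[l]) || is.na(g2[l])) next
    a <- as_alleles(g1[l])
    b <- as_alleles(g2[l])
    match_prob <- 0
    for (x in a) for (y in b) match_prob <- match_prob + (x == y) / 4
    vals <- c(vals, match_prob)
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

oracle_kinship <- function(dosage) {
  n <- nrow(dosage)
  Q <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      Q[i, j] <- oracle_ibs_pair(dosage[i, ], dosage[j, ])
    }
  }
  qm <- mean(Q[row(Q) > col(Q)])
  (Q - qm) / (1 - qm)
}

# Least-squares fit of a 4-taxon unrooted topology; returns RSS.
# Topologies indexed by the sibling of taxon 1 (2, 3 or 4).
oracle_nj4_best_topology <- function(D) {
  fit <- function(sib) {
    others <- setdiff(2:4, sib)
    # branches: x1, x_sib, x_a, x_b, internal e
    pairs <- rbind(c(1, sib), c(1, others[1]), c(1, others[2]),
                   c(sib, others[1]), c(sib, others[2]),
                   c(others[1], others[2]))
    X <- matrix(0, 6, 5)
    colnames(X) <- c("b1", "bsib", "ba", "bb", "e")
    leaf_col <- c(1, NA, NA, NA)
    leaf_col[sib] <- 2
    leaf_col[others[1]] <- 3
    leaf_col[others[2]] <- 4
    same_side <- function(i, j) {
      (i %in% c(1, sib)) == (j %in% c(1, sib))
    }
    y <- numeric(6)
    for (r in 1:6) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      X[r, leaf_col[i]] <- 1
      X[r, leaf_col[j]] <- 1
      if (!same_side(i, j)) X[r, 5] <- 1
      y[r] <- D[i, j]
    }
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  rss <- vapply(2:4, fit, numeric(1))
  (2:4)[which.min(rss)]
}

# The sibling of taxon 1 (by tip label position) in a 4-taxon phylo tree.
nj4_sibling_of_first <- function(tree, labels) {
  d <- stats::cophenetic(tree)[labels, labels]
  # in a 4-taxon tree, 1's sibling minimises d(1,x) - d(y,x) summed over the
  # other two taxa; equivalently the four-point condition picks the pairing
  best <- NULL; bestval <- Inf
  for (sib in 2:4) {
    others <- setdiff(2:4, sib)
    val <- d[1, sib] + d[others[1], others[2]]
    if (val < bestval) { bestval <- val; best <- sib }
  }
  best
}

# Small panel builder for fixtures.
make_panel <- function(dosage, chrom = "1", pos = NULL, ref = "A",
                       alt = "G") {
  S <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(S) * 100L
  if (is.null(colnames(dosage))) colnames(dosage) <- paste0("s", seq_len(S))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("a", seq_len(nrow(dosage)))
  snp_panel(dosage, data.frame(snp_id = colnames(dosage),
                               chrom = rep_len(chrom, S), pos = pos,
                               ref = rep_len(ref, S), alt = rep_len(alt, S),
                               stringsAsFactors = FALSE))
}
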