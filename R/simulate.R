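#' Simulation configuration for synthetic SNP panels
#'
#' Bundles and validates every knob of the synthetic-panel generator. The
#' defaults emulate a diverse inbred-line panel: several subpopulations of
#' diploid but largely homozygous accessions, tens of thousands of common
#' biallelic SNPs on 10 chromosomes, modest missingness, and linkage
#' disequilibrium extending roughly 30 kb.
#'
#' Coordinates are compressed relative to a real maize genome (5 Mb per
#' chromosome at roughly 2 kb marker spacing) so that uniformly placed
#' markers carry the same per-window marker counts and LD reach that a chip
#' panel shows on full-length chromosomes.
#'
#' @param n_subpops number of subpopulations (K).
#' @param sizes integer vector of accessions per subpopulation (recycled to
#'   length `n_subpops`); each must be at least 2.
#' @param n_snps total number of SNPs.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length in bp.
#' @param differentiation Balding-Nichols drift parameter in (0, 1); larger
#'   values give stronger subpopulation differentiation.
#' @param inbreeding_coefficient probability in \[0, 1\] that an accession's
#'   two allele draws coincide, collapsing genotypes to homozygotes; the
#'   expected heterozygosity at a locus with frequency p is 2p(1-p)(1-F).
#' @param missing_rate per-call missing probability in \[0, 1).
#' @param maf_floor ancestral allele frequencies are drawn uniformly on
#'   (maf_floor, 1 - maf_floor).
#' @param ld_block_bp LD block length in bp; SNPs within a block share
#'   per-individual allele draws, so LD decays linearly to background over
#'   this distance.
#' @param ld_break per-SNP probability of drawing fresh allele uniforms
#'   instead of the block-shared ones (softens within-block LD).
#' @param planted_regions `NULL` or data.frame with columns `chrom`, `start`,
#'   `end`, `target_d`, and optionally `pop_a`, `pop_b` (subpopulation
#'   indices, default 1 and 2): intervals whose SNPs get allele-frequency
#'   shifts between the named pair sized to reach per-SNP Jost's D
#'   `target_d`.
#' @param qtns `NULL` or data.frame with columns `snp` (index) and `effect`
#'   (additive allele effect) describing quantitative trait nucleotides.
#' @param heritability fraction of phenotypic variance that is genetic, in
#'   (0, 1).
#' @param admixture `NULL`, or list(pops = c(i, j), size = n, proportion = a)
#'   adding `n` two-way admixed accessions whose blocks descend from subpop
#'   `i` with probability `a`, else `j`.
#' @param seed integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subpops = 4, sizes = 100, n_snps = 20000,
                       n_chromosomes = 10, chrom_length_bp = 5e6,
                       differentiation = 0.2, inbreeding_coefficient = 0.9,
                       missing_rate = 0.05, maf_floor = 0.05,
                       ld_block_bp = 30000, ld_break = 0.1,
                       planted_regions = NULL, qtns = NULL,
                       heritability = 0.6, admixture = NULL, seed = 1L) {
  sizes <- rep_len(as.integer(sizes), n_subpops)
  stopifnot(n_subpops >= 1, all(sizes >= 2), n_snps >= 1,
            n_chromosomes >= 1, chrom_length_bp >= n_snps / n_chromosomes)
  if (!(differentiation > 0 && differentiation < 1))
    stop("differentiation must lie strictly in (0, 1)")
  if (inbreeding_coefficient < 0 || inbreeding_coefficient > 1)
    stop("inbreeding_coefficient must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (maf_floor < 0 || maf_floor >= 0.5)
    stop("maf_floor must lie in [0, 0.5)")
  if (!(heritability > 0 && heritability < 1))
    stop("heritability must lie strictly in (0, 1)")
  if (!is.null(planted_regions)) {
    planted_regions <- as.data.frame(planted_regions)
    stopifnot(all(c("chrom", "start", "end", "target_d") %in%
                    names(planted_regions)))
    if (is.null(planted_regions$pop_a)) planted_regions$pop_a <- 1L
    if (is.null(planted_regions$pop_b)) planted_regions$pop_b <- 2L
    if (any(planted_regions$start < 1) ||
        any(planted_regions$end > chrom_length_bp))
      stop("planted regions must lie within chromosome bounds")
    if (any(planted_regions$target_d <= 0 | planted_regions$target_d > 1))
      stop("target_d must lie in (0, 1]")
  }
  if (!is.null(qtns)) {
    qtns <- as.data.frame(qtns)
    stopifnot(all(c("snp", "effect") %in% names(qtns)),
              all(qtns$snp >= 1 & qtns$snp <= n_snps))
  }
  structure(list(
    n_subpops = n_subpops, sizes = sizes, n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp),
    differentiation = differentiation,
    inbreeding_coefficient = inbreeding_coefficient,
    missing_rate = missing_rate, maf_floor = maf_floor,
    ld_block_bp = as.integer(ld_block_bp), ld_break = ld_break,
    planted_regions = planted_regions, qtns = qtns,
    heritability = heritability, admixture = admixture,
    seed = as.integer(seed)), class = "sim_config")
}

# Deterministic per-stage seeds so each stage is independently reproducible.
stage_seeds <- function(seed, n = 8L) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  s <- sample.int(.Machine$integer.max, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

#' Balding-Nichols subpopulation allele frequencies
#'
#' Draws, for each subpopulation and SNP, an allele frequency from a Beta
#' distribution with mean equal to the ancestral frequency p and variance
#' theta * p(1-p), where theta is the drift parameter: the Balding-Nichols
#' model. theta -> 0 recovers the ancestral frequencies; theta -> 1 fixes
#' alternative alleles at random.
#'
#' @param ancestral_freqs numeric vector of ancestral frequencies in (0, 1).
#' @param differentiation drift parameter theta in (0, 1).
#' @param n_subpops number of subpopulations.
#' @param seed integer seed.
#' @return `n_subpops` x `length(ancestral_freqs)` matrix of frequencies.
#' @examples
#' f <- simulate_subpop_frequencies(rep(0.5, 5), 0.2, 2, seed = 1)
#' dim(f)
#' @export
simulate_subpop_frequencies <- function(ancestral_freqs, differentiation,
                                        n_subpops, seed = 1L) {
  if (any(ancestral_freqs <= 0) || any(ancestral_freqs >= 1))
    stop("ancestral frequencies must lie strictly in (0, 1)")
  if (!(differentiation > 0 && differentiation < 1))
    stop("differentiation must lie strictly in (0, 1)")
  set.seed(seed)
  L <- length(ancestral_freqs)
  scale <- (1 - differentiation) / differentiation
  out <- matrix(NA_real_, n_subpops, L)
  for (k in seq_len(n_subpops)) {
    out[k, ] <- stats::rbeta(L, ancestral_freqs * scale,
                             (1 - ancestral_freqs) * scale)
  }
  rownames(out) <- paste0("pop", seq_len(n_subpops))
  out
}

#' Plant differentiated regions into a frequency table
#'
#' Overwrites the allele frequencies of SNPs falling inside each requested
#' interval so that the per-SNP Jost's D between the named subpopulation pair
#' equals `target_d`: frequencies are set to 0.5 + delta and 0.5 - delta with
#' delta = sqrt(D / (8 - 4 D)), the closed-form solution of the two-deme D
#' formula for symmetric frequencies. SNPs outside all regions are untouched.
#'
#' @param subpop_freqs subpop x SNP frequency matrix.
#' @param map SNP map (`snp_id`, `chrom`, `pos`).
#' @param planted_regions data.frame as in [sim_config()]; `NULL` or empty
#'   returns `subpop_freqs` unchanged.
#' @return The modified frequency matrix, with attribute `planted_snps`
#'   listing the affected SNP indices per region.
#' @export
plant_differentiated_regions <- function(subpop_freqs, map, planted_regions) {
  if (is.null(planted_regions) || nrow(planted_regions) == 0)
    return(subpop_freqs)
  planted <- vector("list", nrow(planted_regions))
  for (r in seq_len(nrow(planted_regions))) {
    reg <- planted_regions[r, ]
    idx <- which(map$chrom == as.character(reg$chrom) &
                   map$pos >= reg$start & map$pos <= reg$end)
    if (length(idx) == 0)
      stop("planted region ", r, " (", reg$chrom, ":", reg$start, "-",
           reg$end, ") contains no SNPs")
    delta <- sqrt(reg$target_d / (8 - 4 * reg$target_d))
    a <- if (is.null(reg$pop_a)) 1L else as.integer(reg$pop_a)
    b <- if (is.null(reg$pop_b)) 2L else as.integer(reg$pop_b)
    subpop_freqs[a, idx] <- 0.5 + delta
    subpop_freqs[b, idx] <- 0.5 - delta
    planted[[r]] <- idx
  }
  attr(subpop_freqs, "planted_snps") <- planted
  subpop_freqs
}

# Uniform, unique, sorted SNP positions on each chromosome; SNPs are split
# as evenly as possible across chromosomes.
simulate_map <- function(n_snps, n_chromosomes, chrom_length_bp) {
  per <- diff(round(seq(0, n_snps, length.out = n_chromosomes + 1)))
  chrom <- rep(as.character(seq_len(n_chromosomes)), per)
  pos <- unlist(lapply(per, function(n)
    sort(sample.int(chrom_length_bp, n))), use.names = FALSE)
  data.frame(snp_id = sprintf("snp%05d", seq_len(n_snps)),
             chrom = chrom, pos = pos, ref = "A", alt = "G",
             stringsAsFactors = FALSE)
}

# Dosage matrix for one group of n individuals at the given per-SNP
# frequencies, with block-shared uniforms inducing LD and inbreeding
# collapsing the two draws.  `blk` maps SNP -> block index.
sample_group_dosages <- function(n, freqs, blk, inbreeding, ld_break) {
  S <- length(freqs)
  nb <- max(blk)
  U1 <- matrix(stats::runif(n * nb), n, nb)
  U2 <- matrix(stats::runif(n * nb), n, nb)
  collapse <- matrix(stats::runif(n * nb) < inbreeding, n, nb)
  U2[collapse] <- U1[collapse]
  V1 <- U1[, blk, drop = FALSE]
  V2 <- U2[, blk, drop = FALSE]
  fresh <- which(stats::runif(S) < ld_break)
  for (s in fresh) {
    u1 <- stats::runif(n)
    u2 <- stats::runif(n)
    co <- stats::runif(n) < inbreeding
    u2[co] <- u1[co]
    V1[, s] <- u1
    V2[, s] <- u2
  }
  P <- matrix(freqs, n, S, byrow = TRUE)
  d <- (V1 < P) + (V2 < P)
  storage.mode(d) <- "integer"
  d
}

#' Simulate diploid genotypes from subpopulation frequencies
#'
#' Samples allele dosages per accession from its subpopulation's frequencies.
#' SNPs within an LD block (default 30 kb) share each accession's uniform
#' allele draws, so nearby SNPs are correlated while marginal frequencies are
#' exact; with probability `ld_break` a SNP draws fresh uniforms.
#' Inbreeding makes both allele draws coincide with probability
#' `inbreeding_coefficient`, so expected heterozygosity is 2p(1-p)(1-F).
#' Calls are then masked at `missing_rate`.
#'
#' @param subpop_freqs subpop x SNP frequency matrix (e.g. from
#'   [simulate_subpop_frequencies()], possibly after
#'   [plant_differentiated_regions()]).
#' @param config a [sim_config()].
#' @param map optional precomputed SNP map; generated if `NULL`.
#' @return list with `panel` (an [snp_panel()]), `assignment` (factor of
#'   subpopulation labels per accession) and `truth` (a `sim_truth` list:
#'   `ancestral_freqs` if known, `subpop_freqs`, `true_assignment`,
#'   `planted_region_coords`, `qtn_effects`).
#' @export
simulate_genotypes <- function(subpop_freqs, config, map = NULL) {
  stopifnot(inherits(config, "sim_config"),
            nrow(subpop_freqs) >= config$n_subpops,
            ncol(subpop_freqs) == config$n_snps)
  seeds <- stage_seeds(config$seed)
  set.seed(seeds[2])
  if (is.null(map))
    map <- simulate_map(config$n_snps, config$n_chromosomes,
                        config$chrom_length_bp)
  blk <- block_index(map, config$ld_block_bp)
  groups <- lapply(seq_len(config$n_subpops), function(k)
    sample_group_dosages(config$sizes[k], subpop_freqs[k, ], blk,
                         config$inbreeding_coefficient, config$ld_break))
  labels <- rep(rownames(subpop_freqs)[seq_len(config$n_subpops)],
                config$sizes)
  if (!is.null(config$admixture)) {
    adm <- config$admixture
    na <- adm$size
    origin <- matrix(sample(adm$pops, na * max(blk), replace = TRUE,
                            prob = c(adm$proportion, 1 - adm$proportion)),
                     na, max(blk))
    fmix <- t(apply(origin, 1, function(o) subpop_freqs[cbind(o[blk],
                                                              seq_along(blk))]))
    dmix <- matrix(0L, na, config$n_snps)
    for (i in seq_len(na)) {
      dmix[i, ] <- sample_group_dosages(1, fmix[i, ], blk,
                                        config$inbreeding_coefficient,
                                        config$ld_break)
    }
    groups <- c(groups, list(dmix))
    labels <- c(labels, rep("admixed", na))
  }
  dosage <- do.call(rbind, groups)
  if (config$missing_rate > 0) {
    dosage[matrix(stats::runif(length(dosage)) < config$missing_rate,
                  nrow(dosage))] <- NA_integer_
  }
  rownames(dosage) <- sprintf("acc%04d", seq_len(nrow(dosage)))
  panel <- snp_panel(dosage, map)
  assignment <- factor(labels, levels = unique(labels))
  names(assignment) <- rownames(dosage)
  truth <- structure(list(
    ancestral_freqs = attr(subpop_freqs, "ancestral_freqs"),
    subpop_freqs = subpop_freqs,
    true_assignment = assignment,
    planted_region_coords = config$planted_regions,
    qtn_effects = config$qtns), class = "sim_truth")
  list(panel = panel, assignment = assignment, truth = truth)
}

# SNP -> LD-block index (blocks tile each chromosome).
block_index <- function(map, block_bp) {
  key <- paste(map$chrom, (map$pos - 1L) %/% block_bp)
  as.integer(factor(key, levels = unique(key)))
}

#' Simulate a quantitative phenotype from planted QTNs
#'
#' phenotype = sum over QTNs of dosage x effect, plus Gaussian noise scaled so
#' the genetic fraction of variance equals `heritability`. Missing QTN
#' dosages are imputed to the SNP mean for the genetic value.
#'
#' @param panel an [snp_panel()].
#' @param qtn_effects data.frame with columns `snp` (index or SNP id) and
#'   `effect`.
#' @param heritability genetic variance fraction in (0, 1\].
#' @param seed integer seed.
#' @return Named numeric phenotype vector (one value per accession) with
#'   attribute `genetic_value`.
#' @export
simulate_phenotype <- function(panel, qtn_effects, heritability, seed = 1L) {
  if (!(heritability > 0 && heritability <= 1))
    stop("heritability must lie in (0, 1]")
  qtn_effects <- as.data.frame(qtn_effects)
  idx <- qtn_effects$snp
  if (is.character(idx)) idx <- match(idx, panel$map$snp_id)
  if (any(is.na(idx)) || any(idx < 1) || any(idx > ncol(panel$dosage)))
    stop("QTN indices out of range")
  G <- panel$dosage[, idx, drop = FALSE]
  for (j in seq_len(ncol(G))) {
    m <- is.na(G[, j])
    if (any(m)) G[m, j] <- mean(G[, j], na.rm = TRUE)
  }
  g <- drop(G %*% qtn_effects$effect)
  var_g <- stats::var(g)
  if (var_g == 0)
    stop("zero genetic variance: QTNs are monomorphic or effects all zero")
  set.seed(seed)
  noise_sd <- sqrt(var_g * (1 - heritability) / heritability)
  y <- g + stats::rnorm(length(g), sd = noise_sd)
  names(y) <- rownames(panel$dosage)
  attr(y, "genetic_value") <- g
  y
}

#' Simulate a complete synthetic panel with ground truth
#'
#' One-call wrapper: draws ancestral frequencies, Balding-Nichols
#' subpopulation frequencies, plants any requested differentiated regions,
#' samples genotypes and (if QTNs are configured) a phenotype.
#'
#' @param config a [sim_config()].
#' @return list with `panel`, `assignment`, `truth` and (when QTNs are
#'   present) `phenotype`.
#' @examples
#' sim <- simulate_panel(sim_config(n_subpops = 2, sizes = 20, n_snps = 200,
#'                                  n_chromosomes = 2, seed = 7))
#' sim$panel
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- stage_seeds(config$seed)
  set.seed(seeds[4])
  map <- simulate_map(config$n_snps, config$n_chromosomes,
                      config$chrom_length_bp)
  # one ancestral frequency per LD block: aligned marginals are what let
  # block-sharing of allele draws show up as r2 between neighbouring SNPs
  set.seed(seeds[1])
  blk <- block_index(map, config$ld_block_bp)
  anc <- stats::runif(max(blk), config$maf_floor, 1 - config$maf_floor)[blk]
  freqs <- simulate_subpop_frequencies(anc, config$differentiation,
                                       config$n_subpops, seed = seeds[3])
  freqs <- plant_differentiated_regions(freqs, map, config$planted_regions)
  attr(freqs, "ancestral_freqs") <- anc
  sim <- simulate_genotypes(freqs, config, map = map)
  if (!is.null(config$qtns)) {
    sim$phenotype <- simulate_phenotype(sim$panel, config$qtns,
                                        config$heritability, seed = seeds[5])
  }
  sim
}
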