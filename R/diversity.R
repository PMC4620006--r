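#' Per-locus allele frequencies
#'
#' Biallelic allele frequencies over non-missing calls, plus the number of
#' genotyped accessions per SNP.
#'
#' @param panel an [snp_panel()].
#' @return data.frame with columns `snp_id`, `p_ref`, `p_alt`, `n_called`.
#' @export
locus_frequencies <- function(panel) {
  p <- alt_freq(panel)
  data.frame(snp_id = panel$map$snp_id,
             p_ref = 1 - p, p_alt = p,
             n_called = colSums(!is.na(panel$dosage)),
             stringsAsFactors = FALSE)
}

#' Gene diversity (expected heterozygosity) per locus
#'
#' The probability that two alleles drawn at random from the sample differ:
#' GD = 1 - sum(p_u^2) over allele frequencies p_u.
#'
#' @param freqs numeric vector of allele frequencies for one locus (any
#'   number of alleles), or a matrix with one locus per row.
#' @return Gene diversity value(s) in \[0, 1\].
#' @examples
#' gene_diversity(c(0.7, 0.3))  # 0.42
#' @export
gene_diversity <- function(freqs) {
  if (is.matrix(freqs)) return(1 - rowSums(freqs^2))
  1 - sum(freqs^2)
}

#' Polymorphism information content per locus
#'
#' PIC = 1 - sum_u(p_u^2) - sum_{u<v} 2 p_u^2 p_v^2: gene diversity further
#' penalised by the probability that two independently drawn genotypes are
#' both uninformative heterozygote pairs. Always <= gene diversity.
#'
#' @param freqs numeric vector of allele frequencies for one locus, or a
#'   matrix with one locus per row.
#' @return PIC value(s) in \[0, 1\].
#' @examples
#' pic(c(0.5, 0.5))  # 0.375
#' @export
pic <- function(freqs) {
  if (is.matrix(freqs)) {
    s2 <- rowSums(freqs^2)
    s4 <- rowSums(freqs^4)
    # sum_{u<v} 2 p_u^2 p_v^2 = (sum p^2)^2 - sum p^4
    return(1 - s2 - (s2^2 - s4))
  }
  s2 <- sum(freqs^2)
  1 - s2 - (s2^2 - sum(freqs^4))
}

#' Per-accession heterozygosity
#'
#' The fraction of an accession's non-missing loci that are heterozygous
#' (dosage 1).
#'
#' @param panel an [snp_panel()].
#' @return Named numeric vector, one value per accession; `NaN` (with a
#'   warning) for accessions with no called loci.
#' @export
heterozygosity <- function(panel) {
  called <- rowSums(!is.na(panel$dosage))
  het <- rowSums(panel$dosage == 1L, na.rm = TRUE) / called
  if (any(called == 0))
    warning(sum(called == 0), " accession(s) with no called loci")
  het
}

#' Diversity summary by group
#'
#' Mean gene diversity, PIC and heterozygosity, computed per group of
#' accessions (and overall) in the style of a panel diversity table: GD and
#' PIC are means over loci of the per-locus values at the group's allele
#' frequencies; heterozygosity is the mean over the group's accessions.
#'
#' @param panel an [snp_panel()].
#' @param assignment optional factor/vector of group labels per accession;
#'   `NULL` summarises the whole panel only.
#' @return data.frame with columns `group`, `n_accessions`, `gene_diversity`,
#'   `pic`, `heterozygosity`.
#' @export
diversity_summary <- function(panel, assignment = NULL) {
  one <- function(sub, label) {
    p <- alt_freq(sub)
    ok <- !is.nan(p)
    fr <- cbind(p[ok], 1 - p[ok])
    data.frame(group = label, n_accessions = nrow(sub$dosage),
               gene_diversity = mean(gene_diversity(fr)),
               pic = mean(pic(fr)),
               heterozygosity = mean(heterozygosity(sub), na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  out <- one(panel, "Total")
  if (!is.null(assignment)) {
    assignment <- as.factor(assignment)
    stopifnot(length(assignment) == nrow(panel$dosage))
    for (g in levels(assignment)) {
      out <- rbind(out, one(panel[assignment == g, ], g))
    }
  }
  rownames(out) <- NULL
  out
}
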