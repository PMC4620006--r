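---
title: "Methods: differentiation scans, structure inference and association mapping for diverse SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differentiation scans, structure inference and association mapping for diverse SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jostscan)
```

# Scope and model overview

`jostscan` analyses diverse panels of inbred diploid accessions genotyped at
tens of thousands of biallelic SNPs — the situation typical of maize
germplasm collections. The pipeline runs, in order: panel merging and SNP
screening; per-locus and pairwise statistics (gene diversity, PIC,
heterozygosity, identity-by-state distance, centered-IBS kinship, LD
r-squared); structure inference by Patterson-normalised PCA and
neighbor-joining clustering, with a marker-subsampling sufficiency curve;
a windowed Jost's D genome scan calibrated by LD decay, with region calling
and QTL-interval overlap; and a mixed linear model association scan with
Bonferroni thresholding.

Every stage is validated against a synthetic-panel generator whose ground
truth (subpopulation frequencies, planted differentiated regions, planted
QTNs) is known exactly, because diverse real panels of this kind rarely ship
with reusable truth.

# The differentiation statistic

For a set of $n$ subpopulations, a locus has within-subpopulation gene
diversity $H_S$ (the equal-weight mean of $1-\sum_u p_u^2$ across
subpopulations, corrected for sample size by
$\tilde n/(\tilde n - 1)$ with $\tilde n$ the harmonic mean of the
subpopulations' called sample sizes) and total diversity $H_T$ computed
from the equal-weight pooled allele frequencies. Jost's D is

$$ D = \frac{H_T - H_S}{1 - H_S}\cdot\frac{n}{n-1}. $$

D is 0 for identical allele frequencies and exactly 1 when alternative
alleles are fixed in two subpopulations, which is what makes it readable as
a proportion of complete differentiation. Some sources print the final
factor as a division; under division a two-deme fixed difference scores
0.25, which contradicts the statistic's defining property, so
multiplication is the default and the literal-division variant is kept
behind `n_correction = "divide"` for comparison only. The sample-size
correction makes individual null loci slightly negative on average (about
$-0.01$ at 60 accessions per group); genome averages of truly
differentiated panels sit far above this bias.

Loci where any compared subpopulation has fewer than two called accessions,
or where the corrected $H_S$ reaches 1, are masked rather than guessed.

## Window scan and region calling

The scan tiles each chromosome with non-overlapping windows anchored at
position 1. The window length is twice the panel's LD decay distance — the
distance at which binned mean r-squared first drops below 0.1, linearly
interpolated between bin midpoints and anchored at $r^2(0)=1$ — so a window
spans roughly one independent linkage neighbourhood on each side of a
focal site. Window means are taken over unmasked SNPs; empty windows are
omitted rather than reported as zero.

Regions are windows whose mean D strictly exceeds a cutoff: the genome-wide
mean per-SNP D, twice that mean, or an absolute level (default 0.2).
Adjacent qualifying windows merge into a single region, since a selected
haplotype longer than one window should be reported once. Two readings of
"the average level" are possible — the mean over SNPs or over windows —
and both are implemented (`cutoff_basis`); per-SNP is the default because
window occupancy varies and SNP weighting is the less arbitrary average.
QTL overlap reports strict containment (region fully inside the QTL
interval) as the primary count and any positional overlap alongside.

# Kinship, IBS and the mixed model

Per-locus IBS between two accessions is the probability that one allele
drawn at random from each is identical: in dosage terms
$(d_i d_j + (2-d_i)(2-d_j))/4$, so heterozygote-involving pairs (including
het-het) score 0.5. Kinship is background-centered IBS,
$F_{ij} = (Q_{ij}-Q_m)/(1-Q_m)$, with $Q_m$ the mean over distinct pairs
(the diagonal is excluded to avoid self-inflation). Negative values are
clamped to zero for reporting, as GWAS toolkits conventionally do, while
the raw matrix is retained and used by the mixed model.

The association model is the standard single-variance-component mixed
model: $y = \mu + \text{covariates} + x\beta + g + e$ with
$\mathrm{cov}(g) \propto$ kinship. Variance components are estimated once
by REML on the null model (eigendecomposition of the kinship, profiled over
the residual/polygenic ratio) and fixed across SNPs — the
population-parameters-previously-determined scheme — so each SNP reduces to
a generalized least-squares t-test. With an identity kinship and no
covariates this reproduces ordinary least-squares p-values to numerical
precision, which is tested. Structure covariates default to leading
Patterson PCs; externally produced membership proportions can be supplied
as a plain matrix instead. On structured null simulations the genomic
inflation factor stays below 1.1 with kinship and PCs included and exceeds
1.2 without them, which is the point of carrying both.

Missing dosages are mean-imputed for testing only; monomorphic SNPs are
skipped, and the Bonferroni threshold $-\log_{10}(\alpha/m)$ counts only
tested markers. QTN calls use a strict inequality at the threshold.

# Structure inference choices

PCA uses the Patterson normalisation: per-SNP centering and division by
$\sqrt{p(1-p)}$, with missing entries imputed to the SNP mean before
scaling so they contribute nothing after centering. Monomorphic SNPs are
dropped with a count. Scores are eigenvectors of the accession covariance
scaled by singular values; components are defined up to sign, so all
comparisons between PCA runs use absolute correlations after greedy
matching of components — raw signed correlations would be meaningless
under sign flips and occasional component swaps.

The marker-sufficiency (ascertainment) curve subsamples m evenly spread
SNPs — the genome is tiled into m equal-length windows and each window
contributes its most diverse SNP (ties: lower missingness, then lower
position) — reruns the PCA, and averages the matched absolute correlations
of the first five PCs against the full panel, over replicate subsamples
that jitter the window offsets. Jittered offsets preserve even genome
coverage while giving honest replicate variance; fully random draws would
not be comparable to the deliberately spread subsets the procedure is
meant to mimic. The curve is exactly 1 at the full marker count. Note that
the five-PC average is only meaningful when the panel has at least five
structure-bearing dimensions (six or more subpopulations); with fewer, the
trailing PCs are within-population noise and drag the average down at
every subset size.

Trees come from classic Saitou-Nei neighbor-joining on the IBS distance
matrix (via ape). Clusters are extracted by cutting the K-1 longest
internal branches and reading connected components; when a cut strands a
tipless internal node the procedure keeps cutting until K tip-bearing
components exist, so `K = number of tips` degenerates to singletons as
expected. This cut rule reproduces planted subpopulations exactly at
strong drift and degrades smoothly as drift vanishes.

# The synthetic-panel generator

Subpopulation allele frequencies follow the Balding-Nichols model: given an
ancestral frequency $p$ and drift parameter $\theta\in(0,1)$, each
subpopulation draws its frequency from
$\mathrm{Beta}\!\left(p\frac{1-\theta}{\theta},
(1-p)\frac{1-\theta}{\theta}\right)$, i.e. mean $p$ and variance
$\theta\,p(1-p)$. This is the simplest standard model with tunable
differentiation; drift 0.1 produces a genome background of mean per-SNP
D near 0.05 and drift 0.2 near 0.11, spanning the range reported for
diverse maize germplasm.

Genotypes are sampled through a marginal-preserving copula: each accession
carries two uniform draws per LD block, and an allele at SNP $s$ is the
indicator $u < p_{ks}$. SNPs in the same block therefore share allele
draws (high r-squared), while marginal frequencies stay exact, so planted
frequency shifts and the law-of-large-numbers convergence of sample
frequencies are preserved. A per-SNP "break" probability (default 0.1)
draws fresh uniforms, softening within-block LD. Ancestral frequencies are
drawn once per block (uniform on `(maf_floor, 1 - maf_floor)`): aligned
within-block marginals are what allow shared draws to appear as
correlation, while the Balding-Nichols draws remain independent per SNP so
that per-SNP D values are essentially independent — the property the region
scan's false-positive control rests on.

Inbreeding sets the accession's second uniform equal to the first with
probability F per block, giving expected heterozygosity
$2p(1-p)(1-F)$ exactly; the default F = 0.9 reproduces the ~0.03-0.05
heterozygosity of inbred-line panels. (This collapses genotypes
block-wise rather than call-wise; the per-genotype collapse probability is
identical.) Missing calls are masked independently at `missing_rate`
(default 0.05). Planted differentiated regions override the frequencies of
SNPs inside the interval to $0.5\pm\delta$ with
$\delta=\sqrt{D^\ast/(8-4D^\ast)}$, the closed-form symmetric solution
giving per-SNP Jost's D exactly $D^\ast$. Planted QTNs produce a phenotype
as dosage-weighted effects plus Gaussian noise scaled so the genetic
variance fraction equals the requested heritability; zero genetic variance
is rejected rather than silently returning noise, since the noise scale is
defined relative to it.

Two-way admixed accessions are available as an option (each LD block
descends from one of two named subpopulations with a fixed probability);
no reference proportions exist to calibrate them, so they default to off.

Coordinates are deliberately compressed: 10 chromosomes of 5 Mb at ~2 kb
marker spacing, rather than full-length chromosomes at chip density. With
uniformly placed markers this keeps per-window marker counts and a 20-50 kb
LD reach simultaneously realistic; full-length chromosomes at chip density
would make short-range LD invisible. The LD block length (default 30 kb)
is recovered by the decay profile in low-structure panels; pooling strongly
differentiated subpopulations dilutes panel-wide r-squared (the
between-subpopulation variance is uncorrelated noise across SNPs), so the
decay distance of a structured panel reads below the block length. That
shortening is a property of marginal-preserving block LD, not of the decay
estimator.

What the generator does not emulate: coalescent genealogies (no recombination
gradients, no allele-frequency spectrum from demography), ascertainment bias
of chip design, genotyping error beyond missingness, and multi-allelic or
structural variation. Passing tests therefore show the pipeline's statistics
are correct and well calibrated under idealised panel structure; they do not
certify behaviour under demographic histories the generator cannot produce.

# Panel merging and screening rules

Panels merge on the (SNP name, chromosome, position) triple, intersecting
SNP sets across panels; accessions concatenate and must be globally unique.
When a later panel reports the complementary-strand allele pair, its
alleles are complemented onto the first panel's strand; swapped ref/alt
order flips dosages ($d \to 2-d$); anything else is dropped and reported.
A/T and C/G SNPs are their own complements, so strand cannot be resolved
by letters alone: they are dropped by default, with `ambiguous = "keep"`
trusting marker names instead. Screening keeps SNPs with MAF strictly
above 0.05 and missingness strictly below 0.2 (ties fail, reading the
thresholds literally), and requires a mapped position. Positions are
1-based inclusive everywhere in reports; BED input/output converts to and
from 0-based half-open.

# Numerical and reproducibility choices

All randomness flows from one integer seed through fixed per-stage
sub-seeds, so identical configurations are bit-reproducible and stages can
be re-run independently. Kinship matrices are symmetrised and negative
eigenvalues raised to zero before REML. The REML profile is optimised over
$\log\delta \in [-11.5, 11.5]$ with `optimize`. LD decay bins default to
5 kb up to 200 kb. PCA rank deficiencies truncate with a warning rather
than padding with noise components.

# Problem sizes used in validation

The shipped validation suite runs, per check: estimator-vs-oracle
agreement on 1,000 random loci at 60 accessions; a two-island drift
recovery at 2x200 accessions and 5,000 SNPs across drifts 0.02-0.4; a
planted-region scan on 10-chromosome, 10,000-SNP panels over 20 seeds
(3 planted regions at D = 0.5 over a 0.05 background); structure recovery
at 3x40 accessions and 1,500 SNPs; a sufficiency curve on a 6-subpopulation
3,000-SNP panel with 20 replicate subsamples; and GWAS calibration on
10,000 independent null SNPs at 400 accessions plus 20 power replicates at
500 accessions and 5,000 SNPs with a 10%-variance QTN. These sizes were
chosen so each property is measured with useful precision while the whole
suite stays desk-scale.

# Known limitations

- D is computed per biallelic SNP; multi-allelic loci and haplotype-based
  differentiation are out of scope.
- The window scan's error control assumes per-SNP D values are close to
  independent given the window size; panels whose differentiation is
  block-correlated at scales much longer than the LD decay distance will
  show more false regions than the planted-truth suite suggests.
- The mixed model fixes variance components at the null fit (P3D); loci of
  very large effect are tested slightly conservatively compared to exact
  per-SNP REML.
- Cluster extraction from the tree is a geometric rule, not a model-based
  assignment; it reports a partition for any K without arbitrating what K
  should be.
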