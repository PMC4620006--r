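test_that("Balding-Nichols frequencies recover the ancestral values in the zero-drift limit", {
  anc <- runif(500, 0.1, 0.9)
  f <- simulate_subpop_frequencies(anc, 1e-7, 3, seed = 1)
  expect_equal(dim(f), c(3, 500))
  expect_lt(max(abs(sweep(f, 2, anc))), 0.01)
})

test_that("Balding-Nichols rejects out-of-range parameters", {
  expect_error(simulate_subpop_frequencies(c(0.5, 1), 0.2, 2), "strictly")
  expect_error(simulate_subpop_frequencies(0.5, 0, 2), "strictly")
  expect_error(simulate_subpop_frequencies(0.5, 1, 2), "strictly")
})

test_that("realized mean Jost's D of Beta draws matches a Monte-Carlo oracle of the same model", {
  # analytic-by-simulation reference on the true-frequency scale
  theta <- 0.2
  set.seed(99)
  mc_d <- function(n) {
    p <- rep(0.5, n)
    sc <- (1 - theta) / theta
    p1 <- rbeta(n, p * sc, (1 - p) * sc)
    p2 <- rbeta(n, p * sc, (1 - p) * sc)
    hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    pb <- (p1 + p2) / 2
    mean((2 * pb * (1 - pb) - hs) / (1 - hs) * 2)
  }
  reference <- mc_d(400000)
  f <- simulate_subpop_frequencies(rep(0.5, 10000), theta, 2, seed = 2)
  hs <- (2 * f[1, ] * (1 - f[1, ]) + 2 * f[2, ] * (1 - f[2, ])) / 2
  pb <- colMeans(f)
  d <- (2 * pb * (1 - pb) - hs) / (1 - hs) * 2
  expect_equal(mean(d), reference, tolerance = 0.02)
})

test_that("frequency draws are deterministic under a fixed seed", {
  anc <- runif(50)
  a <- simulate_subpop_frequencies(anc, 0.3, 4, seed = 11)
  b <- simulate_subpop_frequencies(anc, 0.3, 4, seed = 11)
  expect_identical(a, b)
})

test_that("a fixed config and seed give bit-identical panels", {
  cfg <- sim_config(n_subpops = 2, sizes = 10, n_snps = 150,
                    n_chromosomes = 2, chrom_length_bp = 1e5, seed = 5)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$panel$dosage, s2$panel$dosage)
  expect_identical(s1$panel$map, s2$panel$map)
})

test_that("full inbreeding forces zero heterozygosity everywhere", {
  cfg <- sim_config(n_subpops = 2, sizes = 15, n_snps = 300,
                    n_chromosomes = 2, chrom_length_bp = 1e5,
                    inbreeding_coefficient = 1, missing_rate = 0, seed = 3)
  sim <- simulate_panel(cfg)
  expect_true(all(heterozygosity(sim$panel) == 0))
})

test_that("heterozygosity matches the closed form 2p(1-p)(1-F)", {
  # frequencies pinned near 0.5 via a tight maf floor; F = 0.9 gives the
  # inbred-panel heterozygosity scale ~0.05
  cfg <- sim_config(n_subpops = 1, sizes = 400, n_snps = 1000,
                    n_chromosomes = 2, chrom_length_bp = 1e6,
                    differentiation = 1e-6, inbreeding_coefficient = 0.9,
                    missing_rate = 0, maf_floor = 0.45, seed = 8)
  sim <- simulate_panel(cfg)
  p <- attr(sim$truth$subpop_freqs, "ancestral_freqs")
  expected <- mean(2 * p * (1 - p) * (1 - 0.9))
  expect_equal(mean(heterozygosity(sim$panel)), expected, tolerance = 0.1)
  expect_equal(mean(heterozygosity(sim$panel)), 0.05, tolerance = 0.005)
})

test_that("masked-call fraction is binomially consistent with missing_rate", {
  cfg <- sim_config(n_subpops = 2, sizes = 50, n_snps = 1000,
                    n_chromosomes = 2, chrom_length_bp = 1e6,
                    missing_rate = 0.1, seed = 4)
  sim <- simulate_panel(cfg)
  n_calls <- length(sim$panel$dosage)
  frac <- mean(is.na(sim$panel$dosage))
  se <- sqrt(0.1 * 0.9 / n_calls)
  expect_lt(abs(frac - 0.1), 4 * se)
})

test_that("sampled allele frequencies converge to the subpopulation frequencies", {
  cfg <- sim_config(n_subpops = 1, sizes = 2000, n_snps = 60,
                    n_chromosomes = 1, chrom_length_bp = 1e6,
                    missing_rate = 0, seed = 6)
  sim <- simulate_panel(cfg)
  expect_lt(max(abs(alt_freq(sim$panel) - sim$truth$subpop_freqs[1, ])),
            0.05)
})

test_that("planting to fixation yields per-SNP D of exactly 1", {
  pr <- data.frame(chrom = "1", start = 1, end = 5e4, target_d = 1)
  cfg <- sim_config(n_subpops = 2, sizes = 100, n_snps = 400,
                    n_chromosomes = 2, chrom_length_bp = 5e5,
                    missing_rate = 0, planted_regions = pr, seed = 7)
  sim <- simulate_panel(cfg)
  idx <- which(sim$panel$map$chrom == "1" & sim$panel$map$pos <= 5e4)
  expect_gt(length(idx), 0)
  f <- sim$truth$subpop_freqs
  expect_true(all(f[1, idx] == 1 & f[2, idx] == 0))
  d <- dest_per_locus(sim$panel, sim$assignment)$d
  expect_true(all(d[idx] == 1))
})

test_that("planting is the identity when no regions are requested", {
  f <- matrix(runif(20), 2, 10)
  map <- data.frame(snp_id = paste0("s", 1:10), chrom = "1",
                    pos = 1:10 * 100, ref = "A", alt = "G")
  expect_identical(plant_differentiated_regions(f, map, NULL), f)
})

test_that("a planted shift targeting D = 0.3 realizes that per-SNP D on the shifted frequencies", {
  f <- matrix(0.5, 2, 10)
  map <- data.frame(snp_id = paste0("s", 1:10), chrom = "1",
                    pos = 1:10 * 100, ref = "A", alt = "G")
  pr <- data.frame(chrom = "1", start = 1, end = 500, target_d = 0.3)
  g <- plant_differentiated_regions(f, map, pr)
  p1 <- g[1, 1]; p2 <- g[2, 1]
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  pb <- (p1 + p2) / 2
  d <- (2 * pb * (1 - pb) - hs) / (1 - hs) * 2
  expect_equal(d, 0.3, tolerance = 1e-12)
  expect_identical(g[, 6:10], f[, 6:10])   # outside SNPs untouched
})

test_that("a region containing no SNPs is reported as an error", {
  f <- matrix(0.5, 2, 3)
  map <- data.frame(snp_id = paste0("s", 1:3), chrom = "1",
                    pos = c(100, 200, 300), ref = "A", alt = "G")
  pr <- data.frame(chrom = "2", start = 1, end = 500, target_d = 0.5)
  expect_error(plant_differentiated_regions(f, map, pr), "no SNPs")
})

test_that("planted-region SNPs have higher expected D than background", {
  pr <- data.frame(chrom = "1", start = 1e5, end = 2e5, target_d = 0.5)
  cfg <- sim_config(n_subpops = 2, sizes = 80, n_snps = 1000,
                    n_chromosomes = 2, chrom_length_bp = 1e6,
                    differentiation = 0.1, planted_regions = pr, seed = 12)
  sim <- simulate_panel(cfg)
  idx <- which(sim$panel$map$chrom == "1" & sim$panel$map$pos >= 1e5 &
                 sim$panel$map$pos <= 2e5)
  d <- dest_per_locus(sim$panel, sim$assignment)$d
  expect_gt(mean(d[idx], na.rm = TRUE), mean(d[-idx], na.rm = TRUE))
})

test_that("the noiseless-heritability phenotype preserves dosage rank order", {
  cfg <- sim_config(n_subpops = 2, sizes = 30, n_snps = 100,
                    n_chromosomes = 1, chrom_length_bp = 1e5,
                    missing_rate = 0, seed = 9)
  sim <- simulate_panel(cfg)
  y <- simulate_phenotype(sim$panel, data.frame(snp = 50, effect = 1),
                          heritability = 1, seed = 1)
  expect_equal(as.numeric(y), as.numeric(sim$panel$dosage[, 50]))
})

test_that("zero genetic variance is rejected when heritability is positive", {
  cfg <- sim_config(n_subpops = 1, sizes = 20, n_snps = 50,
                    n_chromosomes = 1, chrom_length_bp = 1e5,
                    missing_rate = 0, seed = 10)
  sim <- simulate_panel(cfg)
  expect_error(simulate_phenotype(sim$panel,
                                  data.frame(snp = 1, effect = 0), 0.5),
               "zero genetic variance")
})

test_that("realized genetic variance fraction tracks the requested heritability", {
  cfg <- sim_config(n_subpops = 2, sizes = 250, n_snps = 200,
                    n_chromosomes = 1, chrom_length_bp = 1e6,
                    missing_rate = 0, seed = 13)
  sim <- simulate_panel(cfg)
  fracs <- vapply(1:10, function(s) {
    y <- simulate_phenotype(sim$panel, data.frame(snp = 100, effect = 1),
                            heritability = 0.5, seed = s)
    g <- attr(y, "genetic_value")
    var(g) / var(y)
  }, numeric(1))
  expect_equal(mean(fracs), 0.5, tolerance = 0.05)
})

test_that("config validation rejects out-of-range settings", {
  expect_error(sim_config(sizes = 1), "sizes")
  expect_error(sim_config(differentiation = 0), "differentiation")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(heritability = 1.2), "heritability")
  expect_error(sim_config(planted_regions = data.frame(
    chrom = "1", start = 1, end = 1e9, target_d = 0.5)), "bounds")
})

test_that("optional two-way admixture adds intermediate accessions", {
  cfg <- sim_config(n_subpops = 2, sizes = 25, n_snps = 600,
                    n_chromosomes = 2, chrom_length_bp = 5e5,
                    differentiation = 0.4, missing_rate = 0,
                    admixture = list(pops = c(1, 2), size = 10,
                                     proportion = 0.5), seed = 16)
  sim <- simulate_panel(cfg)
  expect_equal(sum(sim$assignment == "admixed"), 10)
  expect_equal(nrow(sim$panel$dosage), 60)
  # admixed accessions sit between the parental groups on PC1
  pc <- pca_patterson(sim$panel, 1)
  m1 <- mean(pc$scores[sim$assignment == "pop1", 1])
  m2 <- mean(pc$scores[sim$assignment == "pop2", 1])
  ma <- mean(pc$scores[sim$assignment == "admixed", 1])
  expect_true((ma > min(m1, m2)) && (ma < max(m1, m2)))
})
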