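two_group_panel <- function(n1, n2, p1, p2, seed = 1) {
  set.seed(seed)
  S <- length(p1)
  d <- rbind(matrix(rbinom(n1 * S, 2, rep(p1, each = n1)), n1),
             matrix(rbinom(n2 * S, 2, rep(p2, each = n2)), n2))
  storage.mode(d) <- "integer"
  rownames(d) <- paste0("a", seq_len(n1 + n2))
  list(panel = make_panel(d),
       assignment = factor(rep(c("g1", "g2"), c(n1, n2))))
}

test_that("identical frequencies give near-zero D and fixed differences give exactly 1", {
  tg <- two_group_panel(300, 300, rep(0.4, 200), rep(0.4, 200), seed = 1)
  d0 <- dest_per_locus(tg$panel, tg$assignment)$d
  expect_lt(abs(mean(d0, na.rm = TRUE)), 0.01)
  d <- rbind(matrix(0L, 5, 10), matrix(2L, 5, 10))
  rownames(d) <- paste0("a", 1:10)
  fixed <- dest_per_locus(make_panel(d),
                          factor(rep(c("g1", "g2"), each = 5)))
  expect_true(all(fixed$d == 1))
  # the literal-division variant: ((H_T - H_S)/(1 - H_S)) / 2 = 0.25 at a
  # two-deme fixed difference, far from the expected unity
  div <- dest_per_locus(make_panel(d),
                        factor(rep(c("g1", "g2"), each = 5)),
                        n_correction = "divide")
  expect_true(all(div$d == 0.25))
})

test_that("per-locus D, with missing data, matches the brute-force oracle to 1e-12", {
  set.seed(2)
  n <- 50
  S <- 300
  d <- matrix(rbinom(2 * n * S, 2, runif(2 * n * S, 0.05, 0.95)), 2 * n, S)
  d[sample(length(d), length(d) * 0.1)] <- NA
  storage.mode(d) <- "integer"
  rownames(d) <- paste0("a", seq_len(2 * n))
  panel <- make_panel(d)
  grp <- factor(rep(c("g1", "g2"), each = n))
  got <- dest_per_locus(panel, grp)$d
  want <- vapply(seq_len(S), function(s)
    oracle_dest_pair(d[grp == "g1", s], d[grp == "g2", s]), numeric(1))
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("frequencies 0.8 vs 0.3 with 50 accessions each match the first-principles estimator", {
  tg <- two_group_panel(50, 50, rep(0.8, 400), rep(0.3, 400), seed = 3)
  got <- dest_per_locus(tg$panel, tg$assignment)$d
  want <- vapply(seq_len(400), function(s)
    oracle_dest_pair(tg$panel$dosage[tg$assignment == "g1", s],
                     tg$panel$dosage[tg$assignment == "g2", s]),
    numeric(1))
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("D is invariant to swapping subpopulation labels", {
  tg <- two_group_panel(40, 60, runif(100, 0.1, 0.9), runif(100, 0.1, 0.9),
                        seed = 4)
  a <- dest_per_locus(tg$panel, tg$assignment, pair = c("g1", "g2"))$d
  b <- dest_per_locus(tg$panel, tg$assignment, pair = c("g2", "g1"))$d
  expect_equal(a, b, tolerance = 1e-14)
})

test_that("a subpopulation with fewer than 2 called accessions masks the locus", {
  d <- rbind(c(0L, NA), c(0L, NA), c(2L, 0L), c(2L, 2L))
  rownames(d) <- paste0("a", 1:4)
  res <- dest_per_locus(make_panel(d), factor(c("g1", "g1", "g2", "g2")))
  expect_false(is.na(res$d[1]))
  expect_true(is.na(res$d[2]))
})

test_that("the pairwise matrix is symmetric with an exactly zero diagonal", {
  sim <- simulate_panel(sim_config(n_subpops = 3, sizes = 30, n_snps = 500,
                                   n_chromosomes = 2, chrom_length_bp = 1e6,
                                   differentiation = 0.2, seed = 5))
  M <- pairwise_dest_matrix(sim$panel, sim$assignment)
  expect_true(isSymmetric(M))
  expect_identical(unname(diag(M)), rep(0, 3))
  expect_true(all(M[upper.tri(M)] > 0))
})

test_that("permuting assignment labels collapses genome-average D to about zero", {
  sim <- simulate_panel(sim_config(n_subpops = 2, sizes = 60, n_snps = 800,
                                   n_chromosomes = 2, chrom_length_bp = 1e6,
                                   differentiation = 0.2, seed = 6))
  real <- mean(dest_per_locus(sim$panel, sim$assignment)$d, na.rm = TRUE)
  set.seed(7)
  perm_means <- replicate(20, {
    perm <- sample(sim$assignment)
    mean(dest_per_locus(sim$panel, perm)$d, na.rm = TRUE)
  })
  expect_gt(real, 0.05)
  # small negative bias (~ -0.01) is expected: H_S is sample-corrected
  # upward while pooled H_T is not
  expect_lt(max(abs(perm_means)), 0.02)
})

test_that("genome-average D is monotone in the drift parameter", {
  means <- vapply(c(0.02, 0.1, 0.4), function(th) {
    sim <- simulate_panel(sim_config(n_subpops = 2, sizes = 80,
                                     n_snps = 800, n_chromosomes = 2,
                                     chrom_length_bp = 1e6,
                                     differentiation = th, seed = 8))
    mean(dest_per_locus(sim$panel, sim$assignment)$d, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("window means aggregate per-SNP D as hand-computed", {
  vals <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  map <- data.frame(snp_id = paste0("s", 1:10), chrom = "1",
                    pos = c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100) * 10L,
                    ref = "A", alt = "G")
  w <- window_scan(stats::setNames(vals, map$snp_id), map,
                   window_size_bp = 500)
  expect_equal(nrow(w), 2)
  expect_equal(w$mean_dest, c(mean(vals[1:5]), mean(vals[6:10])))
  expect_equal(w$start, c(1L, 501L))
  # constant field: every window mean equals the constant
  w2 <- window_scan(setNames(rep(0.3, 10), map$snp_id), map, 250)
  expect_true(all(w2$mean_dest == 0.3))
  # degenerate window covers the chromosome
  w3 <- window_scan(setNames(vals, map$snp_id), map, 1e6)
  expect_equal(nrow(w3), 1)
  expect_equal(w3$mean_dest, mean(vals))
})

test_that("region calling thresholds and merging behave on constructed fields", {
  map <- data.frame(snp_id = paste0("s", 1:20), chrom = "1",
                    pos = seq(50L, 1000L, by = 50L), ref = "A", alt = "G")
  flat <- setNames(rep(0.25, 20), map$snp_id)
  scan_flat <- list(windows = window_scan(flat, map, 100), d = flat)
  expect_equal(nrow(call_regions(scan_flat, "twice_mean")), 0)
  just_below <- setNames(rep(0.19, 20), map$snp_id)
  scan_jb <- list(windows = window_scan(just_below, map, 100),
                  d = just_below)
  expect_equal(nrow(call_regions(scan_jb, "absolute",
                                 absolute_level = 0.2)), 0)
  # two adjacent hot windows merge into one region; an isolated one stays
  vals <- rep(0.05, 20)
  vals[3:6] <- 0.8     # windows 2 and 3 (pos 150-300)
  vals[15:16] <- 0.8   # window 8 (pos 750-800)
  d <- setNames(vals, map$snp_id)
  reg <- call_regions(list(windows = window_scan(d, map, 100), d = d),
                      "twice_mean")
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start, c(101L, 701L))
  expect_equal(reg$end, c(300L, 800L))
})

test_that("QTL overlap distinguishes containment from mere overlap", {
  regions <- data.frame(chrom = c("1", "1", "2"),
                        start = c(100L, 400L, 100L),
                        end = c(200L, 600L, 200L))
  qtl <- data.frame(chrom = c("1", "1"), start = c(50L, 450L),
                    end = c(500L, 550L), trait_class = c("FT", "PA"),
                    source = "x")
  ov <- overlap_qtl(regions, qtl)
  expect_equal(ov$hits$contained, c(TRUE, FALSE, FALSE))
  expect_equal(ov$hits$any_overlap, c(TRUE, TRUE, FALSE))
  expect_equal(ov$n_contained, 1)
  expect_equal(ov$n_any_overlap, 2)
})

test_that("containment of random regions matches the QTL coverage fraction", {
  set.seed(9)
  # QTL tiling covering half the chromosome in alternating 10 kb blocks
  starts <- seq(1L, 1e6L, by = 2e4L)
  qtl <- data.frame(chrom = "1", start = starts, end = starts + 9999L,
                    trait_class = "FT", source = "sim")
  pos <- sample.int(9.8e5, 400)
  regions <- data.frame(chrom = "1", start = pos, end = pos + 99L)
  ov <- overlap_qtl(regions, qtl)
  # a 100 bp region is fully inside a covering 10 kb block ~ half the time
  expect_equal(ov$n_contained / ov$n_regions, 0.5 * (9901 / 10000),
               tolerance = 0.15)
})

test_that("BED round-trip respects the 0-based half-open convention", {
  f <- tempfile(fileext = ".bed")
  writeLines("1\t99\t200\tFT\tsrc", f)
  q <- read_qtl_bed(f)
  expect_equal(q$start, 100L)
  expect_equal(q$end, 200L)
  regions <- data.frame(chrom = "1", start = 100L, end = 200L)
  f2 <- tempfile(fileext = ".bed")
  write_regions_bed(regions, f2)
  expect_equal(read_qtl_bed(f2)[, c("chrom", "start", "end")],
               data.frame(chrom = "1", start = 100L, end = 200L))
})

test_that("regions shared across pair scans are intersected correctly", {
  r1 <- data.frame(chrom = "1", start = c(100L, 900L),
                   end = c(300L, 1000L))
  r2 <- data.frame(chrom = "1", start = 250L, end = 400L)
  r3 <- data.frame(chrom = "2", start = 100L, end = 200L)
  same <- common_regions(list(a = r1, b = r1), min_pairs = 2)
  expect_equal(nrow(same), 2)
  disjoint <- common_regions(list(a = r1, b = r3), min_pairs = 2)
  expect_equal(nrow(disjoint), 0)
  three <- common_regions(list(a = r1, b = r2,
                               c = data.frame(chrom = "1", start = 280L,
                                              end = 320L)), min_pairs = 3)
  expect_equal(nrow(three), 1)
  expect_equal(three$n_pairs, 3)
  expect_equal(three$pairs, "a,b,c")
})
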