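# Core coSNP statistics against arithmetic, enumeration and permutation
# oracles.

test_that("site classification partitions sites and counts match set logic", {
  g <- toy_gene_genome(paste(rep("GCT", 10), collapse = ""), pad = 2)
  sites <- build_site_table(g$map, g$genome_A, g$genome_B)
  # 30 sites at coords 2..31; A-SNPs at three coords, B at two, one shared
  mk <- function(pos, ref) data.frame(chrom = "chrA", pos = pos, ref = ref,
                                      alt = "A", maf = 0.2)
  ref_at <- function(p) sites$ref_A[match(p, sites$coord_A)]
  va <- mk(c(2L, 5L, 11L), ref_at(c(2, 5, 11)))
  vb <- data.frame(chrom = "chrB", pos = c(5L, 20L),
                   ref = sites$ref_B[match(c(5, 20), sites$coord_B)],
                   alt = "A", maf = 0.3)
  cl <- classify_sites(sites, va, vb)
  expect_identical(as.vector(table(cl$class)), c(1L, 2L, 1L, 26L))
  cnt <- cosnp_counts(cl)
  expect_equal(cnt, data.frame(n_sites = 30, n_A = 3, n_B = 2, n_co = 1))
  # variants at unknown positions are dropped with a warning
  va_bad <- rbind(va, data.frame(chrom = "chrA", pos = 999L, ref = "A",
                                 alt = "C", maf = 0.1))
  expect_warning(classify_sites(sites, va_bad, vb), "dropped")
})

test_that("minus-strand variants are complemented onto the coding strand", {
  g <- toy_gene_genome("ATGGCTTTA", strand_A = "-")
  sites <- build_site_table(g$map, g$genome_A, g$genome_B)
  # coding-strand A at CDS position 0 sits at genomic coord 12 as a T
  va <- data.frame(chrom = "chrA", pos = 12L, ref = "T", alt = "C", maf = 0.1)
  vb <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                   alt = character(0), maf = numeric(0))
  cl <- classify_sites(sites, va, vb)
  hit <- cl[cl$snp_A, ]
  expect_equal(nrow(hit), 1)
  expect_identical(hit$ref_A, "A")
  expect_identical(hit$pair_A, "A/G")  # C complements to G
})

test_that("cosnp_oe equals the defining ratio and handles edge cases", {
  expect_equal(cosnp_oe(100, 10, 10, 1), 1)
  expect_equal(cosnp_oe(1000, 50, 40, 8), 4)
  expect_equal(cosnp_oe(500, 20, 30, 0), 0)
  expect_error(cosnp_oe(100, 0, 10, 0), "undefined")
  set.seed(1)
  for (i in 1:100) {
    n <- sample(50:500, 1)
    a <- sample(n, sample(5:30, 1))
    b <- sample(n, sample(5:30, 1))
    co <- length(intersect(a, b))
    # brute-force recount of the defining frequencies
    oracle <- (co / n) / ((length(a) / n) * (length(b) / n))
    expect_equal(cosnp_oe(n, length(a), length(b), co), oracle)
  }
})

test_that("chi-square independence matches the textbook formula and permutation", {
  # exactly independent margins -> statistic 0
  r0 <- suppressWarnings(
    chisq_independence(data.frame(n_sites = 1000, n_A = 50, n_B = 40,
                                  n_co = 2)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # formula oracle for the spec's table
  cnt <- data.frame(n_sites = 1000, n_A = 50, n_B = 40, n_co = 8)
  obs <- matrix(c(8, 42, 32, 918), 2, 2)
  expd <- outer(rowSums(obs), colSums(obs)) / 1000
  stat_oracle <- sum((obs - expd)^2 / expd)
  r <- suppressWarnings(chisq_independence(cnt))  # expected coSNP cell is 2
  expect_equal(r$statistic, stat_oracle, tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(stat_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # permutation null with fixed margins (r2dtable oracle)
  set.seed(99)
  sim <- r2dtable(10000, rowSums(obs), colSums(obs))
  stat_of <- function(m) sum((m - expd)^2 / expd)
  p_perm <- mean(vapply(sim, stat_of, numeric(1)) >= stat_oracle - 1e-9)
  se <- sqrt(p_perm * (1 - p_perm) / 10000)
  expect_lt(abs(p_perm - r$p_value), 3 * se + 1e-3)
  # low expected counts are flagged
  expect_warning(chisq_independence(data.frame(n_sites = 40, n_A = 4, n_B = 4,
                                               n_co = 1)), "unreliable")
})

test_that("pattern O/E matches a brute-force tally and normalises", {
  # degenerate marginals: every SNP C/T in both species
  d <- toy_classified(snp_A = rep(c(TRUE, FALSE), c(6, 4)),
                      snp_B = rep(c(TRUE, FALSE), c(3, 7)),
                      pair_A = "C/T", pair_B = "C/T")
  po <- pattern_oe(d)
  expect_equal(po$n_co, 3)
  expect_equal(unname(po$oe["C/T", "C/T"]), 1)
  expect_equal(sum(po$O), 1)
  # constructed stratum with mixed patterns vs exhaustive recount
  set.seed(7)
  n <- 400
  snp_A <- runif(n) < 0.4
  snp_B <- runif(n) < 0.35
  pa <- sample(SNP_PATTERNS, n, replace = TRUE)
  pb <- sample(SNP_PATTERNS, n, replace = TRUE)
  d2 <- toy_classified(snp_A, snp_B)
  d2$pair_A <- ifelse(snp_A, pa, NA)
  d2$pair_B <- ifelse(snp_B, pb, NA)
  po2 <- pattern_oe(d2)
  co <- snp_A & snp_B
  for (p in SNP_PATTERNS) for (q in SNP_PATTERNS) {
    O <- sum(co & pa == p & pb == q) / sum(co)
    E <- mean(pa[snp_A] == p) * mean(pb[snp_B] == q)
    expect_equal(unname(po2$O[p, q]), O)
    expect_equal(unname(po2$oe[p, q]), O / E)
  }
  expect_equal(sum(po2$O), 1)
  expect_equal(unname(po2$same_allele), unname(diag(po2$oe)))
  # empty stratum
  e <- pattern_oe(toy_classified(logical(4), logical(4)))
  expect_equal(e$n_co, 0)
})

test_that("site frequency spectrum bins and KS comparison behave", {
  expect_equal(unname(site_frequency_spectrum(rep(0.5, 10))[10]), 1)
  sfs <- site_frequency_spectrum(c(0.02, 0.04, 0.07, 0.12, 0.5),
                                 bin_edges = c(0, 0.05, 0.1, 0.5))
  expect_equal(unname(sfs), c(2, 1, 2) / 5)
  expect_error(site_frequency_spectrum(numeric(0)), "empty")
  expect_error(site_frequency_spectrum(c(0.2, 0.6)), "0.5")
  # folded neutral generator gives a monotone decreasing spectrum
  set.seed(3)
  m <- 200
  j <- seq_len(m / 2)
  maf <- sample(j, 20000, replace = TRUE, prob = 1 / j + 1 / (m - j)) / m
  spec <- site_frequency_spectrum(maf, bin_edges = seq(0, 0.5, 0.1))
  expect_true(all(diff(spec) < 0))
  # KS: identical -> 0, disjoint -> 1, toy vs direct ECDF oracle
  x <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(compare_sfs(x, x)$statistic, 0)
  expect_equal(compare_sfs(x, x + 0.0999)$statistic, 0.25)
  expect_equal(compare_sfs(c(0.01, 0.02, 0.03), c(0.2, 0.3, 0.4))$statistic, 1)
  y <- c(0.05, 0.15, 0.25)
  grid <- sort(unique(c(x, y)))
  oracle <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
  expect_equal(compare_sfs(x, y)$statistic, oracle)
  expect_error(compare_sfs(x, 0.1), "at least 2")
})

test_that("rare-variant fractions and the exact comparison", {
  expect_equal(rare_variant_fraction(c(0.02, 0.2, 0.3)), 0)
  expect_equal(rare_variant_fraction(c(rep(0.005, 3), rep(0.2, 7))), 0.3)
  cmp <- compare_rare_fraction(c(rep(0.005, 8), rep(0.3, 2)),
                               c(rep(0.005, 3), rep(0.3, 7)))
  expect_equal(cmp$fraction_1, 0.8)
  expect_equal(cmp$fraction_2, 0.3)
  expect_equal(cmp$p_value, fisher_p_enum(8, 2, 3, 7), tolerance = 1e-9)
})
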