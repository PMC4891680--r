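# Window classes, covariates, constraint binning, nearest-neighbour pairing
# and the enrichment tests.

test_that("window classes follow the dominance hierarchy", {
  cosnps <- data.frame(chrom = "chr1",
                       coord = c(5, 50, 120, 250, 310),
                       degeneracy = c("four", "zero", "two_three",
                                      "four", "four"))
  w <- classify_cosnp_windows(cosnps, c(chr1 = 400), width = 100)
  expect_equal(as.character(w$cosnp_class), c("zero", "two_three", "four", "four"))
  # recount oracle: window of a coSNP = floor(coord/width)
  for (i in seq_len(nrow(w))) {
    inw <- cosnps[cosnps$coord >= w$start[i] & cosnps$coord < w$end[i], ]
    want <- if (any(inw$degeneracy == "zero")) "zero"
            else if (any(inw$degeneracy == "two_three")) "two_three"
            else if (any(inw$degeneracy == "four")) "four" else "none"
    expect_identical(as.character(w$cosnp_class[i]), want)
  }
  expect_warning(classify_cosnp_windows(
    data.frame(chrom = "chr1", coord = 999, degeneracy = "zero"),
    c(chr1 = 400), width = 100), "outside")
})

test_that("window class comparisons run KS and equal-proportion tests", {
  set.seed(8)
  w <- data.frame(cosnp_class = factor(rep(c("zero", "two_three", "four"),
                                           each = 40),
                                       levels = WINDOW_CLASSES),
                  tajimas_d = rnorm(120))
  r <- compare_window_classes(w)
  expect_equal(nrow(r$ks), 3)
  expect_true(all(r$ks$ks_p >= 0 & r$ks$ks_p <= 1))
  expect_equal(sum(r$high_d$n), 120)
  expect_s3_class(r$equal_prop, "data.frame")
})

test_that("window covariates are exact recounts and drop empty windows", {
  d <- toy_classified(snp_A = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                      snp_B = rep(FALSE, 6))
  d$coord_A <- c(0L, 5L, 9L, 10L, 15L, 30L)
  wc <- window_covariates(d, width = 10)
  expect_equal(wc$n_sites, c(3, 2, 1))
  expect_equal(wc$snp_density, c(2 / 3, 1 / 2, 0))
  rm <- data.frame(chrom = "chrA", start = c(0, 10), end = c(10, 20),
                   rate = c(1.5, 2.5))
  wc2 <- window_covariates(d, recomb_map = rm, width = 10)
  expect_equal(nrow(wc2), 2)  # window without map coverage excluded
  expect_equal(wc2$recomb_rate, c(1.5, 2.5))
})

test_that("equal-size groups partition by rank with ties to the lower bin", {
  g <- equal_size_groups(1:10, 5)
  expect_equal(as.vector(table(g)), rep(2, 5))
  expect_equal(g[order(1:10)], rep(1:5, each = 2))
  g2 <- equal_size_groups(c(1, 2, 2, 2, 5, 6, 7, 8, 9, 10), 5)
  expect_equal(length(g2), 10)
  expect_equal(sum(table(g2)), 10)
  expect_true(all(g2[2:4] == g2[2]))  # ties share the lower bin
  expect_equal(equal_size_groups(c(3, 1, 2), 3), c(3, 1, 2))  # k = n
  expect_warning(gs <- equal_size_groups(rep(1, 5), 2), "identical")
  expect_equal(gs, rep(1L, 5))
  expect_error(equal_size_groups(1:3, 5), "at least")
})

test_that("group trend recovers monotone O/E with the rank-formula oracle", {
  up <- data.frame(group = 1:6, n_sites = 1000, n_A = 50, n_B = 40,
                   n_co = c(2, 3, 4, 6, 8, 11))
  tr <- group_oe_trend(up)
  expect_equal(tr$rho, 1)
  expect_lt(tr$p_value, 0.05)
  down <- up; down$n_co <- rev(up$n_co)
  expect_equal(group_oe_trend(down)$rho, -1)
  expect_equal(group_oe_trend(down, alternative = "less")$rho, -1)
  # oracle: Spearman rho = 1 - 6*sum(d^2)/(n(n^2-1)) on untied toy data
  toy <- data.frame(group = 1:5, n_sites = 1000, n_A = 50, n_B = 40,
                    n_co = c(4, 2, 7, 3, 9))
  r <- group_oe_trend(toy, alternative = "two.sided")
  d2 <- sum((rank(toy$group) - rank(cosnp_oe(toy)))^2)
  expect_equal(r$rho, 1 - 6 * d2 / (5 * 24))
  # groups with an undefined ratio are dropped and counted
  z <- up; z$n_B[2] <- 0
  expect_warning(tz <- group_oe_trend(z), "zero SNP margin")
  expect_equal(tz$dropped_groups, 1)
  expect_equal(nrow(tz$table), 5)
})

test_that("nearest-neighbour matching is deterministic and order-invariant", {
  focal <- data.frame(gene_id = "g1", coord_A = 100L)
  cand <- data.frame(gene_id = rep("g1", 2), coord_A = c(95L, 107L))
  expect_equal(nearest_neighbor_match(focal, cand)$matched_coord_A, 95)
  tie <- data.frame(gene_id = rep("g1", 2), coord_A = c(96L, 104L))
  expect_equal(nearest_neighbor_match(focal, tie)$matched_coord_A, 96)
  expect_equal(nearest_neighbor_match(focal, tie[2:1, ])$matched_coord_A, 96)
  # no candidate in the gene -> focal dropped and counted
  other <- data.frame(gene_id = "g2", coord_A = 5L)
  m <- nearest_neighbor_match(focal, other)
  expect_equal(nrow(m), 0)
  expect_equal(attr(m, "dropped_focal"), 1)
  # order invariance on a random instance
  set.seed(5)
  f2 <- data.frame(gene_id = sample(c("a", "b"), 20, TRUE),
                   coord_A = sample(1000, 20))
  c2 <- data.frame(gene_id = sample(c("a", "b"), 50, TRUE),
                   coord_A = sample(1000, 50))
  m1 <- nearest_neighbor_match(f2, c2)
  m2 <- nearest_neighbor_match(f2, c2[sample(50), ])
  expect_equal(m1, m2)
})

test_that("paired score tests report both variants", {
  set.seed(2)
  x <- rnorm(30); y <- x + 0.5 + rnorm(30, 0, 0.2)
  t1 <- paired_score_test(x, y)
  expect_lt(t1$p_value, 1e-6)
  expect_lt(t1$estimate, 0)
  t2 <- paired_score_test(x, y, method = "wilcoxon")
  expect_lt(t2$p_value, 1e-4)
  expect_error(paired_score_test(1, 2), "pairs")
})

test_that("damaging calls respect the published thresholds exactly", {
  sc <- data.frame(sift = c(0.05, 0.051, 0.01),
                   grantham = c(100, 101, 50),
                   polyphen = c("possibly", "probably", "benign"))
  expect_equal(damaging_call(sc, "sift"), c(TRUE, FALSE, TRUE))
  expect_equal(damaging_call(sc, "grantham"), c(FALSE, TRUE, FALSE))
  expect_equal(damaging_call(sc, "polyphen"), c(TRUE, TRUE, FALSE))
  g1 <- data.frame(sift = c(rep(0.01, 2), rep(0.5, 8)))
  g2 <- data.frame(sift = c(rep(0.01, 6), rep(0.5, 4)))
  df <- damaging_fraction(g1, g2, "sift")
  expect_equal(df$fraction_1, 0.2)
  expect_equal(df$fraction_2, 0.6)
  expect_equal(df$p_value, fisher_p_enum(2, 8, 6, 4), tolerance = 1e-9)
})

test_that("2x2 enrichment and equal-proportions tests match oracles", {
  eq <- two_by_two_enrichment(10, 90, 10, 90)
  expect_equal(eq$odds_ratio, 1)
  r <- two_by_two_enrichment(10, 90, 5, 95)
  expect_equal(r$odds_ratio, (10 * 95) / (90 * 5))
  expect_equal(r$p_value, fisher_p_enum(10, 90, 5, 95), tolerance = 1e-9)
  expect_error(two_by_two_enrichment(0, 0, 5, 95), "empty class")
  expect_true(is.na(two_by_two_enrichment(10, 0, 5, 95)$odds_ratio))
  # equal proportions: identical -> statistic 0
  e0 <- equal_proportions_test(c(10, 20, 30), c(100, 200, 300))
  expect_equal(e0$statistic, 0)
  # 3-class formula oracle (pooled-proportion Pearson chi-square)
  s <- c(12, 25, 9); t <- c(80, 120, 50)
  p_pool <- sum(s) / sum(t)
  stat <- sum((s - t * p_pool)^2 / (t * p_pool) +
              ((t - s) - t * (1 - p_pool))^2 / (t * (1 - p_pool)))
  e1 <- equal_proportions_test(s, t)
  expect_equal(e1$statistic, stat, tolerance = 1e-12)
  expect_equal(e1$df, 2)
  # two classes reduce to the 2x2 chi-square
  e2 <- equal_proportions_test(c(8, 32), c(50, 950))
  c2 <- suppressWarnings(
    chisq_independence(data.frame(n_sites = 1000, n_A = 50, n_B = 40,
                                  n_co = 8)))
  expect_equal(e2$statistic, c2$statistic, tolerance = 1e-12)
})
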