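# Synthetic-data generators: structural validity, format round-trips, and
# quick versions of the planted-mechanism closed forms (the full-size checks
# live in the acceptance suite).

test_that("generated genomes are frame-correct, stop-free and divergence-0 works", {
  spec <- synthetic_spec(n_genes = 40, codons_per_gene = 60, divergence = 0)
  g <- gen_ortholog_genome(spec, seed = 2)
  expect_true(all((g$map$end_A - g$map$start_A) ==
                  (g$map$end_B - g$map$start_B)))
  sites <- build_site_table(g$map, g$genome_A, g$genome_B)
  expect_length(attr(sites, "skipped_genes"), 0)  # no stop / frame failure
  expect_equal(nrow(sites), 40 * 60 * 3)
  expect_identical(sites$ref_A, sites$ref_B)      # divergence 0
  expect_true(any(table(g$map$gene_id) == 2))     # some genes split in blocks
  expect_true(any(g$map$strand_A == "-"))
  g0 <- gen_ortholog_genome(synthetic_spec(n_genes = 0))
  expect_equal(nrow(g0$map), 0)
})

test_that("divergence produces mismatches at roughly the requested rate", {
  spec <- synthetic_spec(n_genes = 60, codons_per_gene = 80, divergence = 0.02)
  g <- gen_ortholog_genome(spec, seed = 3)
  sites <- build_site_table(g$map, g$genome_A, g$genome_B)
  rate <- mean(sites$ref_A != sites$ref_B)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.03)
})

test_that("a full synthetic dataset round-trips through the file formats", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_genes = 30, codons_per_gene = 50)
  write_synthetic_dataset(dir, spec, seed = 11)
  genome_A <- Biostrings::readDNAStringSet(file.path(dir, "genome_A.fa"))
  genome_B <- Biostrings::readDNAStringSet(file.path(dir, "genome_B.fa"))
  map <- read_orthology_map(file.path(dir, "orthology_map.tsv"))
  va <- read_snp_vcf(file.path(dir, "snps_A.vcf"))
  vb <- read_snp_vcf(file.path(dir, "snps_B.vcf"))
  sites <- build_site_table(map, genome_A, genome_B)
  cl <- classify_sites(sites, va, vb)
  # every written variant lands on a known site with a matching reference
  expect_equal(sum(cl$snp_A), nrow(va))
  expect_equal(sum(cl$snp_B), nrow(vb))
  # regenerating in memory with the same seed gives the same counts
  set.seed(11)
  g <- gen_ortholog_genome(spec)
  sites2 <- build_site_table(g$map, g$genome_A, g$genome_B)
  vs <- gen_snp_sets(sites2, g$genes, spec)
  cl2 <- classify_sites(sites2, vs$variants_A, vs$variants_B)
  expect_equal(cosnp_counts(cl), cosnp_counts(cl2))
})

test_that("pure independence settings give O/E near 1 downstream", {
  spec <- synthetic_spec(n_genes = 150, codons_per_gene = 120, rate_cv = 0,
                         tolerant_fraction = rep(1, 5),
                         shared_ancestral_fraction = 0,
                         target_snp_density = c(A = 0.03, B = 0.03))
  set.seed(17)
  g <- gen_ortholog_genome(spec)
  sites <- build_site_table(g$map, g$genome_A, g$genome_B)
  oe <- sapply(1:8, function(i) {
    vs <- gen_snp_sets(sites, g$genes, spec)
    cl <- classify_sites(sites, vs$variants_A, vs$variants_B)
    cosnp_oe(cosnp_counts(cl))
  })
  se <- sd(oe) / sqrt(length(oe))
  expect_lt(abs(mean(oe) - 1), 4 * se + 0.02)
})

test_that("identical-allele sharing follows the configured fraction", {
  spec <- synthetic_spec(n_genes = 150, codons_per_gene = 120,
                         divergence = 0, rate_cv = 0,
                         tolerant_fraction = rep(1, 5),
                         shared_ancestral_fraction = 1,
                         target_snp_density = c(A = 0.1, B = 0.1))
  set.seed(23)
  g <- gen_ortholog_genome(spec)
  sites <- build_site_table(g$map, g$genome_A, g$genome_B)
  vs <- gen_snp_sets(sites, g$genes, spec)
  cl <- classify_sites(sites, vs$variants_A, vs$variants_B)
  co <- !is.na(cl$class) & cl$class == "coSNP"
  expect_gt(sum(co), 50)
  expect_true(all(cl$pair_A[co] == cl$pair_B[co]))
  po <- pattern_oe(cl)
  expect_gt(mean(po$same_allele, na.rm = TRUE), 1)  # diagonal enriched
})

test_that("genotype panels and window haplotypes are structurally sound", {
  p <- gen_genotype_panel(20, 500, seed = 4)
  expect_equal(dim(p$genotypes), c(500, 20))
  expect_true(all(p$genotypes %in% 0:2))
  expect_true(all(p$freq > 0 & p$freq <= 0.5))
  for (m in c("neutral", "uniform", "beta")) {
    q <- gen_genotype_panel(10, 200, maf_model = m, seed = 1)$freq
    expect_true(all(q > 0 & q <= 0.5))
  }
  h <- gen_window_haplotypes(4, n_haplotypes = 12, theta = 8, seed = 9)
  expect_length(h, 4)
  expect_true(all(vapply(h, nrow, 1L) == 12))
  d <- suppressWarnings(vapply(h, tajimas_d, numeric(1)))
  expect_true(all(is.finite(d) | is.na(d)))
})

test_that("null annotation settings carry no planted signal", {
  spec <- synthetic_spec(n_genes = 80, codons_per_gene = 60,
                         conservation_shift = 0, damaging_diff = 0,
                         label_enrichment = c(gwas = 1, disease = 1,
                                              essential = 1, housekeeping = 1),
                         target_snp_density = c(A = 0.08, B = 0.08))
  set.seed(29)
  g <- gen_ortholog_genome(spec)
  sites <- build_site_table(g$map, g$genome_A, g$genome_B)
  vs <- gen_snp_sets(sites, g$genes, spec)
  cl <- classify_sites(sites, vs$variants_A, vs$variants_B)
  ann <- gen_annotations(cl, g$genes, spec)
  co <- ann$gwas_sites$cosnp
  fe <- two_by_two_enrichment(sum(ann$gwas_sites$gwas[co]), sum(co) - sum(ann$gwas_sites$gwas[co]),
                              sum(ann$gwas_sites$gwas[!co]), sum(!co) - sum(ann$gwas_sites$gwas[!co]))
  expect_gt(fe$p_value, 0.001)
  dmg <- damaging_fraction(ann$impact_scores[ann$impact_scores$cosnp, ],
                           ann$impact_scores[!ann$impact_scores$cosnp, ],
                           "sift")
  expect_gt(dmg$p_value, 0.001)
})
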