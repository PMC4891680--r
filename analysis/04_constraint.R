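#!/usr/bin/env Rscript
# Step 4 — selective constraint and functional comparisons.
#
# (i) Bins genes into equal-size groups by exon conservation (PhastCons-like)
#     and by gene dN/dS and tests the Spearman trend of zero-fold coSNP O/E
#     against constraint — the planted tolerant-fraction mechanism predicts a
#     positive trend at zero-fold sites and none at four-fold sites.
# (ii) Pairs each zero-fold coSNP with its nearest same-gene zero-fold
#      non-coSNP/nonSNP and compares conservation scores (paired t-test).
# (iii) Compares damaging fractions (SIFT/Grantham/PolyPhen-2 rules) of
#      coSNPs vs non-coSNPs, GWAS-site enrichment, gene-label enrichment and
#      the dN/dS of genes with vs without zero-fold coSNPs.

library(cosnpr)

dataset_dir <- "scratch/dataset"
genome_A <- Biostrings::readDNAStringSet(file.path(dataset_dir, "genome_A.fa"))
genome_B <- Biostrings::readDNAStringSet(file.path(dataset_dir, "genome_B.fa"))
map <- read_orthology_map(file.path(dataset_dir, "orthology_map.tsv"))
sites <- build_site_table(map, genome_A, genome_B)
cl <- classify_sites(sites,
                     read_snp_vcf(file.path(dataset_dir, "snps_A.vcf")),
                     read_snp_vcf(file.path(dataset_dir, "snps_B.vcf")))
exon <- read.delim(file.path(dataset_dir, "exon_scores.tsv"))
genes <- read.delim(file.path(dataset_dir, "gene_scores.tsv"))
site_scores <- read.delim(file.path(dataset_dir, "site_scores.tsv"))
impact <- read.delim(file.path(dataset_dir, "impact_scores.tsv"))
gwas <- read.delim(file.path(dataset_dir, "gwas_sites.tsv"))

# (i) constraint-binned O/E trends, per degeneracy class
bin_trend <- function(score_by_gene, label, k = 5, higher_is_constrained = TRUE) {
  grp <- equal_size_groups(if (higher_is_constrained) score_by_gene$score
                           else -score_by_gene$score, k)
  gmap <- setNames(grp, score_by_gene$gene_id)
  out <- NULL
  for (cls in c("zero", "two_three", "four")) {
    d <- cl[cl$degeneracy == cls, ]
    d$group <- gmap[d$gene_id]
    cnt <- cosnp_counts(d[!is.na(d$group), ], by = "group",
                        exclude_cpg = "either")
    cnt$group <- as.integer(cnt$group)
    tr <- tryCatch(group_oe_trend(cnt, alternative = "greater"),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr)) next
    out <- rbind(out, cbind(constraint = label, degeneracy = cls, tr$table,
                            rho = tr$rho, p_one_tailed = tr$p_value))
  }
  out
}
trend <- rbind(
  bin_trend(data.frame(gene_id = exon$gene_id, score = exon$phastcons),
            "phastcons"),
  bin_trend(data.frame(gene_id = genes$gene_id, score = genes$dn_ds),
            "dn_ds", higher_is_constrained = FALSE))
write.table(trend, "results/04_constraint_trend.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Spearman trend of coSNP O/E vs constraint rank (one-tailed):\n")
print(unique(trend[, c("constraint", "degeneracy", "rho", "p_one_tailed")]),
      row.names = FALSE)

# (ii) nearest-neighbour conservation comparison at zero-fold sites
zs <- cl[cl$degeneracy == "zero" & !is.na(cl$class), ]
focal <- zs[zs$class == "coSNP", c("gene_id", "coord_A")]
score_of <- function(coord) site_scores$phylop[match(coord, site_scores$coord_A)]
nn <- NULL
for (other in c("nonco_A_only", "nonco_B_only", "nonSNP")) {
  cand <- zs[zs$class == other, c("gene_id", "coord_A")]
  pairs <- nearest_neighbor_match(focal, cand)
  if (nrow(pairs) < 3) next
  pt <- paired_score_test(score_of(pairs$coord_A),
                          score_of(pairs$matched_coord_A))
  nn <- rbind(nn, data.frame(comparison = other, n_pairs = pt$n_pairs,
                             mean_diff = pt$estimate, p_value = pt$p_value))
}
write.table(nn, "results/04_nearest_neighbor.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nConservation of zero-fold coSNPs vs matched neighbours (paired t):\n")
print(nn, row.names = FALSE)

# (iii) damaging fractions, GWAS and gene-label enrichment, dN/dS contrast
dmg <- do.call(rbind, lapply(c("sift", "grantham", "polyphen"), function(m)
  damaging_fraction(impact[impact$cosnp, ], impact[!impact$cosnp, ], m)))
write.table(dmg, "results/04_damaging.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nDamaging fractions, coSNP vs non-coSNP (zero-fold, nonsynonymous):\n")
print(dmg, row.names = FALSE)

gz <- gwas[gwas$degeneracy == "zero", ]
gw <- two_by_two_enrichment(sum(gz$gwas[gz$cosnp]), sum(gz$cosnp) - sum(gz$gwas[gz$cosnp]),
                            sum(gz$gwas[!gz$cosnp]), sum(!gz$cosnp) - sum(gz$gwas[!gz$cosnp]))
labels <- do.call(rbind, lapply(c("disease", "essential", "housekeeping"),
  function(lab) {
    y <- genes[[lab]]; g <- genes$has_cosnp_i0
    cbind(label = lab,
          two_by_two_enrichment(sum(y[g]), sum(g) - sum(y[g]),
                                sum(y[!g]), sum(!g) - sum(y[!g])))
  }))
dnds_p <- wilcox.test(genes$dn_ds[genes$has_cosnp_i0],
                      genes$dn_ds[!genes$has_cosnp_i0])$p.value
enr <- rbind(cbind(label = "gwas_site_zero_fold", gw), labels)
write.table(cbind(enr, dnds_wilcox_p = dnds_p), "results/04_enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nEnrichment (odds ratio, Fisher two-tailed p):\n")
print(enr, row.names = FALSE)
cat(sprintf("dN/dS, genes with vs without zero-fold coSNPs: Wilcoxon p = %.3g\n",
            dnds_p))
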