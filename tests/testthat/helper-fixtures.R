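# Shared in-code fixtures: tiny deterministic genomes, site tables and count
# tables used across test files. Everything is built programmatically.

# A one-gene genome pair: CDS `cds` embedded in `pad` bases of flanking
# sequence on both sides, identical in the two species unless `cds_B` given.
toy_gene_genome <- function(cds, strand_A = "+", strand_B = strand_A,
                            pad = 4, cds_B = cds) {
  stopifnot(nchar(cds) %% 3 == 0)
  left <- paste(rep("T", pad), collapse = "")
  right <- paste(rep("A", pad), collapse = "")
  emb <- function(s, strand) {
    body <- if (strand == "-") cosnpr:::.revcomp_chr(s) else s
    paste0(left, body, right)
  }
  map <- data.frame(gene_id = "g1",
                    chrom_A = "chrA", start_A = pad,
                    end_A = pad + nchar(cds), strand_A = strand_A,
                    chrom_B = "chrB", start_B = pad,
                    end_B = pad + nchar(cds_B), strand_B = strand_B,
                    stringsAsFactors = FALSE)
  list(map = map,
       genome_A = Biostrings::DNAStringSet(c(chrA = emb(cds, strand_A))),
       genome_B = Biostrings::DNAStringSet(c(chrB = emb(cds_B, strand_B))))
}

# A bare classified-site scaffold for count/statistics tests: n sites of one
# gene on the plus strand with the given polymorphism flags.
toy_classified <- function(snp_A, snp_B, degeneracy = "zero",
                           pair_A = "A/C", pair_B = "A/C",
                           maf_A = 0.1, maf_B = 0.1) {
  n <- length(snp_A)
  cls <- ifelse(snp_A & snp_B, "coSNP",
         ifelse(snp_A, "nonco_A_only",
         ifelse(snp_B, "nonco_B_only", "nonSNP")))
  data.frame(gene_id = "g1", codon_index = 0L, codon_pos = 0L,
             chrom_A = "chrA", coord_A = seq_len(n) - 1L, strand_A = "+",
             ref_A = "A", chrom_B = "chrB", coord_B = seq_len(n) - 1L,
             strand_B = "+", ref_B = "A",
             degeneracy = rep_len(degeneracy, n),
             cpg_A = FALSE, cpg_B = FALSE, masked = FALSE,
             snp_A = snp_A, maf_A = ifelse(snp_A, maf_A, NA_real_),
             pair_A = ifelse(snp_A, rep_len(pair_A, n), NA_character_),
             snp_B = snp_B, maf_B = ifelse(snp_B, maf_B, NA_real_),
             pair_B = ifelse(snp_B, rep_len(pair_B, n), NA_character_),
             class = factor(cls, levels = cosnpr:::.CLASS_LEVELS),
             stringsAsFactors = FALSE)
}

# Exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration,
# independent of stats::fisher.test.
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
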