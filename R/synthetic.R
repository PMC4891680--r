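# Synthetic-data generation: orthologous coding genomes, SNP sets with the
# mechanism knobs the analysis is designed to detect (per-site mutation-rate
# heterogeneity, constrained-site masks, shared ancestral polymorphism,
# configurable MAF spectra), and correlated annotation tables. Every stage of
# the pipeline can run from these outputs with no external download.

#' Specification of the synthetic study conditions
#'
#' Defaults emulate a human/chimpanzee-like coding comparison: ~1% coding
#' divergence, SNP densities of 3% (species A, a large human-like panel) and
#' 1% (species B, a small chimp-like panel), a gamma mutation-rate field with
#' CV^2 = 1 shared by the two species, five constraint tiers whose tolerant
#' fraction at zero-fold sites falls from 1 to 0.2, a 20% identical-allele
#' share among planted coSNPs, a folded neutral MAF spectrum with a flatter
#' mixture for coSNPs, and a transition fraction matching Ts/Tv = 2.7.
#'
#' @param n_genes number of orthologous genes.
#' @param codons_per_gene codons per gene.
#' @param divergence per-site substitution probability between the two
#'   reference sequences.
#' @param intergenic mean intergenic gap in bp.
#' @param rate_cv coefficient of variation of the shared gamma per-site
#'   mutation-rate field (mean 1); 0 disables heterogeneity.
#' @param n_constraint_tiers number of gene constraint tiers.
#' @param tolerant_fraction per-tier fraction of zero-fold sites tolerant of
#'   mutation (length n_constraint_tiers; tier 1 = weakest constraint).
#' @param shared_ancestral_fraction probability that a coSNP is planted with
#'   the identical allele pair in both species.
#' @param target_snp_density named per-species SNP density c(A = , B = ).
#' @param maf_model "neutral" (folded density proportional to 1/x,
#'   discretised on `maf_n_chrom` chromosomes), "uniform", or "beta"
#'   (0.5 * Beta(beta_shape)).
#' @param maf_n_chrom chromosomes for the discretised neutral spectrum.
#' @param beta_shape shape parameters for the beta MAF model.
#' @param cosnp_flat_weight weight of the uniform mixture component used for
#'   coSNP MAFs (emulates their flatter folded spectrum).
#' @param ts_prob probability a new allele is a transition (0.73 matches
#'   Ts/Tv = 2.7).
#' @param conservation_shift planted drop in per-site conservation score at
#'   coSNP sites, in units of the score noise SD.
#' @param damaging_diff planted drop in damaging probability for coSNPs
#'   relative to non-coSNPs at zero-fold sites.
#' @param label_enrichment named odds multipliers for site/gene labels of
#'   coSNP-carrying sites/genes (gwas, disease, essential, housekeeping).
#' @return a "synthetic_spec" list.
#' @export
synthetic_spec <- function(n_genes = 500, codons_per_gene = 160,
                           divergence = 0.01, intergenic = 1520,
                           rate_cv = 1, n_constraint_tiers = 5,
                           tolerant_fraction = seq(1, 0.2,
                             length.out = n_constraint_tiers),
                           shared_ancestral_fraction = 0.2,
                           target_snp_density = c(A = 0.03, B = 0.01),
                           maf_model = c("neutral", "uniform", "beta"),
                           maf_n_chrom = 200, beta_shape = c(0.5, 1),
                           cosnp_flat_weight = 0.3, ts_prob = 0.73,
                           conservation_shift = 0.5, damaging_diff = 0.15,
                           label_enrichment = c(gwas = 2, disease = 1.5,
                                                essential = 0.6,
                                                housekeeping = 0.7)) {
  maf_model <- match.arg(maf_model)
  stopifnot(length(tolerant_fraction) == n_constraint_tiers,
            all(tolerant_fraction > 0), all(tolerant_fraction <= 1),
            shared_ancestral_fraction >= 0, shared_ancestral_fraction <= 1,
            all(target_snp_density > 0), rate_cv >= 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

.sense_codons <- function(genetic_code = Biostrings::GENETIC_CODE) {
  names(genetic_code)[genetic_code != "*"]
}

.rand_seq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

#' Generate an orthologous genome pair with gene models
#'
#' Genes are random sense-codon sequences (stop-free by construction);
#' species B is derived from species A by per-site substitution at the
#' specified divergence, resampling any substitution that would create an
#' internal stop. Genes are laid out on one chromosome per species with
#' random intergenic spacers and random strands (some genes change strand
#' between the species), and long genes are split into two colinear blocks,
#' exercising the multi-block orthology-map path.
#'
#' @param spec a [synthetic_spec()].
#' @param seed optional RNG seed.
#' @return list with genome_A, genome_B (DNAStringSet), map (orthology block
#'   data.frame) and genes (gene_id, tier, n_codons).
#' @export
gen_ortholog_genome <- function(spec = synthetic_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_genes
  if (n == 0) {
    return(list(genome_A = Biostrings::DNAStringSet(c(chrA = "ACGT")),
                genome_B = Biostrings::DNAStringSet(c(chrB = "ACGT")),
                map = .empty_map(),
                genes = data.frame(gene_id = character(0), tier = integer(0),
                                   n_codons = integer(0))))
  }
  sense <- .sense_codons()
  gene_id <- sprintf("g%04d", seq_len(n))
  n_cod <- rep(spec$codons_per_gene, n)
  cds_A <- vapply(n_cod, function(k)
    paste(sample(sense, k, replace = TRUE), collapse = ""), character(1))
  cds_B <- vapply(cds_A, .diverge_cds, character(1),
                  divergence = spec$divergence, USE.NAMES = FALSE)
  strand_A <- sample(c("+", "-"), n, replace = TRUE)
  flip <- runif(n) < 0.1
  strand_B <- ifelse(flip, ifelse(strand_A == "+", "-", "+"), strand_A)
  lay_A <- .layout(cds_A, strand_A, spec$intergenic)
  lay_B <- .layout(cds_B, strand_B, spec$intergenic)
  # one or two colinear blocks per gene (split at a random codon boundary)
  len <- n_cod * 3L
  do_split <- n_cod >= 20 & runif(n) < 0.3
  split_at <- ifelse(do_split, 3L * floor(runif(n, 1, n_cod)), 0L)
  rows <- lapply(seq_len(n), function(i) {
    g <- data.frame(gene_id = gene_id[i],
                    chrom_A = "chrA", chrom_B = "chrB",
                    strand_A = strand_A[i], strand_B = strand_B[i],
                    stringsAsFactors = FALSE)
    m <- split_at[i]
    if (m <= 0 || m >= len[i]) {
      cbind(g, .block_span(lay_A$start[i], len[i], strand_A[i], 0L, len[i], "A"),
            .block_span(lay_B$start[i], len[i], strand_B[i], 0L, len[i], "B"))
    } else {
      rbind(
        cbind(g, .block_span(lay_A$start[i], len[i], strand_A[i], 0L, m, "A"),
              .block_span(lay_B$start[i], len[i], strand_B[i], 0L, m, "B")),
        cbind(g, .block_span(lay_A$start[i], len[i], strand_A[i], m, len[i], "A"),
              .block_span(lay_B$start[i], len[i], strand_B[i], m, len[i], "B")))
    }
  })
  map <- do.call(rbind, rows)
  map <- map[, .ORTHOLOGY_COLS]
  list(genome_A = Biostrings::DNAStringSet(c(chrA = lay_A$seq)),
       genome_B = Biostrings::DNAStringSet(c(chrB = lay_B$seq)),
       map = validate_orthology_map(map),
       genes = data.frame(gene_id = gene_id,
                          tier = sample.int(spec$n_constraint_tiers, n,
                                            replace = TRUE),
                          n_codons = n_cod, stringsAsFactors = FALSE))
}

.empty_map <- function() {
  x <- data.frame(gene_id = character(0), chrom_A = character(0),
                  start_A = integer(0), end_A = integer(0),
                  strand_A = character(0), chrom_B = character(0),
                  start_B = integer(0), end_B = integer(0),
                  strand_B = character(0))
  x
}

# genomic span of CDS interval [from, to) for a gene occupying
# [gstart, gstart + len) on the given strand
.block_span <- function(gstart, len, strand, from, to, sp) {
  if (strand == "+") {
    s <- gstart + from; e <- gstart + to
  } else {
    s <- gstart + len - to; e <- gstart + len - from
  }
  out <- data.frame(s, e)
  names(out) <- paste0(c("start_", "end_"), sp)
  out
}

.layout <- function(cds, strand, intergenic) {
  n <- length(cds)
  gaps <- pmax(10L, as.integer(round(runif(n + 1, 0.5, 1.5) * intergenic)))
  segs <- character(2 * n + 1)
  start <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    segs[2 * i - 1] <- .rand_seq(gaps[i])
    pos <- pos + gaps[i]
    start[i] <- pos
    g <- if (strand[i] == "-") .revcomp_chr(cds[i]) else cds[i]
    segs[2 * i] <- g
    pos <- pos + nchar(cds[i])
  }
  segs[2 * n + 1] <- .rand_seq(gaps[n + 1])
  list(seq = paste(segs, collapse = ""), start = start)
}

.diverge_cds <- function(cds, divergence) {
  ch <- strsplit(cds, "")[[1]]
  n <- length(ch)
  hit <- which(runif(n) < divergence)
  if (!length(hit)) return(cds)
  ch[hit] <- vapply(ch[hit], function(b) sample(.BASES[.BASES != b], 1),
                    character(1))
  # resample substitutions that created a stop codon (revert to original)
  code <- Biostrings::GENETIC_CODE
  orig <- strsplit(cds, "")[[1]]
  repeat {
    codons <- vapply(seq_len(n / 3), function(i)
      paste(ch[(3 * i - 2):(3 * i)], collapse = ""), character(1))
    bad <- which(code[codons] == "*")
    if (!length(bad)) break
    for (i in bad) ch[(3 * i - 2):(3 * i)] <- orig[(3 * i - 2):(3 * i)]
  }
  paste(ch, collapse = "")
}

.draw_maf <- function(n, spec, flat = FALSE) {
  if (!n) return(numeric(0))
  flat_draw <- flat & runif(n) < spec$cosnp_flat_weight
  m <- spec$maf_n_chrom
  base <- switch(spec$maf_model,
    neutral = {
      j <- seq_len(m %/% 2)
      w <- 1 / j + 1 / (m - j)
      sample(j, n, replace = TRUE, prob = w) / m
    },
    uniform = runif(n, 1 / m, 0.5),
    beta = pmax(1 / m, 0.5 * rbeta(n, spec$beta_shape[1], spec$beta_shape[2])))
  base[flat_draw] <- runif(sum(flat_draw), 1 / m, 0.5)
  base
}

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

.draw_alt <- function(ref, ts_prob) {
  n <- length(ref)
  ts <- runif(n) < ts_prob
  alt <- .TRANSITION[ref]
  tv <- !ts
  if (any(tv)) {
    alt[tv] <- vapply(ref[tv], function(b) {
      sample(setdiff(.BASES, c(b, .TRANSITION[[b]])), 1)
    }, character(1))
  }
  alt
}

#' Generate per-species SNP sets over a site table
#'
#' Per-site hit probabilities are proportional to a gamma rate field shared
#' by the two species (mean 1, CV = rate_cv) times a tolerance indicator:
#' zero-fold sites of a gene in constraint tier t are mutable only with
#' probability tolerant_fraction[t] (the tolerant subset is a property of
#' the site, shared by both species); all other sites are always mutable.
#' Probabilities are normalised so each species hits its target density over
#' eligible sites. Hits are drawn independently per species; at sites hit in
#' both, the species-B allele pair is forced identical to A's with
#' probability shared_ancestral_fraction (emulating shared ancestral
#' polymorphism). MAFs follow the spec's model, with a flatter uniform
#' mixture for coSNPs. Under these mechanisms the expected coSNP O/E in a
#' stratum with tolerant fraction f is (1 + CV^2)/f.
#'
#' @param sites site table from [build_site_table()].
#' @param genes gene table with gene_id and tier (from
#'   [gen_ortholog_genome()]).
#' @param spec a [synthetic_spec()].
#' @param seed optional RNG seed.
#' @return list with variants_A and variants_B (genome-strand data.frames
#'   accepted by [classify_sites()] or [write_snp_vcf()]).
#' @export
gen_snp_sets <- function(sites, genes, spec = synthetic_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eligible <- !sites$masked & sites$degeneracy != "ambiguous"
  n <- nrow(sites)
  rate <- if (spec$rate_cv > 0) {
    shape <- 1 / spec$rate_cv^2
    rgamma(n, shape = shape, rate = shape)
  } else rep(1, n)
  tier <- genes$tier[match(sites$gene_id, genes$gene_id)]
  f <- spec$tolerant_fraction[tier]
  tol <- ifelse(sites$degeneracy == "zero", runif(n) < f, TRUE)
  w <- rate * tol * eligible
  if (!any(w > 0)) stop("no mutable site: requested density unreachable")
  w_mean <- mean(w[eligible])
  p_A <- pmin(spec$target_snp_density[["A"]] * w / w_mean, 0.5)
  p_B <- pmin(spec$target_snp_density[["B"]] * w / w_mean, 0.5)
  hit_A <- runif(n) < p_A
  hit_B <- runif(n) < p_B
  co <- hit_A & hit_B
  alt_A <- rep(NA_character_, n)
  alt_B <- rep(NA_character_, n)
  alt_A[hit_A] <- .draw_alt(sites$ref_A[hit_A], spec$ts_prob)
  alt_B[hit_B] <- .draw_alt(sites$ref_B[hit_B], spec$ts_prob)
  share <- co & runif(n) < spec$shared_ancestral_fraction &
    sites$ref_A == sites$ref_B
  alt_B[share] <- alt_A[share]
  maf_A <- rep(NA_real_, n)
  maf_B <- rep(NA_real_, n)
  maf_A[hit_A] <- .draw_maf(sum(hit_A), spec, flat = co[hit_A])
  maf_B[hit_B] <- .draw_maf(sum(hit_B), spec, flat = co[hit_B])
  to_genome <- function(which_hit, sp, alt, maf) {
    i <- which(which_hit)
    strand <- sites[[paste0("strand_", sp)]][i]
    minus <- strand == "-"
    ref_c <- sites[[paste0("ref_", sp)]][i]
    alt_c <- alt[i]
    data.frame(chrom = sites[[paste0("chrom_", sp)]][i],
               pos = sites[[paste0("coord_", sp)]][i],
               ref = ifelse(minus, .comp[ref_c], ref_c),
               alt = ifelse(minus, .comp[alt_c], alt_c),
               maf = maf[i], stringsAsFactors = FALSE)
  }
  list(variants_A = to_genome(hit_A, "A", alt_A, maf_A),
       variants_B = to_genome(hit_B, "B", alt_B, maf_B))
}

.logistic <- function(x) 1 / (1 + exp(-x))

#' Generate annotation tables correlated with the planted structure
#'
#' Emulates the external annotations the real analysis consumes. Planted
#' directions: exon conservation and gene dN/dS track the constraint tier
#' (higher tier = more conserved, lower dN/dS); per-site conservation scores
#' are lower by `conservation_shift` noise-SDs at coSNP sites; the damaging
#' probability of nonsynonymous variants is lower by `damaging_diff` at
#' coSNPs; GWAS site labels and gene disease/essential/housekeeping labels
#' follow the configured enrichment odds for coSNP-carrying sites/genes.
#' Setting all effects to zero (and odds to 1) yields null annotations for
#' calibration checks.
#'
#' @param classified classified site table from [classify_sites()].
#' @param genes gene table with gene_id and tier.
#' @param spec a [synthetic_spec()].
#' @param seed optional RNG seed.
#' @return list with exon_scores, gene_scores, site_scores, impact_scores,
#'   gwas_sites and recomb_map data.frames.
#' @export
gen_annotations <- function(classified, genes, spec = synthetic_spec(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Tn <- spec$n_constraint_tiers
  tier_frac <- if (Tn > 1) (genes$tier - 1) / (Tn - 1) else rep(0.5, nrow(genes))
  exon_scores <- data.frame(
    exon_id = genes$gene_id, gene_id = genes$gene_id,
    phastcons = pmin(1, pmax(0, 0.25 + 0.55 * tier_frac +
                               rnorm(nrow(genes), 0, 0.08))))
  zero_co <- classified$degeneracy == "zero" & !is.na(classified$class) &
    classified$class == "coSNP"
  has_i0 <- tapply(zero_co, classified$gene_id, any)
  gene_scores <- data.frame(
    gene_id = genes$gene_id,
    tier = genes$tier,
    dn_ds = exp(rnorm(nrow(genes), log(0.6) - 1.2 * tier_frac, 0.35)),
    has_cosnp_i0 = as.logical(has_i0[genes$gene_id]))
  gene_scores$has_cosnp_i0[is.na(gene_scores$has_cosnp_i0)] <- FALSE
  odds <- spec$label_enrichment
  base_lo <- c(disease = -1.4, essential = -2.2, housekeeping = -1.7)
  for (lab in names(base_lo)) {
    lo <- base_lo[[lab]] + log(odds[[lab]]) * gene_scores$has_cosnp_i0
    gene_scores[[lab]] <- runif(nrow(gene_scores)) < .logistic(lo)
  }
  # per-site conservation at examined sites (phyloP- and GERP-like scales)
  ex <- classified[!classified$masked & classified$degeneracy != "ambiguous", ,
                   drop = FALSE]
  site_tier <- tier_frac[match(ex$gene_id, genes$gene_id)]
  is_co <- !is.na(ex$class) & ex$class == "coSNP"
  mu_site <- 1.5 * site_tier + 0.8 * (ex$degeneracy == "zero") -
    spec$conservation_shift * is_co
  site_scores <- data.frame(
    gene_id = ex$gene_id, chrom_A = ex$chrom_A, coord_A = ex$coord_A,
    phylop = mu_site + rnorm(nrow(ex)),
    gerp = 2 * (mu_site + rnorm(nrow(ex))))
  # impact scores for nonsynonymous (zero-fold) species-A SNPs
  ns <- ex[ex$degeneracy == "zero" & ex$snp_A, , drop = FALSE]
  ns_co <- !is.na(ns$class) & ns$class == "coSNP"
  p_dam <- 0.45 - spec$damaging_diff * ns_co
  latent <- runif(nrow(ns)) < p_dam
  agree <- function() runif(nrow(ns)) < 0.8
  d_sift <- ifelse(agree(), latent, !latent)
  d_gran <- ifelse(agree(), latent, !latent)
  d_poly <- ifelse(agree(), latent, !latent)
  impact_scores <- data.frame(
    gene_id = ns$gene_id, chrom_A = ns$chrom_A, coord_A = ns$coord_A,
    cosnp = ns_co,
    sift = ifelse(d_sift, runif(nrow(ns), 0, 0.05), runif(nrow(ns), 0.051, 1)),
    grantham = ifelse(d_gran, runif(nrow(ns), 101, 215),
                      runif(nrow(ns), 5, 100)),
    polyphen = ifelse(d_poly, sample(c("possibly", "probably"), nrow(ns),
                                     replace = TRUE), "benign"))
  # GWAS labels over species-A SNP sites
  snp <- ex[ex$snp_A, , drop = FALSE]
  snp_co <- !is.na(snp$class) & snp$class == "coSNP"
  lo <- -4.6 + log(odds[["gwas"]]) * snp_co
  gwas_sites <- data.frame(
    gene_id = snp$gene_id, chrom_A = snp$chrom_A, coord_A = snp$coord_A,
    degeneracy = snp$degeneracy, cosnp = snp_co,
    gwas = runif(nrow(snp)) < .logistic(lo))
  span <- max(classified$coord_A) + 1
  wstart <- seq(0, span - 1, by = 1e6)
  recomb_map <- data.frame(chrom = "chrA", start = wstart,
                           end = pmin(wstart + 1e6, span),
                           rate = rgamma(length(wstart), shape = 4, scale = 0.3))
  list(exon_scores = exon_scores, gene_scores = gene_scores,
       site_scores = site_scores, impact_scores = impact_scores,
       gwas_sites = gwas_sites, recomb_map = recomb_map)
}

#' Simulate a diploid genotype panel for discovery-curve experiments
#'
#' Sites carry a population minor-allele frequency drawn from the chosen
#' spectrum; individuals are Binomial(2, q) genotypes. The default "power"
#' spectrum mixes a rare-variant power-law tail (density proportional to
#' q^(-1-b), b = `discovery_exponent`, down to a low-frequency cutoff) with
#' a small fraction of common variants; in this rare-variant-heavy regime —
#' the rare excess real exome panels show — the number of sites discovered
#' in k individuals grows as k^b, a true power law, which is the regime the
#' log-linear discovery model is designed to extrapolate (the defaults make
#' the expected subsampled discovery curve log-log linear from k = 2 through
#' the full panel). The folded neutral 1/x spectrum instead gives
#' logarithmic growth, and a bounded common-variant ("beta", "uniform")
#' spectrum saturates; a power-law fit extrapolated far beyond the fitted
#' range overshoots both.
#'
#' @param n_individuals panel size.
#' @param n_sites polymorphic site count.
#' @param maf_model "power" (default), "beta", "neutral" or "uniform".
#' @param discovery_exponent b of the power spectrum (0 < b < 1).
#' @param q_min low-frequency cutoff for the power/neutral spectra (default
#'   well below 1/(2 n), so discovery keeps growing through the full panel).
#' @param common_weight fraction of sites drawn from the common component
#'   (uniform on (0.2, 0.5)) of the power spectrum.
#' @param beta_shape beta shape parameters.
#' @param partner_density fraction of sites polymorphic in the fixed partner
#'   species.
#' @param seed optional RNG seed.
#' @return list with genotypes (sites x individuals matrix of 0/1/2),
#'   freq (true site frequencies) and partner_snp (logical).
#' @export
gen_genotype_panel <- function(n_individuals, n_sites,
                               maf_model = c("power", "beta", "neutral",
                                             "uniform"),
                               discovery_exponent = 0.55,
                               q_min = 0.05 / n_individuals,
                               common_weight = 0.05,
                               beta_shape = c(0.5, 1), partner_density = 0.2,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  maf_model <- match.arg(maf_model)
  qmin <- 1 / (2 * n_individuals)
  q <- switch(maf_model,
    power = {
      b <- discovery_exponent
      stopifnot(b > 0, b < 1)
      u <- runif(n_sites)
      # inverse CDF of density ~ q^(-1-b) on (q_min, 0.5]
      qq <- (q_min^(-b) - u * (q_min^(-b) - 0.5^(-b)))^(-1 / b)
      com <- runif(n_sites) < common_weight
      qq[com] <- runif(sum(com), 0.2, 0.5)
      qq
    },
    beta = pmax(qmin, 0.5 * rbeta(n_sites, beta_shape[1], beta_shape[2])),
    neutral = q_min * (0.5 / q_min)^runif(n_sites),
    uniform = runif(n_sites, qmin, 0.5))
  g <- matrix(rbinom(n_sites * n_individuals, 2, rep(q, n_individuals)),
              nrow = n_sites)
  list(genotypes = g, freq = q,
       partner_snp = runif(n_sites) < partner_density)
}

#' Neutral coalescent haplotype matrices for genomic windows
#'
#' One sample of n haplotypes per window from a standard coalescent tree
#' (ape::rcoal) with Poisson mutations placed on branches in proportion to
#' branch length; used to attach self-contained Tajima's D values to window
#' records.
#'
#' @param n_windows number of windows.
#' @param n_haplotypes haplotypes per window.
#' @param theta population-scaled mutation rate per window.
#' @param seed optional RNG seed.
#' @return list of 0/1 haplotype matrices (rows = haplotypes).
#' @export
gen_window_haplotypes <- function(n_windows, n_haplotypes = 20, theta = 10,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_windows), function(w) {
    tr <- ape::rcoal(n_haplotypes)
    tips_below <- .edge_tips(tr)
    n_mut <- rpois(1, theta / 2 * sum(tr$edge.length))
    if (n_mut == 0)
      return(matrix(0L, n_haplotypes, 0))
    edges <- sample.int(nrow(tr$edge), n_mut, replace = TRUE,
                        prob = tr$edge.length)
    m <- matrix(0L, n_haplotypes, n_mut)
    for (j in seq_len(n_mut)) m[tips_below[[edges[j]]], j] <- 1L
    m
  })
}

# tips below each edge of an ape phylo tree
.edge_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  below <- vector("list", max(tree$edge))
  for (i in seq_len(n_tip)) below[[i]] <- i
  # accumulate tips bottom-up: postorder visits descendant edges first
  for (e in ape::postorder(tree)) {
    child <- tree$edge[e, 2]
    parent <- tree$edge[e, 1]
    if (is.null(below[[parent]])) below[[parent]] <- integer(0)
    below[[parent]] <- c(below[[parent]], below[[child]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) below[[tree$edge[e, 2]]])
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits the standard files every pipeline stage consumes: per-species FASTA
#' references, uncompressed VCFs, the TSV orthology map, and the annotation
#' TSVs.
#'
#' @param dir output directory (created if needed).
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed for the whole dataset.
#' @return invisibly, the list of written paths.
#' @export
write_synthetic_dataset <- function(dir, spec = synthetic_spec(), seed = 1) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- gen_ortholog_genome(spec)
  sites <- build_site_table(g$map, g$genome_A, g$genome_B)
  vs <- gen_snp_sets(sites, g$genes, spec)
  cl <- classify_sites(sites, vs$variants_A, vs$variants_B)
  ann <- gen_annotations(cl, g$genes, spec)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(g$genome_A, p("genome_A.fa"))
  Biostrings::writeXStringSet(g$genome_B, p("genome_B.fa"))
  write_orthology_map(g$map, p("orthology_map.tsv"))
  write_snp_vcf(vs$variants_A, p("snps_A.vcf"),
                contigs = setNames(Biostrings::width(g$genome_A),
                                   names(g$genome_A)))
  write_snp_vcf(vs$variants_B, p("snps_B.vcf"),
                contigs = setNames(Biostrings::width(g$genome_B),
                                   names(g$genome_B)))
  for (nm in names(ann))
    utils::write.table(ann[[nm]], p(paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(g$genes, p("genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(dir = dir,
                 files = list.files(dir, full.names = TRUE)))
}
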