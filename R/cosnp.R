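# Core coSNP statistics: site classification, observed/expected coSNP ratio,
# chi-square independence, dimorphic allele-pattern O/E, site frequency
# spectra, and rare-variant comparisons.

#' Dimorphic nucleotide patterns
#' @export
SNP_PATTERNS <- c("A/C", "A/G", "A/T", "C/G", "C/T", "G/T")

.CLASS_LEVELS <- c("coSNP", "nonco_A_only", "nonco_B_only", "nonSNP")

.pair_label <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "/"), paste(b, a, sep = "/"))
}

# Match one species' variants onto the site table; returns per-site snp flag,
# maf and coding-strand allele pair, plus a count of dropped variants.
.match_variants <- function(sites, variants, species) {
  chrom_col <- paste0("chrom_", species)
  coord_col <- paste0("coord_", species)
  strand_col <- paste0("strand_", species)
  ref_col <- paste0("ref_", species)
  skey <- paste(sites[[chrom_col]], sites[[coord_col]])
  vkey <- paste(variants$chrom, variants$pos)
  idx <- match(vkey, skey)
  unknown <- is.na(idx)
  usable <- !unknown
  at_bad <- usable & (sites$masked[idx] | sites$degeneracy[idx] == "ambiguous")
  usable <- usable & !at_bad
  # alleles onto the coding strand
  minus <- usable & sites[[strand_col]][idx] == "-"
  ref_c <- ifelse(minus, .comp[variants$ref], variants$ref)
  alt_c <- ifelse(minus, .comp[variants$alt], variants$alt)
  mismatch <- usable & ref_c != sites[[ref_col]][idx]
  usable <- usable & !mismatch
  dropped <- c(unknown_site = sum(unknown), masked_or_ambiguous = sum(at_bad),
               ref_mismatch = sum(mismatch, na.rm = TRUE))
  n <- nrow(sites)
  snp <- logical(n); maf <- rep(NA_real_, n); pair <- rep(NA_character_, n)
  j <- idx[usable]
  snp[j] <- TRUE
  maf[j] <- variants$maf[usable]
  pair[j] <- .pair_label(ref_c[usable], alt_c[usable])
  list(snp = snp, maf = maf, pair = pair, dropped = dropped)
}

#' Classify orthologous sites by joint polymorphism status
#'
#' Matches each species' biallelic variants onto the site table (converting
#' alleles to the coding strand for minus-strand genes) and assigns every
#' unmasked, unambiguous site one of four classes: coSNP (polymorphic in both
#' species; alleles need not match), nonco_A_only, nonco_B_only, or nonSNP.
#' Variants at unknown, masked or ambiguous sites, or whose reference allele
#' disagrees with the site table, are dropped with a warning and counted in
#' the "dropped_variants" attribute. Sites listed in a variants object's
#' "multiallelic_pos" attribute are masked (they leave the denominator).
#'
#' @param sites site table from [build_site_table()].
#' @param variants_A,variants_B data.frame(chrom, pos, ref, alt, maf) per
#'   species, e.g. from [read_snp_vcf()].
#' @return the site table with columns snp_A, maf_A, pair_A, snp_B, maf_B,
#'   pair_B and class added.
#' @export
classify_sites <- function(sites, variants_A, variants_B) {
  for (sp in c("A", "B")) {
    v <- if (sp == "A") variants_A else variants_B
    multi <- attr(v, "multiallelic_pos")
    if (!is.null(multi) && nrow(multi)) {
      key <- paste(sites[[paste0("chrom_", sp)]], sites[[paste0("coord_", sp)]])
      sites$masked <- sites$masked | key %in% paste(multi$chrom, multi$pos)
    }
  }
  ma <- .match_variants(sites, variants_A, "A")
  mb <- .match_variants(sites, variants_B, "B")
  drops <- rbind(A = ma$dropped, B = mb$dropped)
  if (sum(drops) > 0)
    warning(sum(drops), " variants dropped (unknown site / masked / ref mismatch)")
  sites$snp_A <- ma$snp; sites$maf_A <- ma$maf; sites$pair_A <- ma$pair
  sites$snp_B <- mb$snp; sites$maf_B <- mb$maf; sites$pair_B <- mb$pair
  cls <- ifelse(sites$snp_A & sites$snp_B, "coSNP",
         ifelse(sites$snp_A, "nonco_A_only",
         ifelse(sites$snp_B, "nonco_B_only", "nonSNP")))
  cls[sites$masked | sites$degeneracy == "ambiguous"] <- NA
  sites$class <- factor(cls, levels = .CLASS_LEVELS)
  attr(sites, "dropped_variants") <- drops
  sites
}

# The examined-site filter shared by every denominator: unmasked, unambiguous,
# and optionally CpG-excluded (removing CpG sites from numerator AND
# denominator keeps O and E on the same site universe).
.examined <- function(sites, exclude_cpg) {
  keep <- !sites$masked & sites$degeneracy != "ambiguous"
  switch(exclude_cpg,
         none = keep,
         either = keep & !(sites$cpg_A | sites$cpg_B),
         A = keep & !sites$cpg_A,
         B = keep & !sites$cpg_B,
         both = keep & !(sites$cpg_A & sites$cpg_B),
         stop("unknown exclude_cpg policy: ", exclude_cpg))
}

#' Tally coSNP counts, optionally per stratum
#'
#' @param sites classified site table from [classify_sites()].
#' @param by character vector of stratum columns (e.g. "degeneracy"); NULL
#'   for a single overall stratum.
#' @param exclude_cpg CpG exclusion policy: "none" (default), "either"
#'   (excluded if flagged in either species' reference, the conservative
#'   choice used for the headline analyses), "A", "B", or "both".
#' @return data.frame of stratum labels plus n_sites, n_A, n_B, n_co.
#' @export
cosnp_counts <- function(sites, by = NULL,
                         exclude_cpg = c("none", "either", "A", "B", "both")) {
  exclude_cpg <- match.arg(exclude_cpg)
  keep <- .examined(sites, exclude_cpg)
  d <- sites[keep, , drop = FALSE]
  tally <- function(x) {
    data.frame(n_sites = nrow(x), n_A = sum(x$snp_A), n_B = sum(x$snp_B),
               n_co = sum(x$snp_A & x$snp_B))
  }
  if (is.null(by)) return(tally(d))
  f <- interaction(d[by], drop = TRUE, sep = "\r")
  parts <- split(d, f)
  out <- do.call(rbind, lapply(parts, tally))
  labs <- do.call(rbind, strsplit(names(parts), "\r", fixed = TRUE))
  labs <- as.data.frame(labs, stringsAsFactors = FALSE)
  names(labs) <- by
  out <- cbind(labs, out)
  rownames(out) <- NULL
  out
}

#' Observed-to-expected coSNP ratio
#'
#' coSNP_O/E = (n_co/n_sites) / ((n_A/n_sites)(n_B/n_sites))
#'           = n_co * n_sites / (n_A * n_B).
#' Equals 1 when SNPs are placed independently at random in the two species.
#'
#' @param n_sites examined orthologous sites (or a CoSNP-count data.frame
#'   with columns n_sites, n_A, n_B, n_co, in which case the other arguments
#'   are ignored).
#' @param n_A,n_B sites polymorphic in species A / B.
#' @param n_co sites polymorphic in both.
#' @param strict if TRUE (default) a zero margin is an error; if FALSE the
#'   ratio is NA for such entries.
#' @return numeric vector of ratios.
#' @examples
#' cosnp_oe(100, 10, 10, 1)    # 1
#' cosnp_oe(1000, 50, 40, 8)   # 4
#' @export
cosnp_oe <- function(n_sites, n_A, n_B, n_co, strict = TRUE) {
  if (is.data.frame(n_sites)) {
    d <- n_sites
    return(cosnp_oe(d$n_sites, d$n_A, d$n_B, d$n_co, strict = strict))
  }
  bad <- n_A == 0 | n_B == 0
  if (any(bad)) {
    if (strict) stop("coSNP_O/E undefined: a species has zero SNPs in the stratum")
    warning(sum(bad), " strata with a zero SNP margin; ratio set to NA")
  }
  oe <- n_co * n_sites / (n_A * n_B)
  oe[bad] <- NA_real_
  oe
}

#' Chi-square independence test for joint polymorphism
#'
#' Assembles the 2x2 table {SNP in A yes/no} x {SNP in B yes/no} over the
#' examined sites and applies Pearson's chi-square with 1 df (no continuity
#' correction by default).
#'
#' @param counts data.frame (or one-row list) with n_sites, n_A, n_B, n_co.
#' @param correct apply Yates' continuity correction (default FALSE; counts
#'   are large in the intended use).
#' @return data.frame with statistic, df, p_value and low_expected (TRUE when
#'   some expected cell is below 5, in which case the asymptotic p-value is
#'   unreliable).
#' @export
chisq_independence <- function(counts, correct = FALSE) {
  with(counts, {
    if (any(n_co > pmin(n_A, n_B)) || any(pmax(n_A, n_B) > n_sites))
      stop("invalid counts: need n_co <= min(n_A, n_B) <= n_sites")
    one <- function(ns, na, nb, nc) {
      tab <- matrix(c(nc, na - nc, nb - nc, ns - na - nb + nc), 2, 2)
      exp_min <- min(outer(rowSums(tab), colSums(tab)) / ns)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      data.frame(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), low_expected = exp_min < 5)
    }
    out <- do.call(rbind, mapply(one, n_sites, n_A, n_B, n_co, SIMPLIFY = FALSE))
    if (any(out$low_expected))
      warning("expected cell count below 5; asymptotic p-value unreliable")
    rownames(out) <- NULL
    out
  })
}

#' Observed/expected table of dimorphic allele-pattern combinations
#'
#' For each pair of patterns (p in A, q in B) among the six dimorphic
#' nucleotide patterns, O is the fraction of coSNPs in the stratum exhibiting
#' (p, q) and E is the product of the marginal pattern frequencies among all
#' A-SNPs and all B-SNPs of the stratum. The diagonal (same two alleles in
#' both species, the configuration expected of shared ancestral
#' polymorphisms) is returned separately.
#'
#' @param stratum classified site table subset (one stratum).
#' @param exclude_cpg CpG policy, see [cosnp_counts()].
#' @return list with n_co, O, E, oe (6x6 matrices; oe is NA where E = 0) and
#'   same_allele (named length-6 vector of diagonal O/E values).
#' @export
pattern_oe <- function(stratum, exclude_cpg = "none") {
  d <- stratum[.examined(stratum, exclude_cpg), , drop = FALSE]
  empty <- matrix(NA_real_, 6, 6, dimnames = list(SNP_PATTERNS, SNP_PATTERNS))
  if (!nrow(d) || !any(d$snp_A & d$snp_B, na.rm = TRUE))
    return(list(n_co = 0L, O = empty, E = empty, oe = empty,
                same_allele = setNames(rep(NA_real_, 6), SNP_PATTERNS)))
  fa <- factor(d$pair_A[d$snp_A], levels = SNP_PATTERNS)
  fb <- factor(d$pair_B[d$snp_B], levels = SNP_PATTERNS)
  co <- d$snp_A & d$snp_B
  O <- table(factor(d$pair_A[co], levels = SNP_PATTERNS),
             factor(d$pair_B[co], levels = SNP_PATTERNS))
  n_co <- sum(co)
  O <- unclass(O) / n_co
  E <- outer(as.vector(table(fa)) / length(fa),
             as.vector(table(fb)) / length(fb))
  dimnames(O) <- dimnames(E) <- list(SNP_PATTERNS, SNP_PATTERNS)
  oe <- ifelse(E > 0, O / E, NA_real_)
  list(n_co = n_co, O = O, E = E, oe = oe,
       same_allele = setNames(diag(oe), SNP_PATTERNS))
}

#' Folded site frequency spectrum
#'
#' @param maf minor allele frequencies in (0, 0.5].
#' @param bin_edges increasing bin edges spanning (0, 0.5]; left-open bins.
#' @return named numeric vector of per-bin proportions summing to 1.
#' @export
site_frequency_spectrum <- function(maf, bin_edges = seq(0, 0.5, by = 0.05)) {
  maf <- maf[!is.na(maf)]
  if (!length(maf)) stop("empty variant set")
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  h <- table(cut(maf, breaks = bin_edges, include.lowest = FALSE))
  prop <- as.vector(h) / length(maf)
  setNames(prop, levels(cut(numeric(0), breaks = bin_edges)))
}

#' Two-sample Kolmogorov-Smirnov comparison of MAF distributions
#'
#' Applied to the raw (unbinned) minor allele frequencies; a flatter folded
#' spectrum (relative excess of common variants) shifts the ECDF downward.
#'
#' @param maf1,maf2 minor allele frequency vectors.
#' @return list with statistic and p_value.
#' @export
compare_sfs <- function(maf1, maf2) {
  maf1 <- maf1[!is.na(maf1)]; maf2 <- maf2[!is.na(maf2)]
  if (length(maf1) < 2 || length(maf2) < 2)
    stop("need at least 2 variants per sample")
  kt <- suppressWarnings(stats::ks.test(maf1, maf2))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Fraction of rare variants
#'
#' @param maf minor allele frequencies.
#' @param cutoff rare-variant threshold (strict <; default 1%).
#' @return proportion of variants with maf < cutoff.
#' @export
rare_variant_fraction <- function(maf, cutoff = 0.01) {
  maf <- maf[!is.na(maf)]
  if (!length(maf)) stop("empty variant set")
  if (cutoff <= 0 || cutoff >= 0.5) stop("cutoff must lie in (0, 0.5)")
  mean(maf < cutoff)
}

#' Compare rare-variant fractions between two groups
#'
#' Two-tailed Fisher's exact test on the 2x2 table of rare/common counts.
#'
#' @param maf1,maf2 minor allele frequency vectors for the two groups.
#' @param cutoff rare-variant threshold (default 1%).
#' @return data.frame with the two fractions, odds ratio (conditional MLE)
#'   and exact p-value.
#' @export
compare_rare_fraction <- function(maf1, maf2, cutoff = 0.01) {
  f1 <- rare_variant_fraction(maf1, cutoff)
  f2 <- rare_variant_fraction(maf2, cutoff)
  maf1 <- maf1[!is.na(maf1)]; maf2 <- maf2[!is.na(maf2)]
  tab <- matrix(c(sum(maf1 < cutoff), sum(maf1 >= cutoff),
                  sum(maf2 < cutoff), sum(maf2 >= cutoff)), 2, 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  data.frame(fraction_1 = f1, fraction_2 = f2,
             odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}
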