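# Window-, group- and pairing-based analyses: coSNP window classes and their
# Tajima's D comparisons, SNP-density/recombination covariates, constraint
# binning with Spearman trend tests, nearest-neighbour functional pairing,
# damaging-fraction and 2x2 enrichment tests.

WINDOW_CLASSES <- c("zero", "two_three", "four", "none")

#' Assign fixed-width windows a coSNP degeneracy class
#'
#' Windows are anchored at position 0 of each chromosome. The class follows
#' the dominance hierarchy: any zero-fold coSNP makes the window class
#' "zero"; else any two-/three-fold coSNP makes it "two_three"; else any
#' four-fold coSNP makes it "four"; windows with no coSNP are "none". So a
#' "two_three" window may contain four-fold coSNPs, and a "zero" window may
#' contain coSNPs of every class.
#'
#' @param cosnps data.frame with chrom, coord (species-A genomic position)
#'   and degeneracy for each coSNP.
#' @param chrom_lengths named vector of chromosome lengths; coSNPs beyond a
#'   chromosome end are dropped with a warning.
#' @param width window width in bp (default 100 kb, the Tajima's D scale).
#' @return data.frame with chrom, start, end, cosnp_class for every window.
#' @export
classify_cosnp_windows <- function(cosnps, chrom_lengths, width = 1e5) {
  wins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0, chrom_lengths[[ch]] - 1, by = width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + width, chrom_lengths[[ch]]),
               stringsAsFactors = FALSE)
  }))
  outside <- !cosnps$chrom %in% names(chrom_lengths) |
    cosnps$coord >= chrom_lengths[cosnps$chrom] | cosnps$coord < 0
  if (any(outside)) {
    warning(sum(outside), " coSNPs outside all windows dropped")
    cosnps <- cosnps[!outside, , drop = FALSE]
  }
  wkey <- paste(wins$chrom, wins$start %/% width)
  ckey <- paste(cosnps$chrom, cosnps$coord %/% width)
  has <- function(cls) wkey %in% ckey[cosnps$degeneracy == cls]
  cls <- ifelse(has("zero"), "zero",
         ifelse(has("two_three"), "two_three",
         ifelse(has("four"), "four", "none")))
  wins$cosnp_class <- factor(cls, levels = WINDOW_CLASSES)
  wins
}

#' Compare Tajima's D across coSNP window classes
#'
#' Pairwise two-sample Kolmogorov-Smirnov tests on the D distributions, plus
#' a chi-square test of equal proportions of windows with D >= `d_threshold`
#' (the conventional flag for balancing selection or population contraction).
#'
#' @param windows data.frame with cosnp_class and tajimas_d columns; windows
#'   with class "none" or undefined D are ignored.
#' @param d_threshold threshold for the high-D proportion (default 2).
#' @return list with `ks` (data.frame of pairwise KS statistics/p-values),
#'   `high_d` (per-class counts and proportions) and `equal_prop`
#'   (chi-square statistic and p-value).
#' @export
compare_window_classes <- function(windows, d_threshold = 2) {
  d <- windows[!is.na(windows$tajimas_d) & windows$cosnp_class != "none", ,
               drop = FALSE]
  d$cosnp_class <- droplevels(d$cosnp_class)
  cls <- levels(d$cosnp_class)
  if (length(cls) < 2) stop("need at least 2 window classes")
  pairs <- utils::combn(cls, 2)
  ks <- do.call(rbind, apply(pairs, 2, function(p) {
    r <- compare_sfs(d$tajimas_d[d$cosnp_class == p[1]],
                     d$tajimas_d[d$cosnp_class == p[2]])
    data.frame(class_1 = p[1], class_2 = p[2],
               ks_statistic = r$statistic, ks_p = r$p_value)
  }))
  high <- tapply(d$tajimas_d >= d_threshold, d$cosnp_class, sum)
  tot <- tapply(d$tajimas_d, d$cosnp_class, length)
  ep <- equal_proportions_test(as.vector(high), as.vector(tot))
  list(ks = ks,
       high_d = data.frame(class = cls, n = as.vector(tot),
                           n_high = as.vector(high),
                           prop_high = as.vector(high / tot)),
       equal_prop = ep)
}

#' Per-window SNP density and mean recombination rate
#'
#' Density is the single-species SNP count divided by the number of examined
#' sites in the window; windows with no examined site, or not covered by the
#' recombination map, are excluded.
#'
#' @param sites classified site table ([classify_sites()]).
#' @param species which species' SNPs define the density ("A" or "B").
#' @param recomb_map optional data.frame(chrom, start, end, rate) of map
#'   intervals; the window rate is the mean rate of overlapping intervals.
#' @param width window width in bp (default 1 Mb).
#' @param exclude_cpg CpG policy, see [cosnp_counts()].
#' @return data.frame with chrom, start, n_sites, n_snp, snp_density and
#'   (when a map is given) recomb_rate.
#' @export
window_covariates <- function(sites, species = "A", recomb_map = NULL,
                              width = 1e6, exclude_cpg = "none") {
  d <- sites[.examined(sites, exclude_cpg), , drop = FALSE]
  chrom <- d[[paste0("chrom_", species)]]
  coord <- d[[paste0("coord_", species)]]
  snp <- d[[paste0("snp_", species)]]
  win <- coord %/% width
  key <- paste(chrom, win)
  n_sites <- tapply(coord, key, length)
  n_snp <- tapply(snp, key, sum)
  lab <- do.call(rbind, strsplit(names(n_sites), " ", fixed = TRUE))
  out <- data.frame(chrom = lab[, 1],
                    start = as.numeric(lab[, 2]) * width,
                    n_sites = as.vector(n_sites), n_snp = as.vector(n_snp),
                    snp_density = as.vector(n_snp / n_sites),
                    stringsAsFactors = FALSE)
  if (!is.null(recomb_map)) {
    out$recomb_rate <- vapply(seq_len(nrow(out)), function(i) {
      m <- recomb_map[recomb_map$chrom == out$chrom[i] &
                        recomb_map$start < out$start[i] + width &
                        recomb_map$end > out$start[i], , drop = FALSE]
      if (!nrow(m)) NA_real_ else mean(m$rate)
    }, numeric(1))
    out <- out[!is.na(out$recomb_rate), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Quantile bins of (near-)equal size
#'
#' Ranks the scores and cuts the rank range into `k_groups` bins; with all
#' scores distinct the group sizes differ by at most 1. Tied scores share the
#' minimum rank and are therefore assigned to the lower bin.
#'
#' @param score numeric vector.
#' @param k_groups number of groups (>= 2, <= length(score)).
#' @return integer vector of group labels 1..k (1 = lowest scores); a single
#'   group with a warning when all scores are identical.
#' @export
equal_size_groups <- function(score, k_groups) {
  n <- length(score)
  if (k_groups < 2) stop("k_groups must be >= 2")
  if (n < k_groups) stop("need at least k_groups observations")
  if (length(unique(score)) == 1L) {
    warning("all scores identical; single group returned")
    return(rep(1L, n))
  }
  r <- rank(score, ties.method = "min")
  as.integer(((r - 1L) * k_groups) %/% n) + 1L
}

#' coSNP O/E per constraint group with a Spearman trend test
#'
#' @param counts data.frame of per-group CoSNP counts with a `group` column
#'   (integer rank of the constraint bin, 1 = weakest constraint) and
#'   n_sites, n_A, n_B, n_co.
#' @param alternative trend direction for the Spearman test: "greater"
#'   (one-tailed, O/E increasing with constraint rank; the direction expected
#'   at zero-fold sites under purifying selection), "less", or "two.sided".
#' @return list with `table` (the counts plus an oe column; groups with an
#'   undefined ratio are dropped with a note) and `rho`, `p_value`.
#' @export
group_oe_trend <- function(counts, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  counts$oe <- suppressWarnings(cosnp_oe(counts, strict = FALSE))
  dropped <- sum(is.na(counts$oe))
  if (dropped > 0)
    warning(dropped, " groups with an undefined O/E (zero SNP margin) dropped")
  tab <- counts[!is.na(counts$oe), , drop = FALSE]
  if (nrow(tab) < 3) stop("need at least 3 groups with a defined O/E")
  ct <- suppressWarnings(
    stats::cor.test(tab$group, tab$oe, method = "spearman",
                    alternative = alternative))
  list(table = tab, rho = unname(ct$estimate), p_value = ct$p.value,
       dropped_groups = dropped)
}

#' Nearest-neighbour site matching within genes
#'
#' Pairs each focal site with the nearest candidate site (absolute distance
#' in species-A coordinates) within the same gene; ties are broken toward the
#' lower coordinate, which makes the output invariant to input ordering.
#' Focal sites whose gene contains no candidate are dropped.
#'
#' @param focal data.frame with gene_id and coord_A for the focal sites
#'   (e.g. zero-fold coSNPs).
#' @param candidates data.frame with gene_id and coord_A for one comparison
#'   class (e.g. zero-fold human non-coSNPs), restricted to the same
#'   degeneracy class by the caller.
#' @return data.frame with focal gene_id/coord_A, matched candidate coord_A
#'   and the distance; one row per retained focal site.
#' @export
nearest_neighbor_match <- function(focal, candidates) {
  by_gene <- split(candidates$coord_A, candidates$gene_id)
  rows <- lapply(seq_len(nrow(focal)), function(i) {
    cand <- by_gene[[as.character(focal$gene_id[i])]]
    cand <- cand[cand != focal$coord_A[i]]
    if (is.null(cand) || !length(cand)) return(NULL)
    dist <- abs(cand - focal$coord_A[i])
    best <- cand[dist == min(dist)]
    data.frame(gene_id = focal$gene_id[i], coord_A = focal$coord_A[i],
               matched_coord_A = min(best), distance = min(dist),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene_id = character(0), coord_A = integer(0),
                                      matched_coord_A = integer(0),
                                      distance = integer(0))
  attr(out, "dropped_focal") <- dropped
  out
}

#' Paired comparison of scores between matched sites
#'
#' @param x,y paired score vectors (e.g. conservation of focal coSNPs and of
#'   their matched neighbours); pairs with a missing value are dropped.
#' @param method "t" (paired t-test, default) or "wilcoxon" (paired Wilcoxon
#'   signed-rank).
#' @param alternative test tail, passed through.
#' @return list with estimate (mean of differences), statistic and p_value.
#' @export
paired_score_test <- function(x, y, method = c("t", "wilcoxon"),
                              alternative = "two.sided") {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 complete pairs")
  if (method == "t") {
    tt <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
  } else {
    tt <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, alternative = alternative))
  }
  list(estimate = mean(x - y), statistic = unname(tt$statistic),
       p_value = tt$p.value, method = method, n_pairs = length(x))
}

#' Damaging-substitution calls from impact scores
#'
#' A nonsynonymous variant is called damaging when SIFT <= 0.05 (boundary
#' inclusive), Grantham > 100 (strict), or the PolyPhen-2 category is
#' "possibly" or "probably" damaging; each metric is evaluated separately and
#' variants missing a score are excluded from that metric.
#'
#' @param scores data.frame with any of the columns sift, grantham, polyphen
#'   (character: "benign", "possibly", "probably").
#' @param metric which score to use: "sift", "grantham" or "polyphen".
#' @return logical vector (NA where the score is missing).
#' @export
damaging_call <- function(scores, metric = c("sift", "grantham", "polyphen")) {
  metric <- match.arg(metric)
  switch(metric,
         sift = scores$sift <= 0.05,
         grantham = scores$grantham > 100,
         polyphen = ifelse(is.na(scores$polyphen), NA,
                           scores$polyphen %in% c("possibly", "probably")))
}

#' Compare damaging fractions between two variant groups
#'
#' @param scores1,scores2 impact-score data.frames for the two groups (e.g.
#'   coSNPs and non-coSNPs at zero-fold sites), see [damaging_call()].
#' @param metric score to use.
#' @return data.frame with per-group damaging fractions, numbers scored,
#'   odds ratio and the two-tailed Fisher exact p-value.
#' @export
damaging_fraction <- function(scores1, scores2,
                              metric = c("sift", "grantham", "polyphen")) {
  metric <- match.arg(metric)
  d1 <- damaging_call(scores1, metric); d1 <- d1[!is.na(d1)]
  d2 <- damaging_call(scores2, metric); d2 <- d2[!is.na(d2)]
  if (!length(d1) || !length(d2)) stop("a group has no scored variant")
  fe <- two_by_two_enrichment(sum(d1), sum(!d1), sum(d2), sum(!d2))
  data.frame(metric = metric, fraction_1 = mean(d1), fraction_2 = mean(d2),
             n_1 = length(d1), n_2 = length(d2),
             odds_ratio = fe$odds_ratio, p_value = fe$p_value)
}

#' 2x2 enrichment test (sample odds ratio + Fisher's exact p)
#'
#' @param in_yes,in_no counts inside the class of interest (e.g. coSNPs that
#'   are / are not GWAS sites).
#' @param out_yes,out_no counts outside the class.
#' @return data.frame with odds_ratio (sample OR, (in_yes*out_no)/(in_no*out_yes);
#'   NA when a margin is zero) and the two-tailed exact p_value.
#' @export
two_by_two_enrichment <- function(in_yes, in_no, out_yes, out_no) {
  cnt <- c(in_yes, in_no, out_yes, out_no)
  if (any(cnt < 0)) stop("counts must be non-negative")
  if (in_yes + in_no == 0 || out_yes + out_no == 0)
    stop("empty class: a row of the 2x2 table has no observations")
  tab <- matrix(cnt, 2, 2, byrow = TRUE)
  or <- if (in_no == 0 || out_yes == 0) NA_real_
        else (in_yes * out_no) / (in_no * out_yes)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  data.frame(odds_ratio = or, p_value = ft$p.value)
}

#' Chi-square test of equal proportions across classes
#'
#' @param successes vector of success counts per class.
#' @param totals vector of totals per class.
#' @return data.frame with statistic, df and p_value (Pearson chi-square,
#'   no continuity correction).
#' @export
equal_proportions_test <- function(successes, totals) {
  if (length(successes) < 2) stop("need at least 2 classes")
  if (any(totals <= 0)) stop("zero total in a class")
  pt <- suppressWarnings(stats::prop.test(successes, totals, correct = FALSE))
  data.frame(statistic = unname(pt$statistic), df = unname(pt$parameter),
             p_value = pt$p.value)
}
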