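# SNP/coSNP discovery curves by individual subsampling and log-linear
# (power-law) projection to large cohort sizes.

#' SNP and coSNP discovery curve by individual subsampling
#'
#' For each cohort size k = 2..K, draws random subsets of individuals without
#' replacement and counts the sites segregating within the subsample (a SNP)
#' and, among those, the sites that are also polymorphic in the fixed
#' partner-species SNP set (a coSNP); counts are averaged over the draws.
#' When `draws` is at least the number of distinct k-subsets, all subsets are
#' enumerated exactly instead of sampled; k = K always uses the single full
#' cohort.
#'
#' @param genotypes matrix of alternate-allele counts (0/1/2), one row per
#'   site, one column per individual.
#' @param partner_snp logical vector (one per site): polymorphic in the
#'   partner species.
#' @param draws random subsets per k (default 5).
#' @param seed optional seed for the subsampling.
#' @return data.frame with k, mean_snp_count, mean_cosnp_count.
#' @export
discovery_curve <- function(genotypes, partner_snp, draws = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- ncol(genotypes)
  if (K < 2) stop("need at least 2 individuals")
  if (length(partner_snp) != nrow(genotypes))
    stop("partner_snp must have one entry per site")
  count_subset <- function(cols) {
    g <- genotypes[, cols, drop = FALSE]
    ac <- rowSums(g)
    seg <- ac > 0 & ac < 2 * length(cols)
    c(sum(seg), sum(seg & partner_snp))
  }
  rows <- lapply(2:K, function(k) {
    if (k == K) {
      m <- count_subset(seq_len(K))
    } else if (choose(K, k) <= draws) {
      subs <- utils::combn(K, k, simplify = FALSE)
      m <- rowMeans(vapply(subs, count_subset, numeric(2)))
    } else {
      m <- rowMeans(vapply(seq_len(draws), function(i) {
        count_subset(sample.int(K, k))
      }, numeric(2)))
    }
    data.frame(k = k, mean_snp_count = m[1], mean_cosnp_count = m[2])
  })
  do.call(rbind, rows)
}

#' Fit a log-linear (power-law) model to a discovery curve
#'
#' Ordinary least squares of log(count) on log(k), natural logs, so that
#' count(k) = exp(a) * k^b. Points with a zero count are dropped with a
#' warning.
#'
#' @param k cohort sizes.
#' @param count mean discovered counts at each k.
#' @return list with intercept a, slope b, r_squared and n_points.
#' @export
fit_log_linear <- function(k, count) {
  ok <- count > 0
  if (any(!ok)) warning(sum(!ok), " zero-count points dropped from the fit")
  k <- k[ok]; count <- count[ok]
  if (length(unique(k)) < 2)
    stop("need at least 2 distinct k with positive counts")
  fit <- stats::lm(log(count) ~ log(k))
  # summary.lm warns on noiseless (exact power-law) input; harmless here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
       r_squared = r2, n_points = length(k))
}

#' Project counts and coSNP O/E to a target cohort size
#'
#' Evaluates the fitted power laws at k_target for the species' SNP count and
#' the coSNP count, then recomputes coSNP_O/E with the projected counts over
#' the fixed orthologous site universe (which does not grow with cohort
#' size) against the fixed partner-species SNP count.
#'
#' @param fit_snp,fit_cosnp fits from [fit_log_linear()].
#' @param k_target projected number of individuals (default 1000).
#' @param n_sites examined orthologous sites.
#' @param n_partner SNP count of the fixed partner species.
#' @return data.frame with k_target, projected snp_count, cosnp_count and oe;
#'   warns when the projected coSNP count exceeds the projected SNP count
#'   (extrapolation inconsistency).
#' @export
project_oe <- function(fit_snp, fit_cosnp, k_target = 1000, n_sites, n_partner) {
  snp <- exp(fit_snp$a + fit_snp$b * log(k_target))
  cosnp <- exp(fit_cosnp$a + fit_cosnp$b * log(k_target))
  if (cosnp > snp)
    warning("projected coSNP count exceeds projected SNP count")
  data.frame(k_target = k_target, snp_count = snp, cosnp_count = cosnp,
             oe = cosnp * n_sites / (snp * n_partner))
}
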