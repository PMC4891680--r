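# R-level interface to the compiled two-population Wright-Fisher simulator:
# scenario configs, the 12-scenario grid, Wilcoxon selection contrasts, and
# the two-way ANOVA of selection x mutation rate.

#' Configuration for the two-population forward simulation
#'
#' Defaults are the full-scale experiment: two populations of N = 1e4
#' diploids split from a common burnt-in ancestor and evolved independently
#' for 1000 generations over a 2.5 Mb region with r = 1e-8, new mutations
#' all carrying selection coefficient s with codominance h = 0.5. See
#' [desk_sim_config()] for the diffusion-rescaled preset used for desk runs.
#'
#' @param N diploid population size per population.
#' @param L region length in bp.
#' @param mu per-base per-generation mutation rate.
#' @param s selection coefficient of new mutations (<= 0).
#' @param h dominance coefficient (default 0.5, codominant).
#' @param r per-base recombination rate.
#' @param generations_post_split generations of independent evolution.
#' @param burn_in_generations ancestral burn-in before the split (default
#'   10 * 2N; 0 gives the clean independence null with no shared ancestral
#'   polymorphism).
#' @param sample_size individuals per population used for SNP ascertainment
#'   (NULL = whole population).
#' @param iterations replicate simulations.
#' @return a "sim_config" list.
#' @export
sim_config <- function(N = 10000, L = 2.5e6, mu = 1e-8, s = -0.01, h = 0.5,
                       r = 1e-8, generations_post_split = 1000,
                       burn_in_generations = 10 * 2 * N,
                       sample_size = NULL, iterations = 1000) {
  stopifnot(N >= 1, L >= 1, iterations >= 1, mu >= 0, r >= 0,
            s <= 0, h >= 0, h <= 1,
            generations_post_split >= 0, burn_in_generations >= 0)
  if (1 + s <= 0) stop("s <= -1 gives non-positive fitness")
  structure(list(N = as.integer(N), L = as.integer(L), mu = mu, s = s, h = h,
                 r = r,
                 generations_post_split = as.integer(generations_post_split),
                 burn_in_generations = as.integer(burn_in_generations),
                 sample_size = if (is.null(sample_size)) 0L else as.integer(sample_size),
                 iterations = as.integer(iterations)),
            class = "sim_config")
}

#' Diffusion-rescaled desk preset
#'
#' Rescales the full-scale scenario by a factor `scale` while preserving the
#' diffusion-scale parameters: N and post-split time shrink by `scale`
#' (keeping t/2N), mu and r grow by `scale` (keeping theta = 4N*mu per site
#' and the population crossover rate), and the region shrinks to `L`. The
#' ancestral burn-in is 2 * 2N generations: long relative to the sojourn time
#' of deleterious variants and to the post-split horizon, so the split starts
#' from mutation-selection-drift balance at a fraction of the 10 * 2N cost.
#'
#' @param mu,s full-scale mutation rate and selection coefficient.
#' @param N,L desk-scale population size and region length.
#' @param scale rescaling factor relative to the full-scale N = 1e4.
#' @param iterations replicate count.
#' @param ... passed on to [sim_config()].
#' @return a "sim_config" list.
#' @export
desk_sim_config <- function(mu = 1e-8, s = -0.01, N = 500, L = 2e4,
                            scale = 10000 / N, iterations = 200, ...) {
  sim_config(N = N, L = L, mu = mu * scale, s = s, r = 1e-8 * scale,
             generations_post_split = round(1000 / scale),
             burn_in_generations = 2 * 2 * N,
             iterations = iterations, ...)
}

#' Simulate a pair of diverging populations
#'
#' Burns in one ancestral Wright-Fisher population to mutation-selection-
#' drift balance, duplicates it into two populations, evolves them
#' independently, and ascertains SNPs as sites segregating in a sample of
#' `sample_size` individuals per population (whole population by default).
#' coSNP_O/E is computed per iteration from the two SNP position sets with
#' n_sites = L; iterations in which a population has no SNP have an
#' undefined ratio (oe = NA, flagged in `undefined`).
#'
#' Uses R's RNG: call set.seed() first for reproducible runs.
#'
#' @param config a [sim_config()].
#' @param site_rates optional per-site relative mutation-rate field (length
#'   L, mean 1) imposing mutation-rate heterogeneity shared by the two
#'   populations.
#' @return data.frame with one row per iteration: iteration, seg_A, seg_B,
#'   n_co, oe, undefined.
#' @export
simulate_pair <- function(config, site_rates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  m <- .wf_sim_pair_cpp(config$N, config$L, config$mu, config$s, config$h,
                        config$r, config$generations_post_split,
                        config$burn_in_generations, config$sample_size,
                        config$iterations,
                        if (is.null(site_rates)) numeric(0) else site_rates)
  seg_A <- m[, 1]; seg_B <- m[, 2]; n_co <- m[, 3]
  undef <- seg_A == 0 | seg_B == 0
  oe <- ifelse(undef, NA_real_, n_co * as.numeric(config$L) / (seg_A * seg_B))
  data.frame(iteration = seq_len(nrow(m)), seg_A = seg_A, seg_B = seg_B,
             n_co = n_co, oe = oe, undefined = undef)
}

#' Run a selection-by-mutation scenario grid
#'
#' Runs every combination of the selection and mutation-rate levels (the
#' full-scale experiment uses four s levels and three mu levels, i.e. twelve
#' scenarios) with a deterministic per-scenario RNG stream derived from
#' `seed`.
#'
#' @param s_levels selection coefficients.
#' @param mu_levels full-scale mutation rates.
#' @param iterations iterations per scenario.
#' @param seed master seed.
#' @param config_fn function(mu, s, iterations) returning a [sim_config()];
#'   default [desk_sim_config()].
#' @return data.frame of per-iteration results with s and mu scenario labels.
#' @export
run_sim_grid <- function(s_levels = c(-0.01, -0.05, -0.1, -0.15),
                         mu_levels = c(1e-8, 5e-8, 1e-7),
                         iterations = 200, seed = 1,
                         config_fn = desk_sim_config) {
  stopifnot(length(s_levels) >= 1, length(mu_levels) >= 1)
  grid <- expand.grid(s = s_levels, mu = mu_levels, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    set.seed((seed * 1000L + i) %% .Machine$integer.max)
    cfg <- config_fn(mu = grid$mu[i], s = grid$s[i], iterations = iterations)
    cbind(s = grid$s[i], mu = grid$mu[i], simulate_pair(cfg))
  })
  do.call(rbind, res)
}

#' Wilcoxon rank-sum contrasts of coSNP O/E between selection levels
#'
#' Two-tailed rank-sum tests (normal approximation with tie correction)
#' between adjacent selection levels and between the two extremes, within
#' each mutation-rate level; iterations with an undefined ratio are dropped.
#'
#' @param results grid results from [run_sim_grid()].
#' @return data.frame with mu, s_1, s_2, n_1, n_2, median_1, median_2 and
#'   p_value.
#' @export
selection_contrast <- function(results) {
  res <- results[!results$undefined, , drop = FALSE]
  s_lv <- sort(unique(res$s), decreasing = TRUE)  # weak -> strong selection
  if (length(s_lv) < 2) stop("need at least 2 selection levels")
  pairs <- cbind(s_lv[-length(s_lv)], s_lv[-1])
  if (length(s_lv) > 2) pairs <- rbind(pairs, c(s_lv[1], s_lv[length(s_lv)]))
  out <- list()
  for (mu in sort(unique(res$mu))) {
    for (k in seq_len(nrow(pairs))) {
      x <- res$oe[res$mu == mu & res$s == pairs[k, 1]]
      y <- res$oe[res$mu == mu & res$s == pairs[k, 2]]
      if (length(x) < 2 || length(y) < 2)
        stop("need >= 2 valid iterations per level")
      p <- if (length(unique(c(x, y))) == 1L) 1
           else suppressWarnings(stats::wilcox.test(x, y))$p.value
      out[[length(out) + 1L]] <- data.frame(
        mu = mu, s_1 = pairs[k, 1], s_2 = pairs[k, 2],
        n_1 = length(x), n_2 = length(y),
        median_1 = stats::median(x), median_2 = stats::median(y), p_value = p)
    }
  }
  do.call(rbind, out)
}

#' Two-way ANOVA of coSNP O/E on selection and mutation rate
#'
#' Type II sums of squares (equal to type I/III under the balanced grid) for
#' the main effects of selection level and mutation-rate level and their
#' interaction.
#'
#' @param results grid results from [run_sim_grid()].
#' @return data.frame with term, sum_sq, df, f_value, p_value.
#' @export
interaction_anova <- function(results) {
  res <- results[!results$undefined, , drop = FALSE]
  res$s_f <- factor(res$s)
  res$mu_f <- factor(res$mu)
  if (nlevels(res$s_f) < 2 || nlevels(res$mu_f) < 2)
    stop("need at least 2 levels of each factor")
  cell_n <- table(res$s_f, res$mu_f)
  if (any(cell_n < 2)) stop("need >= 2 replicates per cell for the interaction")
  fit <- stats::lm(oe ~ s_f * mu_f, data = res)
  a <- car::Anova(fit, type = 2)
  data.frame(term = rownames(a), sum_sq = a[["Sum Sq"]], df = a[["Df"]],
             f_value = a[["F value"]], p_value = a[["Pr(>F)"]],
             row.names = NULL)
}

#' Expected segregating sites under neutrality (Watterson)
#'
#' E[S] = theta * a_{n-1} with theta = 4 N mu L and a_{n-1} the harmonic
#' number over the sampled haplotypes; used to calibrate the simulator.
#'
#' @param N diploid population size.
#' @param mu per-base mutation rate.
#' @param L region length.
#' @param n_haplotypes sampled haplotypes (default 2N).
#' @return expected number of segregating sites.
#' @export
watterson_expected_s <- function(N, mu, L, n_haplotypes = 2 * N) {
  theta <- 4 * N * mu * L
  theta * sum(1 / seq_len(n_haplotypes - 1))
}

#' @importFrom stats median
NULL
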