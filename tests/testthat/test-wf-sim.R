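# Wright-Fisher simulator: determinism, neutral calibration, the
# independence null, mutation-rate heterogeneity, and the scenario grid
# machinery (small configurations; the full calibrations live in the
# acceptance suite).

small_cfg <- function(...) {
  sim_config(N = 100, L = 2000, mu = 5e-6, r = 2e-7,
             generations_post_split = 50, burn_in_generations = 200,
             iterations = 5, ...)
}

test_that("identical seeds reproduce identical results", {
  set.seed(5); a <- simulate_pair(small_cfg(s = -0.05))
  set.seed(5); b <- simulate_pair(small_cfg(s = -0.05))
  expect_identical(a, b)
  set.seed(6); c <- simulate_pair(small_cfg(s = -0.05))
  expect_false(identical(a, c))
})

test_that("configuration validation rejects impossible parameters", {
  expect_error(sim_config(s = 0.1), "s")
  expect_error(sim_config(s = -1.5), "fitness|s")
  expect_error(sim_config(N = 0), "N")
  expect_error(sim_config(h = 2), "h")
})

test_that("mutation-free start stays monomorphic", {
  set.seed(1)
  r <- simulate_pair(sim_config(N = 50, L = 1000, mu = 0, s = 0, r = 0,
                                generations_post_split = 20,
                                burn_in_generations = 20, iterations = 3))
  expect_true(all(r$seg_A == 0 & r$seg_B == 0))
  expect_true(all(r$undefined))
  expect_true(all(is.na(r$oe)))
})

test_that("neutral segregating sites are near the Watterson expectation", {
  set.seed(30)
  cfg <- sim_config(N = 100, L = 2000, mu = 5e-6, s = 0, r = 2e-7,
                    generations_post_split = 0, burn_in_generations = 2000,
                    iterations = 60)
  r <- simulate_pair(cfg)
  expected <- watterson_expected_s(100, 5e-6, 2000)
  expect_lt(abs(mean(r$seg_A) / expected - 1), 0.15)
})

test_that("independent evolution from a monomorphic split gives O/E near 1", {
  set.seed(12)
  cfg <- sim_config(N = 200, L = 5000, mu = 5e-6, s = 0, r = 2e-7,
                    generations_post_split = 100, burn_in_generations = 0,
                    iterations = 200)
  r <- simulate_pair(cfg)
  ok <- !r$undefined
  se <- sd(r$oe[ok]) / sqrt(sum(ok))
  expect_lt(abs(mean(r$oe[ok]) - 1), 3 * se)
})

test_that("a shared mutation-rate field elevates O/E above 1", {
  set.seed(31)
  rates <- rgamma(5000, 1, 1)  # CV^2 = 1
  cfg <- sim_config(N = 200, L = 5000, mu = 5e-6, s = 0, r = 2e-7,
                    generations_post_split = 100, burn_in_generations = 0,
                    iterations = 150)
  r <- simulate_pair(cfg, site_rates = rates)
  ok <- !r$undefined
  se <- sd(r$oe[ok]) / sqrt(sum(ok))
  expect_gt(mean(r$oe[ok]), 1 + 3 * se)  # significantly above the null
  expect_lt(abs(mean(r$oe[ok]) - 2), 0.5)  # near the 1 + CV^2 closed form
})

test_that("the scenario grid is labelled, deterministic and contrastable", {
  cfg_fn <- function(mu, s, iterations)
    sim_config(N = 60, L = 1500, mu = mu * 50, s = s, r = 5e-7,
               generations_post_split = 20, burn_in_generations = 120,
               iterations = iterations)
  g1 <- run_sim_grid(s_levels = c(-0.01, -0.15), mu_levels = c(1e-7, 2e-7),
                     iterations = 8, seed = 3, config_fn = cfg_fn)
  expect_equal(nrow(g1), 2 * 2 * 8)
  expect_equal(nrow(unique(g1[c("s", "mu")])), 4)
  g2 <- run_sim_grid(s_levels = c(-0.01, -0.15), mu_levels = c(1e-7, 2e-7),
                     iterations = 8, seed = 3, config_fn = cfg_fn)
  expect_identical(g1, g2)
})

test_that("rank-sum contrasts match exact enumeration for separated samples", {
  # completely separated samples of size 20: two-sided p = 2 / choose(40, 20)
  res <- data.frame(s = rep(c(-0.01, -0.15), each = 20), mu = 1e-8,
                    oe = c(101:120, 1:20), undefined = FALSE)
  ct <- selection_contrast(res)
  expect_equal(ct$p_value, 2 / choose(40, 20), tolerance = 1e-9)
  expect_equal(ct$median_1, 110.5)
  # identical distributions -> p = 1
  res2 <- res; res2$oe <- rep(1:20, 2)
  expect_equal(selection_contrast(res2)$p_value, 1)
  # a planted shift shrinks p (monotonicity smoke test)
  set.seed(44)
  base <- rnorm(50)
  p_of_shift <- sapply(c(0.2, 1, 3), function(d) {
    r <- data.frame(s = rep(c(-0.01, -0.15), each = 50), mu = 1e-8,
                    oe = c(base + d, base), undefined = FALSE)
    selection_contrast(r)$p_value
  })
  expect_true(all(diff(p_of_shift) < 0))
})

test_that("the two-way ANOVA detects a planted interaction and validates input", {
  set.seed(55)
  grid <- expand.grid(s = c(-0.01, -0.05), mu = c(1e-8, 5e-8),
                      rep = 1:40)
  # multiplicative (non-additive) response
  grid$oe <- with(grid, exp(1 + 2 * (s == -0.05) * (mu == 5e-8))) +
    rnorm(nrow(grid), 0, 0.5)
  grid$undefined <- FALSE
  a <- interaction_anova(grid)
  expect_lt(a$p_value[a$term == "s_f:mu_f"], 1e-6)
  # additive response: interaction not flagged at a fixed seed
  grid$oe <- with(grid, 2 * (s == -0.05) + 3 * (mu == 5e-8)) +
    rnorm(nrow(grid), 0, 1)
  a2 <- interaction_anova(grid)
  expect_gt(a2$p_value[a2$term == "s_f:mu_f"], 0.001)
  # single replicate per cell leaves no residual df
  one <- expand.grid(s = c(-0.01, -0.05), mu = c(1e-8, 5e-8))
  one$oe <- 1:4; one$undefined <- FALSE
  expect_error(interaction_anova(one), "replicates")
})
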