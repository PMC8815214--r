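test_that("Balding-Nichols subpopulation frequencies have the model's moments", {
  expect_error(draw_subpop_freqs(0, 0.01), "open interval")
  expect_error(draw_subpop_freqs(0.5, 1), "open interval")

  set.seed(1)
  # p = 0.5, fst = 0.01: Beta(a, b) with a = b = 49.5, mean p, var p(1-p)fst
  fr <- draw_subpop_freqs(rep(0.5, 40000), 0.01)
  expect_equal(mean(fr), 0.5, tolerance = 0.005)
  expect_equal(stats::var(c(fr)), 0.5 * 0.5 * 0.01, tolerance = 0.05)
  # fst -> 0: draws concentrate at p
  fr2 <- draw_subpop_freqs(rep(0.3, 5000), 1e-4)
  expect_lt(max(abs(fr2 - 0.3)), 0.05)
})

test_that("simulated panels carry the configured differentiation (Weir-Cockerham)", {
  set.seed(2)
  sc <- sim_config_common(n_cohort = 1000, n_snps = 5000, fst = 0.01)
  panel <- simulate_panel(sc)
  expect_equal(sum(panel$subpop == 1), 500)
  fst_hat <- wc_fst(panel$dosages, panel$subpop)
  expect_gt(fst_hat, 0.007)
  expect_lt(fst_hat, 0.013)
})

test_that("within-subpopulation genotypes satisfy Hardy-Weinberg equilibrium", {
  set.seed(3)
  sc <- sim_config_common(n_cohort = 400, n_snps = 4000, fst = 0.01)
  panel <- simulate_panel(sc)
  d1 <- panel$dosages[panel$subpop == 1, ]
  p_hwe <- vapply(seq_len(ncol(d1)), function(s) {
    x <- d1[, s]
    hwe_exact_p(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  # the exact test is conservative on discrete data: rejection at 0.05 must
  # not exceed the nominal rate by more than Monte-Carlo error
  expect_lt(mean(p_hwe < 0.05), 0.065)
  # and the test must not be degenerate either
  expect_gt(mean(p_hwe < 0.5), 0.2)
})

test_that("candidate SNP follows its subpopulation-specific frequencies", {
  set.seed(4)
  sc <- sim_config_common(n_cohort = 40000, candidate_freqs = c(0.25, 0.85))
  sub <- rep(1:2, each = 20000)
  g <- simulate_candidate(sc, sub)
  expect_equal(mean(g[sub == 1]), 0.5, tolerance = 0.02)
  expect_equal(mean(g[sub == 2]), 1.7, tolerance = 0.02)

  # p1 = p2: identical candidate distribution across subpopulations
  sc_eq <- sim_config_common(n_cohort = 40000, candidate_freqs = c(0.5, 0.5))
  g_eq <- simulate_candidate(sc_eq, sub)
  expect_equal(mean(g_eq[sub == 1]), mean(g_eq[sub == 2]), tolerance = 0.03)
})

test_that("generators are reproducible from their seed", {
  sc <- sim_config_common(n_cohort = 60, n_snps = 40, seed = 99)
  expect_identical(simulate_panel(sc)$dosages, simulate_panel(sc)$dosages)
  sr <- sim_config_rare(n_haplotypes = 40, region_length = 5000, seed = 77)
  r1 <- simulate_coalescent_region(sr)
  r2 <- simulate_coalescent_region(sr)
  expect_identical(r1$dosages, r2$dosages)
  expect_identical(r1$positions, r2$positions)
})

test_that("coalescent simulator matches Watterson's expected segregating sites", {
  # theta = 4 Ne mu L = 2 with a sample of n = 10 haplotypes, single deme
  set.seed(5)
  theta <- 2
  sr <- sim_config_rare(n_haplotypes = 10, Ne = 1e5, mu = 1e-8,
                        region_length = theta / (4 * 1e5 * 1e-8),
                        n_demes = 1)
  m <- 3000
  S <- vapply(seq_len(m), function(i) {
    ncol(suppressWarnings(simulate_coalescent_region(sr))$dosages)
  }, numeric(1))
  a1 <- sum(1 / (1:9))
  expected <- theta * a1
  mc_se <- stats::sd(S) / sqrt(m)
  expect_lt(abs(mean(S) - expected), 3 * mc_se + 0.02)
})

test_that("degenerate coalescent inputs behave as documented", {
  sr0 <- sim_config_rare(n_haplotypes = 4, mu = 0, region_length = 1000,
                         n_demes = 1, seed = 1)
  expect_warning(reg <- simulate_coalescent_region(sr0), "no segregating")
  expect_equal(ncol(reg$dosages), 0)
  expect_error(simulate_coalescent_region(sim_config_rare(n_haplotypes = 8),
                                          n_per_deme = c(3, 5)),
               "even")
})

test_that("high migration approaches the panmictic coalescent", {
  # two island-model demes of size Ne each approach, as M grows, a single
  # panmictic population of size 2 Ne (the ms convention)
  set.seed(6)
  theta <- 3
  L <- theta / (4 * 1e5 * 1e-8)
  m <- 1200
  sims <- function(cfg) {
    vapply(seq_len(m), function(i) {
      ncol(suppressWarnings(simulate_coalescent_region(cfg))$dosages)
    }, numeric(1))
  }
  S_one <- sims(sim_config_rare(n_haplotypes = 20, Ne = 2e5,
                                region_length = L, n_demes = 1))
  S_two <- sims(sim_config_rare(n_haplotypes = 20, Ne = 1e5,
                                region_length = L, n_demes = 2, M = 1000))
  se <- sqrt(stats::var(S_one) / m + stats::var(S_two) / m)
  expect_lt(abs(mean(S_one) - mean(S_two)), 3 * se)
})

test_that("coalescent diploids are paired within deme and dosages are valid", {
  set.seed(7)
  sr <- sim_config_rare(n_haplotypes = 200, region_length = 3000)
  reg <- simulate_coalescent_region(sr)
  expect_equal(tabulate(reg$subpop, 2), c(50, 50))
  expect_true(all(reg$dosages %in% 0:2))
  expect_true(all(diff(reg$positions) >= 0))
  f <- colMeans(reg$dosages) / 2
  expect_true(all(f > 0 & f < 1))
})

test_that("sub-locus splitting partitions the mutation rate", {
  set.seed(8)
  theta <- 4
  L <- theta / (4 * 1e5 * 1e-8)
  m <- 800
  tot <- function(k) {
    cfg <- sim_config_rare(n_haplotypes = 12, region_length = L,
                           n_demes = 1, n_subloci = k)
    mean(vapply(seq_len(m), function(i) {
      ncol(suppressWarnings(simulate_coalescent_region(cfg))$dosages)
    }, numeric(1)))
  }
  # expected S is theta * a_n regardless of how the region is split
  expect_lt(abs(tot(1) - tot(4)), 0.5)
})
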