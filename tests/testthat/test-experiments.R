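small_null_cfg <- function(methods, m_reps, root_seed = 5,
                           n_cohort = 600, n_snps = 300) {
  experiment_config(
    scenario = "null", methods = methods, m_reps = m_reps,
    sim_common = sim_config_common(n_cohort = n_cohort, n_snps = n_snps),
    pheno = pheno_config(), root_seed = root_seed
  )
}

test_that("experiment configuration enforces its invariants", {
  expect_error(small_null_cfg("lmm", 0), "at least 1")
  expect_error(small_null_cfg("burden", 3), "must be among")
  expect_error(
    experiment_config("rare_null", "burden", 3,
                      sim_common = sim_config_common(n_cohort = 600)),
    "sim_config_rare"
  )
  expect_error(
    experiment_config("power", "lmm", 3,
                      sim_common = sim_config_common(n_cohort = 600),
                      pheno = pheno_config(beta = 0)),
    "beta"
  )
})

test_that("experiments are bit-reproducible from the root seed", {
  cfg <- small_null_cfg(c("lmm", "pca", "uncorrected"), 3)
  r1 <- suppressWarnings(run_experiment(cfg))
  r2 <- suppressWarnings(run_experiment(cfg))
  expect_identical(r1$pvalues, r2$pvalues)
  expect_identical(r1$summary, r2$summary)
})

test_that("the rejection-rate estimator is calibrated on a uniform stub", {
  cfg <- small_null_cfg("uniform_stub", 400, n_cohort = 100, n_snps = 20)
  res <- run_experiment(cfg)
  r <- res$summary$rejection_rate
  expect_lt(abs(r - 0.05), 3 * res$summary$mc_se + 0.01)
  expect_equal(res$summary$n_used, 400)
  # degenerate p-values never reject at alpha = 0.05
  pv <- rep(0.5, 50)
  expect_equal(mean(pv < cfg$alpha), 0)
})

test_that("method failures are recorded as missing and bounded", {
  # a rare-variant config with zero mutation rate produces no variants, so
  # every set test fails and the experiment must refuse to summarize
  cfg <- experiment_config(
    scenario = "rare_null", methods = "burden", m_reps = 5,
    sim_common = sim_config_common(n_cohort = 400, n_snps = 100),
    sim_rare = sim_config_rare(n_haplotypes = 400, mu = 0),
    pheno = pheno_config(), root_seed = 2
  )
  expect_error(suppressWarnings(run_experiment(cfg)), "10%")
})

test_that("rare-variant replicates run end to end", {
  cfg <- experiment_config(
    scenario = "rare_null", methods = c("burden", "skat", "skato", "hybrid"),
    m_reps = 2,
    sim_common = sim_config_common(n_cohort = 500, n_snps = 250),
    sim_rare = sim_config_rare(n_haplotypes = 500 * 2, region_length = 10000),
    pheno = pheno_config(), root_seed = 3
  )
  res <- run_experiment(cfg)
  expect_equal(nrow(res$pvalues), 8)
  expect_true(all(res$pvalues$p_value >= 0 & res$pvalues$p_value <= 1))
})

test_that("the frequency sweep traces a flat profile for a calibrated stub", {
  cfg <- small_null_cfg("uniform_stub", 80, n_cohort = 100, n_snps = 20)
  sw <- freq_sweep(cfg, p2_grid = c(0.5, 0.7, 0.9))
  expect_equal(nrow(sw), 3)
  expect_true(all(abs(sw$rejection_rate - 0.05) < 3 * sw$mc_se + 0.05))
  fitln <- stats::lm(rejection_rate ~ p2, data = sw)
  slope_t <- summary(fitln)$coefficients["p2", "t value"]
  expect_lt(abs(slope_t), 10)
})

test_that("qq data follow the midpoint plotting convention", {
  one <- qq_data(0.5)
  expect_equal(one$expected, -log10(0.5))
  expect_equal(one$observed, -log10(0.5))

  set.seed(81)
  p <- stats::runif(1000)
  qq <- qq_data(p)
  # DKW bound at 99% on the uniform ecdf
  eps <- sqrt(log(2 / 0.01) / (2 * 1000))
  expect_lt(max(abs(sort(p) - (seq_len(1000) - 0.5) / 1000)), eps + 0.001)
  expect_equal(qq$observed, sort(-log10(p)), tolerance = 1e-12)

  # spiked small p-values lift the upper tail above the identity
  p_spiked <- c(stats::runif(500), rep(1e-6, 20))
  qq_s <- qq_data(p_spiked)
  top <- qq_s[qq_s$expected > 2, ]
  expect_true(all(top$observed > top$expected))

  expect_equal(attr(qq_data(c(0.1, NA, 0.5)), "n_missing"), 1)
  expect_error(qq_data(c(NA_real_, NA_real_)), "non-missing")
})

test_that("tidiers and plots expose the experiment surface", {
  cfg <- small_null_cfg(c("pca", "uncorrected"), 3)
  res <- run_experiment(cfg)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$method, c("pca", "uncorrected"))
  gl <- glance(res)
  expect_equal(gl$m_reps, 3L)
  pl <- autoplot(res)
  expect_s3_class(pl, "ggplot")
  sw <- freq_sweep(small_null_cfg("uniform_stub", 5, n_cohort = 100,
                                  n_snps = 20), p2_grid = c(0.5, 0.9))
  expect_s3_class(plot_freq_sweep(sw), "ggplot")
})
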