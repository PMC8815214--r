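#' Configure a replicated simulation experiment
#'
#' Bundles the genotype, phenotype and testing configuration for a
#' Monte-Carlo estimate of type I error or power under extreme phenotype
#' sampling with population stratification.
#'
#' Scenarios:
#' * `"null"` — common candidate SNP with subpopulation-specific
#'   frequencies, phenotype independent of genotype (type I error).
#' * `"power"` — candidate causal with effect `pheno$beta`, equal
#'   candidate frequency in both subpopulations.
#' * `"rare_null"` — coalescent rare-variant region tested with the
#'   GLMM-framework set tests, phenotype independent of genotype.
#'
#' Genotypes are simulated only for the extreme-sampled individuals: under
#' every scenario the genotypes of unselected individuals are conditionally
#' independent of the analysis given subpopulation labels (the power-case
#' causal candidate is simulated cohort-wide before selection), so this is
#' distributionally identical to simulating the full cohort. The GRM and
#' PCs are computed per replicate within the extreme sample, matching the
#' design premise that genotypes exist only for sampled individuals.
#'
#' @param scenario One of `"null"`, `"power"`, `"rare_null"`.
#' @param methods Methods to run each replicate. Common-variant scenarios:
#'   any of `"lmm"`, `"glmm"`, `"liability"`, `"pca"`, `"uncorrected"`,
#'   plus the calibration stub `"uniform_stub"` (reports a Uniform(0,1)
#'   p-value; useful for validating the harness). Rare-variant scenario:
#'   any of `"burden"`, `"skat"`, `"skato"`, `"hybrid"`.
#' @param m_reps Number of replicates (>= 1).
#' @param sim_common A [sim_config_common()]; defines the cohort, the
#'   background panel and (for common scenarios) the candidate SNP.
#' @param sim_rare A [sim_config_rare()]; required for `"rare_null"`.
#' @param pheno A [pheno_config()].
#' @param alpha Nominal level for rejection proportions (default 0.05).
#' @param n_pcs Principal components for the PCA baseline (default 5).
#' @param n_covariate_pcs Principal components included as *fixed*
#'   covariates in the mixed-model null fits (LMM, GLMM, and the
#'   liability-scale LMM). Defaults to 5 for the common-variant scenarios
#'   — the standard single-variant GWAS pipeline, in which the random
#'   effect handles residual and cryptic structure while the leading
#'   ancestry axes enter as covariates — and to 0 for `"rare_null"`, whose
#'   set tests are run against a covariate-free null model as in the
#'   rare-variant software defaults. See the methods vignette for why the
#'   distinction matters under extreme candidate differentiation.
#' @param root_seed Root seed; per-replicate streams are derived from it so
#'   each replicate is independently reproducible.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(scenario = c("null", "power", "rare_null"),
                              methods,
                              m_reps,
                              sim_common,
                              sim_rare = NULL,
                              pheno = pheno_config(),
                              alpha = 0.05,
                              n_pcs = 5L,
                              n_covariate_pcs = NULL,
                              root_seed = 1L) {
  scenario <- match.arg(scenario)
  common_methods <- c("lmm", "glmm", "liability", "pca", "uncorrected",
                      "uniform_stub")
  rare_methods <- c("burden", "skat", "skato", "hybrid", "uniform_stub")
  allowed <- if (scenario == "rare_null") rare_methods else common_methods
  if (!length(methods) || !all(methods %in% allowed)) {
    stop("methods for scenario '", scenario, "' must be among: ",
         paste(allowed, collapse = ", "))
  }
  if (m_reps < 1) stop("m_reps must be at least 1")
  stopifnot(alpha > 0, alpha < 1, inherits(sim_common, "sim_config_common"),
            inherits(pheno, "pheno_config"))
  if (scenario == "rare_null" && !inherits(sim_rare, "sim_config_rare")) {
    stop("scenario 'rare_null' needs a sim_config_rare in `sim_rare`")
  }
  if (scenario == "power" && pheno$beta == 0) {
    stop("power scenario needs pheno$beta != 0")
  }
  if (is.null(n_covariate_pcs)) {
    n_covariate_pcs <- if (scenario == "rare_null") 0L else 5L
  }
  structure(
    list(scenario = scenario, methods = unique(methods),
         m_reps = as.integer(m_reps),
         sim_common = sim_common, sim_rare = sim_rare, pheno = pheno,
         alpha = alpha, n_pcs = as.integer(n_pcs),
         n_covariate_pcs = as.integer(n_covariate_pcs),
         root_seed = as.integer(root_seed)),
    class = "experiment_config"
  )
}

#' Run a replicated experiment
#'
#' For each replicate: simulate the cohort's subpopulation labels and
#' phenotypes, ascertain the phenotype extremes, simulate genotypes for the
#' selected individuals (background panel, candidate SNP or coalescent
#' region), compute the standardized GRM within the sample, run every
#' requested method, and record its p-value. Method failures within a
#' replicate are recorded as missing; the experiment errors only if more
#' than 10% of a method's replicates are missing.
#'
#' @param cfg An [experiment_config()].
#' @return An `experiment_result`: `pvalues` (tibble: `replicate`, `method`,
#'   `p_value`), `summary` (tibble: `method`, `rejection_rate`, `mc_se`,
#'   `n_used`, `n_missing`), the config, and elapsed time. Fully
#'   reproducible from `root_seed`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  t0 <- proc.time()[["elapsed"]]
  rep_fun <- if (cfg$scenario == "rare_null") replicate_rare else replicate_common
  rows <- vector("list", cfg$m_reps)
  for (i in seq_len(cfg$m_reps)) {
    p <- rep_fun(cfg, derive_seed(cfg$root_seed, i))
    rows[[i]] <- tibble::tibble(replicate = i, method = names(p),
                                p_value = unname(p))
  }
  pvalues <- dplyr::bind_rows(rows)
  summary <- pvalues |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      rejection_rate = mean(.data$p_value < cfg$alpha, na.rm = TRUE),
      n_used = sum(!is.na(.data$p_value)),
      n_missing = sum(is.na(.data$p_value)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mc_se = sqrt(.data$rejection_rate * (1 - .data$rejection_rate) /
                     .data$n_used)
    ) |>
    dplyr::select("method", "rejection_rate", "mc_se", "n_used", "n_missing")
  bad <- summary$method[summary$n_missing > 0.1 * cfg$m_reps]
  if (length(bad)) {
    stop("more than 10% of replicates failed for: ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(pvalues = pvalues, summary = summary, config = cfg,
         elapsed = proc.time()[["elapsed"]] - t0),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> scenario '%s', %d replicates, alpha = %g\n",
              x$config$scenario, x$config$m_reps, x$config$alpha))
  print(x$summary)
  invisible(x)
}

# One common-variant replicate; returns a named p-value vector.
replicate_common <- function(cfg, seed) {
  set.seed(seed)
  sc <- cfg$sim_common
  subpop_full <- subpop_labels(sc)
  power <- cfg$scenario == "power"
  g_full <- if (power) simulate_candidate(sc, subpop_full) else NULL
  y <- simulate_phenotype(cfg$pheno, subpop_full, g_full)
  eps <- eps_select(y, cfg$pheno$tail_fraction)
  yb <- eps$group
  subpop_sel <- subpop_full[eps$index]
  needs_rel <- any(cfg$methods %in% c("lmm", "glmm", "liability", "pca"))
  panel <- if (needs_rel) simulate_panel(sc, subpop = subpop_sel) else NULL
  g <- if (power) g_full[eps$index] else simulate_candidate(sc, subpop_sel)
  rel <- if (needs_rel) compute_grm(panel) else NULL
  X_mm <- if (needs_rel && cfg$n_covariate_pcs > 0) {
    top_pcs(rel, cfg$n_covariate_pcs)
  } else NULL

  run_one <- function(method) {
    switch(method,
      lmm = {
        null <- fit_lmm_null(as.numeric(yb), rel, X = X_mm)
        lmm_score_test(null, g)$p_value
      },
      glmm = {
        null <- fit_glmm_null(yb, rel, X = X_mm)
        glmm_score_test(null, g, force = TRUE)$p_value
      },
      liability = {
        fit <- estimate_liabilities(yb, panel, rel = rel)
        liability_assoc(fit, rel, g, X = X_mm)$p_value
      },
      pca = pca_logistic_test(yb, g, top_pcs(rel, cfg$n_pcs))$p_value,
      uncorrected = uncorrected_logistic_test(yb, g)$p_value,
      uniform_stub = stats::runif(1)
    )
  }
  vapply(cfg$methods, function(m) {
    tryCatch(suppressWarnings(run_one(m)), error = function(e) NA_real_)
  }, numeric(1))
}

# One rare-variant replicate. The coalescent region is simulated directly
# for the selected individuals' haplotypes (sampling consistency of the
# coalescent: a subsample's genealogy is itself a structured coalescent).
replicate_rare <- function(cfg, seed) {
  set.seed(seed)
  sc <- cfg$sim_common
  subpop_full <- subpop_labels(sc)
  y <- simulate_phenotype(cfg$pheno, subpop_full)
  eps <- eps_select(y, cfg$pheno$tail_fraction)
  yb <- eps$group
  subpop_sel <- subpop_full[eps$index]
  n_by_deme <- tabulate(subpop_sel, nbins = cfg$sim_rare$n_demes)
  region <- simulate_coalescent_region(cfg$sim_rare,
                                       n_per_deme = 2L * n_by_deme)
  # align region individuals (grouped by deme) with the selected cohort rows
  dos <- matrix(0L, length(yb), ncol(region$dosages))
  for (d in seq_len(cfg$sim_rare$n_demes)) {
    dos[subpop_sel == d, ] <- region$dosages[region$subpop == d, , drop = FALSE]
  }
  panel <- simulate_panel(sc, subpop = subpop_sel)
  rel <- compute_grm(panel)
  X_mm <- if (cfg$n_covariate_pcs > 0) top_pcs(rel, cfg$n_covariate_pcs) else NULL
  null <- tryCatch(fit_glmm_null(yb, rel, X = X_mm), error = function(e) NULL)
  if (is.null(null)) {
    return(stats::setNames(rep(NA_real_, length(cfg$methods)), cfg$methods))
  }
  set <- tryCatch(variant_set(dos), error = function(e) NULL)
  test_map <- c(burden = "burden", skat = "skat", skato = "skato",
                hybrid = "hybrid")
  wanted <- intersect(cfg$methods, names(test_map))
  res <- if (!is.null(set) && length(wanted)) {
    need <- unique(c(wanted, if ("skato" %in% wanted) "skat",
                     if ("hybrid" %in% wanted) "burden"))
    tryCatch(smmat_tests(null, set, tests = need, force = TRUE),
             error = function(e) NULL)
  } else NULL
  vapply(cfg$methods, function(m) {
    if (m == "uniform_stub") return(stats::runif(1))
    if (is.null(res)) return(NA_real_)
    col <- paste0("p_", m)
    if (col %in% names(res)) res[[col]] else NA_real_
  }, numeric(1))
}

#' Allele-frequency sweep of the type I error rate
#'
#' Re-runs a null-scenario experiment over a grid of the candidate SNP's
#' subpopulation-2 allele frequency `p2` with `p1` held fixed, tracing how
#' each method's empirical size responds to increasing candidate
#' differentiation. At `p2 = p1` there is no stratification at the
#' candidate.
#'
#' @param cfg An [experiment_config()] with scenario `"null"`; its
#'   `candidate_freqs[1]` is the fixed `p1`.
#' @param p2_grid Grid of `p2` values (default `seq(0.5, 0.9, by = 0.1)`).
#' @return A `freq_sweep_result` tibble: `p2`, `method`, `rejection_rate`,
#'   `mc_se`, `n_used`.
#' @export
freq_sweep <- function(cfg, p2_grid = seq(0.5, 0.9, by = 0.1)) {
  stopifnot(inherits(cfg, "experiment_config"), cfg$scenario == "null")
  out <- purrr::map2_dfr(p2_grid, seq_along(p2_grid), function(p2, i) {
    cfg_i <- cfg
    cfg_i$sim_common$candidate_freqs[2] <- p2
    cfg_i$root_seed <- derive_seed(cfg$root_seed, 100000L + i)
    res <- run_experiment(cfg_i)
    dplyr::mutate(res$summary, p2 = p2, .before = 1)
  })
  out <- dplyr::select(out, "p2", "method", "rejection_rate", "mc_se", "n_used")
  class(out) <- c("freq_sweep_result", class(out))
  out
}

#' QQ-plot data for a p-value vector
#'
#' Sorted observed `-log10` p-values against the expected midpoint plotting
#' positions `-log10((i - 0.5) / n)`. Missing values are dropped; their
#' count is recorded in the `n_missing` attribute.
#'
#' @param p Numeric vector of p-values.
#' @return Tibble with `expected` and `observed` columns.
#' @export
qq_data <- function(p) {
  n_missing <- sum(is.na(p))
  p <- p[!is.na(p)]
  if (!length(p)) stop("no non-missing p-values")
  n <- length(p)
  out <- tibble::tibble(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(sort(p))
  )
  out <- out[order(out$expected), ]
  attr(out, "n_missing") <- n_missing
  out
}
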