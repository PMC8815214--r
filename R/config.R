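#' Simulation configuration for common-variant panels
#'
#' Describes a stratified cohort of two subpopulations whose background SNPs
#' follow the Balding-Nichols model: per SNP an ancestral '1'-allele frequency
#' `p` is drawn uniformly from `ancestral_freq_range`, and each subpopulation's
#' frequency is an independent draw from
#' `Beta(p (1 - fst) / fst, (1 - p)(1 - fst) / fst)`, so that the expected
#' differentiation between the subpopulations equals `fst`.
#'
#' @param n_cohort Number of individuals in the full cohort.
#' @param n_snps Number of background SNPs (default 5000).
#' @param fst Differentiation parameter in (0, 1) (default 0.01).
#' @param pop_fractions Length-2 proportions of the two subpopulations,
#'   summing to 1 (default equal).
#' @param ancestral_freq_range Interval within (0, 1) for the ancestral
#'   '1'-allele frequency (default `c(0.1, 0.9)`).
#' @param candidate_freqs Length-2 vector `(p1, p2)`: '1'-allele frequency of
#'   the separately simulated candidate SNP in each subpopulation.
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return A `sim_config_common` list.
#' @export
sim_config_common <- function(n_cohort,
                              n_snps = 5000L,
                              fst = 0.01,
                              pop_fractions = c(0.5, 0.5),
                              ancestral_freq_range = c(0.1, 0.9),
                              candidate_freqs = c(0.25, 0.85),
                              seed = NULL) {
  stopifnot(
    length(n_cohort) == 1L, n_cohort >= 2,
    length(n_snps) == 1L, n_snps >= 1,
    length(fst) == 1L, fst > 0, fst < 1,
    length(pop_fractions) == 2L, all(pop_fractions > 0),
    abs(sum(pop_fractions) - 1) < 1e-8,
    length(ancestral_freq_range) == 2L,
    ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
    ancestral_freq_range[1] <= ancestral_freq_range[2],
    length(candidate_freqs) == 2L,
    all(candidate_freqs > 0), all(candidate_freqs < 1)
  )
  structure(
    list(
      n_cohort = as.integer(n_cohort),
      n_snps = as.integer(n_snps),
      fst = fst,
      pop_fractions = pop_fractions,
      ancestral_freq_range = ancestral_freq_range,
      candidate_freqs = candidate_freqs,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config_common"
  )
}

#' Simulation configuration for coalescent rare-variant regions
#'
#' Describes a structured-coalescent simulation of a candidate region:
#' `n_haplotypes` lineages split equally across `n_demes` demes of an island
#' model with scaled migration rate `M = 4 Ne m` (ms convention), with
#' infinite-sites mutations at total scaled rate `theta = 4 Ne mu
#' region_length`. Haplotypes are paired at random within deme into diploids.
#'
#' @param n_haplotypes Total haplotypes; must be even and divisible by
#'   `n_demes` (default 10000).
#' @param Ne Effective population size (default 1e5).
#' @param mu Per-site per-generation mutation rate (default 1e-8).
#' @param region_length Region length in bases (default 30000).
#' @param M Scaled migration parameter `4 Ne m` between the demes
#'   (default 10). Ignored when `n_demes = 1`.
#' @param n_demes Number of demes, 1 or 2 (default 2).
#' @param n_subloci Number of independent genealogies the region is split
#'   into (default 1, i.e. no intra-region recombination; see the methods
#'   vignette).
#' @param maf_cap Optional upper bound on sample minor allele frequency for
#'   variants retained in the panel (default `NULL`: all polymorphic sites).
#' @param seed RNG seed, or `NULL`.
#' @return A `sim_config_rare` list.
#' @export
sim_config_rare <- function(n_haplotypes = 10000L,
                            Ne = 1e5,
                            mu = 1e-8,
                            region_length = 30000,
                            M = 10,
                            n_demes = 2L,
                            n_subloci = 1L,
                            maf_cap = NULL,
                            seed = NULL) {
  stopifnot(
    length(n_haplotypes) == 1L, n_haplotypes >= 2,
    n_haplotypes %% 2L == 0L,
    n_demes %in% c(1L, 2L),
    n_haplotypes %% n_demes == 0L,
    (n_haplotypes / n_demes) %% 2L == 0L,
    Ne > 0, mu >= 0, region_length > 0, M > 0,
    n_subloci >= 1L,
    is.null(maf_cap) || (maf_cap > 0 && maf_cap <= 0.5)
  )
  structure(
    list(
      n_haplotypes = as.integer(n_haplotypes),
      Ne = Ne,
      mu = mu,
      region_length = region_length,
      M = M,
      n_demes = as.integer(n_demes),
      n_subloci = as.integer(n_subloci),
      maf_cap = maf_cap,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config_rare"
  )
}

#' Phenotype-model configuration
#'
#' Continuous phenotypes are drawn as
#' `y_j ~ Normal(mu_subpop(j) + beta * G_j, sigma2)` where `G_j` is the
#' candidate dosage (used only when `beta != 0`). The extreme phenotype
#' sample keeps the `floor(tail_fraction * N)` largest and smallest values.
#'
#' @param mu_subpop Length-2 subpopulation phenotype means
#'   (default `c(0.07, -0.07)`).
#' @param sigma2 Residual variance (default 1).
#' @param beta Causal effect size of the candidate dosage (default 0).
#' @param tail_fraction Fraction of the cohort selected per tail, in
#'   (0, 0.5) (default 0.10).
#' @param seed RNG seed, or `NULL`.
#' @return A `pheno_config` list.
#' @export
pheno_config <- function(mu_subpop = c(0.07, -0.07),
                         sigma2 = 1,
                         beta = 0,
                         tail_fraction = 0.10,
                         seed = NULL) {
  stopifnot(
    length(mu_subpop) == 2L,
    length(sigma2) == 1L, sigma2 > 0,
    length(beta) == 1L, is.finite(beta),
    length(tail_fraction) == 1L, tail_fraction > 0, tail_fraction < 0.5
  )
  structure(
    list(
      mu_subpop = mu_subpop,
      sigma2 = sigma2,
      beta = beta,
      tail_fraction = tail_fraction,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "pheno_config"
  )
}

# Derive a 32-bit sub-seed from a root seed and a stream index, so replicate
# streams are decoupled from one another and individually reproducible.
# Splitmix-style integer hash, kept in [1, 2^31 - 2].
derive_seed <- function(root_seed, index) {
  x <- (as.double(root_seed) * 2654435761 + as.double(index) * 40503 + 977) %%
    2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x + 1)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
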