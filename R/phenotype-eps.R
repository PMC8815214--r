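#' Simulate continuous phenotypes
#'
#' Draws `y_j ~ Normal(mu_subpop(j) + beta * G_j, sigma2)` independently
#' across individuals. The candidate dosage `G` enters only when
#' `cfg$beta != 0` (power scenarios); under the null scenarios the phenotype
#' depends on the genotypes only through subpopulation membership.
#'
#' @param cfg A [pheno_config()].
#' @param subpop Integer subpopulation labels.
#' @param dosage Candidate dosage vector; required iff `cfg$beta != 0`.
#' @return Numeric phenotype vector.
#' @export
simulate_phenotype <- function(cfg, subpop, dosage = NULL) {
  stopifnot(inherits(cfg, "pheno_config"))
  if (cfg$beta != 0 && is.null(dosage)) {
    stop("a candidate dosage vector is required when beta != 0")
  }
  if (!is.null(dosage) && length(dosage) != length(subpop)) {
    stop("dosage and subpop lengths differ")
  }
  with_seed(cfg$seed, {
    mu <- cfg$mu_subpop[subpop]
    if (cfg$beta != 0) mu <- mu + cfg$beta * dosage
    stats::rnorm(length(subpop), mean = mu, sd = sqrt(cfg$sigma2))
  })
}

#' Select the extreme phenotype sample
#'
#' Keeps the `floor(tail_fraction * N)` largest and smallest phenotype
#' values. Upper-tail individuals are coded `1`, lower-tail `0`; the 0/1
#' label is the binary trait analysed downstream and is also usable directly
#' as a continuous 0.0/1.0 phenotype for the linear mixed model pathway.
#' Ties at a cutoff are broken by lowest index (strict rank order); with
#' continuous phenotypes ties have probability zero.
#'
#' @param y Numeric phenotype vector for the full cohort (length >= 10).
#' @param tail_fraction Fraction selected per tail, in (0, 0.5).
#' @return A tibble of class `eps_sample` with one row per selected
#'   individual: `index` (position in the cohort), `y` and `group`
#'   (1 = upper tail, 0 = lower tail), ordered by `index`.
#' @export
eps_select <- function(y, tail_fraction = 0.10) {
  n <- length(y)
  if (n < 10) stop("extreme selection needs at least 10 individuals")
  stopifnot(tail_fraction > 0, tail_fraction < 0.5)
  n_tail <- floor(tail_fraction * n)
  if (n_tail < 1) stop("tail_fraction selects zero individuals per tail")
  ord <- order(y, seq_len(n)) # ties broken by lowest index
  lower <- ord[seq_len(n_tail)]
  upper <- ord[seq.int(n - n_tail + 1L, n)]
  out <- tibble::tibble(
    index = c(lower, upper),
    y = y[c(lower, upper)],
    group = rep(c(0L, 1L), each = n_tail)
  )
  out <- out[order(out$index), ]
  class(out) <- c("eps_sample", class(out))
  attr(out, "tail_fraction") <- tail_fraction
  attr(out, "n_cohort") <- n
  out
}
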