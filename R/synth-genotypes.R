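#' Construct a genotype panel
#'
#' Lightweight container for a diploid dosage matrix with per-individual
#' subpopulation labels, realized per-subpopulation allele frequencies and,
#' for sequence-like panels, base positions.
#'
#' @param dosages Integer matrix, individuals x SNPs, entries in \{0, 1, 2\}.
#' @param subpop Integer vector of subpopulation labels (1-based), one per
#'   individual.
#' @param snp_freqs Tibble with one row per SNP giving the realized
#'   '1'-allele frequency per subpopulation (columns `freq1`, `freq2`, ...),
#'   or `NULL`.
#' @param positions Optional numeric vector of per-SNP base positions.
#' @return A `genotype_panel` object.
#' @export
genotype_panel <- function(dosages, subpop, snp_freqs = NULL, positions = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  subpop <- as.integer(subpop)
  stopifnot(
    nrow(dosages) == length(subpop),
    all(is.na(dosages) | dosages %in% 0:2),
    is.null(positions) || length(positions) == ncol(dosages)
  )
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("ind%05d", seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("snp%05d", seq_len(ncol(dosages)))
  }
  structure(
    list(dosages = dosages, subpop = subpop,
         snp_freqs = snp_freqs, positions = positions),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d individuals x %d SNPs, %d subpopulation(s)%s\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$subpop)),
    if (!is.null(x$positions)) sprintf(", region panel") else ""
  ))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Balding-Nichols subpopulation allele frequencies
#'
#' Draws the two subpopulation '1'-allele frequencies for SNPs with ancestral
#' frequency `p` under differentiation `fst`: independent draws from
#' `Beta(p (1 - fst) / fst, (1 - p)(1 - fst) / fst)`, whose mean is `p` and
#' variance `p (1 - p) fst`.
#'
#' @param p Ancestral '1'-allele frequency (vectorized), in (0, 1).
#' @param fst Differentiation parameter in (0, 1).
#' @return Matrix with `length(p)` rows and columns `freq1`, `freq2`.
#' @export
draw_subpop_freqs <- function(p, fst) {
  if (any(p <= 0) || any(p >= 1)) {
    stop("ancestral frequency `p` must lie in the open interval (0, 1)")
  }
  if (length(fst) != 1L || fst <= 0 || fst >= 1) {
    stop("`fst` must be a single value in the open interval (0, 1)")
  }
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  cbind(freq1 = stats::rbeta(length(p), a, b),
        freq2 = stats::rbeta(length(p), a, b))
}

# Subpopulation labels implied by a common-variant config: the first
# round(N * f1) individuals are subpopulation 1, the rest subpopulation 2.
subpop_labels <- function(cfg, n = cfg$n_cohort) {
  n1 <- round(n * cfg$pop_fractions[1])
  c(rep(1L, n1), rep(2L, n - n1))
}

#' Simulate a Balding-Nichols background SNP panel
#'
#' For each SNP an ancestral frequency is drawn uniformly from
#' `cfg$ancestral_freq_range`, subpopulation frequencies via
#' [draw_subpop_freqs()], and dosages as `Binomial(2, p_subpop)`
#' (Hardy-Weinberg equilibrium within subpopulation). The candidate SNP is
#' never part of this panel; see [simulate_candidate()].
#'
#' @param cfg A [sim_config_common()] configuration.
#' @param subpop Optional integer vector of subpopulation labels; defaults to
#'   the deterministic split implied by `cfg$pop_fractions`. Supplying labels
#'   lets callers simulate genotypes for an ascertained subset of a cohort.
#' @return A [genotype_panel()].
#' @export
simulate_panel <- function(cfg, subpop = NULL) {
  stopifnot(inherits(cfg, "sim_config_common"))
  with_seed(cfg$seed, {
    if (is.null(subpop)) subpop <- subpop_labels(cfg)
    n <- length(subpop)
    s <- cfg$n_snps
    p_anc <- stats::runif(s, cfg$ancestral_freq_range[1],
                          cfg$ancestral_freq_range[2])
    fr <- draw_subpop_freqs(p_anc, cfg$fst)
    # per-individual success probability depends only on subpopulation
    dos <- matrix(0L, n, s)
    for (k in 1:2) {
      idx <- which(subpop == k)
      if (length(idx)) {
        dos[idx, ] <- stats::rbinom(length(idx) * s, 2L,
                                    rep(fr[, k], each = length(idx)))
      }
    }
    genotype_panel(
      dos, subpop,
      snp_freqs = tibble::tibble(snp_id = sprintf("snp%05d", seq_len(s)),
                                 ancestral = p_anc,
                                 freq1 = fr[, 1], freq2 = fr[, 2])
    )
  })
}

#' Simulate the candidate SNP
#'
#' The candidate SNP is generated separately from the background panel, with
#' subpopulation-specific '1'-allele frequencies `cfg$candidate_freqs`
#' (dosage `Binomial(2, p_k)` in subpopulation `k`). Under the null scenarios
#' it is independent of both the panel and the phenotype; setting
#' `p1 = p2` gives the no-stratification control.
#'
#' @param cfg A [sim_config_common()] configuration with `candidate_freqs`.
#' @param subpop Integer subpopulation labels of the individuals to simulate;
#'   defaults to the cohort split implied by `cfg`.
#' @return Integer dosage vector.
#' @export
simulate_candidate <- function(cfg, subpop = NULL) {
  stopifnot(inherits(cfg, "sim_config_common"))
  if (is.null(subpop)) subpop <- subpop_labels(cfg)
  stats::rbinom(length(subpop), 2L, cfg$candidate_freqs[subpop])
}

#' Simulate a coalescent rare-variant region
#'
#' Simulates a symmetric island-model structured coalescent for
#' `cfg$n_haplotypes` lineages split across `cfg$n_demes` demes (pairwise
#' coalescence at rate 1 per pair within deme on the 2*Ne-generation time
#' scale; per-lineage migration at rate `M/2`), drops infinite-sites
#' mutations on branches at total rate `theta/2` with
#' `theta = 4 Ne mu region_length`, and pairs haplotypes uniformly at random
#' within deme into diploid dosages. With `n_subloci > 1` the region is split
#' into independent genealogies, each carrying `theta / n_subloci`.
#'
#' Monomorphic output (e.g. `mu = 0`) yields an empty panel with a warning.
#'
#' @param cfg A [sim_config_rare()] configuration.
#' @param n_per_deme Optional integer vector overriding the per-deme
#'   haplotype counts (each even); defaults to an equal split of
#'   `cfg$n_haplotypes`. Sampling consistency of the coalescent makes the
#'   genealogy of a subsample itself a structured coalescent, so ascertained
#'   subsets of a larger cohort can be simulated directly.
#' @return A [genotype_panel()] with `positions`.
#' @export
simulate_coalescent_region <- function(cfg, n_per_deme = NULL) {
  stopifnot(inherits(cfg, "sim_config_rare"))
  with_seed(cfg$seed, {
    if (is.null(n_per_deme)) {
      n_per_deme <- rep(cfg$n_haplotypes / cfg$n_demes, cfg$n_demes)
    }
    n_per_deme <- as.integer(n_per_deme)
    if (any(n_per_deme %% 2L != 0L) || any(n_per_deme <= 0L)) {
      stop("each deme needs a positive, even haplotype count for diploid pairing")
    }
    theta <- 4 * cfg$Ne * cfg$mu * cfg$region_length
    k <- cfg$n_subloci
    n_hap <- sum(n_per_deme)

    hap_cols <- list(); pos <- numeric(0)
    bounds <- round(seq(0, cfg$region_length, length.out = k + 1))
    for (j in seq_len(k)) {
      sim <- sim_island_genealogy(n_per_deme, M = cfg$M)
      mut <- drop_mutations(sim, theta = theta / k, n_hap = n_hap)
      if (length(mut$carriers)) {
        hap_cols <- c(hap_cols, mut$carriers)
        pos <- c(pos, bounds[j] + stats::runif(length(mut$carriers),
                                               0, bounds[j + 1] - bounds[j]))
      }
    }
    hap_deme <- rep(seq_along(n_per_deme), n_per_deme)

    # uniform random perfect matching within deme
    ind_of_hap <- integer(n_hap)
    n_ind <- n_hap / 2L
    off <- 0L
    for (d in seq_along(n_per_deme)) {
      haps <- which(hap_deme == d)
      haps <- haps[sample.int(length(haps))]
      ind_of_hap[haps] <- off + rep(seq_len(length(haps) / 2L), each = 2L)
      off <- off + length(haps) %/% 2L
    }
    subpop <- integer(n_ind)
    subpop[ind_of_hap] <- hap_deme

    s <- length(hap_cols)
    if (s == 0L) {
      warning("no segregating sites in simulated region; returning empty panel")
      return(genotype_panel(matrix(0L, n_ind, 0), subpop,
                            snp_freqs = tibble::tibble(snp_id = character(0)),
                            positions = numeric(0)))
    }
    dos <- matrix(0L, n_ind, s)
    for (v in seq_len(s)) {
      tab <- tabulate(ind_of_hap[hap_cols[[v]]], nbins = n_ind)
      dos[, v] <- tab
    }
    # drop sites monomorphic among the diploids and apply the optional MAF cap
    freq <- colMeans(dos) / 2
    keep <- freq > 0 & freq < 1
    if (!is.null(cfg$maf_cap)) keep <- keep & pmin(freq, 1 - freq) <= cfg$maf_cap
    dos <- dos[, keep, drop = FALSE]
    pos <- pos[keep]
    ord <- order(pos)
    dos <- dos[, ord, drop = FALSE]
    pos <- pos[ord]
    if (ncol(dos) == 0L) {
      warning("no polymorphic sites retained in simulated region")
    }
    f1 <- if (any(subpop == 1L)) colMeans(dos[subpop == 1L, , drop = FALSE]) / 2 else rep(NA_real_, ncol(dos))
    f2 <- if (any(subpop == 2L)) colMeans(dos[subpop == 2L, , drop = FALSE]) / 2 else rep(NA_real_, ncol(dos))
    colnames(dos) <- sprintf("rv%05d", seq_len(ncol(dos)))
    genotype_panel(
      dos, subpop,
      snp_freqs = tibble::tibble(snp_id = colnames(dos), freq1 = f1, freq2 = f2),
      positions = pos
    )
  })
}

# Structured-coalescent genealogy for an island model.
# Returns parent/child arrays with branch lengths, time in 2*Ne generations.
# Leaves are nodes 1..n; internal nodes are appended in coalescence order.
sim_island_genealogy <- function(n_per_deme, M) {
  n <- sum(n_per_deme)
  n_demes <- length(n_per_deme)
  # active lineages per deme (node ids)
  active <- split(seq_len(n), rep(seq_len(n_demes), n_per_deme))
  active <- lapply(seq_len(n_demes), function(d) active[[as.character(d)]] %||% integer(0))
  node_time <- numeric(2L * n - 1L)
  child1 <- child2 <- integer(n - 1L)
  t_now <- 0
  next_node <- n + 1L
  repeat {
    k <- lengths(active)
    if (sum(k) == 1L) break
    coal_rate <- k * (k - 1) / 2
    mig_rate <- if (n_demes > 1L) k * M / 2 else rep(0, n_demes)
    total <- sum(coal_rate) + sum(mig_rate)
    t_now <- t_now + stats::rexp(1L, total)
    u <- stats::runif(1L, 0, total)
    if (u <= sum(coal_rate)) {
      d <- sample.int(n_demes, 1L, prob = coal_rate)
      pick <- sample.int(k[d], 2L)
      a <- active[[d]][pick[1]]; b <- active[[d]][pick[2]]
      node_time[next_node] <- t_now
      child1[next_node - n] <- a
      child2[next_node - n] <- b
      active[[d]] <- c(active[[d]][-pick], next_node)
      next_node <- next_node + 1L
    } else {
      d <- sample.int(n_demes, 1L, prob = mig_rate)
      pick <- sample.int(k[d], 1L)
      lineage <- active[[d]][pick]
      active[[d]] <- active[[d]][-pick]
      dest <- if (n_demes == 2L) 3L - d else sample(setdiff(seq_len(n_demes), d), 1L)
      active[[dest]] <- c(active[[dest]], lineage)
    }
  }
  list(n = n, node_time = node_time, child1 = child1, child2 = child2)
}

# Drop infinite-sites mutations on the genealogy at total rate theta/2 per
# unit branch length; returns, per mutation, the vector of carrier leaves.
drop_mutations <- function(sim, theta, n_hap) {
  n <- sim$n
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  for (i in seq_len(n - 1L)) {
    parent[sim$child1[i]] <- n + i
    parent[sim$child2[i]] <- n + i
  }
  # branch length above each non-root node
  has_parent <- parent > 0L
  blen <- numeric(n_nodes)
  blen[has_parent] <- sim$node_time[parent[has_parent]] - sim$node_time[has_parent]
  total_len <- sum(blen)
  n_mut <- stats::rpois(1L, theta / 2 * total_len)
  if (n_mut == 0L) return(list(carriers = list()))
  branch <- sample.int(n_nodes, n_mut, replace = TRUE, prob = blen)
  # leaf sets per node, built bottom-up (children precede parents by id order)
  leafset <- vector("list", n_nodes)
  for (i in seq_len(n)) leafset[[i]] <- i
  for (i in seq_len(n - 1L)) {
    leafset[[n + i]] <- c(leafset[[sim$child1[i]]], leafset[[sim$child2[i]]])
  }
  list(carriers = lapply(branch, function(b) leafset[[b]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
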