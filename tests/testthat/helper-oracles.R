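# Independent oracles used across the test suite. These deliberately avoid
# the package's own code paths.

# Weir-Cockerham multi-SNP Fst estimator (ratio-of-sums), two subpopulations,
# from a dosage matrix and subpopulation labels.
wc_fst <- function(dosages, subpop) {
  pops <- sort(unique(subpop))
  r <- length(pops)
  n_i <- vapply(pops, function(k) sum(subpop == k), numeric(1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  a_sum <- 0
  bc_sum <- 0
  for (s in seq_len(ncol(dosages))) {
    x <- dosages[, s]
    p_i <- vapply(pops, function(k) mean(x[subpop == k]) / 2, numeric(1))
    h_i <- vapply(pops, function(k) mean(x[subpop == k] == 1), numeric(1))
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    bc_sum <- bc_sum + a + b + cc
  }
  a_sum / bc_sum
}

# Exact Hardy-Weinberg test (Wigginton et al. style) from genotype counts.
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  het_obs <- n_ab
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hets, function(h) {
    homr <- (rare - h) / 2
    homc <- n - h - homr
    lfactorial(n) - lfactorial(h) - lfactorial(homr) - lfactorial(homc) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(het_obs, hets)] * (1 + 1e-12)])
}

# Share of subpopulation 1 in the upper tail of the two-component normal
# mixture, by numerical root-finding/integration.
upper_tail_share <- function(mu1, mu2, sigma2, tail_fraction,
                             w1 = 0.5) {
  sd <- sqrt(sigma2)
  f <- function(t) {
    w1 * stats::pnorm(t, mu1, sd, lower.tail = FALSE) +
      (1 - w1) * stats::pnorm(t, mu2, sd, lower.tail = FALSE) - tail_fraction
  }
  t <- stats::uniroot(f, c(-10, 10), tol = 1e-12)$root
  w1 * stats::pnorm(t, mu1, sd, lower.tail = FALSE) / tail_fraction
}

# Dense restricted log-likelihood of the LMM at a given variance ratio,
# computed with plain matrix algebra (no spectral shortcut).
dense_reml_loglik <- function(lambda, y, X, G) {
  n <- length(y)
  p <- ncol(X)
  H <- lambda * G + diag(n)
  Hi <- solve(H)
  XtHiX <- t(X) %*% Hi %*% X
  beta <- solve(XtHiX, t(X) %*% Hi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Hi %*% r)
  sigma_e2 <- rss / (n - p)
  as.numeric(-0.5 * ((n - p) * log(2 * pi * sigma_e2) +
                       determinant(H, logarithm = TRUE)$modulus +
                       determinant(XtHiX, logarithm = TRUE)$modulus -
                       determinant(crossprod(X), logarithm = TRUE)$modulus +
                       (n - p)))
}

# Dense GLS Wald test with explicit covariance solve.
dense_gls_wald <- function(lambda, y, X, G, g) {
  n <- length(y)
  Xg <- cbind(X, g)
  H <- lambda * G + diag(n)
  Hi <- solve(H)
  XtHiX <- t(Xg) %*% Hi %*% Xg
  beta <- solve(XtHiX, t(Xg) %*% Hi %*% y)
  r <- y - Xg %*% beta
  sigma_e2 <- drop(t(r) %*% Hi %*% r) / (n - ncol(Xg))
  covb <- solve(XtHiX) * sigma_e2
  j <- ncol(Xg)
  stat <- beta[j] / sqrt(covb[j, j])
  list(beta = beta[j], stat = stat,
       p = 2 * stats::pt(-abs(stat), n - ncol(Xg)))
}

# Independent PQL fixed point: alternate full dense mixed-model working-LMM
# solves (Henderson system) with a bisection root of the REML score in tau.
dense_pql_fit <- function(y, X, G, tol = 1e-8, maxit = 200) {
  n <- length(y)
  alpha <- rep(0, ncol(X))
  eta <- drop(X %*% alpha)
  tau <- 0.3
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-10)
    Yt <- eta + (y - mu) / W
    score_tau <- function(tt) {
      S <- diag(1 / W) + tt * G
      Si <- solve(S)
      XtSiX <- t(X) %*% Si %*% X
      P <- Si - Si %*% X %*% solve(XtSiX, t(X) %*% Si)
      PY <- P %*% Yt
      -0.5 * (sum(diag(P %*% G)) - drop(t(PY) %*% G %*% PY))
    }
    # root of the REML score in tau (or boundary at ~0)
    lo <- 1e-6; hi <- 5
    if (score_tau(lo) <= 0) {
      tau_new <- 0
    } else {
      while (score_tau(hi) > 0 && hi < 1000) hi <- hi * 2
      tau_new <- stats::uniroot(score_tau, c(lo, hi), tol = 1e-10)$root
    }
    S <- diag(1 / W) + tau_new * G
    Si <- solve(S)
    XtSiX <- t(X) %*% Si %*% X
    alpha_new <- drop(solve(XtSiX, t(X) %*% Si %*% Yt))
    resid <- Yt - X %*% alpha_new
    b <- tau_new * drop(G %*% Si %*% resid)
    eta_new <- drop(X %*% alpha_new) + b
    if (max(abs(c(alpha_new - alpha, tau_new - tau))) <
        tol * max(1, max(abs(c(alpha_new, tau_new))))) {
      return(list(tau = tau_new, alpha = alpha_new))
    }
    alpha <- alpha_new; tau <- tau_new; eta <- eta_new
  }
  list(tau = tau, alpha = alpha)
}

# Long-to-wide p-value matrix (one row per replicate, column per method).
pvalue_matrix <- function(pvalues) {
  methods <- unique(pvalues$method)
  sapply(methods, function(m) {
    sel <- pvalues$method == m
    pvalues$p_value[sel][order(pvalues$replicate[sel])]
  })
}

# Small stratified fixture shared by several association tests.
make_strat_fixture <- function(n_cohort = 1200, n_snps = 600, seed = 101,
                               candidate_freqs = c(0.25, 0.85)) {
  set.seed(seed)
  sc <- sim_config_common(n_cohort = n_cohort, n_snps = n_snps,
                          candidate_freqs = candidate_freqs)
  sub <- rep(1:2, length.out = n_cohort)
  y <- simulate_phenotype(pheno_config(), sub)
  eps <- eps_select(y, 0.1)
  subs <- sub[eps$index]
  panel <- simulate_panel(sc, subpop = subs)
  g <- simulate_candidate(sc, subs)
  list(eps = eps, panel = panel, g = g, subpop = subs,
       rel = compute_grm(panel))
}
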