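make_glmm_fixture <- function(n = 60, p_snps = 120, seed = 41, tau = 0.4) {
  set.seed(seed)
  X <- matrix(stats::rbinom(n * p_snps, 2, stats::runif(p_snps, 0.2, 0.8)),
              nrow = n, byrow = TRUE)
  rel <- compute_grm(X)
  b <- drop(chol(rel$grm + 1e-6 * diag(n)) %*% stats::rnorm(n)) * sqrt(tau)
  y <- stats::rbinom(n, 1, stats::plogis(0.2 + b))
  g <- stats::rbinom(n, 2, 0.3)
  list(y = y, g = g, rel = rel, G = rel$grm)
}

test_that("with tau fixed at zero the PQL fit is plain logistic regression", {
  fx <- make_glmm_fixture()
  fit0 <- fit_glmm_null(fx$y, fx$rel, tau = 0)
  ref <- stats::glm(fx$y ~ 1, family = stats::binomial())
  expect_equal(unname(fit0$alpha_hat), unname(stats::coef(ref)),
               tolerance = 1e-7)
  expect_equal(unname(fit0$mu_hat), unname(stats::fitted(ref)),
               tolerance = 1e-7)

  # balanced labels, intercept-only: logit(0.5) = 0
  y_bal <- rep(0:1, each = 30)
  fitb <- fit_glmm_null(y_bal, fx$rel, tau = 0)
  expect_equal(unname(fitb$alpha_hat[1]), 0, tolerance = 1e-8)
})

test_that("PQL/AI-REML matches an independent dense fixed-point solver", {
  fx <- make_glmm_fixture(seed = 42)
  fit <- fit_glmm_null(fx$y, fx$rel)
  oracle <- dense_pql_fit(fx$y, matrix(1, length(fx$y), 1), fx$G)
  expect_equal(fit$tau_hat, oracle$tau, tolerance = 1e-4)
  expect_equal(unname(fit$alpha_hat), unname(oracle$alpha), tolerance = 1e-4)
  expect_true(fit$converged)
  # the projection annihilates the covariate space
  expect_lt(max(abs(fit$working_P %*% fit$X)), 1e-6)
})

test_that("the GLMM score test matches the classical logistic score test", {
  # 2x3 genotype-by-group table, tau = 0, intercept only
  counts0 <- c(25, 10, 5) # genotype 0/1/2 in group 0
  counts1 <- c(15, 18, 12)
  g <- c(rep(0:2, counts0), rep(0:2, counts1))
  y <- c(rep(0, sum(counts0)), rep(1, sum(counts1)))
  n <- length(y)
  rel <- as_relatedness_model(diag(n))
  fit <- fit_glmm_null(y, rel, tau = 0)
  res <- glmm_score_test(fit, g)
  # textbook score test: T = g'(y - ybar), var = ybar(1-ybar) * g'(I - 11'/n)g
  Tm <- sum(g * (y - mean(y)))
  vr <- mean(y) * (1 - mean(y)) * sum((g - mean(g))^2)
  expect_equal(res$stat, Tm / sqrt(vr), tolerance = 1e-8)
  expect_equal(res$p_value, 2 * stats::pnorm(-abs(Tm / sqrt(vr))),
               tolerance = 1e-10)

  # degenerate variant
  expect_true(is.na(glmm_score_test(fit, rep(2, n))$p_value))
})

test_that("score test is invariant to consistent permutation of individuals", {
  fx <- make_glmm_fixture(seed = 43)
  fit <- fit_glmm_null(fx$y, fx$rel)
  p0 <- glmm_score_test(fit, fx$g)$p_value
  perm <- sample.int(length(fx$y))
  fit_p <- fit_glmm_null(fx$y[perm], as_relatedness_model(fx$G[perm, perm]))
  expect_equal(glmm_score_test(fit_p, fx$g[perm])$p_value, p0,
               tolerance = 1e-6)
})

test_that("burden test collapses to the single-variant score test and scales out weights", {
  fx <- make_glmm_fixture(seed = 44)
  fit <- fit_glmm_null(fx$y, fx$rel)
  g_rare <- stats::rbinom(length(fx$y), 2, 0.04)
  set1 <- variant_set(matrix(g_rare, ncol = 1), weights = 1)
  expect_equal(burden_test(fit, set1),
               glmm_score_test(fit, g_rare)$p_value, tolerance = 1e-12)

  dos <- matrix(stats::rbinom(length(fx$y) * 8, 2, 0.05), ncol = 8)
  w <- stats::runif(8, 0.5, 2)
  p1 <- smmat_tests(fit, variant_set(dos, weights = w))
  p2 <- smmat_tests(fit, variant_set(dos, weights = 2 * w))
  expect_equal(p1$p_burden, p2$p_burden, tolerance = 1e-12)
  expect_equal(p1$p_skat, p2$p_skat, tolerance = 1e-12)
  expect_equal(p1$p_skato, p2$p_skato, tolerance = 1e-10)
  expect_equal(p1$p_hybrid, p2$p_hybrid, tolerance = 1e-12)
})

test_that("set tests are invariant to variant ordering", {
  fx <- make_glmm_fixture(seed = 45)
  fit <- fit_glmm_null(fx$y, fx$rel)
  dos <- matrix(stats::rbinom(length(fx$y) * 10, 2, 0.05), ncol = 10)
  perm <- sample.int(10)
  r1 <- smmat_tests(fit, variant_set(dos))
  r2 <- smmat_tests(fit, variant_set(dos[, perm]))
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("a single-variant SKAT reduces to the squared score statistic", {
  fx <- make_glmm_fixture(seed = 46)
  fit <- fit_glmm_null(fx$y, fx$rel)
  g_rare <- stats::rbinom(length(fx$y), 2, 0.06)
  sv <- glmm_score_test(fit, g_rare)
  set1 <- variant_set(matrix(g_rare, ncol = 1), weights = 1)
  # rank-1 quadratic form: chi-square with 1 df of the squared z-score
  p_expected <- stats::pchisq(sv$stat^2, 1, lower.tail = FALSE)
  expect_equal(skat_test(fit, set1), p_expected, tolerance = 1e-8)
  expect_equal(skat_test(fit, set1, method = "exact"), p_expected,
               tolerance = 1e-5)
  expect_equal(skat_o_test(fit, set1), p_expected, tolerance = 1e-8)
})

test_that("quadratic-form tail probabilities match a Monte-Carlo mixture oracle", {
  lambda <- c(3.1, 2.2, 1.4, 0.7, 0.2)
  set.seed(47)
  draws <- colSums(lambda * matrix(stats::rchisq(5 * 1e6, 1), nrow = 5))
  for (q in stats::quantile(draws, c(0.8, 0.9, 0.95, 0.99))) {
    p_mc <- mean(draws > q)
    p_liu <- epstrat:::liu_pvalue(q, c(sum(lambda), sum(lambda^2),
                                       sum(lambda^3), sum(lambda^4)))
    p_imhof <- epstrat:::imhof_pvalue(q, lambda)
    expect_lt(abs(p_liu - p_mc) / p_mc, 0.10)
    expect_lt(abs(p_imhof - p_mc) / p_mc, 0.05)
  }
})

test_that("SKAT-O recovers its kernel limits on a degenerate grid", {
  fx <- make_glmm_fixture(seed = 48)
  fit <- fit_glmm_null(fx$y, fx$rel)
  dos <- matrix(stats::rbinom(length(fx$y) * 12, 2, 0.05), ncol = 12)
  set <- variant_set(dos)
  res <- smmat_tests(fit, set)
  ker <- epstrat:::set_kernel(fit, set)
  p_rho0 <- epstrat:::skat_o_pvalue(ker, rho_grid = 0)
  p_rho1 <- epstrat:::skat_o_pvalue(ker, rho_grid = 1)
  expect_equal(p_rho0, res$p_skat, tolerance = 0.03)
  expect_equal(p_rho1, res$p_burden, tolerance = 0.03)
  # the optimal combination cannot beat its best component by construction
  expect_gte(res$p_skato, min(res$p_skat, res$p_burden) * 0.99)
})

test_that("sample-space kernel reproduces a dense variant-space computation", {
  # wide set (more variants than individuals) exercises the Cholesky route
  set.seed(49)
  n <- 70
  fx <- make_glmm_fixture(n = n, seed = 49)
  fit <- fit_glmm_null(fx$y, fx$rel)
  dos <- matrix(stats::rbinom(n * 90, 2, 0.06), ncol = 90)
  set <- variant_set(dos)
  res <- smmat_tests(fit, set, method = "liu")

  # dense oracle entirely in variant space
  Gw <- sweep(set$dosages, 2, set$weights, "*")
  U <- drop(crossprod(Gw, fx$y - fit$mu_hat))
  V <- crossprod(Gw, fit$working_P %*% Gw)
  s1 <- sum(V)
  p_burden <- 2 * stats::pnorm(-abs(sum(U)) / sqrt(s1))
  lam <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-10 * max(lam)]
  p_skat <- epstrat:::liu_pvalue(sum(U^2), c(sum(lam), sum(lam^2),
                                             sum(lam^3), sum(lam^4)))
  v1 <- drop(V %*% rep(1, ncol(V)))
  U_adj <- U - v1 * sum(U) / s1
  A <- V - tcrossprod(v1) / s1
  lamA <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lamA <- lamA[lamA > 1e-10 * max(lamA)]
  p_adj <- epstrat:::liu_pvalue(sum(U_adj^2), c(sum(lamA), sum(lamA^2),
                                                sum(lamA^3), sum(lamA^4)))
  p_hybrid <- stats::pchisq(-2 * (log(p_burden) + log(p_adj)), 4,
                            lower.tail = FALSE)
  expect_equal(res$p_burden, p_burden, tolerance = 1e-9)
  expect_equal(res$p_skat, p_skat, tolerance = 1e-7)
  expect_equal(res$p_hybrid, p_hybrid, tolerance = 1e-6)
})

test_that("hybrid components behave as an orthogonal decomposition", {
  fx <- make_glmm_fixture(seed = 50)
  fit <- fit_glmm_null(fx$y, fx$rel)
  # set where every variant is the same column: burden captures everything
  g_rare <- stats::rbinom(length(fx$y), 2, 0.1)
  dos_same <- cbind(g_rare, g_rare, g_rare)
  res <- smmat_tests(fit, variant_set(dos_same, weights = rep(1, 3)))
  expect_equal(res$p_hybrid,
               stats::pchisq(-2 * log(res$p_burden), 4, lower.tail = FALSE),
               tolerance = 1e-6)

  # under the null the two hybrid components are asymptotically independent
  set.seed(51)
  n <- 80
  X <- matrix(stats::rbinom(n * 150, 2, 0.4), nrow = n)
  rel <- compute_grm(X)
  comps <- t(vapply(1:150, function(i) {
    y <- stats::rbinom(n, 1, 0.5)
    fit_i <- fit_glmm_null(y, rel, tau = 0)
    dos <- matrix(stats::rbinom(n * 10, 2, 0.06), ncol = 10)
    ker <- epstrat:::set_kernel(fit_i, variant_set(dos))
    pb <- 2 * stats::pnorm(-abs(ker$TB) / sqrt(ker$s1))
    U_adj <- ker$U - ker$v1 * ker$TB / ker$s1
    pa <- epstrat:::qf_pvalue(sum(U_adj^2), mom = ker$mom_adj())
    c(pb, pa)
  }, numeric(2)))
  ct <- stats::cor.test(-log(comps[, 1]), -log(comps[, 2]))
  expect_gt(ct$p.value, 0.001)
})
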