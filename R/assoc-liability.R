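#' Estimate latent liabilities by regularized probit MAP
#'
#' Liability-threshold view of the binary tail indicator: each individual
#' carries an unobserved liability `z_i = x_i' beta_g + e_i` and is in the
#' upper group when the liability exceeds a threshold. The genetic
#' coefficients are estimated as the posterior mode (MAP) of a probit model
#' with a Gaussian (ridge) prior:
#' maximize `sum_i log Phi((2 y_i - 1)(x_i' beta_g + beta_0)) -
#' (lambda_r / 2) ||beta_g||^2`
#' by Newton ascent. The estimated liability is the genetic component only,
#' `zhat_i = x_i' betahat_g`.
#'
#' With many more SNPs than individuals the ascent runs in the dual: the
#' optimum satisfies `beta_g = X' a`, so the problem reduces to the
#' eigenbasis of `K = X X'` (proportional to the standardized GRM), making
#' each Newton step O(n^3) instead of O(p^3).
#'
#' The default regularization treats the prior as per-SNP effect variance
#' `h2 / p` against residual variance `1 - h2`, i.e.
#' `lambda_r = p (1 - h2) / h2` with heritability parameter `h2 = 0.5`.
#'
#' @param y Binary 0/1 response.
#' @param geno A [genotype_panel()] or dosage matrix (individuals x SNPs);
#'   the candidate SNP must not be included (mirror of its exclusion from
#'   the GRM).
#' @param exclude SNP indices to drop before fitting.
#' @param ridge_lambda Regularization strength `lambda_r > 0`; default
#'   `p (1 - h2) / h2`.
#' @param h2 Heritability parameter used for the default `ridge_lambda`.
#' @param standardize Standardize dosage columns as for the GRM (default
#'   `TRUE`; set `FALSE` for pre-standardized or artificial matrices).
#' @param rel Optional `relatedness_model` computed from the *same*
#'   standardized genotype matrix; its cached eigendecomposition is then
#'   reused for `K = p * GRM` instead of decomposing `K` afresh.
#' @param tol,maxit Newton convergence controls.
#' @return A `liability_fit`: `beta_g_hat` (per retained SNP), `beta0_hat`,
#'   `z_hat`, `ridge_lambda`, `converged`.
#' @export
estimate_liabilities <- function(y, geno, exclude = integer(0),
                                 ridge_lambda = NULL, h2 = 0.5,
                                 standardize = TRUE, rel = NULL,
                                 tol = 1e-10, maxit = 50L) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  X <- if (inherits(geno, "genotype_panel")) geno$dosages else as.matrix(geno)
  if (length(exclude)) X <- X[, -exclude, drop = FALSE]
  if (nrow(X) != length(y)) stop("genotype rows do not match response length")
  X <- X * 1.0
  if (standardize) {
    phat <- colMeans(X) / 2
    poly <- phat > 0 & phat < 1
    X <- X[, poly, drop = FALSE]
    phat <- phat[poly]
    X <- sweep(sweep(X, 2L, 2 * phat, "-"), 2L,
               sqrt(2 * phat * (1 - phat)), "/")
  }
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(ridge_lambda)) {
    stopifnot(h2 > 0, h2 < 1)
    ridge_lambda <- max(p, 1) * (1 - h2) / h2
  }
  if (ridge_lambda <= 0) stop("ridge_lambda must be positive")

  if (!is.null(rel) && standardize &&
      isTRUE(rel$n_snps_used == p) && nrow(rel$grm) == n) {
    e <- grm_eigen(rel)
    evals <- e$values * p
  } else {
    e <- eigen(tcrossprod(X), symmetric = TRUE)
    evals <- pmax(e$values, 0)
  }
  keep <- evals > 1e-10 * max(evals, 1)
  U <- e$vectors[, keep, drop = FALSE]
  s <- evals[keep]
  r <- length(s)
  sgn <- 2 * y - 1

  d <- numeric(r)
  b0 <- stats::qnorm(pmin(pmax(mean(y), 1e-6), 1 - 1e-6))
  eta <- rep(b0, n)
  objective <- function(eta, d) {
    sum(stats::pnorm(sgn * eta, log.p = TRUE)) -
      ridge_lambda / 2 * sum(d^2 / s)
  }
  obj <- objective(eta, d)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    u <- sgn * eta
    m <- exp(stats::dnorm(u, log = TRUE) - stats::pnorm(u, log.p = TRUE))
    grad_eta <- sgn * m
    w <- u * m + m^2 # negative curvature of log Phi, in (0, 1)
    if (r > 0) {
      gd <- drop(crossprod(U, grad_eta)) - ridge_lambda * d / s
      g0 <- sum(grad_eta)
      UW <- U * w
      H <- rbind(cbind(crossprod(U, UW) + diag(ridge_lambda / s, r),
                       colSums(UW)),
                 c(colSums(UW), sum(w)))
      step <- solve(H, c(gd, g0))
      step_d <- step[seq_len(r)]
      step_b0 <- step[r + 1L]
    } else {
      step_d <- numeric(0)
      step_b0 <- sum(grad_eta) / sum(w)
    }
    # step halving to guarantee ascent of the strictly concave objective
    h <- 1
    repeat {
      d_new <- d + h * step_d
      b0_new <- b0 + h * step_b0
      eta_new <- (if (r > 0) drop(U %*% d_new) else 0) + b0_new
      obj_new <- objective(eta_new, d_new)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      h <- h / 2
      if (h < 1e-8) {
        stop("probit MAP ascent failed to make progress; ",
             "increase ridge_lambda")
      }
    }
    if (max(abs(eta_new)) > 30) {
      stop("probit MAP estimates diverging (near-separable data); ",
           "increase ridge_lambda")
    }
    delta <- abs(obj_new - obj)
    d <- d_new; b0 <- b0_new; eta <- eta_new; obj <- obj_new
    if (delta < tol * (abs(obj) + 1)) {
      converged <- TRUE
      break
    }
  }
  alpha <- if (r > 0) drop(U %*% (d / s)) else numeric(n)
  beta_g <- drop(crossprod(X, alpha))
  z_hat <- if (r > 0) drop(U %*% d) else numeric(n)
  structure(
    list(beta_g_hat = beta_g, beta0_hat = b0, z_hat = z_hat,
         ridge_lambda = ridge_lambda, n_snps_used = p,
         loglik_penalized = obj, converged = converged, n = n),
    class = "liability_fit"
  )
}

#' Liability-threshold association test
#'
#' Tests a candidate variant against the estimated liabilities with the
#' linear mixed model: [fit_lmm_null()] on `z_hat` (liabilities are treated
#' as a normally distributed quantitative trait), then [lmm_score_test()]
#' on the candidate dosage. The candidate must have been excluded from the
#' liability-estimation genotype matrix and from the GRM.
#'
#' @param fit A `liability_fit`.
#' @param rel A `relatedness_model`.
#' @param g Candidate dosage vector.
#' @param X Optional fixed covariates (e.g. ancestry principal components)
#'   for the liability-scale mixed model.
#' @param ... Passed to [lmm_score_test()].
#' @return One-row tibble as in [lmm_score_test()]; degenerate (constant)
#'   liabilities yield a missing p-value.
#' @export
liability_assoc <- function(fit, rel, g, X = NULL, ...) {
  stopifnot(inherits(fit, "liability_fit"))
  if (stats::var(fit$z_hat) < 1e-14) {
    return(tibble::tibble(beta_hat = NA_real_, se = NA_real_,
                          stat = NA_real_, p_value = NA_real_,
                          n_used = fit$n))
  }
  null <- fit_lmm_null(fit$z_hat, rel, X = X)
  lmm_score_test(null, g, ...)
}
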