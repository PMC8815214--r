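#' Fit the null logistic mixed model by PQL with AI-REML
#'
#' Model: `logit(p_i) = x_i' alpha + b_i` with `b ~ N(0, tau G)`. The fit
#' alternates penalized quasi-likelihood steps — working response
#' `Ytilde = eta + W^{-1}(y - mu)` with `W = diag(mu (1 - mu))`, generalized
#' least squares for `alpha` under `Sigma = W^{-1} + tau G` — with
#' average-information REML updates of the variance component `tau` on the
#' working linear mixed model, to joint convergence (relative change
#' `< tol`, at most `maxit` iterations). `tau` is floored at zero. One null
#' fit serves the score tests of every candidate variant.
#'
#' @param y Binary 0/1 response.
#' @param rel A `relatedness_model`.
#' @param X Covariates (intercept added when absent).
#' @param tau Fix the variance component at this value instead of estimating
#'   it (`tau = 0` reduces the fit to plain logistic IRLS).
#' @param tol Convergence tolerance on relative parameter change.
#' @param maxit Maximum outer iterations.
#' @return A `glmm_null_fit`: `tau_hat`, `alpha_hat`, `mu_hat`, residuals
#'   `y - mu_hat`, the projection matrix `P = Sigma^{-1} - Sigma^{-1} X
#'   (X' Sigma^{-1} X)^{-1} X' Sigma^{-1}`, and a `converged` flag.
#' @export
fit_glmm_null <- function(y, rel, X = NULL, tau = NULL,
                          tol = 1e-6, maxit = 100L) {
  stopifnot(inherits(rel, "relatedness_model"))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  n <- length(y)
  if (n != nrow(rel$grm)) stop("response length does not match GRM order")
  X <- prep_covariates(X, n)
  G <- rel$grm
  fixed_tau <- !is.null(tau)

  glm0 <- stats::glm.fit(X, y, family = stats::binomial())
  alpha <- glm0$coefficients
  eta <- drop(X %*% alpha)
  mu <- stats::plogis(eta)
  tau_cur <- if (fixed_tau) tau else 0.5
  converged <- FALSE

  for (it in seq_len(maxit)) {
    W <- pmax(mu * (1 - mu), 1e-10)
    Ytil <- eta + (y - mu) / W
    if (tau_cur > 0) {
      Sigma <- tau_cur * G
      diag(Sigma) <- diag(Sigma) + 1 / W
      Sigma_inv <- chol2inv(chol(Sigma))
    } else {
      Sigma_inv <- diag(W)
    }
    SiX <- Sigma_inv %*% X
    XtSiX <- crossprod(X, SiX)
    alpha_new <- drop(solve(XtSiX, crossprod(SiX, Ytil)))
    P <- Sigma_inv - SiX %*% solve(XtSiX, t(SiX))
    PY <- drop(P %*% Ytil)

    if (!fixed_tau) {
      GPY <- drop(G %*% PY)
      score <- -0.5 * (sum(P * G) - sum(PY * GPY))
      AI <- 0.5 * drop(crossprod(GPY, P %*% GPY))
      tau_new <- tau_cur + score / AI
      if (!is.finite(tau_new)) tau_new <- tau_cur
      # an overshoot below zero signals a boundary solution: back off fast,
      # then pin to the boundary
      if (tau_new < 0) tau_new <- if (tau_cur < 1e-4) 0 else tau_cur / 10
      if (tau_new < 1e-8) tau_new <- 0
    } else {
      tau_new <- tau_cur
    }

    # BLUP update of the linear predictor
    b_new <- if (tau_new > 0) tau_new * drop(G %*% PY) else numeric(n)
    eta_new <- drop(X %*% alpha_new) + b_new

    delta <- max(abs(c(alpha_new - alpha, tau_new - tau_cur))) /
      max(1, max(abs(c(alpha_new, tau_new))))
    alpha <- alpha_new
    tau_cur <- tau_new
    eta <- eta_new
    mu <- stats::plogis(eta)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("PQL/AI-REML did not converge within ", maxit, " iterations")
  }
  structure(
    list(tau_hat = tau_cur, alpha_hat = alpha, mu_hat = mu,
         residuals = y - mu, working_P = P, y = y, X = X,
         converged = converged, n = n, n_iter = it),
    class = "glmm_null_fit"
  )
}

#' Single-variant GLMM score test
#'
#' Score statistic `T = g'(y - mu_hat)` with variance `g' P g` from the null
#' logistic mixed model; two-sided p-value from the standard normal
#' reference. Degenerate variants (`var <= 0`) get a missing p-value.
#'
#' @param null A `glmm_null_fit`.
#' @param g Dosage (or collapsed burden) vector.
#' @param force Run even when the null fit did not converge.
#' @return One-row tibble: `score`, `var`, `stat`, `p_value`, `n_used`.
#' @export
glmm_score_test <- function(null, g, force = FALSE) {
  stopifnot(inherits(null, "glmm_null_fit"))
  if (!null$converged && !force) {
    stop("null model did not converge; pass force = TRUE to test anyway")
  }
  if (length(g) != null$n) stop("dosage length does not match null model")
  T_stat <- sum(g * null$residuals)
  v <- drop(crossprod(g, null$working_P %*% g))
  if (!is.finite(v) || v <= 1e-12) {
    return(tibble::tibble(score = T_stat, var = v, stat = NA_real_,
                          p_value = NA_real_, n_used = null$n))
  }
  z <- T_stat / sqrt(v)
  tibble::tibble(score = T_stat, var = v, stat = z,
                 p_value = 2 * stats::pnorm(-abs(z)), n_used = null$n)
}

#' Construct a rare-variant set
#'
#' Bundles a dosage matrix with per-variant minor allele frequencies and
#' weights. Variants are flipped to minor-allele coding, monomorphic
#' variants dropped. Default weights follow the SKAT convention: the
#' `Beta(1, 25)` density evaluated at the sample MAF; `"flat"` gives unit
#' weights.
#'
#' @param dosages Individuals x variants dosage matrix.
#' @param weights Explicit non-negative per-variant weights (overrides
#'   `weight_scheme`).
#' @param weight_scheme `"beta"` (default) or `"flat"`.
#' @return A `variant_set` with `dosages`, `mafs`, `weights`.
#' @export
variant_set <- function(dosages, weights = NULL,
                        weight_scheme = c("beta", "flat")) {
  weight_scheme <- match.arg(weight_scheme)
  dosages <- as.matrix(dosages)
  f <- colMeans(dosages) / 2
  keep <- f > 0 & f < 1
  if (!any(keep)) stop("no polymorphic variants in set")
  dosages <- dosages[, keep, drop = FALSE]
  f <- f[keep]
  flip <- f > 0.5
  if (any(flip)) {
    dosages[, flip] <- 2 - dosages[, flip]
    f[flip] <- 1 - f[flip]
  }
  if (is.null(weights)) {
    weights <- switch(weight_scheme,
                      beta = stats::dbeta(f, 1, 25),
                      flat = rep(1, length(f)))
  } else {
    weights <- weights[keep]
    if (any(weights < 0)) stop("weights must be non-negative")
  }
  structure(list(dosages = dosages, mafs = f, weights = weights),
            class = "variant_set")
}

# Shared machinery for the set tests: weighted score vector U and the
# spectral ingredients of its covariance V = Gw' P Gw. All eigenvalue
# problems are posed on the smaller of variant space (q x q, via V itself)
# and sample space (via Z = C Gw with P = C'C from a pivoted Cholesky,
# whose Gram matrix Z Z' shares V's nonzero spectrum), so wide variant sets
# from sequence regions stay tractable.
set_kernel <- function(null, set) {
  Gw <- sweep(set$dosages, 2L, set$weights, "*")
  U <- drop(crossprod(Gw, null$residuals))
  q <- length(U)
  n <- null$n
  if (q <= n) {
    # variant-space Gram: K = V = Gw' P Gw
    K <- crossprod(Gw, null$working_P %*% Gw)
    zK <- drop(K %*% rep(1, q)) # burden direction inside the Gram space
    s1 <- sum(zK)
    burden_dir <- rep(1, q) # unit-coefficient direction; |dir|^2 weighting
    dir_norm2 <- q
  } else {
    # sample-space Gram: K = Z Z' with Z = C Gw, P = C'C (pivoted Cholesky);
    # shares V's nonzero spectrum, and the burden direction 1 maps to Z 1
    cp <- suppressWarnings(chol(null$working_P, pivot = TRUE))
    r <- attr(cp, "rank")
    C <- cp[seq_len(r), order(attr(cp, "pivot")), drop = FALSE]
    Z <- C %*% Gw
    K <- tcrossprod(Z)
    zbar <- drop(Z %*% rep(1, q))
    s1 <- sum(zbar^2)
    zK <- zbar
    dir_norm2 <- NULL
  }
  cache <- new.env(parent = emptyenv())
  side <- if (q <= n) "variant" else "sample"

  # In variant space the rho-kernel is R^{1/2} K R^{1/2}; in sample space it
  # is (1 - rho) K + rho zbar zbar'. Both share the nonzero spectrum of the
  # other side's counterpart.
  rho_matrix <- function(rho) {
    if (side == "sample") {
      (1 - rho) * K + rho * tcrossprod(zK)
    } else {
      a <- sqrt(1 - rho)
      cc <- (sqrt(1 - rho + q * rho) - a) / q
      one <- rep(1, q)
      a^2 * K + a * cc * (outer(zK, one) + outer(one, zK)) +
        cc^2 * s1 * tcrossprod(one)
    }
  }
  adj_matrix <- function() {
    if (is.null(cache$A)) {
      if (side == "sample") {
        wz <- drop(K %*% zK)
        cache$A <- K - (outer(zK, wz) + outer(wz, zK)) / s1 +
          tcrossprod(zK) * (sum(zK * wz) / s1^2)
      } else {
        v1 <- drop(K %*% rep(1, q))
        cache$A <- K - tcrossprod(v1) / s1
      }
    }
    cache$A
  }
  mom4 <- function(M) {
    M2 <- M %*% M
    c(sum(diag(M)), sum(M * M), sum(M2 * M), sum(M2 * M2))
  }
  # spectral moments tr(M^k), k = 1..4, of the rho kernel via trace algebra:
  # only one K^2 product, no per-rho eigendecomposition (sample side)
  mom_rho <- function(rho) {
    if (side == "variant") return(mom4(rho_matrix(rho)))
    if (is.null(cache$tK)) {
      K2 <- K %*% K
      wz <- drop(K %*% zK)
      w2z <- drop(K2 %*% zK)
      cache$tK <- c(sum(diag(K)), sum(K * K), sum(K2 * K), sum(K2 * K2))
      cache$zKz <- sum(zK * wz)
      cache$zK2z <- sum(zK * w2z)
      cache$zK3z <- sum(wz * w2z)
    }
    t_ <- cache$tK; a <- 1 - rho; b <- rho
    c(a * t_[1] + b * s1,
      a^2 * t_[2] + 2 * a * b * cache$zKz + b^2 * s1^2,
      a^3 * t_[3] + 3 * a^2 * b * cache$zK2z + 3 * a * b^2 * s1 * cache$zKz +
        b^3 * s1^3,
      a^4 * t_[4] + 4 * a^3 * b * cache$zK3z +
        a^2 * b^2 * (4 * s1 * cache$zK2z + 2 * cache$zKz^2) +
        4 * a * b^3 * s1^2 * cache$zKz + b^4 * s1^4)
  }
  list(
    U = U, q = q, s1 = s1, TB = sum(U), QS = sum(U^2), QB = sum(U)^2,
    lam_skat = function() qf_eigenvalues(K),
    lam_adj = function() qf_eigenvalues(adj_matrix()),
    lam_rho = function(rho) qf_eigenvalues(rho_matrix(rho)),
    mom_skat = function() {
      if (is.null(cache$momK)) cache$momK <- mom4(K)
      cache$momK
    },
    mom_adj = function() {
      if (is.null(cache$momA)) cache$momA <- mom4(adj_matrix())
      cache$momA
    },
    mom_rho = mom_rho,
    # |V 1|^2 and v1 = V 1 in variant space (matrix-vector products)
    sum_v1_sq = if (side == "sample") sum(drop(K %*% zK) * zK) else sum(zK^2),
    # 4 v1' A v1 / s1, the burden-SKAT coupling variance in the optimal test
    var_zeta = if (s1 > 1e-12) {
      if (side == "sample") {
        wz <- drop(K %*% zK)
        zKz <- sum(zK * wz)
        zK2z <- sum(wz * wz)
        4 * (zK2z - zKz^2 / s1) / s1
      } else {
        4 * (drop(crossprod(zK, K %*% zK)) - sum(zK^2)^2 / s1) / s1
      }
    } else NA_real_,
    v1 = {
      b_collapse <- rowSums(Gw)
      drop(crossprod(Gw, null$working_P %*% b_collapse))
    }
  )
}

#' Rare-variant set tests in the logistic mixed model framework
#'
#' Given a null logistic mixed model and a weighted variant set, computes
#' any of the four set tests sharing one score vector `U = Gw'(y - mu_hat)`
#' and covariance `V = Gw' P Gw`:
#'
#' * `burden`: score test of the weighted sum of dosages (normal reference
#'   on `(1'U) / sqrt(1'V1)`).
#' * `skat`: variance-component quadratic form `Q = U'U` referred to its
#'   null mixture-of-chi-square distribution with eigenvalue weights from
#'   `V`.
#' * `skato`: minimum-p combination of burden and SKAT kernels over the grid
#'   `rho = (0, 0.1^2, ..., 0.5^2, 0.5, 1)` with the one-dimensional
#'   integration of the optimal-test construction.
#' * `hybrid`: Fisher combination (chi-square, 4 df) of the burden p-value
#'   with the SKAT p-value of the score vector orthogonalized against the
#'   burden direction; the two components are asymptotically independent.
#'
#' @param null A `glmm_null_fit`.
#' @param set A [variant_set()].
#' @param tests Character subset of `c("burden", "skat", "skato", "hybrid")`.
#' @param method Quadratic-form tail method: `"liu"` moment matching
#'   (default) or `"exact"` characteristic-function inversion.
#' @param force Run even when the null fit did not converge.
#' @return One-row tibble with `n_variants` and one `p_*` column per
#'   requested test.
#' @export
smmat_tests <- function(null, set,
                        tests = c("burden", "skat", "skato", "hybrid"),
                        method = c("liu", "exact"), force = FALSE) {
  method <- match.arg(method)
  tests <- match.arg(tests, several.ok = TRUE)
  stopifnot(inherits(null, "glmm_null_fit"), inherits(set, "variant_set"))
  if (!null$converged && !force) {
    stop("null model did not converge; pass force = TRUE to test anyway")
  }
  ker <- set_kernel(null, set)
  out <- tibble::tibble(n_variants = ker$q)

  p_burden <- if (ker$s1 > 1e-12) {
    2 * stats::pnorm(-abs(ker$TB) / sqrt(ker$s1))
  } else NA_real_

  if ("burden" %in% tests) out$p_burden <- p_burden
  p_skat <- NULL
  if (any(c("skat", "skato") %in% tests)) {
    p_skat <- if (method == "liu") {
      qf_pvalue(ker$QS, mom = ker$mom_skat(), method = "liu")
    } else {
      qf_pvalue(ker$QS, lambda = ker$lam_skat(), method = "exact")
    }
  }
  if ("skat" %in% tests) out$p_skat <- p_skat
  if ("skato" %in% tests) {
    out$p_skato <- skat_o_pvalue(ker, method, p_skat = p_skat)
  }
  if ("hybrid" %in% tests) {
    if (is.na(p_burden) || ker$s1 <= 1e-12) {
      out$p_hybrid <- NA_real_
    } else {
      U_adj <- ker$U - ker$v1 * (ker$TB / ker$s1)
      p_adj <- if (method == "liu") {
        qf_pvalue(sum(U_adj^2), mom = ker$mom_adj(), method = "liu")
      } else {
        qf_pvalue(sum(U_adj^2), lambda = ker$lam_adj(), method = "exact")
      }
      if (is.na(p_adj)) p_adj <- 1 # burden captured the whole set
      fisher <- -2 * (log(p_burden) + log(p_adj))
      out$p_hybrid <- stats::pchisq(fisher, df = 4, lower.tail = FALSE)
    }
  }
  out
}

#' @rdname smmat_tests
#' @export
burden_test <- function(null, set, force = FALSE) {
  smmat_tests(null, set, tests = "burden", force = force)$p_burden
}

#' @rdname smmat_tests
#' @export
skat_test <- function(null, set, method = c("liu", "exact"), force = FALSE) {
  smmat_tests(null, set, tests = "skat", method = method, force = force)$p_skat
}

#' @rdname smmat_tests
#' @export
skat_o_test <- function(null, set, method = c("liu", "exact"), force = FALSE) {
  smmat_tests(null, set, tests = c("skat", "skato"), method = method,
              force = force)$p_skato
}

#' @rdname smmat_tests
#' @export
efficient_hybrid_test <- function(null, set, method = c("liu", "exact"),
                                  force = FALSE) {
  smmat_tests(null, set, tests = c("burden", "hybrid"), method = method,
              force = force)$p_hybrid
}

qf_eigenvalues <- function(V, tol = 1e-10) {
  lam <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam[lam > tol * max(lam, 0)]
}

# Tail probability P(Q > q) for Q = sum lambda_k chi^2_1, given either the
# eigenvalues or their first four power sums (spectral moments).
qf_pvalue <- function(q, lambda = NULL, mom = NULL,
                      method = c("liu", "exact")) {
  method <- match.arg(method)
  if (method == "liu") {
    if (is.null(mom)) mom <- c(sum(lambda), sum(lambda^2),
                               sum(lambda^3), sum(lambda^4))
    if (mom[2] <= 1e-24) return(NA_real_)
    liu_pvalue(q, mom)
  } else {
    if (!length(lambda)) return(NA_real_)
    imhof_pvalue(q, lambda)
  }
}

liu_params <- function(mom) {
  c1 <- mom[1]; c2 <- mom[2]; c3 <- mom[3]; c4 <- mom[4]
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  list(muQ = c1, sigmaQ = sqrt(2 * c2), l = l, d = d,
       muX = l + d, sigmaX = sqrt(2 * (l + 2 * d)))
}

# Liu-Tang-Zhang moment-matched tail probability (modified version that
# matches kurtosis, giving a conservative far tail). `mom` holds the first
# four spectral power sums.
liu_pvalue <- function(q, mom) {
  p <- liu_params(mom)
  tstar <- (q - p$muQ) / p$sigmaQ
  stats::pchisq(tstar * p$sigmaX + p$muX, df = p$l, ncp = p$d,
                lower.tail = FALSE)
}

liu_quantile <- function(pval, mom) {
  p <- liu_params(mom)
  qx <- stats::qchisq(pval, df = p$l, ncp = p$d, lower.tail = FALSE)
  (qx - p$muX) / p$sigmaX * p$sigmaQ + p$muQ
}

# Imhof characteristic-function inversion (exact up to quadrature error).
imhof_pvalue <- function(q, lambda) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    log_rho <- 0.25 * colSums(log1p(outer(lambda, u)^2))
    sin(theta) / (u * exp(log_rho))
  }
  int <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-8,
                          subdivisions = 10000L, stop.on.error = FALSE)
  min(max(0.5 + int$value / pi, 1e-15), 1)
}

# Optimal (min-p over rho) combination of burden and SKAT kernels,
# following the standard one-dimensional-integration construction.
skat_o_pvalue <- function(ker, method = c("liu", "exact"), p_skat = NULL,
                          rho_grid = c(0, (1:5 / 10)^2, 0.5, 1)) {
  method <- match.arg(method)
  if (ker$q == 1L) { # single variant: all kernels coincide
    return(qf_pvalue(ker$QS, lambda = ker$lam_skat(),
                     mom = ker$mom_skat(), method = method))
  }
  if (ker$s1 <= 1e-12) return(p_skat %||% NA_real_)

  rho_eff <- pmin(rho_grid, 0.999)
  p_each <- numeric(length(rho_grid))
  qmin <- numeric(length(rho_grid))
  mom_list <- vector("list", length(rho_grid))
  for (i in seq_along(rho_grid)) {
    rho <- rho_eff[i]
    Qr <- (1 - rho) * ker$QS + rho * ker$QB
    mom_list[[i]] <- ker$mom_rho(rho)
    p_each[i] <- if (method == "liu") {
      qf_pvalue(Qr, mom = mom_list[[i]], method = "liu")
    } else {
      qf_pvalue(Qr, lambda = ker$lam_rho(rho), method = "exact")
    }
  }
  pmin_val <- min(p_each, na.rm = TRUE)
  for (i in seq_along(rho_grid)) {
    qmin[i] <- liu_quantile(pmin_val, mom_list[[i]])
  }

  # mixture representation: Q_rho ~ (1 - rho) kappa + tau(rho) eta0,
  # eta0 ~ chi^2_1 the burden-direction component
  momA <- ker$mom_adj()
  muQ <- momA[1]
  varQ <- 2 * momA[2] + ker$var_zeta
  kurQ <- 12 * momA[4] / momA[2]^2
  Df <- 12 / kurQ
  tau_r <- rho_eff * ker$s1 + (1 - rho_eff) * ker$sum_v1_sq / ker$s1

  f <- function(x) {
    sapply(x, function(xx) {
      t_min <- min((qmin - tau_r * xx) / (1 - rho_eff))
      tq <- (t_min - muQ) / sqrt(varQ) * sqrt(2 * Df) + Df
      if (tq <= 0) return(0)
      stats::pchisq(tq, df = Df) * stats::dchisq(xx, df = 1)
    })
  }
  int <- tryCatch(
    stats::integrate(f, 0, 40, subdivisions = 1000L, rel.tol = 1e-7)$value,
    error = function(e) NA_real_
  )
  if (is.na(int)) return(min(pmin_val * length(rho_grid), 1))
  p <- 1 - int
  p <- min(p, pmin_val * length(rho_grid))
  min(max(p, 1e-15), 1)
}
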