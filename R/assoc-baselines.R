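#' Logistic regression with principal-component correction
#'
#' Wald test of the candidate dosage coefficient in
#' `logit P(y = 1) = beta_0 + beta_g g + sum_j gamma_j PC_j`, the standard
#' principal-component correction for population stratification. With
#' `pcs = NULL` (or zero columns) this is exactly the uncorrected logistic
#' baseline.
#'
#' @param y Binary 0/1 response.
#' @param g Candidate dosage vector.
#' @param pcs Matrix of principal-component scores (default `NULL`), e.g.
#'   from [top_pcs()] computed within the extreme-sampled individuals.
#' @return One-row tibble: `beta_hat`, `se`, `stat`, `p_value`, `n_used`,
#'   `converged`. Separation or non-convergence gives a missing p-value
#'   with `converged = FALSE`.
#' @export
pca_logistic_test <- function(y, g, pcs = NULL) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  n <- length(y)
  if (length(g) != n) stop("dosage length does not match response")
  if (stats::var(g) == 0) {
    return(tibble::tibble(beta_hat = NA_real_, se = NA_real_,
                          stat = NA_real_, p_value = NA_real_,
                          n_used = n, converged = NA))
  }
  X <- cbind(`(Intercept)` = 1, g = g)
  if (!is.null(pcs) && NCOL(pcs) > 0) {
    pcs <- as.matrix(pcs)
    if (nrow(pcs) != n) stop("PC rows do not match response length")
    X <- cbind(X, pcs)
  }
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  cov_beta <- tryCatch(chol2inv(fit$qr$qr[seq_len(ncol(X)), , drop = FALSE]),
                       error = function(e) NULL)
  beta_g <- fit$coefficients["g"]
  ok <- fit$converged && !is.null(cov_beta) && all(is.finite(cov_beta)) &&
    abs(beta_g) < 10 # larger log-odds per allele indicates separation
  if (!ok) {
    return(tibble::tibble(beta_hat = unname(beta_g), se = NA_real_,
                          stat = NA_real_, p_value = NA_real_,
                          n_used = n, converged = FALSE))
  }
  se <- sqrt(cov_beta[2, 2])
  z <- beta_g / se
  tibble::tibble(beta_hat = unname(beta_g), se = se, stat = unname(z),
                 p_value = unname(2 * stats::pnorm(-abs(z))),
                 n_used = n, converged = TRUE)
}

#' Uncorrected logistic regression baseline
#'
#' Wald test of the dosage in an intercept-only logistic model — the
#' no-correction reference whose size inflates under stratification.
#'
#' @inheritParams pca_logistic_test
#' @return As [pca_logistic_test()].
#' @export
uncorrected_logistic_test <- function(y, g) {
  pca_logistic_test(y, g, pcs = NULL)
}
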