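#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an LMM null fit
#'
#' @param x An `lmm_null_fit`.
#' @param ... Unused.
#' @return Tibble of fixed-effect estimates.
#' @export
tidy.lmm_null_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta0_hat) %||%
                   paste0("beta", seq_along(x$beta0_hat) - 1L),
                 estimate = unname(x$beta0_hat))
}

#' @rdname tidy.lmm_null_fit
#' @export
glance.lmm_null_fit <- function(x, ...) {
  tibble::tibble(lambda_hat = x$lambda_hat,
                 sigma_a2_hat = x$sigma_a2_hat,
                 sigma_e2_hat = x$sigma_e2_hat,
                 loglik_reml = x$loglik_reml,
                 boundary = x$boundary,
                 n = x$n)
}

#' Tidy a GLMM null fit
#'
#' @param x A `glmm_null_fit`.
#' @param ... Unused.
#' @return Tibble of fixed-effect estimates.
#' @export
tidy.glmm_null_fit <- function(x, ...) {
  tibble::tibble(term = names(x$alpha_hat) %||%
                   colnames(x$X) %||%
                   paste0("alpha", seq_along(x$alpha_hat) - 1L),
                 estimate = unname(x$alpha_hat))
}

#' @rdname tidy.glmm_null_fit
#' @export
glance.glmm_null_fit <- function(x, ...) {
  tibble::tibble(tau_hat = x$tau_hat, converged = x$converged,
                 n_iter = x$n_iter, n = x$n)
}

#' Tidy a liability fit
#'
#' @param x A `liability_fit`.
#' @param ... Unused.
#' @return Tibble of per-SNP probit MAP coefficients.
#' @export
tidy.liability_fit <- function(x, ...) {
  tibble::tibble(term = paste0("snp", seq_along(x$beta_g_hat)),
                 estimate = x$beta_g_hat)
}

#' @rdname tidy.liability_fit
#' @export
glance.liability_fit <- function(x, ...) {
  tibble::tibble(beta0_hat = x$beta0_hat, ridge_lambda = x$ridge_lambda,
                 n_snps_used = x$n_snps_used,
                 loglik_penalized = x$loglik_penalized,
                 converged = x$converged, n = x$n)
}

#' Tidy an experiment result
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return The per-method summary tibble (rejection rates with Monte-Carlo
#'   standard errors).
#' @export
tidy.experiment_result <- function(x, ...) x$summary

#' @rdname tidy.experiment_result
#' @export
glance.experiment_result <- function(x, ...) {
  tibble::tibble(scenario = x$config$scenario,
                 m_reps = x$config$m_reps,
                 alpha = x$config$alpha,
                 n_cohort = x$config$sim_common$n_cohort,
                 elapsed_s = x$elapsed)
}
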