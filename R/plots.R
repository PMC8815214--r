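#' QQ plot of experiment p-values
#'
#' Observed versus expected `-log10` p-value quantiles per method, with the
#' identity line. Points above the line in the upper tail are the signature
#' of inflated test statistics.
#'
#' @param object An `experiment_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.experiment_result <- function(object, ...) {
  dat <- object$pvalues |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(~ qq_data(.x$p_value)) |>
    dplyr::ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(.data$expected, .data$observed,
                                    colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.experiment_result
#' @param result An `experiment_result`.
#' @export
plot_qq <- function(result, ...) autoplot.experiment_result(result, ...)

#' Plot an allele-frequency sweep
#'
#' Empirical size against the subpopulation-2 candidate allele frequency,
#' one line per method, with 3 Monte-Carlo-SE ribbons and the nominal level
#' marked.
#'
#' @param object A `freq_sweep_result` from [freq_sweep()].
#' @param alpha Nominal level drawn as a horizontal reference (default
#'   0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.freq_sweep_result <- function(object, alpha = 0.05, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$p2, .data$rejection_rate,
                                       colour = .data$method)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2, colour = "grey40") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$rejection_rate - 3 * .data$mc_se, 0),
                   ymax = .data$rejection_rate + 3 * .data$mc_se,
                   fill = .data$method),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(p[2]), y = "empirical size",
                  colour = "method", fill = "method") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.freq_sweep_result
#' @param sweep A `freq_sweep_result`.
#' @export
plot_freq_sweep <- function(sweep, alpha = 0.05, ...) {
  autoplot.freq_sweep_result(sweep, alpha = alpha, ...)
}
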