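#' Q-Q plot of gene-level p-values from a scan
#'
#' Observed versus expected `-log10` p-values for the multi-trait test and
#' each single-trait omnibus test, the standard diagnostic for genome-wide
#' p-value inflation.
#'
#' @param object An `omga_scan` tibble.
#' @param traits Character vector of traits to show; default all plus the
#'   combined `"multi"` test.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.omga_scan <- function(object, traits = NULL, ...) {
  long <- tidy.omga_scan(object)
  if (!is.null(traits)) long <- dplyr::filter(long, .data$trait %in% traits)
  long <- dplyr::filter(long, !is.na(.data$p_value))
  long <- dplyr::group_by(long, .data$trait)
  long <- dplyr::mutate(long,
    expected = -log10(stats::ppoints(dplyr::n()))[rank(.data$p_value, ties.method = "first")],
    observed = -log10(.data$p_value))
  long <- dplyr::ungroup(long)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_bw()
}

#' Power / type-I error curves from simulation results
#'
#' @param object An `omga_sim` tibble (rows from
#'   [empirical_rejection_rate()], typically bound over a grid).
#' @param x One of `"n"`, `"p"`, `"rho"` for the horizontal axis (default
#'   `"n"`).
#' @param ... Unused.
#' @return A ggplot object with Wilson 95% error bars, faceted by scenario.
#' @export
autoplot.omga_sim <- function(object, x = "n", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[x]], y = .data$rate,
                               colour = .data$method, group = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
                           width = 0.02 * diff(range(object[[x]], finite = TRUE)) + 1e-9) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(y = "rejection rate") +
    ggplot2::theme_bw()
}
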