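#' Plot an MMSE curve
#'
#' @param object an [mmse_curve()] tibble.
#' @param ... unused.
#' @return A ggplot: MSampEn against scale factor; undefined scales appear as
#'   open points at the bottom of the panel.
#' @export
autoplot.mmse_curve <- function(object, ...) {
  ggplot2::ggplot(object[object$defined, ],
                  ggplot2::aes(x = .data$scale, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$scale) +
    ggplot2::labs(x = "scale factor (cumulative IMF index)",
                  y = "MSampEn") +
    ggplot2::theme_minimal()
}

#' Plot group-level MMSE curves per scheme
#'
#' Mean +/- 1 SD MMSE curve per group, faceted by scheme, mirroring the usual
#' presentation of coactivation-complexity results.
#'
#' @param object an `mmse_analysis` from [run_analysis()].
#' @param schemes optional scheme ids to include (default all).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mmse_analysis <- function(object, schemes = NULL, ...) {
  d <- object$summary_group
  if (!is.null(schemes)) d <- d[d$scheme_id %in% schemes, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scale, y = .data$mean,
                                  colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~scheme_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "scale factor", y = "MSampEn (group mean ± 1 SD)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mmse_analysis
#' @export
plot_group_curves <- function(object, schemes = NULL, ...) {
  autoplot.mmse_analysis(object, schemes = schemes, ...)
}
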