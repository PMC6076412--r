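#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_segment geom_hline
#'   geom_vline labs theme_minimal scale_x_continuous
NULL

#' Tornado diagram of one-way sensitivity results
#'
#' Horizontal bars spanning the INHB at each parameter's low and high bound,
#' with a vertical line at the base-case INHB.
#'
#' @param object A `cea_tornado` tibble from [one_way()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cea_tornado <- function(object, ...) {
  df <- object |>
    mutate(parameter = factor(.data$parameter, levels = rev(.data$parameter)))
  ggplot(df, aes(y = .data$parameter)) +
    geom_vline(xintercept = df$inhb_base[[1]], linetype = "dashed", colour = "grey40") +
    geom_segment(aes(x = .data$inhb_low, xend = .data$inhb_high,
                     yend = .data$parameter),
                 linewidth = 4, colour = "steelblue", alpha = 0.8) +
    labs(x = sprintf("Incremental net health benefit (QALYs) at $%s/QALY",
                     format(attr(object, "lambda"), big.mark = ",")),
         y = NULL, title = "One-way sensitivity analysis") +
    theme_minimal()
}

#' @rdname autoplot.cea_tornado
#' @export
plot_tornado <- function(object, ...) autoplot.cea_tornado(object, ...)

#' Cost-effectiveness plane of PSA draws
#'
#' Scatter of incremental QALYs against incremental cost across simulations,
#' with the willingness-to-pay threshold drawn as a line through the origin.
#'
#' @param object A `cea_psa` tibble from [run_psa()].
#' @param lambda Willingness-to-pay line, US$/QALY (default 22,073).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cea_psa <- function(object, lambda = 22073, ...) {
  ggplot(object, aes(.data$delta_effect, .data$delta_cost)) +
    geom_hline(yintercept = 0, colour = "grey60") +
    geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = lambda, intercept = 0,
                         linetype = "dashed", colour = "grey40") +
    geom_point(alpha = 0.35, size = 0.8, colour = "steelblue") +
    labs(x = "Incremental QALYs (FOLFOX4 - sorafenib)",
         y = "Incremental cost (US$)",
         title = "Probabilistic sensitivity analysis") +
    theme_minimal()
}

#' @rdname autoplot.cea_psa
#' @export
plot_ce_plane <- function(object, lambda = 22073, ...) {
  autoplot.cea_psa(object, lambda = lambda, ...)
}

#' Cost-effectiveness acceptability curve
#'
#' @param object A `cea_ceac` tibble from [ceac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cea_ceac <- function(object, ...) {
  ggplot(object, aes(.data$lambda, .data$probability)) +
    geom_line(colour = "steelblue") +
    scale_x_continuous(labels = function(x) format(x, big.mark = ",")) +
    labs(x = "Willingness to pay (US$/QALY)",
         y = "P(FOLFOX4 preferred)",
         title = "Cost-effectiveness acceptability") +
    theme_minimal()
}

#' @rdname autoplot.cea_ceac
#' @export
plot_ceac <- function(object, ...) autoplot.cea_ceac(object, ...)
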