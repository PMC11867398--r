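#' Cost-effectiveness plane
#'
#' Scatter of PSA iterations in the incremental-effect / incremental-cost
#' plane with the willingness-to-pay line.
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay threshold drawn as a line (EUR/QALY).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = 50000) {
  s <- psa$samples
  ggplot2::ggplot(s, ggplot2::aes(x = .data$delta_e, y = .data$delta_c)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, colour = "red") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental costs (EUR)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("WTP = %s EUR/QALY", format(wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param curve A `ceac_curve` tibble from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (EUR/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' Horizontal bars of the swing in incremental cost (or effect) as each
#' parameter moves between its bounds, most influential first.
#'
#' @param dsa A `dsa_result`.
#' @param outcome `"delta_c"` or `"delta_e"`.
#' @param top Number of parameters shown (default 15).
#' @return A ggplot object.
#' @export
plot_tornado <- function(dsa, outcome = c("delta_c", "delta_e"), top = 15) {
  outcome <- match.arg(outcome)
  base_val <- dsa$base[[outcome]]
  swing_col <- if (outcome == "delta_c") "swing_c" else "swing_e"
  keep <- dsa$ranking |>
    dplyr::arrange(dplyr::desc(.data[[swing_col]])) |>
    utils::head(top)
  df <- dsa$results |>
    dplyr::filter(.data$name %in% keep$name) |>
    dplyr::mutate(name = factor(.data$name, levels = rev(keep$name)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$name)) +
    ggplot2::geom_segment(ggplot2::aes(x = base_val, xend = .data[[outcome]],
                                       yend = .data$name, colour = .data$bound),
                          linewidth = 4) +
    ggplot2::geom_vline(xintercept = base_val, linetype = 2, colour = "red") +
    ggplot2::labs(x = if (outcome == "delta_c") "Incremental costs (EUR)" else "Incremental QALYs",
                  y = NULL, colour = "Bound", title = "Deterministic sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Value-of-information plot
#'
#' EVPI and EVPPI per recipient across willingness to pay.
#'
#' @param voi Tidy table from [voi_summary()].
#' @return A ggplot object.
#' @export
plot_voi <- function(voi) {
  ggplot2::ggplot(voi, ggplot2::aes(x = .data$wtp, y = .data$value,
                                    colour = paste(.data$measure, .data$subset))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (EUR/QALY)", y = "EUR per recipient",
                  colour = NULL, title = "Value of information") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` dispatches to the matching `plot_*()` helper:
#' cost-effectiveness plane for `psa_result`, acceptability curve for
#' `ceac_curve`, tornado for `dsa_result`, and the extrapolated curve for
#' `survival_curve`.
#'
#' @param object Result object.
#' @param ... Passed to the underlying helper.
#' @return A ggplot object.
#' @name autoplot-leadcea
NULL

#' @rdname autoplot-leadcea
#' @export
autoplot.psa_result <- function(object, ...) plot_ce_plane(object, ...)

#' @rdname autoplot-leadcea
#' @export
autoplot.ceac_curve <- function(object, ...) plot_ceac(object)

#' @rdname autoplot-leadcea
#' @export
autoplot.dsa_result <- function(object, ...) plot_tornado(object, ...)

#' @rdname autoplot-leadcea
#' @export
autoplot.survival_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Survival probability") +
    ggplot2::theme_minimal()
}
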