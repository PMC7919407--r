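#' Plot unit-cell drift bin series
#'
#' Bin means with +/- one standard deviation error bars for one cell
#' parameter, against bin number.
#'
#' @param bins A bin series from [bin_cell_drift()].
#' @param param Cell parameter to plot: one of `"a", "b", "c", "alpha",
#'   "beta", "gamma"`.
#' @return A ggplot object.
#' @export
plot_cell_drift <- function(bins, param = "c") {
  param <- match.arg(param, c("a", "b", "c", "alpha", "beta", "gamma"))
  mcol <- paste0(param, "_mean")
  scol <- paste0(param, "_sd")
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data[[mcol]])) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data[[mcol]] - .data[[scol]],
      ymax = .data[[mcol]] + .data[[scol]]
    )) +
    ggplot2::labs(
      x = "sequential bin",
      y = sprintf("%s (%s)", param, if (param %in% c("a", "b", "c")) "Å" else "deg")
    )
}

#' Plot a damage ratio series
#'
#' B0/Bn against dose.
#'
#' @param ratios A tibble from [b_ratio_series()] with an added `dose_kgy`
#'   column, or any data frame with `dose_kgy` and `ratio`.
#' @return A ggplot object.
#' @export
plot_b_ratios <- function(ratios) {
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$dose_kgy, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (kGy)", y = expression(B[0] / B[n]))
}
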