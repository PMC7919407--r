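#' Sequential-bin unit-cell drift statistics
#'
#' Divides the full acquisition (all images, including non-hits) into
#' `n_bins` contiguous bins of (nearly) equal image count and reports, per
#' bin, the mean and standard deviation of each cell parameter over the
#' indexed images only -- the standard presentation of cell drift during a
#' serial run. A bin without indexed images is kept with `NA` statistics and
#' flagged.
#'
#' @param stream An observation stream.
#' @param n_bins Number of sequential bins (>= 2, default 10).
#' @return A tibble with one row per bin: `bin`, `image_lo`, `image_hi`
#'   (0-based inclusive index range), `n_images`, `n_indexed`, `flagged`
#'   (no indexed images), and `<param>_mean` / `<param>_sd` for each of
#'   `a, b, c, alpha, beta, gamma`.
#' @export
bin_cell_drift <- function(stream, n_bins = 10) {
  stopifnot(inherits(stream, "ssrox_stream"))
  if (n_bins < 2) abort("`n_bins` must be >= 2", class = "ssrox_error_drift")
  imgs <- stream$images
  n <- nrow(imgs)
  if (n < n_bins) abort("fewer images than bins", class = "ssrox_error_drift")
  bin <- pmin(floor(imgs$image * n_bins / n) + 1L, n_bins)
  imgs$bin <- bin
  ranges <- imgs |>
    dplyr::summarise(
      image_lo = min(.data$image), image_hi = max(.data$image),
      n_images = dplyr::n(), n_indexed = sum(.data$indexed),
      .by = "bin"
    )
  stats <- imgs |>
    dplyr::filter(.data$indexed) |>
    dplyr::summarise(
      dplyr::across(
        c("a", "b", "c", "alpha", "beta", "gamma"),
        list(mean = mean, sd = sd)
      ),
      .by = "bin"
    )
  out <- dplyr::left_join(ranges, stats, by = "bin") |>
    dplyr::mutate(flagged = .data$n_indexed == 0L) |>
    dplyr::arrange(.data$bin)
  as_tibble(out)
}

#' Percent change between two values
#'
#' `100 * (end - start) / start`; e.g. a c axis moving from 38.38 to
#' 38.79 angstrom is a 1.07% (about 1%) increase.
#'
#' @param start Reference value (non-zero).
#' @param end Final value.
#' @return Percent change (vectorised).
#' @export
percent_change <- function(start, end) {
  if (any(start == 0)) abort("`start` must be non-zero", class = "ssrox_error_drift")
  100 * (end - start) / start
}

#' Wilson B factor from merged intensities
#'
#' Bins the merged reflections into equal-count resolution shells inside
#' `[s_min, s_max]`, regresses ln(shell mean intensity) on the shell mean s
#' and reports B = -2 x slope. Shells whose mean intensity is not positive
#' are excluded; fewer than 3 usable shells is an error. The default
#' `s_min = 0.1` (about 3.2 angstrom) avoids the low-resolution non-Wilson
#' regime.
#'
#' @param merged A merged set ([monte_carlo_merge()]) or a truth-set
#'   reflections tibble (any data frame with `s` and an intensity column
#'   `i_merged` or `i_true`).
#' @param s_min,s_max Fit range in s = 1/d^2 (default 0.1 to the data
#'   maximum).
#' @param n_shells Shells for the regression (default 15).
#' @return An object of class `ssrox_wilson_fit`: list with `b_wilson`
#'   (angstrom squared), `intercept` (ln intensity at s = 0), `n_shells`,
#'   `residual_norm` and the shell table.
#' @export
wilson_b <- function(merged, s_min = 0.1, s_max = NULL, n_shells = 15) {
  icol <- if ("i_merged" %in% names(merged)) "i_merged" else "i_true"
  if (!all(c("s", icol) %in% names(merged))) {
    abort("`merged` needs columns `s` and `i_merged` (or `i_true`)",
      class = "ssrox_error_wilson"
    )
  }
  s_max <- s_max %||% max(merged$s)
  sub <- merged[merged$s >= s_min & merged$s <= s_max, ]
  if (nrow(sub) < n_shells) n_shells <- max(3L, nrow(sub) %/% 3L)
  if (nrow(sub) < 9) {
    abort("too few reflections inside the Wilson fit range", class = "ssrox_error_wilson")
  }
  sub <- sub[order(sub$s), ]
  sub$shell <- pmin(floor((seq_len(nrow(sub)) - 1) * n_shells / nrow(sub)) + 1L, n_shells)
  shells <- sub |>
    dplyr::summarise(
      s_mean = mean(.data$s),
      i_mean = mean(.data[[icol]]),
      n = dplyr::n(),
      .by = "shell"
    ) |>
    dplyr::filter(.data$i_mean > 0)
  if (nrow(shells) < 3) {
    abort("fewer than 3 shells with positive mean intensity", class = "ssrox_error_wilson")
  }
  fit <- lm(log(i_mean) ~ s_mean, data = shells)
  slope <- unname(coef(fit)[2])
  structure(
    list(
      b_wilson = -2 * slope,
      intercept = unname(coef(fit)[1]),
      n_shells = nrow(shells),
      residual_norm = sqrt(sum(stats::residuals(fit)^2)),
      shells = as_tibble(shells)
    ),
    class = "ssrox_wilson_fit"
  )
}

#' @export
print.ssrox_wilson_fit <- function(x, ...) {
  cat(sprintf(
    "<Wilson fit> B = %.4g Å² over %d shells (residual %.3g)\n",
    x$b_wilson, x$n_shells, x$residual_norm
  ))
  invisible(x)
}

#' @export
tidy.ssrox_wilson_fit <- function(x, ...) {
  tibble(term = c("b_wilson", "intercept"), estimate = c(x$b_wilson, x$intercept))
}

#' @export
glance.ssrox_wilson_fit <- function(x, ...) {
  tibble(b_wilson = x$b_wilson, n_shells = x$n_shells, residual_norm = x$residual_norm)
}

#' Damage ratio series B0/Bn
#'
#' The dose-series damage metric: the reference B factor divided by each
#' dose point's B factor. Ratios below 1 indicate B inflation (damage)
#' relative to the reference.
#'
#' @param b_ref Reference B factor (> 0).
#' @param b_n Vector of B factors (> 0), or a `ssrox_wilson_fit` list.
#' @return A tibble `b_n, ratio` with `ratio = b_ref / b_n`.
#' @examples
#' b_ratio_series(13.16, c(13.13, 13.60, 15.46, 19.02, 23.18))
#' @export
b_ratio_series <- function(b_ref, b_n) {
  if (is.list(b_n) && !is.data.frame(b_n)) {
    b_n <- vapply(b_n, function(x) {
      if (inherits(x, "ssrox_wilson_fit")) x$b_wilson else as.numeric(x)
    }, numeric(1))
  }
  if (b_ref <= 0 || any(b_n <= 0)) {
    abort("all B factors must be positive", class = "ssrox_error_wilson")
  }
  tibble(b_n = b_n, ratio = b_ref / b_n)
}
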