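#' Per-resolution-shell merging statistics
#'
#' Divides the resolution range into `n_shells` shells containing (as nearly
#' as possible) equal numbers of theoretically possible unique reflections --
#' the equal-count convention of standard serial-crystallography reporting --
#' and computes per shell: completeness (100 x observed unique / possible),
#' mean multiplicity, mean I/sigma, CC1/2 and Rsplit.
#'
#' @param merged A merged set from [monte_carlo_merge()].
#' @param n_shells Number of shells (>= 1, default 20).
#' @param cell,laue Cell and Laue group used to enumerate the possible
#'   reflections; default to the merged set's attributes.
#' @param d_min High-resolution limit for the possible-reflection count;
#'   defaults to the highest resolution present in `merged`.
#' @return A `ssrox_shells` tibble with one row per shell: `shell`, `s_low`,
#'   `s_high`, `s_mid`, `d_high`, `n_possible`, `n_unique`, `completeness`,
#'   `multiplicity`, `i_over_sigma`, `cc_half`, `rsplit`. Shells partition
#'   (0, s_max]; the first shell's `s_low` is 0.
#' @export
shell_statistics <- function(merged, n_shells = 20, cell = NULL, laue = NULL,
                             d_min = NULL) {
  if (n_shells < 1) abort("`n_shells` must be >= 1", class = "ssrox_error_shells")
  cell <- as_cell(cell %||% attr(merged, "cell"))
  laue <- laue %||% attr(merged, "laue")
  d_min <- d_min %||% min(merged$d)
  possible <- enumerate_unique_hkl(cell, d_min, laue)
  s_poss <- sort(possible$s)
  n_poss <- length(s_poss)
  n_shells <- min(n_shells, n_poss)
  # equal-count boundaries over the possible reflections; upper edges inclusive
  cuts <- s_poss[round(seq_len(n_shells) * n_poss / n_shells)]
  cuts[n_shells] <- max(cuts[n_shells], max(merged$s))
  edges <- c(0, cuts)
  shell_of <- function(s) pmin(findInterval(s, edges, left.open = TRUE), n_shells)
  poss_count <- tabulate(shell_of(s_poss), nbins = n_shells)
  merged$shell <- shell_of(merged$s)
  per_shell <- lapply(seq_len(n_shells), function(i) {
    sub <- merged[merged$shell == i, ]
    iosig <- sub$i_merged / sub$sigma_merged
    tibble(
      shell = i,
      s_low = edges[i], s_high = edges[i + 1],
      s_mid = (edges[i] + edges[i + 1]) / 2,
      d_high = 1 / sqrt(edges[i + 1]),
      n_possible = poss_count[i],
      n_unique = nrow(sub),
      completeness = 100 * nrow(sub) / poss_count[i],
      multiplicity = if (nrow(sub) > 0) mean(sub$m) else NA_real_,
      i_over_sigma = if (any(is.finite(iosig))) mean(iosig[is.finite(iosig)]) else NA_real_,
      cc_half = if (nrow(sub) > 0) cc_half(sub) else NA_real_,
      rsplit = if (nrow(both_halves(sub)) > 0) rsplit(sub) else NA_real_
    )
  })
  out <- dplyr::bind_rows(per_shell)
  structure(out, class = c("ssrox_shells", class(out)))
}

#' Plot shell statistics
#'
#' CC1/2 (and optionally Rsplit or I/sigma) against resolution in s = 1/d^2.
#'
#' @param object A shell table from [shell_statistics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssrox_shells <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s_mid, y = .data$cc_half)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(s == 1 / d^2 ~ (ring(A)^-2)),
      y = expression(CC[1 / 2])
    ) +
    ggplot2::ylim(min(0, min(object$cc_half, na.rm = TRUE)), 1)
}
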