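# Per-observation working table used by scaling and merging: canonical
# Laue-unique indices, resolution, and Lorentz-corrected intensity.
obs_working_table <- function(stream, laue = NULL) {
  stopifnot(inherits(stream, "ssrox_stream"))
  laue <- laue %||% stream$header$laue
  obs <- stream$observations
  if (nrow(obs) == 0) {
    abort("stream contains no observations", class = "ssrox_error_merge")
  }
  asu <- hkl_asu(obs$h, obs$k, obs$l, laue)
  s <- inv_d2(stream$header$cell, asu$h, asu$k, asu$l)
  tibble(
    image = obs$image,
    h = asu$h, k = asu$k, l = asu$l, s = s,
    i_corr = obs$i_obs / lorentz_factor(s, stream$header$beam$wavelength),
    sigma_corr = obs$sigma_obs / lorentz_factor(s, stream$header$beam$wavelength)
  )
}

#' Estimate per-image linear scale factors
#'
#' Iterative per-image linear scaling against a merged reference, the
#' standard serial-crystallography scheme: pass 0 merges the (Lorentz
#' corrected) observations unscaled into a reference R; each iteration then
#' sets, for every image j,
#' \deqn{g_j = \sum_h I_{jh} R_h \Big/ \sum_h R_h^2}
#' (the least-squares slope of that image's intensities on the reference) and
#' re-merges with I/g. Scales are renormalised to geometric mean 1 after each
#' pass and clamped to `clamp` to guard degenerate images. The procedure is
#' deterministic.
#'
#' @param stream An observation stream.
#' @param n_iterations Scaling passes (default 3).
#' @param laue Laue group for merging; defaults to the stream's tag.
#' @param clamp Lower/upper clamp applied to the scales.
#' @return A tibble `image, scale` covering every image with observations.
#'   The attribute `n_flagged` counts images whose scale was degenerate and
#'   reset to 1 (a warning is emitted when non-zero).
#' @export
estimate_image_scales <- function(stream, n_iterations = 3, laue = NULL,
                                  clamp = c(0.01, 100)) {
  wt <- obs_working_table(stream, laue)
  imgs <- sort(unique(wt$image))
  g <- setNames(rep(1, length(imgs)), imgs)
  n_flagged <- 0L
  for (iter in seq_len(n_iterations)) {
    ref <- wt |>
      dplyr::mutate(i_scaled = .data$i_corr / g[as.character(.data$image)]) |>
      dplyr::summarise(r = mean(.data$i_scaled), .by = c("h", "k", "l"))
    joined <- dplyr::left_join(wt, ref, by = c("h", "k", "l"))
    upd <- joined |>
      dplyr::summarise(
        num = sum(.data$i_corr * .data$r),
        den = sum(.data$r^2),
        .by = "image"
      )
    g_new <- upd$num / upd$den
    bad <- !is.finite(g_new) | g_new <= 0
    n_flagged <- n_flagged + sum(bad & iter == n_iterations)
    g_new[bad] <- 1
    g_new <- pmin(pmax(g_new, clamp[1]), clamp[2])
    g_new <- g_new / exp(mean(log(g_new)))
    g <- setNames(g_new, upd$image)[as.character(imgs)]
  }
  if (n_flagged > 0) {
    warn(sprintf("%d image scale(s) were degenerate and reset to 1", n_flagged))
  }
  out <- tibble(image = imgs, scale = unname(g))
  attr(out, "n_flagged") <- n_flagged
  out
}

#' Monte Carlo merge of an observation stream
#'
#' Maps every observation to its Laue-unique index, divides out the Lorentz
#' factor and the per-image scale, and averages: the merged intensity is the
#' plain mean of the corrected observations (Monte Carlo merging), the merged
#' sigma is the sample standard deviation over the multiplicity divided by
#' sqrt(m) (undefined, `NA`, for m = 1), and two half-set means are kept by
#' image-index parity (even/odd acquisition index) for CC1/2 and Rsplit.
#'
#' @param stream An observation stream.
#' @param laue Laue group for merging; defaults to the stream's tag.
#' @param scales Optional tibble `image, scale` from
#'   [estimate_image_scales()]; omitted means unit scales.
#' @return A tibble of class `ssrox_merged` with one row per unique
#'   reflection: `h, k, l, d, s, i_merged, sigma_merged, m, i_even, i_odd,
#'   n_even, n_odd` (half means are `NA` when the respective count is 0).
#'   Attributes: `cell`, `laue`, `wavelength`, `n_merged_images`.
#' @export
monte_carlo_merge <- function(stream, laue = NULL, scales = NULL) {
  laue <- laue %||% stream$header$laue
  wt <- obs_working_table(stream, laue)
  if (!is.null(scales)) {
    missing_imgs <- setdiff(unique(wt$image), scales$image)
    if (length(missing_imgs) > 0) {
      abort("`scales` must cover every image with observations",
        class = "ssrox_error_merge"
      )
    }
    wt <- dplyr::left_join(wt, scales, by = "image")
    wt$i_corr <- wt$i_corr / wt$scale
  }
  merged <- wt |>
    dplyr::mutate(even = .data$image %% 2L == 0L) |>
    dplyr::summarise(
      s = .data$s[1],
      i_merged = mean(.data$i_corr),
      sigma_merged = ifelse(dplyr::n() >= 2,
        sd(.data$i_corr) / sqrt(dplyr::n()), NA_real_
      ),
      m = dplyr::n(),
      n_even = sum(.data$even),
      n_odd = sum(!.data$even),
      i_even = ifelse(sum(.data$even) > 0, mean(.data$i_corr[.data$even]), NA_real_),
      i_odd = ifelse(sum(!.data$even) > 0, mean(.data$i_corr[!.data$even]), NA_real_),
      .by = c("h", "k", "l")
    ) |>
    dplyr::mutate(d = 1 / sqrt(.data$s)) |>
    dplyr::select(
      "h", "k", "l", "d", "s", "i_merged", "sigma_merged",
      "m", "i_even", "i_odd", "n_even", "n_odd"
    ) |>
    dplyr::arrange(.data$s)
  structure(
    merged,
    class = c("ssrox_merged", class(merged)),
    cell = stream$header$cell,
    laue = laue,
    wavelength = stream$header$beam$wavelength,
    n_merged_images = length(unique(wt$image))
  )
}

# reflections with both half-set means defined
both_halves <- function(merged) {
  merged[merged$n_even > 0 & merged$n_odd > 0 &
    is.finite(merged$i_even) & is.finite(merged$i_odd), ]
}

#' Half-set discrepancy Rsplit
#'
#' \deqn{R_{split} = 100 \cdot 2^{-1/2}
#'   \frac{\sum_h |I_{even} - I_{odd}|}{\tfrac12 \sum_h (I_{even} + I_{odd})}}
#' over reflections with both half-set means present. The 1/sqrt(2) prefactor
#' compensates for each half holding half the observations.
#'
#' @param merged A merged set ([monte_carlo_merge()]) or any data frame with
#'   `i_even, i_odd, n_even, n_odd`.
#' @return Rsplit in percent.
#' @export
rsplit <- function(merged) {
  el <- both_halves(merged)
  if (nrow(el) == 0) {
    abort("no reflection has both half-set means", class = "ssrox_error_merge")
  }
  100 / sqrt(2) * sum(abs(el$i_even - el$i_odd)) / (0.5 * sum(el$i_even + el$i_odd))
}

#' Half-set correlation CC1/2
#'
#' Pearson correlation between the two half-set merged intensities over
#' reflections with both halves present. Undefined (returned as `NA`) with
#' fewer than 3 pairs or zero variance in either half.
#'
#' @inheritParams rsplit
#' @return The correlation, or `NA_real_` when undefined.
#' @export
cc_half <- function(merged) {
  el <- both_halves(merged)
  if (nrow(el) < 3) return(NA_real_)
  if (sd(el$i_even) == 0 || sd(el$i_odd) == 0) return(NA_real_)
  cor(el$i_even, el$i_odd)
}
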