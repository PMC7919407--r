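# Deterministic part of a drift trajectory at acquisition fraction t in [0, 1]:
# linear start -> end over [0, knot], constant at `end` beyond the knot.
drift_trajectory <- function(rec, t) {
  frac <- pmin(t / rec$knot, 1)
  rec$start + (rec$end - rec$start) * frac
}

#' Unit cell at a given point of the acquisition
#'
#' Evaluates the drift model at one image index: the deterministic
#' piecewise-linear trajectory of each cell parameter plus its seeded
#' per-image Gaussian jitter. With all jitters zero the value is exactly the
#' trajectory. Jitter draws come from a per-image substream keyed on
#' `("cell", image_index)`, so the cell simulated for image i can be
#' recomputed in isolation.
#'
#' @param drift A drift model from [drift_model()].
#' @param image_index 0-based image index in acquisition order.
#' @param total_images Total images in the acquisition.
#' @param seed Master seed of the simulation.
#' @return A unit cell ([unit_cell()]).
#' @export
cell_at <- function(drift, image_index, total_images, seed = 1) {
  stopifnot(inherits(drift, "ssrox_drift"))
  if (image_index < 0 || image_index >= total_images) {
    abort("`image_index` must satisfy 0 <= image_index < total_images",
      class = "ssrox_error_drift"
    )
  }
  t <- if (total_images > 1) image_index / (total_images - 1) else 0
  vals <- purrr::map_dbl(drift, drift_trajectory, t = t)
  jit_sd <- purrr::map_dbl(drift, "jitter")
  if (any(jit_sd > 0)) {
    jit <- with_substream(seed, c("cell", format(image_index)), rnorm(6, 0, 1))
    vals <- vals + jit * jit_sd
  }
  unit_cell(vals[["a"]], vals[["b"]], vals[["c"]],
    vals[["alpha"]], vals[["beta"]], vals[["gamma"]]
  )
}

# All drifted cells of an acquisition as an n x 6 tibble (vectorised, but
# jitter draws use the same per-image substreams as cell_at()).
drift_cells <- function(drift, total_images, seed = 1) {
  t <- if (total_images > 1) (seq_len(total_images) - 1) / (total_images - 1) else 0
  base <- purrr::map(drift, drift_trajectory, t = t)
  jit_sd <- purrr::map_dbl(drift, "jitter")
  if (any(jit_sd > 0)) {
    jit <- vapply(
      seq_len(total_images) - 1L,
      function(i) with_substream(seed, c("cell", format(i)), rnorm(6, 0, 1)),
      numeric(6)
    )
    for (j in seq_along(base)) {
      base[[j]] <- base[[j]] + jit[j, ] * jit_sd[[j]]
    }
  }
  tibble(
    a = rep_len(base$a, total_images), b = rep_len(base$b, total_images),
    c = rep_len(base$c, total_images), alpha = rep_len(base$alpha, total_images),
    beta = rep_len(base$beta, total_images), gamma = rep_len(base$gamma, total_images)
  )
}
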