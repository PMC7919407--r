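#' Generate ground-truth reflection intensities under Wilson statistics
#'
#' Draws one true intensity per symmetry-unique reflection from the acentric
#' Wilson distribution: an exponential law with resolution-dependent mean
#' \deqn{\langle I \rangle(s) = \Sigma_0 \exp(-B\,s/2),}
#' where s = 1/d\eqn{^2}. The decay constant `b_true` is the simulated
#' crystal's overall (Wilson) B factor; downstream analyses should recover it
#' from the merged data. All reflections are treated as acentric.
#'
#' @param cell A unit cell from [unit_cell()].
#' @param d_min Resolution limit in angstrom.
#' @param b_true Overall B factor in angstrom squared (>= 0).
#' @param sigma0 Intensity scale \eqn{\Sigma_0} (> 0), arbitrary photon-scale
#'   units.
#' @param laue Laue group tag, see [hkl_asu()].
#' @param seed Master seed; intensities come from the `"truth"` substream so
#'   later simulation stages never perturb them.
#' @param max_grid Passed to [enumerate_unique_hkl()].
#' @return An object of class `ssrox_truth`: a list with `reflections`
#'   (tibble `h, k, l, d, s, i_true`), and the generating parameters
#'   `cell, d_min, b_true, sigma0, laue, seed`.
#' @examples
#' tr <- generate_truth(tetragonal_cell(78.4, 38.4), d_min = 4, b_true = 25, seed = 1)
#' head(tr$reflections)
#' @export
generate_truth <- function(cell, d_min, b_true, sigma0 = 100, laue = c("4/mmm", "identity"),
                           seed = 1, max_grid = 2e7) {
  cell <- as_cell(cell)
  laue <- match.arg(laue)
  if (!is.finite(b_true) || b_true < 0) {
    abort("`b_true` must be a non-negative B factor", class = "ssrox_error_truth")
  }
  if (!is.finite(sigma0) || sigma0 <= 0) {
    abort("`sigma0` must be a positive intensity scale", class = "ssrox_error_truth")
  }
  refl <- enumerate_unique_hkl(cell, d_min, laue, max_grid = max_grid)
  if (nrow(refl) == 0) {
    abort("no reflections inside the resolution limit", class = "ssrox_error_truth")
  }
  mean_i <- sigma0 * exp(-b_true * refl$s / 2)
  refl$i_true <- with_substream(seed, "truth", rexp(nrow(refl), rate = 1 / mean_i))
  structure(
    list(
      reflections = refl, cell = cell, d_min = d_min,
      b_true = b_true, sigma0 = sigma0, laue = laue, seed = seed
    ),
    class = "ssrox_truth"
  )
}

#' @export
print.ssrox_truth <- function(x, ...) {
  cat(sprintf(
    "<truth set> %d unique reflections to %.3g Å (%s), B = %.3g Å², Sigma0 = %.3g\n",
    nrow(x$reflections), x$d_min, x$laue, x$b_true, x$sigma0
  ))
  invisible(x)
}
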