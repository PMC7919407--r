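#' Fit the logarithmic resolution-versus-photons scaling law
#'
#' Fits \deqn{1/d^2 = a \ln(b\, N_{photon})} by ordinary least squares in the
#' transformed coordinates (ln N, 1/d\eqn{^2}): the slope is `a` and the
#' intercept is `a ln(b)`. Closed form and deterministic. `N_photon` is the
#' total photon count spent on the merged (indexed) images of a data set;
#' see [total_photons()].
#'
#' @param points A data frame with columns `n_photon` and `inv_d2` (or `d`,
#'   from which `inv_d2` is computed). At least 3 points; all `n_photon` and
#'   `inv_d2` must be positive. Two points are accepted as an exact
#'   interpolation.
#' @return An object of class `ssrox_log_scaling`: list with `a_slope`
#'   (angstrom^-2), `b_scale` (photons^-1), `r_squared`, `residuals`, and the
#'   fitted points. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' pts <- tibble::tibble(n_photon = c(2e12, 2e13, 1.3e14))
#' pts$inv_d2 <- 0.044 * log(6.5e-11 * pts$n_photon)
#' fit_log_model(pts)
#' @export
fit_log_model <- function(points) {
  points <- as_tibble(points)
  if (!"inv_d2" %in% names(points)) {
    if (!"d" %in% names(points)) {
      abort("`points` needs a column `inv_d2` or `d`", class = "ssrox_error_scaling")
    }
    points$inv_d2 <- 1 / points$d^2
  }
  if (!"n_photon" %in% names(points)) {
    abort("`points` needs a column `n_photon`", class = "ssrox_error_scaling")
  }
  if (nrow(points) < 2) {
    abort("need at least 2 points", class = "ssrox_error_scaling")
  }
  if (any(points$n_photon <= 0) || any(points$inv_d2 <= 0)) {
    abort("all `n_photon` and `inv_d2` must be positive", class = "ssrox_error_scaling")
  }
  if (diff(range(points$n_photon)) == 0) {
    abort("degenerate abscissa: all `n_photon` identical", class = "ssrox_error_scaling")
  }
  fit <- lm(inv_d2 ~ log(n_photon), data = points)
  a <- unname(coef(fit)[2])
  if (!is.finite(a) || a <= 0) {
    abort("fitted slope `a` is not positive; data do not follow the law",
      class = "ssrox_error_scaling"
    )
  }
  b <- exp(unname(coef(fit)[1]) / a)
  ss_tot <- sum((points$inv_d2 - mean(points$inv_d2))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(
      a_slope = a, b_scale = b, r_squared = r2,
      residuals = unname(stats::residuals(fit)), points = points
    ),
    class = "ssrox_log_scaling"
  )
}

#' Construct a scaling-law model from known constants
#'
#' @param a_slope The slope a in angstrom^-2 (> 0).
#' @param b_scale The scale b in photons^-1 (> 0).
#' @return A `ssrox_log_scaling` object without fit diagnostics.
#' @export
log_scaling_model <- function(a_slope, b_scale) {
  if (a_slope <= 0 || b_scale <= 0) {
    abort("`a_slope` and `b_scale` must be positive", class = "ssrox_error_scaling")
  }
  structure(
    list(
      a_slope = a_slope, b_scale = b_scale, r_squared = NA_real_,
      residuals = numeric(), points = NULL
    ),
    class = "ssrox_log_scaling"
  )
}

#' @export
print.ssrox_log_scaling <- function(x, ...) {
  cat(sprintf(
    "<log scaling law> 1/d^2 = %.4g * ln(%.4g * N_photon)%s\n",
    x$a_slope, x$b_scale,
    if (is.na(x$r_squared)) "" else sprintf("  (R^2 = %.4f)", x$r_squared)
  ))
  invisible(x)
}

#' Predict achievable resolution from a photon budget
#'
#' \deqn{d = [a \ln(b N)]^{-1/2}} for N above the measurability threshold
#' 1/b.
#'
#' @param model A `ssrox_log_scaling` model.
#' @param n_photon Total photons (> 1/b).
#' @return Resolution d in angstrom (vectorised over `n_photon`).
#' @examples
#' m <- log_scaling_model(a_slope = 0.044, b_scale = 6.5e-11)
#' predict_resolution(m, 2000 * 9.3e9) # ~1.8 A
#' @export
predict_resolution <- function(model, n_photon) {
  stopifnot(inherits(model, "ssrox_log_scaling"))
  if (any(n_photon <= 1 / model$b_scale)) {
    abort(
      sprintf(
        "photon count below measurability threshold N0 = %.4g", 1 / model$b_scale
      ),
      class = "ssrox_error_scaling"
    )
  }
  1 / sqrt(model$a_slope * log(model$b_scale * n_photon))
}

#' Zero-crossing photon count of the scaling law
#'
#' The photon count at which the predicted 1/d^2 reaches zero: N0 = 1/b.
#' Below it no meaningful data can be obtained.
#'
#' @param model A `ssrox_log_scaling` model.
#' @return N0 in photons.
#' @export
zero_crossing <- function(model) {
  stopifnot(inherits(model, "ssrox_log_scaling"))
  1 / model$b_scale
}

#' Number of images needed for a target resolution
#'
#' Inverts the scaling law for planning: the smallest integer count of
#' merged images, each worth `photons_per_image` photons, whose total photon
#' budget reaches `d_target`:
#' \deqn{\lceil \exp((1/d^2)/a) / (b \cdot photons\_per\_image) \rceil.}
#'
#' @param model A `ssrox_log_scaling` model.
#' @param d_target Target resolution in angstrom (> 0).
#' @param photons_image Photons per merged image (> 0).
#' @return Integer image count.
#' @export
images_needed <- function(model, d_target, photons_image) {
  stopifnot(inherits(model, "ssrox_log_scaling"))
  if (any(d_target <= 0) || any(photons_image <= 0)) {
    abort("`d_target` and `photons_image` must be positive", class = "ssrox_error_scaling")
  }
  as.integer(ceiling(exp((1 / d_target^2) / model$a_slope) /
    (model$b_scale * photons_image)))
}

#' Wilson-plot interpretation of the scaling law
#'
#' Interprets the fitted (a, b) through the Wilson-plot derivation of the
#' law. The composite constant is \eqn{K = 21.3\,n\,c / I_{min}} (photons^-1),
#' where `I_min` is the minimum measurable intensity, `n` the number of atoms
#' in the unit cell, `c` the proportionality constant between photons and
#' recorded intensity, and 21.3 the zero-angle mean squared atomic scattering
#' factor per atom; a self-consistent constant set reproduces `b` exactly,
#' and the zero-crossing is N0 = 1/b. The slope is mapped to an overall B
#' factor by `b_mapping`, by default
#' \deqn{B = 2/a - 2 k_f,\qquad k_f = 5.08\ \mathrm{\AA^2},}
#' the single-exponential approximation f\eqn{^2}(s) proportional to
#' exp(-k_f s) of the mean squared atomic scattering factor (see the methods
#' vignette for the derivation and its limits).
#'
#' @param model A `ssrox_log_scaling` model.
#' @param n_atoms Atoms in the unit cell (optional).
#' @param c_const Proportionality constant for N_photon (optional).
#' @param i_min Minimum measurable intensity (optional). Any missing
#'   constant leaves `K` and `i_min`-dependent fields `NA` (partial report).
#' @param b_mapping Function mapping the slope `a` to a B factor in angstrom
#'   squared, or `NULL` to skip (B flagged unavailable). The default is the
#'   mapping described above.
#' @param f2_const The zero-angle mean squared scattering factor (21.3).
#' @return A tibble with one row: `a_slope`, `b_scale`, `n0` (= 1/b), `k`
#'   (= 21.3 n c / I_min, `NA` if constants missing), `b_wilson_from_a`,
#'   `i_min`, `n_atoms`, `c_const`, `f2_const`.
#' @export
wilson_interpretation <- function(model, n_atoms = NULL, c_const = NULL,
                                  i_min = NULL, b_mapping = b_from_slope,
                                  f2_const = 21.3) {
  stopifnot(inherits(model, "ssrox_log_scaling"))
  consts <- list(n_atoms = n_atoms, c_const = c_const, i_min = i_min)
  given <- !vapply(consts, is.null, logical(1))
  if (any(given) && any(unlist(consts[given]) <= 0)) {
    abort("supplied constants must be positive", class = "ssrox_error_scaling")
  }
  k <- if (all(given)) f2_const * n_atoms * c_const / i_min else NA_real_
  b_wilson <- if (is.null(b_mapping)) NA_real_ else b_mapping(model$a_slope)
  tibble(
    a_slope = model$a_slope,
    b_scale = model$b_scale,
    n0 = 1 / model$b_scale,
    k = k,
    b_wilson_from_a = b_wilson,
    i_min = i_min %||% NA_real_,
    n_atoms = n_atoms %||% NA_real_,
    c_const = c_const %||% NA_real_,
    f2_const = f2_const
  )
}

#' @rdname wilson_interpretation
#' @param a_slope Slope of the scaling law (angstrom^-2).
#' @param k_f Decay constant (angstrom squared) of the single-exponential
#'   squared-scattering-factor approximation.
#' @export
b_from_slope <- function(a_slope, k_f = 5.08) {
  2 / a_slope - 2 * k_f
}

#' @export
tidy.ssrox_log_scaling <- function(x, ...) {
  tibble(
    term = c("a_slope", "b_scale"),
    estimate = c(x$a_slope, x$b_scale)
  )
}

#' @export
glance.ssrox_log_scaling <- function(x, ...) {
  tibble(
    r_squared = x$r_squared,
    n_points = if (is.null(x$points)) 0L else nrow(x$points),
    n0 = zero_crossing(x)
  )
}

#' @export
autoplot.ssrox_log_scaling <- function(object, ...) {
  if (is.null(object$points)) {
    abort("model has no fitted points to plot", class = "ssrox_error_scaling")
  }
  rng <- range(object$points$n_photon)
  grid <- tibble(n_photon = exp(seq(log(rng[1]), log(rng[2]), length.out = 200)))
  grid$inv_d2 <- object$a_slope * log(object$b_scale * grid$n_photon)
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$n_photon, y = .data$inv_d2)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression(N[photon]),
      y = expression(1 / d^2 ~ (ring(A)^-2))
    )
}
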