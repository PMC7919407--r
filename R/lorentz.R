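#' Lorentz factor for rotation geometry
#'
#' The Lorentz factor L = 1/sin(2\eqn{\theta}) with
#' sin\eqn{\theta} = \eqn{\lambda\sqrt{s}/2} accounts for the speed at which
#' a reflection sweeps through the diffraction condition during rotation.
#' Recorded intensities are inflated by L; the merging correction divides by
#' it. Vectorised over `s`.
#'
#' @param s Resolution abscissa 1/d\eqn{^2}, angstrom\eqn{^{-2}} (> 0).
#' @param wavelength X-ray wavelength in angstrom.
#' @return The factor L (>= 1 at low resolution while 2\eqn{\theta} < 90
#'   degrees).
#' @examples
#' lorentz_factor(0.25, wavelength = 1) # d = 2 A -> 2.0656
#' @export
lorentz_factor <- function(s, wavelength = 1.0) {
  sin_theta <- wavelength * sqrt(s) / 2
  if (any(!is.finite(sin_theta)) || any(sin_theta <= 0) || any(sin_theta >= 1)) {
    abort("reflection outside the diffraction sphere: need 0 < wavelength*sqrt(s)/2 < 1",
      class = "ssrox_error_lorentz"
    )
  }
  1 / sin(2 * asin(sin_theta))
}
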