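#' Apply dose-dependent B-factor damage to an intensity
#'
#' Damps an intensity at resolution s by the damage model's B-factor growth:
#' \deqn{I' = I \exp(-\beta\, f D\, s / 2)}
#' with D the absorbed dose in MGy and f the model's
#' `dose_fraction_applied`. The operation is the identity when any of
#' `dose`, `s` or `beta` is zero, and strictly decreasing in dose otherwise.
#' Vectorised over `i` and `s`.
#'
#' @param i Intensity (any non-negative scale).
#' @param s Resolution abscissa 1/d\eqn{^2}, angstrom\eqn{^{-2}}.
#' @param dose Absorbed dose in MGy (>= 0).
#' @param model A damage model from [damage_model()].
#' @return Damped intensity, same length as `i`.
#' @examples
#' apply_damage(1, s = 0.3459, dose = 0.21, damage_model(beta = 10, dose_fraction_applied = 1))
#' @export
apply_damage <- function(i, s, dose, model = damage_model()) {
  stopifnot(inherits(model, "ssrox_damage"))
  if (any(dose < 0)) {
    abort("`dose` must be >= 0 MGy", class = "ssrox_error_damage")
  }
  i * exp(-model$beta * model$dose_fraction_applied * dose * s / 2)
}
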