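#' Construct a unit cell
#'
#' A unit cell is described by its three edge lengths (angstrom) and three
#' inter-axial angles (degrees). [tetragonal_cell()] is a convenience preset
#' that enforces `a = b` and all angles 90, the metric of the tetragonal
#' lysozyme-like crystals the simulator emulates.
#'
#' @param a,b,c Cell edge lengths in angstrom. All must be positive.
#' @param alpha,beta,gamma Inter-axial angles in degrees, each in (0, 180).
#' @return An object of class `ssrox_cell`: a named list with fields
#'   `a, b, c, alpha, beta, gamma`.
#' @examples
#' cell <- tetragonal_cell(a = 78.4, c = 38.4)
#' d_spacing(cell, h = 1, k = 1, l = 1)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  vals <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(vals))) {
    abort("all cell parameters must be finite numbers", class = "ssrox_error_cell")
  }
  if (any(vals[1:3] <= 0)) {
    abort("cell lengths must be positive", class = "ssrox_error_cell")
  }
  if (any(vals[4:6] <= 0 | vals[4:6] >= 180)) {
    abort("cell angles must lie in (0, 180) degrees", class = "ssrox_error_cell")
  }
  structure(as.list(vals), class = "ssrox_cell")
}

#' @rdname unit_cell
#' @export
tetragonal_cell <- function(a, c) {
  unit_cell(a = a, b = a, c = c, alpha = 90, beta = 90, gamma = 90)
}

#' @export
print.ssrox_cell <- function(x, ...) {
  cat(sprintf(
    "<unit cell> a=%.4g b=%.4g c=%.4g Å  alpha=%.4g beta=%.4g gamma=%.4g°\n",
    x$a, x$b, x$c, x$alpha, x$beta, x$gamma
  ))
  invisible(x)
}

is_cell <- function(x) inherits(x, "ssrox_cell")

as_cell <- function(x) {
  if (is_cell(x)) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    return(unit_cell(x$a, x$b, x$c, x$alpha %||% 90, x$beta %||% 90, x$gamma %||% 90))
  }
  abort("cannot interpret object as a unit cell", class = "ssrox_error_cell")
}

# Reciprocal-metric coefficients for the general (triclinic) case.
# 1/d^2 = S11 h^2 + S22 k^2 + S33 l^2 + 2 S12 hk + 2 S23 kl + 2 S13 hl
cell_reciprocal_metric <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sa <- sin(cell$alpha * pi / 180)
  sb <- sin(cell$beta * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v_factor <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  V <- cell$a * cell$b * cell$c * v_factor
  list(
    S11 = (cell$b * cell$c * sa / V)^2,
    S22 = (cell$a * cell$c * sb / V)^2,
    S33 = (cell$a * cell$b * sg / V)^2,
    S12 = cell$a * cell$b * cell$c^2 * (ca * cb - cg) / V^2,
    S23 = cell$a^2 * cell$b * cell$c * (cb * cg - ca) / V^2,
    S13 = cell$a * cell$b^2 * cell$c * (cg * ca - cb) / V^2,
    volume = V
  )
}

#' Resolution of a reflection
#'
#' `inv_d2()` returns s = 1/d\eqn{^2} (angstrom\eqn{^{-2}}), the square inverse
#' of the Bragg spacing, the abscissa used throughout the package;
#' `d_spacing()` returns d itself. Both are vectorised over `h, k, l`.
#'
#' @param cell A unit cell from [unit_cell()].
#' @param h,k,l Integer Miller indices (vectors of equal length).
#' @return Numeric vector of s values (`inv_d2`) or d values in angstrom
#'   (`d_spacing`).
#' @export
inv_d2 <- function(cell, h, k, l) {
  cell <- as_cell(cell)
  m <- cell_reciprocal_metric(cell)
  m$S11 * h^2 + m$S22 * k^2 + m$S33 * l^2 +
    2 * (m$S12 * h * k + m$S23 * k * l + m$S13 * h * l)
}

#' @rdname inv_d2
#' @export
d_spacing <- function(cell, h, k, l) {
  1 / sqrt(inv_d2(cell, h, k, l))
}
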