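#' Map Miller indices to a canonical Laue-group representative
#'
#' Reduces each (h, k, l) to a unique representative of its orbit under the
#' declared Laue group (rotational symmetry plus the Friedel inversion).
#' Two reflections merge together exactly when their representatives match.
#'
#' Supported groups: `"identity"` (Friedel pair only; half-sphere convention
#' keeping the member with l > 0, or l = 0 and k > 0, or l = k = 0 and h >= 0)
#' and `"4/mmm"` (tetragonal holohedry; representative has
#' max(|h|,|k|) >= min(|h|,|k|) >= 0 and l >= 0).
#'
#' @param h,k,l Integer Miller indices (equal-length vectors).
#' @param laue Laue group tag: `"identity"` or `"4/mmm"`.
#' @return A tibble with columns `h, k, l` holding the canonical indices.
#' @export
hkl_asu <- function(h, k, l, laue = c("4/mmm", "identity")) {
  laue <- match.arg(laue)
  stopifnot(length(h) == length(k), length(k) == length(l))
  if (laue == "4/mmm") {
    hh <- pmax(abs(h), abs(k))
    kk <- pmin(abs(h), abs(k))
    ll <- abs(l)
    return(tibble(h = hh, k = kk, l = ll))
  }
  # identity: fold Friedel mates onto one hemisphere
  neg <- (l < 0) | (l == 0 & k < 0) | (l == 0 & k == 0 & h < 0)
  tibble(
    h = ifelse(neg, -h, h),
    k = ifelse(neg, -k, k),
    l = ifelse(neg, -l, l)
  )
}

#' Enumerate symmetry-unique reflections to a resolution limit
#'
#' Lists every symmetry-unique reciprocal-lattice point with Bragg spacing
#' d >= `d_min` under the declared Laue group. The enumeration bound per axis
#' uses |h| <= a/d (and likewise for k, l), which is exact for any cell.
#'
#' @param cell A unit cell from [unit_cell()].
#' @param d_min Resolution limit in angstrom (> 0); reflections with d below
#'   this are excluded.
#' @param laue Laue group tag, see [hkl_asu()].
#' @param max_grid Safety cap on the raw enumeration grid size before
#'   symmetry reduction; exceeded caps raise an error rather than exhausting
#'   memory.
#' @return A tibble with one row per unique reflection: integer `h, k, l`,
#'   Bragg spacing `d` (angstrom) and `s` = 1/d\eqn{^2} (angstrom\eqn{^{-2}}),
#'   sorted by increasing `s`.
#' @examples
#' nrow(enumerate_unique_hkl(tetragonal_cell(78.4, 38.4), d_min = 5))
#' @export
enumerate_unique_hkl <- function(cell, d_min, laue = c("4/mmm", "identity"),
                                 max_grid = 2e7) {
  cell <- as_cell(cell)
  laue <- match.arg(laue)
  if (!is.finite(d_min) || d_min <= 0) {
    abort("`d_min` must be a positive resolution in angstrom",
      class = "ssrox_error_hkl"
    )
  }
  hmax <- floor(cell$a / d_min)
  kmax <- floor(cell$b / d_min)
  lmax <- floor(cell$c / d_min)
  n_grid <- (2 * hmax + 1) * (2 * kmax + 1) * (2 * lmax + 1)
  if (n_grid > max_grid) {
    abort(
      sprintf(
        "enumeration grid of %.3g points exceeds cap of %.3g; raise `max_grid` or `d_min`",
        n_grid, max_grid
      ),
      class = "ssrox_error_hkl_size"
    )
  }
  grid <- expand.grid(
    h = seq.int(-hmax, hmax), k = seq.int(-kmax, kmax), l = seq.int(-lmax, lmax)
  )
  grid <- grid[!(grid$h == 0 & grid$k == 0 & grid$l == 0), ]
  asu <- hkl_asu(grid$h, grid$k, grid$l, laue)
  asu <- dplyr::distinct(asu)
  s <- inv_d2(cell, asu$h, asu$k, asu$l)
  keep <- s <= 1 / d_min^2 + 1e-12
  out <- tibble(
    h = asu$h[keep], k = asu$k[keep], l = asu$l[keep],
    d = 1 / sqrt(s[keep]), s = s[keep]
  )
  dplyr::arrange(out, .data$s, .data$h, .data$k, .data$l)
}
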