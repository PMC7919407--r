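#' Variable-plateau tanh model for CC1/2 versus resolution
#'
#' The sigmoid used to locate the resolution at which the half-set
#' correlation decays:
#' \deqn{CC(s) = \tfrac12\{1 - \tanh[(s - d_0)/r]\}\, d_{cc} - d_{cc} + b,}
#' with s = 1/d\eqn{^2}. The curve has a low-resolution plateau at `b`
#' (s below d0), a high-resolution plateau at `b - dcc`, a midpoint value
#' `b - dcc/2` at s = d0, and width `r`. Unlike the fixed-plateau variant,
#' `b` is free: sets merged from few images sit below 1 even at low
#' resolution.
#'
#' @param s Resolution abscissa 1/d\eqn{^2} (vectorised).
#' @param params Named list or vector with `d0`, `r`, `dcc`, `b` (a
#'   `cc_fit_params` object is accepted).
#' @return The model CC value(s).
#' @examples
#' cc_model(0.35, list(d0 = 0.35, r = 0.05, dcc = 0.95, b = 0.99)) # b - dcc/2
#' @export
cc_model <- function(s, params) {
  p <- as.list(params)
  0.5 * (1 - tanh((s - p$d0) / p$r)) * p$dcc - p$dcc + p$b
}

new_cc_fit <- function(params, converged, residual_norm, data, message = NULL) {
  structure(
    list(
      params = params, converged = converged,
      residual_norm = residual_norm, data = data, message = message
    ),
    class = "ssrox_cc_fit"
  )
}

#' Fit the tanh CC1/2 curve to shell statistics
#'
#' Nonlinear least squares of [cc_model()] against per-shell CC1/2 values.
#' Initialisation: `b` at the maximum CC, `dcc` at the CC range, `d0` at the
#' first s where CC drops below `b - dcc/2`, `r` at a tenth of the s range.
#' Bounds: `r > 0`, `dcc` in (0, 1.5], `b` in \[-0.5, 1.05\]. Fitting is
#' deterministic given the inputs. Failure to converge (including degenerate
#' flat input) yields a flagged result (`converged = FALSE`) carrying the
#' residuals rather than an error.
#'
#' @param s Shell abscissae: midpoints of the shells in s = 1/d\eqn{^2}.
#'   Alternatively a shell table from [shell_statistics()] (its `s_mid` and
#'   `cc_half` columns are used).
#' @param cc Per-shell CC1/2 values (ignored when `s` is a shell table).
#' @param weights Optional non-negative least-squares weights (e.g. shell
#'   reflection counts); default unweighted.
#' @return An object of class `ssrox_cc_fit` with elements `params`
#'   (`d0, r, dcc, b`), `converged`, `residual_norm` and the fitted data;
#'   supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_cc_curve <- function(s, cc = NULL, weights = NULL) {
  if (is.data.frame(s)) {
    df <- s
    s <- df$s_mid
    cc <- cc %||% df$cc_half
  }
  keep <- is.finite(s) & is.finite(cc)
  s <- s[keep]
  cc <- cc[keep]
  if (!is.null(weights)) weights <- weights[keep]
  if (length(s) < 4) {
    abort("need at least 4 shells to fit the CC curve", class = "ssrox_error_ccfit")
  }
  data <- tibble(s = s, cc = cc)
  b0 <- max(cc)
  dcc0 <- max(b0 - min(cc), 1e-3)
  half <- b0 - dcc0 / 2
  below <- which(cc < half)
  d00 <- if (length(below) > 0) s[below[1]] else stats::median(s)
  r0 <- max(diff(range(s)) / 10, 1e-4)
  start <- list(d0 = d00, r = r0, dcc = min(dcc0, 1.5), b = min(b0, 1.05))
  args <- list(
    cc ~ 0.5 * (1 - tanh((s - d0) / r)) * dcc - dcc + b,
    data = data, start = start,
    lower = c(d0 = -Inf, r = 1e-6, dcc = 1e-6, b = -0.5),
    upper = c(d0 = Inf, r = Inf, dcc = 1.5, b = 1.05),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_cc_fit(
      params = start, converged = FALSE,
      residual_norm = sqrt(sum((cc - cc_model(s, start))^2)),
      data = data, message = conditionMessage(fit)
    ))
  }
  p <- as.list(coef(fit))
  resid_norm <- sqrt(sum((cc - cc_model(s, p))^2))
  # a fit collapsed onto its dcc lower bound carries no sigmoid: flag it
  converged <- fit$convInfo$isConv %||% TRUE
  if (p$dcc <= 2e-6 || sd(cc) < 1e-12) converged <- FALSE
  new_cc_fit(p, converged, resid_norm, data)
}

#' @export
print.ssrox_cc_fit <- function(x, ...) {
  cat(sprintf(
    "<CC1/2 tanh fit> d0=%.5g r=%.5g dcc=%.5g b=%.5g  (residual %.3g%s)\n",
    x$params$d0, x$params$r, x$params$dcc, x$params$b, x$residual_norm,
    if (x$converged) "" else ", NOT converged"
  ))
  invisible(x)
}

#' Resolution at which the fitted CC1/2 curve crosses a threshold
#'
#' Inverts [cc_model()] in closed form:
#' \deqn{s^* = d_0 + r\,\mathrm{artanh}\!\left(1 - \frac{2(\tau + d_{cc} - b)}{d_{cc}}\right)}
#' and reports d = 1/sqrt(s*). Requires the threshold to lie strictly
#' between the two plateaus (`b - dcc < tau < b`) and the crossing to fall at
#' positive s.
#'
#' @param fit A `ssrox_cc_fit` object, or a named list of parameters
#'   `d0, r, dcc, b`.
#' @param tau CC1/2 threshold (default 0.5).
#' @return The resolution d in angstrom. The crossing abscissa is attached
#'   as attribute `s`.
#' @export
resolution_at_threshold <- function(fit, tau = 0.5) {
  p <- if (inherits(fit, "ssrox_cc_fit")) fit$params else as.list(fit)
  if (!(tau > p$b - p$dcc && tau < p$b)) {
    abort(
      sprintf(
        "threshold not crossed: tau = %.4g outside plateau range (%.4g, %.4g)",
        tau, p$b - p$dcc, p$b
      ),
      class = "ssrox_error_threshold"
    )
  }
  s_star <- p$d0 + p$r * atanh(1 - 2 * (tau + p$dcc - p$b) / p$dcc)
  if (!is.finite(s_star) || s_star <= 0) {
    abort("crossing outside physical range: s* <= 0",
      class = "ssrox_error_threshold"
    )
  }
  structure(1 / sqrt(s_star), s = s_star)
}

#' @export
tidy.ssrox_cc_fit <- function(x, ...) {
  tibble(
    term = c("d0", "r", "dcc", "b"),
    estimate = c(x$params$d0, x$params$r, x$params$dcc, x$params$b)
  )
}

#' @export
glance.ssrox_cc_fit <- function(x, ...) {
  d_half <- tryCatch(as.numeric(resolution_at_threshold(x, 0.5)),
    error = function(e) NA_real_
  )
  tibble(
    converged = x$converged, residual_norm = x$residual_norm,
    n_shells = nrow(x$data), d_at_cc_half = d_half
  )
}

#' @export
autoplot.ssrox_cc_fit <- function(object, tau = 0.5, ...) {
  grid <- tibble(s = seq(min(object$data$s), max(object$data$s), length.out = 200))
  grid$cc <- cc_model(grid$s, object$params)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$s, y = .data$cc)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = tau, linetype = 2) +
    ggplot2::labs(
      x = expression(s == 1 / d^2 ~ (ring(A)^-2)),
      y = expression(CC[1 / 2])
    )
}
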