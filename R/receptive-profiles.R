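#' Laplacian-of-Gaussian receptive profile
#'
#' The classical model for the radially symmetric receptive profiles of LGN
#' cells,
#' \deqn{\psi_{LoG}(x,y) = -\frac{1}{\pi\sigma^4}
#'   \left[1 - \frac{x^2+y^2}{2\sigma^2}\right]
#'   e^{-\frac{x^2+y^2}{2\sigma^2}},}
#' i.e. the (negated) Laplacian of a Gaussian of standard deviation
#' `sigma`. At the origin the value is `-1/(pi sigma^4)`; the profile
#' integrates to zero over the plane.
#'
#' @param x,y numeric coordinates (recycled to a common length); on filter
#'   grids these are the normalized coordinates of [filter_grid()].
#' @param sigma positive scalar, Gaussian standard deviation in normalized
#'   grid units.
#' @return numeric vector of profile values.
#' @export
log_profile <- function(x, y, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a positive finite scalar")
  r2 <- (x^2 + y^2) / (2 * sigma^2)
  -1 / (pi * sigma^4) * (1 - r2) * exp(-r2)
}

#' Gabor receptive-profile parameters
#'
#' Parameter container for the Gabor model of V1 simple-cell receptive
#' profiles. The canonical profile (centered, axis-aligned, unit scales) is
#' \deqn{\psi(x,y) = A\, e^{-\frac{x^2+y^2}{2}} \cos(2\pi f x + \phi),}
#' and the general profile is obtained by translating the center to
#' `(x0, y0)`, rotating by `theta` and dilating the Gaussian envelope by
#' `(sigma_x, sigma_y)`. The phase `phi` determines the parity of the
#' filter (odd profiles detect boundaries, even ones interiors).
#'
#' Normalization: `theta` is reduced to `[0, pi)` and `phi` to `[-pi, pi]`,
#' with the carrier rewritten accordingly (these rewrites leave the profile
#' values unchanged).
#'
#' @param A amplitude (any real).
#' @param x0,y0 center, in normalized grid coordinates.
#' @param theta orientation of the carrier axis, radians.
#' @param sigma_x,sigma_y positive envelope scales along/across the carrier
#'   axis.
#' @param f positive carrier frequency, cycles per normalized grid unit.
#' @param phi carrier phase, radians.
#' @return object of class `gabor_params`.
#' @export
gabor_params <- function(A = 1, x0 = 0, y0 = 0, theta = 0,
                         sigma_x = 1, sigma_y = 1, f = 1, phi = 0) {
  vals <- c(A, x0, y0, theta, sigma_x, sigma_y, f, phi)
  if (!all(is.finite(vals))) stop("Gabor parameters must be finite")
  if (sigma_x <= 0 || sigma_y <= 0) stop("'sigma_x' and 'sigma_y' must be positive")
  if (f <= 0) stop("'f' must be positive")
  # canonicalize: A >= 0, f > 0, theta in [0, pi), phi in [-pi, pi]
  if (A < 0) { A <- -A; phi <- phi + pi }
  th <- theta %% (2 * pi)
  if (th >= pi) { th <- th - pi; phi <- -phi }  # u -> -u flips the carrier sign
  p <- list(A = A, x0 = x0, y0 = y0, theta = th,
            sigma_x = sigma_x, sigma_y = sigma_y, f = f, phi = wrap_pi(phi))
  class(p) <- "gabor_params"
  p
}

#' @export
print.gabor_params <- function(x, ...) {
  cat(sprintf(
    "Gabor profile: A=%.4g center=(%.3g, %.3g) theta=%.4g rad sigma=(%.3g, %.3g) f=%.4g phi=%.4g\n",
    x$A, x$x0, x$y0, x$theta, x$sigma_x, x$sigma_y, x$f, x$phi))
  invisible(x)
}

#' Evaluate a Gabor receptive profile
#'
#' @param x,y numeric coordinates (recycled).
#' @param params a [gabor_params()] object (or list with the same fields).
#' @return numeric vector of profile values.
#' @export
gabor_profile <- function(x, y, params) {
  p <- if (inherits(params, "gabor_params")) params else do.call(gabor_params, params)
  dx <- x - p$x0
  dy <- y - p$y0
  u <- dx * cos(p$theta) + dy * sin(p$theta)
  v <- -dx * sin(p$theta) + dy * cos(p$theta)
  p$A * exp(-(u^2 / p$sigma_x^2 + v^2 / p$sigma_y^2) / 2) *
    cos(2 * pi * p$f * u + p$phi)
}

#' Render an analytic profile on the normalized filter grid
#'
#' @param s odd filter side length.
#' @param fun either a `gabor_params` object, a single positive number
#'   (interpreted as a LoG `sigma`), or a function `f(x, y)`.
#' @return `s x s` numeric matrix.
#' @export
render_profile <- function(s, fun) {
  g <- filter_grid(s)
  if (inherits(fun, "gabor_params")) {
    m <- gabor_profile(g$x, g$y, fun)
  } else if (is.numeric(fun) && length(fun) == 1) {
    m <- log_profile(g$x, g$y, fun)
  } else if (is.function(fun)) {
    m <- fun(g$x, g$y)
  } else stop("'fun' must be gabor_params, a LoG sigma, or a function")
  matrix(m, s, s)
}

#' Integral curves of the sub-Riemannian structure on R^2 x S^1
#'
#' The contact structure of the position-orientation space is generated by
#' the vector fields `X1 = (cos theta, sin theta, 0)` and `X2 = (0, 0, 1)`.
#' The integral curves of `X1 + k X2` starting at the origin with horizontal
#' initial orientation are circular arcs of curvature `k`:
#' \deqn{x(t) = \sin(kt)/k,\quad y(t) = (1-\cos(kt))/k,\quad \theta(t) = kt,}
#' with the straight-line limit `(t, 0, 0)` as `k -> 0`. Curves from a
#' general start `(x0, y0, theta0)` are obtained by rotating by `theta0`
#' and translating. The parameter `t` is arc length (the planar projection
#' has unit speed).
#'
#' @param k curvature (any real; `|k| < eps` uses the analytic straight-line
#'   limit).
#' @param t_grid strictly increasing numeric vector of arc-length values
#'   (may include negative values; `t = 0` is the start point).
#' @param start numeric length-3 `(x0, y0, theta0)`.
#' @param eps threshold below which the `k -> 0` limit branch is used;
#'   avoids catastrophic cancellation in `sin(kt)/k` for tiny `k`.
#' @return matrix with columns `x`, `y`, `theta` and one row per `t`.
#' @export
integral_curve <- function(k, t_grid, start = c(0, 0, 0), eps = 1e-8) {
  stopifnot(is.numeric(t_grid), length(t_grid) >= 1, !is.unsorted(t_grid, strictly = TRUE))
  stopifnot(length(start) == 3, all(is.finite(start)), is.finite(k))
  if (abs(k) < eps) {
    bx <- t_grid; by <- rep(0, length(t_grid)); bth <- rep(0, length(t_grid))
  } else {
    bx <- sin(k * t_grid) / k
    by <- (1 - cos(k * t_grid)) / k
    bth <- k * t_grid
  }
  th0 <- start[3]
  x <- start[1] + bx * cos(th0) - by * sin(th0)
  y <- start[2] + bx * sin(th0) + by * cos(th0)
  cbind(x = x, y = y, theta = th0 + bth)
}
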