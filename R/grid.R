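#' Normalized filter coordinate grid
#'
#' Every square filter of side `s` is evaluated on the normalized grid
#' `x, y in linspace(-1, 1, s)`. A single coordinate convention is used
#' throughout the package: `x` increases with the column index (rightward)
#' and `y` increases *upward*, i.e. row 1 of a filter matrix sits at
#' `y = +1`. Orientations are counter-clockwise angles from the positive
#' x-axis, treated as pi-periodic wherever they describe an undirected
#' orientation.
#'
#' @param s odd integer, filter side length in pixels.
#' @return list with components `x` and `y`, each an `s x s` matrix giving
#'   the coordinate of every filter entry, and `step`, the grid spacing
#'   `2/(s-1)` (normalized units per pixel).
#' @export
filter_grid <- function(s) {
  stopifnot(is.numeric(s), length(s) == 1, s >= 2, s == round(s))
  u <- seq(-1, 1, length.out = s)
  list(
    x = matrix(u, s, s, byrow = TRUE),
    y = matrix(rev(u), s, s),
    step = 2 / (s - 1)
  )
}

#' Wrap an angle to [-pi, pi]
#' @param a numeric vector of angles (radians).
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @keywords internal
wrap_pi <- function(a) {
  out <- (a + pi) %% (2 * pi) - pi
  # map the seam -pi -> pi is not needed; keep [-pi, pi) then fix exact -pi
  out[out == -pi] <- pi
  out
}

#' Wrap an orientation to [0, pi)
#' @param a numeric vector of angles (radians).
#' @keywords internal
wrap_orientation <- function(a) a %% pi

#' Smallest pi-periodic difference between two orientations
#'
#' Returns a value in (-pi/2, pi/2]; its magnitude is the undirected
#' angular distance between the orientations.
#' @param a,b numeric vectors of orientations (radians).
#' @keywords internal
orientation_diff <- function(a, b) {
  d <- (a - b) %% pi
  d[d > pi / 2] <- d[d > pi / 2] - pi
  d
}
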