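#' Fit a Laplacian-of-Gaussian model to a square filter
#'
#' Least-squares fit of the LoG receptive-profile model over `sigma`, with
#' a free amplitude multiplier profiled out analytically (a learned
#' filter's scale is arbitrary under batch normalization, and either
#' polarity can emerge, so the multiplier is sign-free; the recovered
#' `sigma` is unaffected). The objective is optimized by a coarse
#' log-spaced scan over `sigma` followed by golden-section refinement.
#'
#' @param filter square odd-sided numeric matrix.
#' @param sigma_range search interval for `sigma` (normalized grid units).
#' @return list of class `log_fit`: `sigma`, `amplitude`, `correlation`
#'   (Pearson, filter vs fitted surface), `p_value`, `fitted` (matrix),
#'   `converged`.
#' @export
fit_log <- function(filter, sigma_range = c(0.02, 1.5)) {
  stopifnot(is.matrix(filter), nrow(filter) == ncol(filter), nrow(filter) %% 2 == 1)
  s <- nrow(filter)
  if (stats::sd(as.vector(filter)) == 0)
    stop("constant filter: correlation with a LoG surface is undefined")
  g <- filter_grid(s)
  fv <- as.vector(filter)
  sse <- function(sig) {
    t <- as.vector(log_profile(g$x, g$y, sig))
    a <- sum(fv * t) / sum(t * t)
    sum((fv - a * t)^2)
  }
  grid <- exp(seq(log(sigma_range[1]), log(sigma_range[2]), length.out = 80))
  vals <- vapply(grid, sse, numeric(1))
  i0 <- which.min(vals)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-10)
  sig <- opt$minimum
  t <- as.vector(log_profile(g$x, g$y, sig))
  a <- sum(fv * t) / sum(t * t)
  fitted <- matrix(a * t, s, s)
  ct <- stats::cor.test(fv, as.vector(fitted))
  out <- list(sigma = sig, amplitude = a,
              correlation = unname(ct$estimate), p_value = ct$p.value,
              fitted = fitted, converged = TRUE)
  class(out) <- "log_fit"
  out
}

gabor_residual <- function(p, x, y, fv) {
  # p: A, x0, y0, theta, log sx, log sy, log f, phi
  pr <- list(A = p[1], x0 = p[2], y0 = p[3], theta = p[4],
             sigma_x = exp(p[5]), sigma_y = exp(p[6]), f = exp(p[7]), phi = p[8])
  class(pr) <- "gabor_params"
  fv - gabor_profile(x, y, pr)
}

#' Fit a Gabor model to a square filter
#'
#' Nonlinear least squares over the full Gabor parameter set (amplitude,
#' center, orientation, two envelope scales, frequency, phase) by
#' Levenberg-Marquardt, with a multi-start grid over orientation, phase
#' and frequency because the objective is nonconvex. Scales and frequency
#' are optimized on the log scale to stay positive. The best start by
#' residual wins; parameters are then canonicalized (`A >= 0`,
#' `theta` in `[0, pi)`, `phi` in `[-pi, pi]`).
#'
#' The carrier frequency is box-bounded by the Nyquist frequency of the
#' sampling grid, `(s-1)/4` cycles per normalized unit: a frequency above
#' it is not identifiable from an `s x s` filter (aliased solutions with
#' super-Nyquist carriers can otherwise fit the samples equally well at a
#' spurious orientation).
#'
#' @param filter square odd-sided numeric matrix.
#' @param theta_starts,phi_starts,freq_starts multi-start grids (frequency
#'   starts above the Nyquist bound are clamped).
#' @param n_refine number of best starts carried into full LM refinement.
#' @return list of class `gabor_fit`: `params` ([gabor_params()]),
#'   `correlation`, `p_value`, `fitted`, `converged`, `sse`.
#' @export
fit_gabor <- function(filter,
                      theta_starts = seq(0, pi, length.out = 9)[-9],
                      phi_starts = c(0, pi / 2, pi, -pi / 2),
                      freq_starts = c(0.5, 1, 2),
                      n_refine = 8) {
  stopifnot(is.matrix(filter), nrow(filter) == ncol(filter), nrow(filter) %% 2 == 1)
  s <- nrow(filter)
  if (stats::sd(as.vector(filter)) == 0)
    stop("constant filter: correlation with a Gabor surface is undefined")
  g <- filter_grid(s)
  fv <- as.vector(filter)
  xv <- as.vector(g$x); yv <- as.vector(g$y)
  # moment-based center / scale initialization
  w <- filter^2
  x0 <- sum(g$x * w) / sum(w); y0 <- sum(g$y * w) / sum(w)
  s0 <- sqrt(sum(((g$x - x0)^2 + (g$y - y0)^2) * w) / (2 * sum(w)))
  s0 <- min(max(s0, 0.15), 1.2)
  A0 <- max(abs(fv))
  f_max <- (s - 1) / 4  # Nyquist on the normalized grid (spacing 2/(s-1))
  freq_starts <- pmin(freq_starts, 0.95 * f_max)
  # bounds: A, x0, y0, theta, log sx, log sy, log f, phi
  lower <- c(-10 * A0, -1.5, -1.5, -Inf, log(0.05), log(0.05), log(0.1), -Inf)
  upper <- c(10 * A0, 1.5, 1.5, Inf, log(3), log(3), log(f_max), Inf)

  starts <- expand.grid(theta = theta_starts, phi = phi_starts, f = freq_starts)
  p_of <- function(i) c(A0, x0, y0, starts$theta[i], log(s0), log(s0),
                        log(starts$f[i]), starts$phi[i])
  sse0 <- vapply(seq_len(nrow(starts)), function(i)
    sum(gabor_residual(p_of(i), xv, yv, fv)^2), numeric(1))
  best_idx <- order(sse0)[seq_len(min(n_refine, nrow(starts)))]

  best <- NULL; best_sse <- Inf; any_conv <- FALSE
  for (i in best_idx) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p_of(i), fn = gabor_residual,
                         x = xv, y = yv, fv = fv, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:4
    any_conv <- any_conv || conv
    if (sse < best_sse) { best_sse <- sse; best <- fit }
  }
  if (is.null(best)) {
    # no start converged at all: best-effort parameters from the best start
    p <- p_of(best_idx[1]); best_sse <- sse0[best_idx[1]]
  } else p <- best$par
  params <- gabor_params(A = p[1], x0 = p[2], y0 = p[3], theta = p[4],
                         sigma_x = exp(p[5]), sigma_y = exp(p[6]),
                         f = exp(p[7]), phi = p[8])
  fitted <- matrix(gabor_profile(xv, yv, params), s, s)
  ct <- stats::cor.test(fv, as.vector(fitted))
  out <- list(params = params, correlation = unname(ct$estimate),
              p_value = ct$p.value, fitted = fitted,
              converged = !is.null(best) && any_conv, sse = best_sse)
  class(out) <- "gabor_fit"
  out
}

#' Classify a Gabor filter as odd or even from its phase
#'
#' Odd if `pi/4 < |phi| <= 3*pi/4`, even otherwise (`phi` is first wrapped
#' to `[-pi, pi]`). The rule depends on `|phi|` only. Boundary values,
#' which the strict-inequality rule leaves uncovered, are resolved by
#' closing the lower end of each interval: `|phi| = pi/4` is even,
#' `|phi| = 3*pi/4` is odd.
#'
#' @param phi phase in radians (vectorized).
#' @return character vector, `"odd"` or `"even"`.
#' @export
classify_parity <- function(phi) {
  a <- abs(wrap_pi(phi))
  ifelse(a > pi / 4 & a <= 3 * pi / 4, "odd", "even")
}

#' Normalize the sign of an even filter
#'
#' Even filters whose central lobe is negative are multiplied by -1 so
#' that galleries and kernel re-parameterizations are polarity-consistent.
#' The "central lobe" sample is the filter value at the grid point nearest
#' the fitted center. Odd filters are returned unchanged.
#'
#' @param filter square numeric matrix.
#' @param fit a `gabor_fit` for this filter.
#' @return list with `filter` (possibly negated) and `flipped` (logical).
#' @export
sign_normalize_even <- function(filter, fit) {
  parity <- classify_parity(fit$params$phi)
  if (parity != "even") return(list(filter = filter, flipped = FALSE))
  s <- nrow(filter)
  u <- seq(-1, 1, length.out = s)
  col <- which.min(abs(u - fit$params$x0))
  row <- which.min(abs(rev(u) - fit$params$y0))
  if (filter[row, col] < 0) list(filter = -filter, flipped = TRUE)
  else list(filter = filter, flipped = FALSE)
}

#' Order filters by fitted orientation
#'
#' @param thetas numeric vector of orientations in `[0, pi)` (or a list of
#'   `gabor_fit` objects).
#' @return integer permutation sorting the filters by ascending
#'   orientation; stable for ties.
#' @export
order_by_orientation <- function(thetas) {
  if (is.list(thetas))
    thetas <- vapply(thetas, function(f) f$params$theta, numeric(1))
  order(wrap_orientation(thetas))  # order() is stable
}

#' Fit Gabor models to a whole filter bank
#'
#' Runs [fit_gabor()] on every filter, classifies parity, applies even-
#' filter sign normalization and computes the orientation ordering.
#' Filters whose best correlation falls below `min_correlation` are
#' flagged as "complex shape" (`retained = FALSE`) and excluded from
#' downstream kernel geometry.
#'
#' @param bank array `(s, s, n)` of filters.
#' @param min_correlation retention threshold.
#' @return list with `table` (one row per filter: all parameters,
#'   correlation, p-value, parity, retained, order index), `fits` (list of
#'   `gabor_fit`), `normalized_bank` (sign-normalized filters).
#' @export
fit_filter_bank <- function(bank, min_correlation = 0.5) {
  stopifnot(length(dim(bank)) == 3)
  n <- dim(bank)[3]
  fits <- vector("list", n)
  normalized <- bank
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fit_gabor(bank[, , i])
    fits[[i]] <- f
    sn <- sign_normalize_even(bank[, , i], f)
    normalized[, , i] <- sn$filter
    p <- f$params
    rows[[i]] <- data.frame(
      filter = i, A = p$A, x0 = p$x0, y0 = p$y0, theta = p$theta,
      sigma_x = p$sigma_x, sigma_y = p$sigma_y, f = p$f, phi = p$phi,
      correlation = f$correlation, p_value = f$p_value,
      parity = classify_parity(p$phi),
      retained = is.finite(f$correlation) && f$correlation >= min_correlation,
      flipped = sn$flipped)
  }
  tab <- do.call(rbind, rows)
  perm <- order_by_orientation(tab$theta)
  tab$order_index <- order(perm)  # rank of each filter in the theta ordering
  list(table = tab, fits = fits, normalized_bank = normalized)
}
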