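# Geometry of the learned lateral kernel in position-orientation space.
#
# Kernel spatial indices: dimension 1 of K(i, j, f, g) is the row
# displacement (image rows), dimension 2 the column displacement. Under
# the package-wide mathematical convention (y up, angles counter-clockwise
# from +x) a stored index pair (a, b), a,b in 1..D, maps to
# x = b - r - 1, y = -(a - r - 1), with r = (D-1)/2.

kernel_radius <- function(K_or_D) {
  D <- if (is.array(K_or_D)) dim(K_or_D)[1] else K_or_D
  (D - 1) / 2
}

shift_slice <- function(M, dr, dc) {
  # translate matrix content by (dr, dc) cells, zero-filling; returns the
  # shifted matrix and the absolute mass shifted out of support
  D <- nrow(M)
  out <- matrix(0, D, D)
  src_r <- seq_len(D); dst_r <- src_r + dr
  src_c <- seq_len(D); dst_c <- src_c + dc
  ok_r <- dst_r >= 1 & dst_r <= D
  ok_c <- dst_c >= 1 & dst_c <= D
  out[dst_r[ok_r], dst_c[ok_c]] <- M[src_r[ok_r], src_c[ok_c]]
  list(M = out, lost = sum(abs(M)) - sum(abs(out)))
}

#' Re-parameterize a lateral kernel into position-orientation coordinates
#'
#' Restricts the 4-D kernel to pairs of filters of the same parity,
#' translates every `(f, g)` spatial slice by the rounded difference of
#' the fitted Gabor centers -- so that displacement `(0, 0)` means the two
#' filter centers coincide -- and permutes the filter axes into ascending
#' orientation order. Values shifted outside the support are dropped
#' (vacated cells zero-filled); the total absolute mass lost this way is
#' returned as a diagnostic.
#'
#' @param K array `(D, D, n, n)` lateral kernel.
#' @param fit_table data frame from [fit_filter_bank()] (columns `x0`,
#'   `y0`, `theta`, `parity`, `retained`), one row per filter in bank
#'   order.
#' @param filter_size side length `s` of the fitted filters; converts the
#'   normalized-grid centers to pixel offsets (`px = unit * (s-1)/2`).
#' @param parities which parity groups to build.
#' @return named list of `reparam_kernel` objects (one per parity with at
#'   least one retained filter), each with `values` `(D, D, m, m)`,
#'   `thetas` (ascending), `filters` (original indices), `parity`, `r`,
#'   and `mass_lost`.
#' @export
reparameterize <- function(K, fit_table, filter_size,
                           parities = c("even", "odd")) {
  stopifnot(length(dim(K)) == 4, dim(K)[3] == dim(K)[4],
            nrow(fit_table) == dim(K)[3])
  D <- dim(K)[1]
  half_px <- (filter_size - 1) / 2
  out <- list()
  dropped <- which(!fit_table$retained)
  if (length(dropped))
    message("excluding ", length(dropped),
            " filter(s) without an adequate Gabor fit: ",
            paste(dropped, collapse = ", "))
  for (par in parities) {
    sel <- which(fit_table$parity == par & fit_table$retained)
    if (length(sel) == 0) next
    ord <- sel[order(wrap_orientation(fit_table$theta[sel]))]
    m <- length(ord)
    vals <- array(0, c(D, D, m, m))
    lost <- 0
    # pixel offsets of fitted centers: columns move with x, rows against y
    pc <- half_px * fit_table$x0
    pr <- -half_px * fit_table$y0
    for (fi in seq_len(m)) for (gi in seq_len(m)) {
      f <- ord[fi]; g <- ord[gi]
      dr <- round(pr[g] - pr[f]); dc <- round(pc[g] - pc[f])
      sh <- shift_slice(matrix(K[, , f, g], D, D), dr, dc)
      vals[, , fi, gi] <- sh$M
      lost <- lost + sh$lost
    }
    rk <- list(values = vals, thetas = wrap_orientation(fit_table$theta[ord]),
               filters = ord, parity = par, r = kernel_radius(D),
               mass_lost = lost)
    class(rk) <- "reparam_kernel"
    out[[par]] <- rk
  }
  out
}

#' Construct a reparam_kernel directly from orientation-indexed values
#'
#' For kernels that are already expressed in relative position and
#' orientation coordinates (e.g. synthetic co-circular kernels).
#'
#' @param values array `(D, D, m, m)`.
#' @param thetas ascending orientations in `[0, pi)`, one per filter axis
#'   index.
#' @param parity `"even"` or `"odd"`.
#' @return `reparam_kernel`.
#' @export
reparam_kernel <- function(values, thetas, parity = "even") {
  stopifnot(length(dim(values)) == 4, dim(values)[3] == length(thetas),
            dim(values)[4] == length(thetas), !is.unsorted(thetas))
  rk <- list(values = values, thetas = thetas, filters = seq_along(thetas),
             parity = parity, r = kernel_radius(dim(values)[1]),
             mass_lost = 0)
  class(rk) <- "reparam_kernel"
  rk
}

#' Orientation-tuning profile within a hypercolumn
#'
#' The zero-displacement slice `theta_g -> K(0, 0, f, g)` of the
#' re-parameterized kernel: the learned pattern of excitation and
#' inhibition between profiles sharing a retinal position, as a function
#' of the partner's orientation. For a trained kernel this takes a
#' "Mexican hat" shape (excitation at the reference orientation, flanking
#' inhibition), the classical sharpening mechanism of orientation tuning.
#'
#' @param rk a `reparam_kernel`.
#' @param f reference filter index (into the ordered axis).
#' @param smooth apply a centered moving average? Orientation is
#'   pi-periodic, so the window wraps around.
#' @param window odd window width (samples).
#' @return list with `theta_g`, `strength`, `raw` and `theta_f`.
#' @export
hypercolumn_profile <- function(rk, f, smooth = TRUE, window = 5) {
  stopifnot(inherits(rk, "reparam_kernel"))
  c0 <- rk$r + 1
  raw <- rk$values[c0, c0, f, ]
  strength <- raw
  if (smooth && length(raw) >= window) {
    half <- (window - 1) / 2
    n <- length(raw)
    ext <- c(raw[(n - half + 1):n], raw, raw[1:half])  # circular padding
    strength <- vapply(seq_len(n), function(i) mean(ext[i:(i + 2 * half)]),
                       numeric(1))
  }
  list(theta_g = rk$thetas, strength = strength, raw = raw,
       theta_f = rk$thetas[f])
}

bilinear_upsample <- function(M, fac) {
  # lattice-preserving refinement: the output grid contains every input
  # sample, so extrema on the lattice survive resampling exactly
  if (fac == 1) return(M)
  D <- nrow(M)
  g <- seq(1, D, by = 1 / fac)
  i0 <- pmin(floor(g), D - 1); w <- g - i0
  R <- M[i0, , drop = FALSE] * (1 - w) + M[i0 + 1, , drop = FALSE] * w
  R[, i0, drop = FALSE] * rep(1 - w, each = nrow(R)) +
    R[, i0 + 1, drop = FALSE] * rep(w, each = nrow(R))
}

#' Project a re-parameterized kernel onto the spatial plane
#'
#' Maximum over the orientation fiber per spatial displacement, optionally
#' upsampled by smooth bilinear interpolation for display.
#'
#' @param rk a `reparam_kernel`.
#' @param f reference filter index.
#' @param upsample integer magnification factor (`1` = no resampling).
#' @return list with `map` (matrix, image-row layout), `x`, `y`
#'   (coordinate vectors in kernel cells, mathematical orientation).
#' @export
project_spatial <- function(rk, f, upsample = 10) {
  stopifnot(inherits(rk, "reparam_kernel"), upsample >= 1)
  M <- apply(rk$values[, , f, , drop = FALSE], c(1, 2), max)
  out <- bilinear_upsample(M, as.integer(upsample))
  D <- nrow(M); r <- rk$r
  xs <- seq(-r, r, length.out = ncol(out))
  ys <- seq(r, -r, length.out = nrow(out))
  list(map = out, x = xs, y = ys)
}

#' Orientation-weighted planar vector field of a lateral kernel
#'
#' At each spatial displacement the kernel values over the orientation
#' fiber weight the unit vectors `v_g = (cos theta_g, sin theta_g)`; the
#' field direction is the normalized weighted sum and the field magnitude
#' is the maximum kernel value over the fiber:
#' `V(i,j) = max_g K(i,j,f,g) * sum_g K(i,j,f,g) v_g / ||sum_g ...||`.
#' Degenerate points (non-positive maximum, or weighted sum cancelling to
#' zero, which can happen when near-antiparallel orientations carry equal
#' weight) receive the zero vector.
#'
#' @param rk a `reparam_kernel`.
#' @param f reference filter index.
#' @param tol threshold below which the weighted-sum norm counts as zero.
#' @return object of class `planar_vector_field`: matrices `vx`, `vy`
#'   (indexed like the kernel's spatial dimensions), `r`, and the
#'   count `n_degenerate`.
#' @export
vector_field <- function(rk, f, tol = 1e-12) {
  stopifnot(inherits(rk, "reparam_kernel"))
  K <- rk$values[, , f, , drop = FALSE]
  D <- dim(K)[1]
  vgx <- cos(rk$thetas); vgy <- sin(rk$thetas)
  vx <- matrix(0, D, D); vy <- matrix(0, D, D)
  ndeg <- 0
  for (a in seq_len(D)) for (b in seq_len(D)) {
    w <- K[a, b, 1, ]
    m <- max(w)
    sx <- sum(w * vgx); sy <- sum(w * vgy)
    nrm <- sqrt(sx^2 + sy^2)
    if (m <= 0 || nrm < tol) { ndeg <- ndeg + 1; next }
    vx[a, b] <- m * sx / nrm
    vy[a, b] <- m * sy / nrm
  }
  new_vector_field(vx, vy, n_degenerate = ndeg)
}

#' Construct a planar vector field on the displacement lattice
#'
#' @param vx,vy square matrices of vector components, indexed
#'   (row, column) with row 1 at `y = +r`, column 1 at `x = -r`.
#' @param n_degenerate bookkeeping count of degenerate lattice points.
#' @return `planar_vector_field`.
#' @export
new_vector_field <- function(vx, vy, n_degenerate = 0) {
  stopifnot(is.matrix(vx), all(dim(vx) == dim(vy)), nrow(vx) == ncol(vx))
  vf <- list(vx = vx, vy = vy, r = kernel_radius(nrow(vx)),
             n_degenerate = n_degenerate)
  class(vf) <- "planar_vector_field"
  vf
}

field_interp <- function(vf, x, y) {
  r <- vf$r; D <- nrow(vf$vx)
  b <- x + r + 1          # fractional column
  a <- r + 1 - y          # fractional row (y up)
  if (a < 1 || a > D || b < 1 || b > D) return(NULL)
  a0 <- min(floor(a), D - 1); b0 <- min(floor(b), D - 1)
  wa <- a - a0; wb <- b - b0
  ix <- function(M)
    (1 - wa) * ((1 - wb) * M[a0, b0] + wb * M[a0, b0 + 1]) +
    wa * ((1 - wb) * M[a0 + 1, b0] + wb * M[a0 + 1, b0 + 1])
  c(ix(vf$vx), ix(vf$vy))
}

integrate_direction <- function(vf, p0, step, max_steps, min_mag, sense) {
  dir_at <- function(p) {
    v <- field_interp(vf, p[1], p[2])
    if (is.null(v)) return(NULL)
    n <- sqrt(sum(v^2))
    if (n < min_mag) return(NULL)
    sense * v / n
  }
  pts <- matrix(NA_real_, max_steps + 1, 2)
  pts[1, ] <- p0
  p <- p0
  np <- 1
  for (s in seq_len(max_steps)) {
    k1 <- dir_at(p); if (is.null(k1)) break
    k2 <- dir_at(p + step / 2 * k1); if (is.null(k2)) break
    k3 <- dir_at(p + step / 2 * k2); if (is.null(k3)) break
    k4 <- dir_at(p + step * k3); if (is.null(k4)) break
    p <- p + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (is.null(field_interp(vf, p[1], p[2]))) break
    np <- np + 1
    pts[np, ] <- p
  }
  pts[seq_len(np), , drop = FALSE]
}

#' Streamlines of a planar vector field (association field)
#'
#' Fixed-step 4th-order Runge-Kutta integration of the field's direction
#' (unit) vectors, with bilinear interpolation between lattice points.
#' Each seed is integrated forward and backward; integration stops at the
#' lattice boundary or where the interpolated field magnitude falls below
#' `min_mag` (degenerate regions). By default the seeds are equally spaced
#' points on the segment through the origin perpendicular to the reference
#' orientation `theta_f` (the trans-axial direction).
#'
#' @param vf a `planar_vector_field`.
#' @param seeds 2-column matrix of seed points `(x, y)`; if `NULL`,
#'   `n_seeds` points spaced `seed_spacing` cells along the trans-axial
#'   segment.
#' @param theta_f reference orientation (radians); required for default
#'   seeds and for downstream arc fitting.
#' @param step integration step in grid cells.
#' @param max_steps per direction.
#' @param min_mag magnitude threshold terminating integration.
#' @param n_seeds,seed_spacing default-seed layout.
#' @return object of class `association_field`: `curves` (list of
#'   2-column matrices, backward part reversed then forward, so the curve
#'   passes through its seed), `seeds`, `anchors` (row index of the seed
#'   within each curve), `theta_f`.
#' @export
streamlines <- function(vf, seeds = NULL, theta_f = NULL, step = 0.1,
                        max_steps = 1e4, min_mag = 1e-9,
                        n_seeds = 7, seed_spacing = 0.5) {
  stopifnot(inherits(vf, "planar_vector_field"))
  if (is.null(seeds)) {
    if (is.null(theta_f)) stop("either 'seeds' or 'theta_f' must be given")
    t <- (seq_len(n_seeds) - (n_seeds + 1) / 2) * seed_spacing
    seeds <- cbind(-t * sin(theta_f), t * cos(theta_f))
  }
  seeds <- matrix(seeds, ncol = 2)
  r <- vf$r
  if (any(abs(seeds) > r)) stop("seed outside the displacement lattice")
  curves <- list(); anchors <- integer(0)
  for (i in seq_len(nrow(seeds))) {
    fwd <- integrate_direction(vf, seeds[i, ], step, max_steps, min_mag, +1)
    bwd <- integrate_direction(vf, seeds[i, ], step, max_steps, min_mag, -1)
    back <- bwd[rev(seq_len(nrow(bwd))), , drop = FALSE]
    curve <- rbind(back[-nrow(back), , drop = FALSE], fwd)
    curves[[i]] <- curve
    anchors[i] <- nrow(back)  # row of the seed within the combined curve
  }
  af <- list(curves = curves, seeds = seeds, anchors = anchors,
             theta_f = theta_f)
  class(af) <- "association_field"
  af
}

#' Fit a circular-arc integral curve to a polyline
#'
#' Finds the curvature `k` of the sub-Riemannian integral-curve arc
#' (see [integral_curve()]) through the curve's anchor point with initial
#' orientation `theta_f` that minimizes the mean Euclidean distance to the
#' polyline, with points matched by signed arc length from the anchor.
#' Segment chord lengths are converted to arc lengths under the candidate
#' curvature (`2/k * asin(k*c/2)`), so a polyline sampled exactly from an
#' arc is matched exactly. `k` is optimized by a bounded scan plus
#' golden-section refinement.
#'
#' @param curve 2-column matrix of points (at least 3).
#' @param theta_f initial orientation of the candidate arcs at the anchor.
#' @param anchor row index of the start/anchor point (1 = the curve's
#'   first point).
#' @param k_range search interval for the curvature.
#' @return list with `k` and `mean_distance`.
#' @export
fit_arc <- function(curve, theta_f, anchor = 1, k_range = c(-5, 5)) {
  curve <- matrix(curve, ncol = 2)
  if (nrow(curve) < 3) stop("curve must have at least 3 points")
  seg <- sqrt(rowSums(diff(curve)^2))
  keep <- c(TRUE, seg > 0)
  pts <- curve[keep, , drop = FALSE]
  seg <- seg[seg > 0]
  anchor <- sum(keep[seq_len(anchor)])
  start <- c(pts[anchor, ], theta_f)
  objective <- function(k) {
    aseg <- if (abs(k) < 1e-8) seg
            else 2 / abs(k) * asin(pmin(1, abs(k) * seg / 2))
    s <- c(0, cumsum(aseg)) - c(0, cumsum(aseg))[anchor]
    arc <- integral_curve(k, s, start = start)
    mean(sqrt((pts[, 1] - arc[, "x"])^2 + (pts[, 2] - arc[, "y"])^2))
  }
  kg <- seq(k_range[1], k_range[2], length.out = 101)
  vals <- vapply(kg, objective, numeric(1))
  i0 <- which.min(vals)
  lo <- kg[max(1, i0 - 1)]; hi <- kg[min(length(kg), i0 + 1)]
  opt <- stats::optimize(objective, c(lo, hi), tol = 1e-9)
  list(k = opt$minimum, mean_distance = opt$objective)
}

#' Fit arcs to every curve of an association field
#'
#' @param af an `association_field` from [streamlines()].
#' @param k_range curvature search interval.
#' @return data frame with one row per seed: seed coordinates, the signed
#'   trans-axial offset of the seed, fitted `k` and mean distance.
#' @export
fit_association_arcs <- function(af, k_range = c(-5, 5)) {
  stopifnot(inherits(af, "association_field"))
  rows <- lapply(seq_along(af$curves), function(i) {
    cv <- af$curves[[i]]
    if (nrow(cv) < 3) return(NULL)
    ft <- fit_arc(cv, af$theta_f, anchor = af$anchors[i], k_range = k_range)
    off <- -af$seeds[i, 1] * sin(af$theta_f) + af$seeds[i, 2] * cos(af$theta_f)
    data.frame(seed = i, seed_x = af$seeds[i, 1], seed_y = af$seeds[i, 2],
               offset = off, k = ft$k, mean_distance = ft$mean_distance)
  })
  do.call(rbind, rows)
}
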