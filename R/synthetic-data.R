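# Synthetic generators with analytic ground truth for every pipeline
# stage: LoG fixtures, Gabor filter banks, co-circular lateral kernels and
# oriented-contour image datasets. All generators are deterministic under
# a fixed seed.

#' Synthetic LoG filter
#'
#' Renders the LoG surface on the normalized grid, plus optional i.i.d.
#' Gaussian noise scaled to the surface's peak absolute value.
#'
#' @param sigma LoG standard deviation (normalized units).
#' @param s odd filter side.
#' @param noise_sd noise standard deviation as a fraction of the peak.
#' @param seed optional integer seed.
#' @return `s x s` matrix.
#' @export
make_log_filter <- function(sigma, s = 11, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- render_profile(s, sigma)
  if (noise_sd > 0)
    m <- m + matrix(stats::rnorm(s * s, sd = noise_sd * max(abs(m))), s, s)
  m
}

#' Synthetic Gabor filter bank with known parameters
#'
#' Samples `n` Gabor parameter sets from the given ranges, renders each on
#' the normalized grid and adds i.i.d. Gaussian noise scaled to the peak
#' of the clean surface. Phases are sampled away from the parity decision
#' boundaries (`|phi|` = pi/4, 3pi/4) by `phi_margin`, so parity ground
#' truth is unambiguous. Orientations are evenly spaced over `[0, pi)`
#' when `theta = "even"`, or sampled uniformly when `theta = "uniform"`.
#'
#' @param n number of filters.
#' @param s odd filter side.
#' @param theta `"even"`, `"uniform"`, or a numeric vector of length `n`.
#' @param A_range,center_range,sigma_range,f_range sampling ranges;
#'   frequencies must stay below the grid's Nyquist band `(s-1)/4` or the
#'   filters are not identifiable from their samples (an error guards
#'   this).
#' @param phi_margin minimum phase distance from the parity boundaries.
#' @param parity `NULL` (phases sampled over the whole circle) or
#'   `"even"`/`"odd"` to restrict phases to one parity class.
#' @param noise_sd noise standard deviation as a fraction of each clean
#'   filter's peak.
#' @param seed integer seed.
#' @return list with `bank` (array `(s, s, n)`) and `truth` (data frame of
#'   the generating parameters, including parity labels).
#' @export
make_gabor_bank <- function(n = 64, s = 7, theta = "even",
                            A_range = c(0.6, 1.4),
                            center_range = c(-0.2, 0.2),
                            sigma_range = c(0.3, 0.55),
                            f_range = c(0.7, 1.35),
                            phi_margin = 0.15,
                            parity = NULL,
                            noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  if (max(f_range) >= (s - 1) / 4)
    stop("'f_range' must stay below the grid Nyquist frequency (s-1)/4")
  if (is.character(theta)) {
    th <- switch(theta,
      even = seq(0, pi, length.out = n + 1)[seq_len(n)],
      uniform = stats::runif(n, 0, pi),
      stop("'theta' must be \"even\", \"uniform\" or a numeric vector"))
  } else {
    stopifnot(length(theta) == n)
    th <- wrap_orientation(theta)
  }
  sample_phi <- function() {
    repeat {
      phi <- stats::runif(1, -pi, pi)
      d <- min(abs(abs(phi) - pi / 4), abs(abs(phi) - 3 * pi / 4))
      if (d < phi_margin) next
      if (is.null(parity) || classify_parity(phi) == parity) return(phi)
    }
  }
  bank <- array(0, c(s, s, n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- gabor_params(
      A = stats::runif(1, A_range[1], A_range[2]),
      x0 = stats::runif(1, center_range[1], center_range[2]),
      y0 = stats::runif(1, center_range[1], center_range[2]),
      theta = th[i],
      sigma_x = stats::runif(1, sigma_range[1], sigma_range[2]),
      sigma_y = stats::runif(1, sigma_range[1], sigma_range[2]),
      f = stats::runif(1, f_range[1], f_range[2]),
      phi = sample_phi())
    m <- render_profile(s, p)
    if (noise_sd > 0)
      m <- m + matrix(stats::rnorm(s * s, sd = noise_sd * max(abs(m))), s, s)
    bank[, , i] <- m
    rows[[i]] <- data.frame(filter = i, A = p$A, x0 = p$x0, y0 = p$y0,
                            theta = p$theta, sigma_x = p$sigma_x,
                            sigma_y = p$sigma_y, f = p$f, phi = p$phi,
                            parity = classify_parity(p$phi))
  }
  list(bank = bank, truth = do.call(rbind, rows))
}

#' Synthetic co-circular lateral connectivity kernel
#'
#' A parametric model of orientation-selective lateral connectivity,
#' built directly in relative position-orientation coordinates
#' `(i, j, theta_f, theta_g)`, qualitatively shaped like the connectivity
#' measured from edge co-occurrence statistics in natural images: spatial
#' decay, concentration along the reference filter's axis, and a
#' preference for the orientation obtained by co-circular transport of
#' `theta_f` to the displaced position. At displacement `(0, 0)` the
#' orientation profile is a difference of Gaussians in the orientation
#' offset (excitation at zero offset, inhibitory flank), so hypercolumn
#' Mexican-hat extraction has analytic ground truth.
#'
#' The co-circular preferred orientation at polar angle `phi` relative to
#' `theta_f` is `theta_f + 2 * beta * (phi - theta_f)` (pi-periodic);
#' `beta = 1` is full co-circularity (tangent to the common circle),
#' `beta = 0` pure collinearity.
#'
#' @param n_theta number of evenly spaced orientations in `[0, pi)`.
#' @param r spatial displacement radius (support side `2r + 1`).
#' @param lambda spatial decay length (cells).
#' @param kappa_e,kappa_i excitatory / inhibitory orientation tuning
#'   widths (radians).
#' @param amp_e,amp_i excitatory / inhibitory amplitudes.
#' @param beta co-circularity strength in `[0, 1]`.
#' @param axial_width across-axis concentration width (cells).
#' @param parity parity tag carried by the result.
#' @return list with `rk` (a [reparam_kernel()]), `K` (its raw array),
#'   `dog` (the ground-truth difference-of-Gaussians function of
#'   orientation offset), and the generating parameters.
#' @export
make_cocircular_kernel <- function(n_theta = 16, r = 6, lambda = 2.5,
                                   kappa_e = 0.35, kappa_i = 0.9,
                                   amp_e = 1, amp_i = 0.5, beta = 1,
                                   axial_width = 1.5, parity = "even") {
  stopifnot(n_theta >= 2, r >= 1, lambda > 0, kappa_e > 0, kappa_i > 0,
            beta >= 0, beta <= 1, axial_width > 0)
  thetas <- seq(0, pi, length.out = n_theta + 1)[seq_len(n_theta)]
  D <- 2 * r + 1
  dog <- function(d) amp_e * exp(-d^2 / (2 * kappa_e^2)) -
    amp_i * exp(-d^2 / (2 * kappa_i^2))
  K <- array(0, c(D, D, n_theta, n_theta))
  for (a in seq_len(D)) for (b in seq_len(D)) {
    x <- b - r - 1; y <- -(a - r - 1)
    d2 <- x^2 + y^2
    for (f in seq_len(n_theta)) {
      thf <- thetas[f]
      if (d2 == 0) {
        K[a, b, f, ] <- dog(orientation_diff(thetas, thf))
        next
      }
      phi <- atan2(y, x)
      # co-circular transport of theta_f to (x, y)
      dphi <- orientation_diff(phi, thf)
      th_star <- thf + 2 * beta * dphi
      axial <- exp(-(-x * sin(thf) + y * cos(thf))^2 / (2 * axial_width^2))
      spatial <- exp(-d2 / (2 * lambda^2))
      # off-center: purely excitatory tuning around the transported
      # orientation (the inhibitory flank lives in the hypercolumn slice)
      K[a, b, f, ] <- spatial * axial * amp_e *
        exp(-orientation_diff(thetas, th_star)^2 / (2 * kappa_e^2))
    }
  }
  list(rk = reparam_kernel(K, thetas, parity), K = K, dog = dog,
       thetas = thetas,
       params = list(n_theta = n_theta, r = r, lambda = lambda,
                     kappa_e = kappa_e, kappa_i = kappa_i,
                     amp_e = amp_e, amp_i = amp_i, beta = beta,
                     axial_width = axial_width))
}

# 1/f ("pink") background noise via FFT filtering of white noise
pink_noise <- function(size, amplitude = 1) {
  w <- matrix(stats::rnorm(size * size), size, size)
  fx <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  fr <- sqrt(outer(fx^2, fx^2, "+"))
  fr[1, 1] <- fr[1, 2]
  spec <- stats::fft(w) / fr
  img <- Re(stats::fft(spec, inverse = TRUE)) / length(w)
  amplitude * img / stats::sd(img)
}

# splat an antialiased curve (dense point list) onto an image canvas:
# each pixel takes the maximum Gaussian falloff from the nearest sample
render_curve_points <- function(img, px, py, width = 0.7, gain = 1) {
  size <- nrow(img)
  keep <- px > -2 & px < size + 3 & py > -2 & py < size + 3
  px <- px[keep]; py <- py[keep]
  if (!length(px)) return(img)
  rows <- matrix(seq_len(size), size, size)
  cols <- t(rows)
  stroke <- matrix(0, size, size)
  for (q in seq_along(px)) {
    d2 <- (rows - py[q])^2 + (cols - px[q])^2
    stroke <- pmax(stroke, exp(-d2 / (2 * width^2)))
  }
  pmax(img, gain * stroke)
}

#' Synthetic oriented-contour image dataset
#'
#' Grayscale images of antialiased smooth contours (circular arcs) over
#' 1/f background noise, emulating key statistics of natural images:
#' broad orientation content, signed contrast (each stroke is randomly
#' bright or dark, as object boundaries are), and spatially correlated
#' 1/f background. The class label is the curvature regime of the
#' contours: class `c` draws each arc's curvature magnitude uniformly
#' from `curvature_ranges[[c]]` (sign random). Arc position and initial
#' orientation are uniform, so the orientation marginal of contour
#' tangents is uniform by construction.
#'
#' @param n_images total images (split evenly over classes).
#' @param size image side in pixels.
#' @param n_classes number of classes (`= length(curvature_ranges)`).
#' @param curvature_ranges list of `c(min, max)` curvature magnitudes
#'   (1/pixels), one per class.
#' @param contours_per_image arcs drawn per image.
#' @param arc_length arc length in pixels.
#' @param line_width Gaussian half-width of the rendered stroke (pixels).
#' @param noise_amplitude standard deviation of the 1/f background
#'   relative to the unit-amplitude strokes.
#' @param seed integer seed.
#' @return list with `x` (array `(size, size, n_images)`, standardized),
#'   `y` (integer labels), `meta` (per-contour data frame: image, class,
#'   curvature, start orientation), `tangents` (vector of tangent angles
#'   mod pi sampled along all contours, for orientation statistics).
#' @export
make_oriented_image_dataset <- function(n_images = 400, size = 16,
                                        n_classes = 2,
                                        curvature_ranges = list(c(0, 0.05),
                                                                c(0.25, 0.45)),
                                        contours_per_image = 2,
                                        arc_length = 14,
                                        line_width = 0.7,
                                        noise_amplitude = 0.4,
                                        seed = 1L) {
  stopifnot(n_classes >= 2, length(curvature_ranges) == n_classes)
  set.seed(seed)
  x <- array(0, c(size, size, n_images))
  y <- integer(n_images)
  meta <- list(); tang <- list()
  for (i in seq_len(n_images)) {
    cls <- ((i - 1) %% n_classes) + 1L
    y[i] <- cls
    img <- pink_noise(size, noise_amplitude)
    for (cc in seq_len(contours_per_image)) {
      kmag <- stats::runif(1, curvature_ranges[[cls]][1], curvature_ranges[[cls]][2])
      k <- kmag * sample(c(-1, 1), 1)
      th0 <- stats::runif(1, 0, 2 * pi)
      p0 <- stats::runif(2, 0.2 * size, 0.8 * size)
      t_grid <- seq(-arc_length / 2, arc_length / 2, by = 0.3)
      cv <- integral_curve(k, t_grid, start = c(p0[1], p0[2], th0))
      # x -> column, y (up) -> row counted from the bottom; strokes carry
      # a random contrast polarity and add to the canvas
      stroke <- render_curve_points(matrix(0, size, size),
                                    cv[, "x"], size + 1 - cv[, "y"],
                                    width = line_width)
      img <- img + sample(c(-1, 1), 1) * stroke
      meta[[length(meta) + 1]] <- data.frame(image = i, class = cls,
                                             curvature = k, theta0 = th0)
      tang[[length(tang) + 1]] <- wrap_orientation(cv[, "theta"])
    }
    x[, , i] <- img
  }
  x <- (x - mean(x)) / stats::sd(x)
  list(x = x, y = y, meta = do.call(rbind, meta), tangents = unlist(tang))
}

#' Assemble a fully synthetic weight bundle with ground truth
#'
#' Builds a bundle shaped like a trained network's ([network_bundle()])
#' entirely from generators: a LoG LGN filter, a single-parity Gabor bank
#' with evenly spaced orientations in a shuffled filter order (centers at
#' the grid origin), and a co-circular lateral kernel indexed consistently
#' with the bank's orientations. Used to validate the whole analysis
#' chain against analytic ground truth.
#'
#' @param n_theta number of filters / orientations.
#' @param s Gabor filter side.
#' @param r lateral-kernel displacement radius.
#' @param log_sigma LGN-filter LoG sigma.
#' @param noise_sd Gabor bank noise level (fraction of peak).
#' @param parity parity of the bank.
#' @param beta co-circularity strength of the kernel.
#' @param seed integer seed (bank sampling and filter-order shuffle).
#' @param ... further arguments to [make_cocircular_kernel()].
#' @return list with the bundle entries (`psi0`, `l1_filters`, `K1`,
#'   `meta`) plus `truth` (bank parameters), `kernel` (the generator
#'   output) and `perm` (the applied filter-order shuffle).
#' @export
make_synthetic_bundle <- function(n_theta = 32, s = 7, r = 6,
                                  log_sigma = 0.184, noise_sd = 0.05,
                                  parity = "even", beta = 1, seed = 1L, ...) {
  ck <- make_cocircular_kernel(n_theta = n_theta, r = r, beta = beta,
                               parity = parity, ...)
  bk <- make_gabor_bank(n = n_theta, s = s, theta = ck$thetas,
                        center_range = c(0, 0), parity = parity,
                        noise_sd = noise_sd, seed = seed)
  perm <- sample(n_theta)  # hide the orientation ordering from the analysis
  list(psi0 = make_log_filter(log_sigma, s = 11),
       l1_filters = bk$bank[, , perm],
       K1 = ck$K[, , perm, perm],
       meta = list(synthetic = TRUE, seed = seed, beta = beta),
       truth = bk$truth[perm, ], kernel = ck, perm = perm)
}

#' Convert an RGB image to grayscale luminance
#'
#' ITU-R BT.601 weights: `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param img array `(H, W, 3)` with values in `[0, 1]`.
#' @return `H x W` matrix.
#' @export
to_grayscale <- function(img) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("'img' must be an (H, W, 3) array")
  matrix(img[, , 1] * 0.299 + img[, , 2] * 0.587 + img[, , 3] * 0.114,
         dim(img)[1], dim(img)[2])
}

#' Write an image dataset as PNG files plus a CSV manifest
#'
#' @param dataset list with `x` (array `(H, W, N)`) and `y` (labels).
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data frame (columns `file`, `label`).
#' @export
write_image_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- dataset$x
  if (length(dim(x)) == 4) x <- array(x, dim(x)[1:3])
  n <- dim(x)[3]
  lo <- min(x); hi <- max(x)
  files <- character(n)
  for (i in seq_len(n)) {
    files[i] <- sprintf("img_%05d.png", i)
    png::writePNG((x[, , i] - lo) / (hi - lo), file.path(dir, files[i]))
  }
  manifest <- data.frame(file = files, label = dataset$y)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read an image dataset written by [write_image_dataset()]
#'
#' @param dir dataset directory containing PNGs and `manifest.csv`.
#' @return list with `x` (array `(H, W, N)`) and `y` (integer labels).
#' @export
read_image_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  imgs <- lapply(file.path(dir, manifest$file), png::readPNG)
  x <- array(unlist(imgs), c(dim(imgs[[1]])[1:2], length(imgs)))
  list(x = x, y = as.integer(manifest$label))
}
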