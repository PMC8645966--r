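test_that("LoG profile has the closed-form origin value and radial symmetry", {
  expect_equal(log_profile(0, 0, 1), -1 / pi, tolerance = 1e-12)
  expect_equal(log_profile(0, 0, 0.5), -1 / (pi * 0.5^4), tolerance = 1e-12)
  # radial symmetry: same value at any rotation of (x, y), and under negation
  set.seed(1)
  for (i in 1:20) {
    r <- runif(1, 0, 2); a1 <- runif(1, 0, 2 * pi); a2 <- runif(1, 0, 2 * pi)
    s <- runif(1, 0.1, 1)
    expect_equal(log_profile(r * cos(a1), r * sin(a1), s),
                 log_profile(r * cos(a2), r * sin(a2), s), tolerance = 1e-12)
    expect_equal(log_profile(r * cos(a1), r * sin(a1), s),
                 log_profile(-r * cos(a1), -r * sin(a1), s), tolerance = 1e-12)
  }
  expect_error(log_profile(0, 0, -1), "positive")
  expect_error(log_profile(0, 0, 0), "positive")
})

test_that("LoG integrates to approximately zero on a wide grid", {
  # grid half-width 1 is > 6 sigma for sigma = 0.15
  g <- filter_grid(101)
  s <- sum(log_profile(g$x, g$y, 0.15)) * g$step^2
  expect_lt(abs(s), 1e-6)
})

test_that("Gabor canonical values and translation equivariance hold", {
  expect_equal(gabor_profile(0, 0, gabor_params(A = 2, phi = 0)), 2,
               tolerance = 1e-12)
  expect_equal(gabor_profile(0, 0, gabor_params(A = 2, phi = pi / 2)), 0,
               tolerance = 1e-12)
  set.seed(2)
  p0 <- gabor_params(A = 1.3, theta = 0.7, sigma_x = 0.5, sigma_y = 0.8,
                     f = 1.2, phi = 0.4)
  pc <- gabor_params(A = 1.3, x0 = 0.3, y0 = -0.2, theta = 0.7,
                     sigma_x = 0.5, sigma_y = 0.8, f = 1.2, phi = 0.4)
  xs <- runif(30, -1, 1); ys <- runif(30, -1, 1)
  expect_equal(gabor_profile(xs, ys, pc),
               gabor_profile(xs - 0.3, ys + 0.2, p0), tolerance = 1e-12)
  expect_error(gabor_params(sigma_x = -1), "positive")
  expect_error(gabor_params(f = 0), "positive")
})

test_that("Gabor profile is equivariant under joint rotation of plane and theta", {
  set.seed(3)
  xs <- runif(50, -1, 1); ys <- runif(50, -1, 1)
  for (rot in c(pi / 7, pi / 3, 1.9)) {
    p1 <- gabor_params(A = 1.1, theta = 0.5, sigma_x = 0.4, sigma_y = 0.7,
                       f = 1.4, phi = 0.9)
    p2 <- gabor_params(A = 1.1, theta = 0.5 + rot, sigma_x = 0.4,
                       sigma_y = 0.7, f = 1.4, phi = 0.9)
    xr <- xs * cos(rot) - ys * sin(rot)
    yr <- xs * sin(rot) + ys * cos(rot)
    expect_lt(max(abs(gabor_profile(xr, yr, p2) - gabor_profile(xs, ys, p1))),
              1e-12)
  }
})

test_that("parameter canonicalization leaves the Gabor surface unchanged", {
  set.seed(4)
  xs <- runif(40, -1, 1); ys <- runif(40, -1, 1)
  # theta wraps by pi, negative amplitude, phi out of range
  base <- list(A = -1.2, x0 = 0.1, y0 = -0.1, theta = 2.5 + pi,
               sigma_x = 0.5, sigma_y = 0.6, f = 1.1, phi = 3.9)
  p <- do.call(gabor_params, base)
  expect_gte(p$A, 0)
  expect_true(p$theta >= 0 && p$theta < pi)
  expect_true(p$phi >= -pi && p$phi <= pi)
  raw <- function(x, y) {
    dx <- x - base$x0; dy <- y - base$y0
    u <- dx * cos(base$theta) + dy * sin(base$theta)
    v <- -dx * sin(base$theta) + dy * cos(base$theta)
    base$A * exp(-(u^2 / base$sigma_x^2 + v^2 / base$sigma_y^2) / 2) *
      cos(2 * pi * base$f * u + base$phi)
  }
  expect_equal(gabor_profile(xs, ys, p), raw(xs, ys), tolerance = 1e-12)
})

test_that("integral curves match the closed form, limit and circle identity", {
  expect_equal(unname(integral_curve(1, c(0, pi / 2))[2, ]),
               c(1, 1, pi / 2), tolerance = 1e-12)
  # straight-line limit below the epsilon threshold
  expect_equal(unname(integral_curve(1e-12, c(0, 1, 2.5))[, "x"]),
               c(0, 1, 2.5), tolerance = 1e-12)
  expect_equal(unname(integral_curve(0, c(0, 1))[2, ]), c(1, 0, 0))
  # all points of a k != 0 curve lie on the circle of radius 1/|k|
  for (k in c(0.5, -0.8, 2)) {
    cv <- integral_curve(k, seq(0, 1.5, by = 0.1))
    expect_lt(max(abs(cv[, "x"]^2 + (cv[, "y"] - 1 / k)^2 - 1 / k^2)), 1e-12)
  }
})

test_that("integral curves with opposite curvature are mirror images", {
  t <- seq(0, 2, by = 0.05)
  a <- integral_curve(0.7, t)
  b <- integral_curve(-0.7, t)
  expect_equal(a[, "x"], b[, "x"], tolerance = 1e-12)
  expect_equal(a[, "y"], -b[, "y"], tolerance = 1e-12)
})

test_that("integral-curve tangents align with the horizontal vector field X1", {
  t <- seq(0, 2, length.out = 4001)
  for (k in c(0.4, -1.1)) {
    cv <- integral_curve(k, t)
    dt <- t[2] - t[1]
    # central-difference tangent vs (cos theta, sin theta)
    mid <- 2:(length(t) - 1)
    tx <- (cv[mid + 1, "x"] - cv[mid - 1, "x"]) / (2 * dt)
    ty <- (cv[mid + 1, "y"] - cv[mid - 1, "y"]) / (2 * dt)
    expect_lt(max(abs(tx - cos(cv[mid, "theta"]))), 1e-6)
    expect_lt(max(abs(ty - sin(cv[mid, "theta"]))), 1e-6)
  }
})

test_that("general starts are roto-translations of the origin curve", {
  t <- seq(0, 1, by = 0.1)
  b <- integral_curve(0.6, t)
  g <- integral_curve(0.6, t, start = c(2, -1, pi / 5))
  expect_equal(g[, "x"], 2 + b[, "x"] * cos(pi / 5) - b[, "y"] * sin(pi / 5),
               tolerance = 1e-12)
  expect_equal(g[, "theta"], b[, "theta"] + pi / 5, tolerance = 1e-12)
})
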