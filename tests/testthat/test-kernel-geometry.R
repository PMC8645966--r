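test_that("reparameterization with coincident centers is a pure ordering permutation", {
  set.seed(3)
  n <- 12
  ck <- make_cocircular_kernel(n_theta = n, r = 4)
  perm <- sample(n)
  ft <- data.frame(x0 = 0, y0 = 0, theta = ck$thetas[perm],
                   parity = "even", retained = TRUE)
  rp <- reparameterize(ck$K[, , perm, perm], ft, filter_size = 7)
  expect_equal(rp$even$values, ck$K, tolerance = 1e-15)
  expect_equal(rp$even$mass_lost, 0)
  expect_equal(rp$even$thetas, ck$thetas)
})

test_that("center offsets shift slices with zero-filled borders and a mass diagnostic", {
  K <- array(0, c(5, 5, 2, 2))
  K[, , 1, 2] <- matrix(1:25, 5, 5)
  K[, , 2, 1] <- matrix(1:25, 5, 5)
  # filter size 7: a normalized offset of 2/6 is exactly one pixel
  ft <- data.frame(x0 = c(0, 2 / 6), y0 = 0, theta = c(0.3, 0.8),
                   parity = "even", retained = TRUE)
  rp <- reparameterize(K, ft, filter_size = 7)
  sl <- rp$even$values[, , 1, 2]   # center of g moved +1 column
  expect_true(all(sl[, 1] == 0))
  expect_equal(sl[, 2:5], matrix(1:25, 5, 5)[, 1:4])
  # the opposite pair shifts the opposite way
  sl2 <- rp$even$values[, , 2, 1]
  expect_true(all(sl2[, 5] == 0))
  expect_equal(sl2[, 1:4], matrix(1:25, 5, 5)[, 2:5])
  # mass loss accounts exactly for both dropped columns
  expect_equal(rp$even$mass_lost, sum(21:25) + sum(1:5))
})

test_that("filters without an adequate fit are excluded with a message", {
  K <- array(1, c(3, 3, 3, 3))
  ft <- data.frame(x0 = 0, y0 = 0, theta = c(0.2, 0.5, 0.9),
                   parity = "even", retained = c(TRUE, FALSE, TRUE))
  expect_message(rp <- reparameterize(K, ft, filter_size = 7), "excluding")
  expect_equal(dim(rp$even$values)[3], 2)
  expect_equal(rp$even$filters, c(1, 3))
})

test_that("hypercolumn profiles recover the generator's interaction shape", {
  ck <- make_cocircular_kernel(n_theta = 32, r = 6)
  prof <- hypercolumn_profile(ck$rk, 1, smooth = FALSE)
  expected <- ck$dog(lgncnn:::orientation_diff(ck$thetas, ck$thetas[1]))
  expect_equal(prof$raw, expected, tolerance = 1e-12)
  # smoothing keeps the shape
  profs <- hypercolumn_profile(ck$rk, 1, smooth = TRUE, window = 5)
  expect_gt(cor(profs$strength, expected), 0.99)
  # a constant kernel gives a flat profile
  flat <- reparam_kernel(array(1, c(5, 5, 4, 4)), seq(0, 3) * pi / 4)
  expect_equal(var(hypercolumn_profile(flat, 2)$strength), 0)
})

test_that("spatial projection takes the fiber maximum and respects upsample = 1", {
  K <- array(0, c(5, 5, 3, 3))
  K[2, 4, 1, 2] <- 2; K[2, 4, 1, 3] <- 1
  rk <- reparam_kernel(K, c(0.3, 0.8, 1.2))
  pr <- project_spatial(rk, 1, upsample = 1)
  expect_equal(dim(pr$map), c(5, 5))
  expect_equal(which(pr$map == max(pr$map), arr.ind = TRUE)[1, ],
               c(row = 2, col = 4))
  expect_equal(max(pr$map), 2)
  pr10 <- project_spatial(rk, 1, upsample = 10)
  expect_equal(dim(pr10$map), c(41, 41))  # lattice-preserving refinement
  expect_equal(max(abs(pr10$map)), 2, tolerance = 1e-12)
})

test_that("the vector field obeys the magnitude law and weighted-sum direction", {
  # single-orientation support: direction equals theta_g exactly
  K <- array(0, c(5, 5, 2, 2))
  K[3, 5, 1, 1] <- 0.7   # displacement x = 2, y = 0, fiber theta = pi/4
  rk <- reparam_kernel(K, c(pi / 4, 3 * pi / 4))
  vf <- vector_field(rk, 1)
  expect_equal(vf$vx[3, 5], 0.7 * cos(pi / 4), tolerance = 1e-12)
  expect_equal(vf$vy[3, 5], 0.7 * sin(pi / 4), tolerance = 1e-12)
  # two equal weights at 0 and pi/2: direction bisects at pi/4
  K2 <- array(0, c(3, 3, 2, 2))
  K2[1, 2, 1, 1] <- 0.5; K2[1, 2, 1, 2] <- 0.5
  vf2 <- vector_field(reparam_kernel(K2, c(0, pi / 2)), 1)
  expect_equal(atan2(vf2$vy[1, 2], vf2$vx[1, 2]), pi / 4, tolerance = 1e-12)
  expect_equal(sqrt(vf2$vx[1, 2]^2 + vf2$vy[1, 2]^2), 0.5, tolerance = 1e-12)
  # magnitude law on a full synthetic kernel, exact wherever defined
  ck <- make_cocircular_kernel(n_theta = 16, r = 5)
  vff <- vector_field(ck$rk, 5)
  mag <- sqrt(vff$vx^2 + vff$vy^2)
  mx <- apply(ck$rk$values[, , 5, ], c(1, 2), max)
  nz <- mag > 0
  expect_lt(max(abs(mag[nz] - mx[nz])), 1e-12)
})

test_that("antiparallel cancellation yields a degenerate zero vector", {
  K <- array(0, c(3, 3, 2, 2))
  eps <- 1e-9
  K[2, 3, 1, 1] <- 0.5; K[2, 3, 1, 2] <- 0.5
  rk <- reparam_kernel(K, c(0, pi - eps))  # near-antiparallel unit vectors
  vf <- vector_field(rk, 1, tol = 1e-6)
  expect_equal(vf$vx[2, 3], 0)
  expect_equal(vf$vy[2, 3], 0)
  expect_gte(vf$n_degenerate, 1)
})

test_that("streamlines follow a uniform field in straight lines", {
  D <- 9
  vf <- new_vector_field(matrix(1, D, D), matrix(0, D, D))
  af <- streamlines(vf, seeds = matrix(c(0, 1), 1, 2), step = 0.1)
  cv <- af$curves[[1]]
  expect_lt(max(abs(cv[, 2] - 1)), 1e-12)
  expect_gt(max(cv[, 1]), 3.5)
  expect_lt(min(cv[, 1]), -3.5)
  # the curve passes through its seed at the recorded anchor
  expect_equal(unname(cv[af$anchors[1], ]), c(0, 1), tolerance = 1e-12)
})

test_that("streamlines reproduce circles on an analytic rotation field", {
  r <- 6; D <- 2 * r + 1; k <- 0.25
  xs <- matrix(rep(-r:r, each = D), D, D)
  ys <- matrix(rep(r:-r, times = D), D, D)
  vf <- new_vector_field(-(ys - 0), xs - 1 / k)  # rotation about (1/k, 0)
  af <- streamlines(vf, seeds = matrix(c(0, 0), 1, 2), step = 0.05,
                    max_steps = 2000)
  cv <- af$curves[[1]]
  rad <- sqrt((cv[, 1] - 1 / k)^2 + cv[, 2]^2)
  expect_lt(max(abs(rad - 1 / k)) * k, 0.02)
  expect_error(streamlines(vf, seeds = matrix(c(10, 0), 1, 2)), "outside")
})

test_that("arc fitting recovers curvature from exact integral curves", {
  for (k in c(-1, -0.5, 0, 0.5, 1)) {
    cv <- integral_curve(k, seq(0, 2, by = 0.05))
    ft <- fit_arc(cv[, 1:2], theta_f = 0)
    expect_lt(abs(ft$k - k), 1e-3)
    expect_lt(ft$mean_distance, 1e-6)
  }
  # straight polyline: curvature collapses to zero
  line <- cbind(seq(0, 3, by = 0.1), seq(0, 3, by = 0.1) * 0.5)
  ft <- fit_arc(line, theta_f = atan(0.5))
  expect_lt(abs(ft$k), 1e-3)
  expect_error(fit_arc(cbind(0, 0), theta_f = 0), "at least 3")
})

test_that("arc fitting handles interior anchors on two-sided curves", {
  cv <- integral_curve(0.7, seq(-1.5, 1.5, by = 0.05))
  ft <- fit_arc(cv[, 1:2], theta_f = 0, anchor = 31)
  expect_lt(abs(ft$k - 0.7), 1e-3)
  expect_lt(ft$mean_distance, 1e-6)
})

test_that("association-field curvature grows with co-circularity and vanishes for collinearity", {
  mean_k <- vapply(c(0, 0.25, 0.5), function(b) {
    ck <- make_cocircular_kernel(n_theta = 32, r = 6, beta = b)
    f <- 17  # reference orientation near pi/2, away from the wrap seam
    af <- streamlines(vector_field(ck$rk, f), theta_f = ck$rk$thetas[f])
    mean(abs(fit_association_arcs(af)$k))
  }, numeric(1))
  expect_lt(mean_k[1], 0.01)
  expect_gt(mean_k[2], 5 * mean_k[1])
  expect_gt(mean_k[3], mean_k[2])
})

test_that("fitted curvature is antisymmetric across the reference-orientation axis", {
  ck <- make_cocircular_kernel(n_theta = 32, r = 6)
  f <- 17
  af <- streamlines(vector_field(ck$rk, f), theta_f = ck$rk$thetas[f])
  arcs <- fit_association_arcs(af)
  arcs <- arcs[abs(arcs$offset) > 1e-9, ]
  m <- merge(arcs, arcs, by = NULL)
  pairs <- m[abs(m$offset.x + m$offset.y) < 1e-9 & m$offset.x > 0, ]
  expect_gt(nrow(pairs), 0)
  expect_lt(max(abs(pairs$k.x + pairs$k.y) / pmax(abs(pairs$k.x), 1e-6)), 0.05)
})
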