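test_that("generators are deterministic under a fixed seed", {
  expect_identical(make_log_filter(0.3, noise_sd = 0.1, seed = 5),
                   make_log_filter(0.3, noise_sd = 0.1, seed = 5))
  b1 <- make_gabor_bank(n = 6, seed = 4)
  b2 <- make_gabor_bank(n = 6, seed = 4)
  expect_identical(b1$bank, b2$bank)
  d1 <- make_oriented_image_dataset(n_images = 8, size = 12, seed = 3)
  d2 <- make_oriented_image_dataset(n_images = 8, size = 12, seed = 3)
  expect_identical(d1$x, d2$x)
  # different seeds differ but recover the same LoG sigma
  fa <- make_log_filter(0.3, noise_sd = 0.05, seed = 1)
  fb <- make_log_filter(0.3, noise_sd = 0.05, seed = 2)
  expect_false(identical(fa, fb))
  expect_lt(abs(fit_log(fa)$sigma - fit_log(fb)$sigma), 0.05 * 0.3 * 2)
})

test_that("the LoG fixture is recovered by the fitter", {
  f <- make_log_filter(0.184, s = 11)
  lf <- fit_log(f)
  expect_lt(abs(lf$sigma - 0.184) / 0.184, 0.01)
  expect_gt(lf$correlation, 1 - 1e-9)
})

test_that("a noiseless Gabor bank is recovered orientation-perfect", {
  bk <- make_gabor_bank(n = 16, s = 7, noise_sd = 0, seed = 5)
  fb <- fit_filter_bank(bk$bank)
  expect_lt(max(angdiff_deg(fb$table$theta, bk$truth$theta)), 1)
  # evenly spaced orientations: ordering is a rotation of the identity
  perm <- order_by_orientation(fb$table$theta)
  spacing <- diff(sort(lgncnn:::wrap_orientation(fb$table$theta[perm])))
  expect_lt(max(abs(spacing - pi / 16)), 0.01)
})

test_that("bank parity restriction and frequency guard work", {
  bk <- make_gabor_bank(n = 10, parity = "even", seed = 6)
  expect_true(all(bk$truth$parity == "even"))
  bko <- make_gabor_bank(n = 10, parity = "odd", seed = 6)
  expect_true(all(bko$truth$parity == "odd"))
  expect_error(make_gabor_bank(n = 4, s = 7, f_range = c(1, 2)), "Nyquist")
})

test_that("the co-circular kernel is mirror-symmetric and DoG-centered", {
  ck <- make_cocircular_kernel(n_theta = 12, r = 4)
  K <- ck$K; D <- dim(K)[1]; n <- dim(K)[3]
  refl <- c(1, n:2)  # theta -> -theta (mod pi) on the even grid
  # reflection (x, -y, -theta_f, -theta_g) leaves the kernel unchanged;
  # y -> -y flips the row index
  err <- 0
  for (f in 1:n) for (g in 1:n)
    err <- max(err, max(abs(K[, , f, g] - K[D:1, , refl[f], refl[g]])))
  expect_lt(err, 1e-12)
  # center slice is the analytic difference of Gaussians
  ctr <- ck$params$r + 1
  for (f in c(1, 5)) {
    expected <- ck$dog(lgncnn:::orientation_diff(ck$thetas, ck$thetas[f]))
    expect_equal(K[ctr, ctr, f, ], expected, tolerance = 1e-12)
  }
})

test_that("the co-circular field points along the reference axis", {
  ck <- make_cocircular_kernel(n_theta = 32, r = 6)
  f <- 17  # theta_f ~ pi/2
  vf <- vector_field(ck$rk, f)
  r <- ck$rk$r
  # displacements strictly along the reference axis, excluding the origin
  dirs <- atan2(vf$vy[-(r + 1), r + 1], vf$vx[-(r + 1), r + 1])
  expect_lt(max(angdiff_deg(dirs, ck$rk$thetas[f])), 5)
})

test_that("the oriented-image dataset has uniform orientation statistics", {
  ds <- make_oriented_image_dataset(n_images = 250, size = 16, seed = 9)
  expect_gte(nrow(ds$meta), 500)
  ks <- suppressWarnings(stats::ks.test(ds$tangents / pi, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
  # standardized images, balanced classes
  expect_equal(mean(ds$x), 0, tolerance = 1e-9)
  expect_equal(sd(ds$x), 1, tolerance = 1e-9)
  expect_equal(as.numeric(table(ds$y)), c(125, 125))
})

test_that("grayscale conversion uses the BT.601 luminance weights", {
  white <- array(1, c(2, 2, 3))
  expect_equal(to_grayscale(white), matrix(1, 2, 2))
  red <- array(0, c(1, 1, 3)); red[, , 1] <- 1
  expect_equal(to_grayscale(red)[1, 1], 0.299)
  gray <- array(0.4, c(2, 2, 3))
  expect_equal(to_grayscale(gray), matrix(0.4, 2, 2))
  expect_error(to_grayscale(array(1, c(2, 2, 4))), "3")
})

test_that("image datasets round-trip through PNG + manifest", {
  ds <- make_oriented_image_dataset(n_images = 4, size = 10, seed = 2)
  dir <- file.path(tempdir(), "lgncnn-ds-test")
  write_image_dataset(ds, dir)
  back <- read_image_dataset(dir)
  expect_equal(back$y, ds$y)
  expect_equal(dim(back$x), dim(ds$x))
  # PNG quantizes to 16 bits after affine rescaling; structure preserved
  expect_gt(cor(as.vector(back$x[, , 1]), as.vector(ds$x[, , 1])), 0.999)
  unlink(dir, recursive = TRUE)
})
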