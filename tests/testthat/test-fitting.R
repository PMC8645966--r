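test_that("LoG fit recovers sigma from exact and noisy surfaces", {
  lf <- fit_log(make_log_filter(0.3, s = 11))
  expect_lt(abs(lf$sigma - 0.3) / 0.3, 0.01)
  expect_gt(lf$correlation, 0.9999)
  # 5% noise (fixed seed): sigma within 5%
  lfn <- fit_log(make_log_filter(0.3, s = 11, noise_sd = 0.05, seed = 3))
  expect_lt(abs(lfn$sigma - 0.3) / 0.3, 0.05)
  expect_error(fit_log(matrix(1, 11, 11)), "constant")
})

test_that("LoG fit is invariant to positive rescaling of the filter", {
  f <- make_log_filter(0.25, s = 11)
  s1 <- fit_log(f)$sigma
  s2 <- fit_log(7.3 * f)$sigma
  expect_lt(abs(s1 - s2), 1e-6)
  # polarity-inverted filters fit with a negative amplitude, same sigma
  s3 <- fit_log(-f)
  expect_lt(abs(s1 - s3$sigma), 1e-6)
  expect_lt(s3$amplitude, 0)
})

test_that("Gabor fit recovers known parameters, exactly and under noise", {
  p <- gabor_params(A = 1, theta = pi / 3, sigma_x = 0.4, sigma_y = 0.4,
                    f = 1.5, phi = pi / 2)
  gf <- fit_gabor(render_profile(11, p))
  expect_lt(angdiff_deg(gf$params$theta, pi / 3), 1)
  expect_lt(abs(gf$params$phi - pi / 2), 0.05)
  expect_gt(gf$correlation, 0.999)
  # 5% noise: orientation within 5 degrees
  set.seed(21)
  m <- render_profile(11, p)
  mn <- m + matrix(rnorm(121, sd = 0.05 * max(abs(m))), 11, 11)
  gfn <- fit_gabor(mn)
  expect_lt(angdiff_deg(gfn$params$theta, pi / 3), 5)
  expect_error(fit_gabor(matrix(0, 7, 7)), "constant")
})

test_that("Gabor fit is rotation-consistent", {
  p <- gabor_params(A = 1, theta = pi / 5, sigma_x = 0.35, sigma_y = 0.5,
                    f = 1.2, phi = 0.3)
  m <- render_profile(9, p)
  # rotating the filter by 90 degrees shifts theta by pi/2 (mod pi);
  # under the y-up convention a +90 deg rotation maps matrix M to
  # counter-clockwise rotation: t(M)[nrow:1, ]
  m90 <- t(m)[nrow(m):1, ]
  th0 <- fit_gabor(m)$params$theta
  th90 <- fit_gabor(m90)$params$theta
  expect_lt(angdiff_deg(th90, th0 + pi / 2), 2)
})

test_that("parity classification follows the phase rule with closed boundaries", {
  expect_equal(classify_parity(pi / 2), "odd")
  expect_equal(classify_parity(0), "even")
  expect_equal(classify_parity(pi), "even")
  expect_equal(classify_parity(pi / 4), "even")      # boundary: even
  expect_equal(classify_parity(3 * pi / 4), "odd")   # boundary: odd
  expect_equal(classify_parity(-0.5), classify_parity(0.5))
  # depends on |phi| only, and survives wrapping
  set.seed(8)
  phis <- runif(50, -pi, pi)
  expect_equal(classify_parity(phis), classify_parity(-phis))
  expect_equal(classify_parity(phis + 2 * pi), classify_parity(phis))
})

test_that("even-filter sign normalization flips negative central lobes idempotently", {
  p <- gabor_params(A = -0.8, theta = 0.4, sigma_x = 0.4, sigma_y = 0.4,
                    f = 1, phi = 0)  # canonicalizes to A > 0, phi = pi
  m <- render_profile(9, p)
  gf <- fit_gabor(m)
  expect_equal(classify_parity(gf$params$phi), "even")
  sn <- sign_normalize_even(m, gf)
  ctr <- (nrow(m) + 1) / 2
  expect_gt(sn$filter[ctr, ctr], 0)
  # round trip: normalizing the flipped output changes nothing further
  sn2 <- sign_normalize_even(sn$filter, fit_gabor(sn$filter))
  expect_false(sn2$flipped)
  # odd filters pass through unchanged
  po <- gabor_params(theta = 0.4, sigma_x = 0.4, sigma_y = 0.4, f = 1,
                     phi = pi / 2)
  mo <- render_profile(9, po)
  expect_equal(sign_normalize_even(mo, fit_gabor(mo))$filter, mo)
})

test_that("orientation ordering sorts ascending and is stable", {
  expect_equal(order_by_orientation(c(0.5, 0.1, 3.0)), c(2, 1, 3))
  expect_equal(order_by_orientation(c(0.1, 0.5, 3.0)), c(1, 2, 3))
  expect_equal(order_by_orientation(c(0.4, 0.4, 0.1)), c(3, 1, 2))
  # evenly spaced bank: neighbors in the ordering differ by the spacing
  bk <- make_gabor_bank(n = 12, s = 7, noise_sd = 0, seed = 9)
  fb <- fit_filter_bank(bk$bank)
  perm <- order_by_orientation(fb$table$theta)
  th <- sort(lgncnn:::wrap_orientation(fb$table$theta[perm]))
  expect_lt(max(abs(diff(th) - pi / 12)), 0.02)
})

test_that("bank fitting recovers a noisy synthetic bank and flags parity", {
  bk <- make_gabor_bank(n = 24, s = 7, noise_sd = 0.05, seed = 11)
  fb <- fit_filter_bank(bk$bank)
  dth <- angdiff_deg(fb$table$theta, bk$truth$theta)
  expect_gte(mean(dth < 5 & fb$table$parity == bk$truth$parity), 0.9)
  expect_gt(mean(fb$table$correlation), 0.95)
  expect_true(all(fb$table$p_value < 0.001))
})
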