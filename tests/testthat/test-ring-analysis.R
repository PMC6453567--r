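angular_image <- function(size, fun) {
  ctr <- (size - 1) / 2
  X <- matrix(0:(size - 1), size, size, byrow = TRUE) - ctr
  Y <- matrix(0:(size - 1), size, size) - ctr
  fun(sqrt(X^2 + Y^2), atan2(Y, X))
}

test_that("ring counting finds a pure harmonic and flags degenerate rings", {
  img <- angular_image(301, function(r, th) 0.5 + 0.2 * cos(24 * th))
  ctr <- c(150, 150)
  res <- count_ring_features(img, ctr, 100)
  expect_equal(res$N, 24)
  expect_false(res$flagged)
  expect_equal(res$N_autocorr, 24, tolerance = 0.1)
  flat <- count_ring_features(matrix(0.7, 301, 301), ctr, 100)
  expect_true(flat$flagged)
  expect_match(flat$reason, "no periodic signal")
  expect_error(count_ring_features(img, ctr, 200),
               class = "biofilmorph_domain_error")  # ring exits the image
})

test_that("counts are invariant under rotation and affine intensity rescaling", {
  img <- angular_image(301, function(r, th) 0.5 + 0.2 * cos(17 * th + 0.3))
  ctr <- c(150, 150)
  n0 <- count_ring_features(img, ctr, 90)$N
  rot <- t(img)[, 301:1]  # 90 degree rotation
  expect_equal(count_ring_features(rot, ctr, 90)$N, n0)
  expect_equal(count_ring_features(0.2 + 3 * img, ctr, 90)$N, n0)
})

test_that("generated stripe counts follow N(r) = round(2 pi r / lambda)", {
  g <- gen_radial_pattern_image(lambda = 1, R_f = 6, size = 512,
                                pixel_size = 0.025, amplitude = 0.1)
  res <- count_ring_features(g$image, g$truth$center, 4, pixel_size = 0.025)
  expect_equal(res$N, round(8 * pi))  # 25
  g2 <- gen_radial_pattern_image(lambda = 0.8, R_f = 6, size = 512,
                                 pixel_size = 0.025, amplitude = 0.1)
  res2 <- count_ring_features(g2$image, g2$truth$center, 5, pixel_size = 0.025)
  expect_equal(res2$N, round(2 * pi * 5 / 0.8))  # 39
})

test_that("wavelength fit inverts exact and generated data", {
  r <- seq(1, 4, by = 0.5)
  exact <- fit_wavelength(data.frame(r = r, t = 0, N = 2 * pi * r / 0.5))
  expect_equal(exact$lambda, 0.5, tolerance = 1e-12)
  # noiseless generator recovery across the wavelength range, within 1%
  for (lam in c(0.4, 1, 2.5)) {
    g <- gen_radial_pattern_image(lambda = lam, R_f = 6, size = 512,
                                  pixel_size = 0.025, amplitude = 0.1)
    fr <- normalize_and_segment(g$image, pixel_size = 0.025)
    radii <- seq(2, 5.5, by = 0.25)
    cnt <- lapply(radii, function(rr)
      count_ring_features(fr$image, g$truth$center, rr, pixel_size = 0.025))
    wf <- fit_wavelength(tibble::tibble(
      r = radii, t = 12,
      N = vapply(cnt, function(x) if (is.na(x$N)) 0L else x$N, 0L),
      flagged = vapply(cnt, `[[`, TRUE, "flagged")))
    expect_equal(wf$lambda, lam, tolerance = 0.01)
  }
})

test_that("wavelength fit handles missing pattern and reports R_p", {
  none <- fit_wavelength(data.frame(r = 1:6, t = 0, N = rep(0, 6)))
  expect_false(none$pattern)
  expect_true(is.na(none$lambda))
  d <- data.frame(r = c(0.5, 1, 2, 3, 4), t = 0, N = c(0, 0, 12, 19, 25))
  wf <- fit_wavelength(d)
  expect_equal(wf$R_p$R_p, 1)  # innermost patterned radius
  expect_error(fit_wavelength(data.frame(r = c(1, 1), t = 0, N = c(3, 3))),
               class = "biofilmorph_domain_error")
})

test_that("edge peaks use topographic prominence on the periodic profile", {
  img <- angular_image(301, function(r, th) 0.9 - 0.1 * cos(12 * th))
  pk <- edge_amplitude_peaks(img, c(150, 150), 100)
  expect_equal(nrow(pk), 12)
  expect_equal(pk$prominence, rep(0.2, 12), tolerance = 1e-3)
  # sub-threshold dips rejected: deep dips unchanged
  img2 <- angular_image(301, function(r, th)
    0.9 - 0.1 * cos(12 * th) - 0.005 * cos(60 * th))
  pk2 <- edge_amplitude_peaks(img2, c(150, 150), 100)
  expect_equal(nrow(pk2), 12)
})

test_that("circular prominence matches the brute-force oracle", {
  y <- withr::with_seed(9, {
    th <- 2 * pi * (0:199) / 200
    0.3 * cos(3 * th) + 0.2 * sin(7 * th) + 0.1 * cos(11 * th + 1)
  })
  ours <- biofilmorph:::peak_prominences_circular(y)
  oracle <- brute_prominences(y)
  expect_equal(ours$index, oracle$index)
  expect_equal(ours$prominence, oracle$prominence, tolerance = 1e-12)
})
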