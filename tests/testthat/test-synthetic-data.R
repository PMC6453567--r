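test_that("generators are pure functions of parameters and seed", {
  a <- gen_radial_pattern_image(lambda = 1, R_f = 4, size = 128,
                                pixel_size = 0.08, noise_sd = 0.05, seed = 3)
  b <- gen_radial_pattern_image(lambda = 1, R_f = 4, size = 128,
                                pixel_size = 0.08, noise_sd = 0.05, seed = 3)
  expect_identical(a$image, b$image)
  c <- gen_radial_pattern_image(lambda = 1, R_f = 4, size = 128,
                                pixel_size = 0.08, noise_sd = 0.05, seed = 4)
  expect_false(identical(a$image, c$image))
  d1 <- gen_stiffness_dataset(0.1, c(0.1, 1, 10), noise_sigma = 0.1, seed = 5)
  d2 <- gen_stiffness_dataset(0.1, c(0.1, 1, 10), noise_sigma = 0.1, seed = 5)
  expect_identical(d1$data, d2$data)
})

test_that("striped image keeps the local stripe spacing within the bifurcation bracket", {
  lam <- 0.9
  g <- gen_radial_pattern_image(lambda = lam, R_f = 6, size = 256,
                                pixel_size = 0.05)
  for (r in seq(1.5, 5.5, by = 0.5)) {
    N <- round(2 * pi * r / lam)
    spacing <- 2 * pi * r / N
    expect_gte(spacing, lam / sqrt(2))
    expect_lte(spacing, lam * sqrt(2))
  }
  expect_error(gen_radial_pattern_image(lambda = 0.05, R_f = 6, size = 128,
                                        pixel_size = 0.05),
               class = "biofilmorph_domain_error")
})

test_that("unpatterned disk yields a no-pattern analysis result", {
  g <- gen_radial_pattern_image(lambda = 1, R_f = 5, size = 384,
                                pixel_size = 0.03, amplitude = 0)
  fr <- normalize_and_segment(g$image, pixel_size = 0.03)
  radii <- seq(2, 4.5, by = 0.5)
  cnt <- lapply(radii, function(r)
    count_ring_features(fr$image, g$truth$center, r, pixel_size = 0.03))
  expect_true(all(vapply(cnt, `[[`, TRUE, "flagged")))
  wf <- fit_wavelength(tibble::tibble(
    r = radii, t = 12, N = 0L,
    flagged = vapply(cnt, `[[`, TRUE, "flagged")))
  expect_false(wf$pattern)
})

test_that("colony series round-trips through the expansion and kinematics analyses", {
  times <- seq(10, 70, by = 3)
  # circular colony: alpha stays 1, breakpoint recovered exactly
  circ <- gen_colony_series(times, R0 = 1, V1 = 0.2, V2 = 0.5, t_c = 40,
                            a_max = 0)
  alphas <- vapply(circ$contours, function(cc) contour_metrics(cc)$alpha, 0)
  expect_equal(alphas, rep(1, length(times)), tolerance = 1e-3)
  ef <- expansion_fit(data.frame(t = times, R = circ$radii$R))
  expect_equal(ef$t_c, circ$truth$t_c, tolerance = 3)
  expect_equal(ef$V_before, 0.2, tolerance = 1e-6)
  expect_equal(ef$V_after, 0.5, tolerance = 1e-6)
  # petalled colony: k curvature minima per late frame
  pet <- gen_colony_series(times, t_c = 40, k = 6L, a_max = 0.15)
  last <- length(times)
  kin <- local_kinematics(pet$contours[[last - 1]], pet$contours[[last]],
                          dt = 3)
  low <- kin$kappa < stats::quantile(kin$kappa, 0.25)
  n_minima <- sum(diff(c(low, low[1])) == 1)  # circular count of low-kappa arcs
  expect_equal(n_minima, 6)
  # single-slope series: no break
  lin <- gen_colony_series(times, V1 = 0.3, V2 = 0.3, t_c = 40, a_max = 0)
  expect_false(expansion_fit(data.frame(t = times, R = lin$radii$R))$break_detected)
})

test_that("rasterised contours match their analytic shape metrics", {
  cc <- gen_colony_series(c(12, 24), R0 = 1, V1 = 0.1, V2 = 0.1, t_c = 40,
                          a_max = 0)$contours[[2]]
  m <- rasterize_contour(cc, size = 256, pixel_size = 0.03)
  got <- mask_metrics(m, pixel_size = 0.03)
  expect_equal(got$A, pi * 3.4^2, tolerance = 0.01)  # R(24) = 1 + 0.1 * 24
  expect_equal(got$alpha, 1, tolerance = 0.01)
})

test_that("stiffness dataset supports exact and noisy recovery", {
  ratios <- 10^seq(log10(0.05), 1, length.out = 8)
  ds0 <- gen_stiffness_dataset(0.2, ratios, noise_sigma = 0)
  fit <- fit_residual_stiffness(ds0$data)
  expect_equal(fit$gr_over_gf, 0.2, tolerance = 1e-3)
  one <- gen_stiffness_dataset(0.2, ratios[1], noise_sigma = 0)
  expect_error(fit_residual_stiffness(one$data),
               class = "biofilmorph_domain_error")
})
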