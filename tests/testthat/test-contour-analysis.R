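polar_contour <- function(fun, n = 1440) {
  th <- 2 * pi * (0:(n - 1)) / n
  r <- fun(th)
  tibble::tibble(x = r * cos(th), y = r * sin(th))
}

test_that("acircularity of reference shapes", {
  circ <- disk_mask(512, 255.5, 255.5, 200)
  expect_equal(mask_metrics(circ)$alpha, 1, tolerance = 0.01)
  X <- matrix(0:511, 512, 512, byrow = TRUE); Y <- matrix(0:511, 512, 512)
  sq <- abs(X - 255.5) <= 150 & abs(Y - 255.5) <= 150
  expect_equal(mask_metrics(sq)$alpha, 4 / pi, tolerance = 0.01)
  # petal contour against numerical quadrature of the exact P and A
  pet <- polar_contour(function(th) 10 * (1 + 0.15 * cos(6 * th)))
  got <- contour_metrics(pet)
  P_ex <- stats::integrate(function(t)
    sqrt((10 * (1 + 0.15 * cos(6 * t)))^2 + (9 * sin(6 * t))^2),
    0, 2 * pi, subdivisions = 2000L)$value
  A_ex <- stats::integrate(function(t) 0.5 * (10 * (1 + 0.15 * cos(6 * t)))^2,
                           0, 2 * pi)$value
  expect_equal(got$alpha, P_ex^2 / (4 * pi * A_ex), tolerance = 0.01)
})

test_that("acircularity respects the isoperimetric bound on random star shapes", {
  for (s in 1:8) {
    coefs <- withr::with_seed(100 + s, rnorm(4, 0, 0.05))
    cont <- polar_contour(function(th)
      5 * (1 + coefs[1] * cos(3 * th) + coefs[2] * sin(4 * th) +
             coefs[3] * cos(5 * th) + coefs[4] * sin(7 * th)))
    expect_gte(contour_metrics(cont)$alpha, 1 - 1e-3)
  }
})

test_that("multiply-connected masks are rejected", {
  m <- disk_mask(256, 60, 60, 25) | disk_mask(256, 180, 180, 25)
  expect_error(extract_contour(m), class = "biofilmorph_segmentation_error")
  expect_error(extract_contour(matrix(FALSE, 32, 32)),
               class = "biofilmorph_segmentation_error")
})

test_that("curvature, normals and velocity on an expanding circle", {
  c0 <- polar_contour(function(th) rep(5, length(th)))
  c1 <- polar_contour(function(th) rep(5.4, length(th)))
  kin <- local_kinematics(c0, c1, dt = 2)
  expect_equal(kin$kappa, rep(1 / 5, 512), tolerance = 0.01)
  expect_equal(kin$v, rep(0.2, 512), tolerance = 0.01)
  # outward normals are radial
  rad <- sqrt(kin$x^2 + kin$y^2)
  dot <- (kin$nx * kin$x + kin$ny * kin$y) / rad
  expect_equal(dot, rep(1, 512), tolerance = 1e-3)
})

test_that("petal curvature matches the analytic polar formula", {
  R <- 10; a <- 0.15; k <- 6
  c0 <- polar_contour(function(th) R * (1 + a * cos(k * th)), n = 2880)
  kin <- local_kinematics(c0, c0, dt = 1, n = 1024)
  th_i <- atan2(kin$y, kin$x)
  r_i <- R * (1 + a * cos(k * th_i))
  rp_i <- -R * a * k * sin(k * th_i)
  rpp_i <- -R * a * k^2 * cos(k * th_i)
  kappa_exact <- polar_curvature(r_i, rp_i, rpp_i)
  expect_equal(kin$kappa, kappa_exact, tolerance = 0.03)
  # six petals leave six arcs of minimal curvature around the contour
  low <- kin$kappa < stats::quantile(kin$kappa, 0.25)
  expect_equal(sum(diff(c(low, low[1])) == 1), 6)
})

test_that("curvature integrates to 2 pi around simple closed contours", {
  shapes <- list(
    polar_contour(function(th) rep(3, length(th))),
    polar_contour(function(th) 4 * (1 + 0.2 * cos(5 * th))),
    polar_contour(function(th) 2 * (1 + 0.1 * sin(3 * th) + 0.05 * cos(8 * th)))
  )
  for (cont in shapes) {
    kin <- local_kinematics(cont, cont, dt = 1)
    polygon_len <- sum(sqrt(diff(c(kin$x, kin$x[1]))^2 +
                              diff(c(kin$y, kin$y[1]))^2))
    ds <- polygon_len / nrow(kin)
    expect_equal(sum(kin$kappa * ds), 2 * pi, tolerance = 0.01)
  }
})

test_that("segmented regression recovers exact breakpoints and flags degenerate series", {
  tt <- seq(10, 70, by = 2)
  R <- 1 + 0.2 * pmin(tt, 40) + 0.5 * pmax(tt - 40, 0)
  ef <- expansion_fit(data.frame(t = tt, R = R))
  expect_true(ef$break_detected)
  expect_equal(ef$t_c, 40)
  expect_equal(ef$V_before, 0.2, tolerance = 1e-9)
  expect_equal(ef$V_after, 0.5, tolerance = 1e-9)
  # single slope: no break
  lin <- expansion_fit(data.frame(t = tt, R = 2 + 0.3 * tt))
  expect_false(lin$break_detected)
  expect_true(is.na(lin$t_c))
  expect_error(expansion_fit(data.frame(t = 1:5, R = 1:5)),
               class = "biofilmorph_domain_error")
})

test_that("breakpoint recovery under noise (seeded replicates)", {
  tt <- seq(0, 58, by = 2)  # 30 points, spacing 2
  R0 <- 1 + 0.2 * pmin(tt, 30) + 0.5 * pmax(tt - 30, 0)
  rng <- diff(range(R0))
  hits <- vapply(1:50, function(s) {
    Rn <- R0 + withr::with_seed(2000 + s, rnorm(length(tt), 0, 0.02 * rng))
    ef <- expansion_fit(data.frame(t = tt, R = Rn))
    ef$break_detected && abs(ef$t_c - 30) <= 2
  }, TRUE)
  expect_gte(mean(hits), 0.88)
})
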