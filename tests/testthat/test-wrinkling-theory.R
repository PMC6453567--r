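test_that("composite foundation stiffness matches the printed formula", {
  expect_equal(composite_stiffness(5, 1, 1, 0.7), 10)     # bilayer limit
  expect_equal(composite_stiffness(3, 2, 5, 0), 12)        # no residual layer
  expect_equal(composite_stiffness(1, 1, 0.1, 0.3), 4 / 4.7)
  # stiff residual layer at large n h_r leaves the validity region
  expect_error(composite_stiffness(3, 1, 10, 1),
               class = "biofilmorph_validity_error")
  expect_error(composite_stiffness(-1, 1, 1, 0.3),
               class = "biofilmorph_domain_error")
})

test_that("film stress combines bending and foundation terms", {
  stk <- stack_from_ratios(1, gr_over_gf = 1, hr_over_hf = 0.3)  # G all equal
  expect_equal(film_stress(1, stk), 1 / 3 + 2)
  # diverges at both ends: interior minimum guaranteed
  expect_gt(film_stress(1e-4, stk), film_stress(1, stk))
  expect_gt(film_stress(1e4, stk), film_stress(1, stk))
})

test_that("bilayer limit reproduces the closed form across four decades", {
  for (ratio in 10^seq(-1, 4, length.out = 11)) {
    stk <- stack_from_ratios(ratio, gr_over_gf = 1 / ratio)  # G_r = G_s
    sol <- solve_wrinkling(stk)
    expect_equal(sol$lambda_cr, bilayer_wavelength(1, 1 / ratio, 1),
                 tolerance = 1e-6)
    expect_lt(sol$stationarity, 1e-8)
  }
})

test_that("solver agrees with a dense grid scan and satisfies exact identities", {
  stk <- stack_from_ratios(7, gr_over_gf = 0.1)
  sol <- solve_wrinkling(stk)
  n_oracle <- grid_ncr(stk)
  cell <- log(1e3 / 1e-3) / 1e4
  expect_lt(abs(log(sol$n_cr / n_oracle)), cell)
  expect_equal(sol$lambda_cr * sol$n_cr, 2 * pi)
  expect_equal(sol$eps_cr * 3 * stk$film$G, sol$S_cr)
})

test_that("wavelength scaling: monotone in G_s, scale invariant, softer interlayer lengthens", {
  lam <- vapply(c(0.5, 1, 2, 5), function(gs)
    solve_wrinkling(layer_stack(elastic_layer(10, 1), elastic_layer(gs, 0.3),
                                elastic_layer(gs, 10)))$lambda_over_hf, 0)
  expect_true(all(diff(lam) < 0))
  base <- solve_wrinkling(stack_from_ratios(40, gr_over_gf = 0.05))
  scaled <- solve_wrinkling(stack_from_ratios(40, gr_over_gf = 0.05,
                                              G_f = 3.7e3, h_f = 1.3e-4))
  expect_equal(scaled$lambda_over_hf, base$lambda_over_hf, tolerance = 1e-9)
  expect_equal(scaled$eps_cr, base$eps_cr, tolerance = 1e-9)
  # G_r < G_s at fixed G_f: longer wavelength than the bilayer value
  tri <- solve_wrinkling(stack_from_ratios(2, gr_over_gf = 0.1))  # G_r < G_s
  expect_gt(tri$lambda_over_hf, 2 * pi * (2 / 3)^(1 / 3))
})

test_that("bilayer closed form scales as printed", {
  expect_equal(bilayer_wavelength(3, 1, 1), 2 * pi)
  expect_equal(bilayer_wavelength(3, 1, 2), 4 * pi)
  expect_equal(bilayer_wavelength(3, 8, 1), pi)
  expect_error(bilayer_wavelength(0, 1, 1), class = "biofilmorph_domain_error")
})

test_that("effective substrate modulus and normalised adhesion", {
  bi <- stack_from_ratios(100, gr_over_gf = 0.01)  # G_r = G_s
  sol <- solve_wrinkling(bi)
  expect_equal(effective_substrate_modulus(sol, bi, 1 / sol$n_cr),
               2 * bi$substrate$G, tolerance = 1e-9)
  expect_equal(effective_substrate_modulus(sol, bi, 2 / sol$n_cr),
               4 * bi$substrate$G, tolerance = 1e-9)
  # interlayer softer than the substrate reduces the effective stiffness
  # below the half-space value 2 G_s (stiff-agar regime: G_f < G_s)
  tri <- stack_from_ratios(0.1, gr_over_gf = 0.1)
  st <- solve_wrinkling(tri)
  expect_lt(st$Gp_s, 2 * tri$substrate$G)
  expect_equal(normalized_adhesion(5e-3, 100e-6, 500)$Gamma_star, 0.1)
  expect_equal(normalized_adhesion(0, 1e-4, 500)$Gamma_star, 0)
  expect_equal(normalized_adhesion(5e-3, 200e-6, 500)$Gamma_star, 0.05)
  expect_match(normalized_adhesion(5e-3, 200e-6, 500)$regime, "delamination")
})

test_that("log-log slope is 1/3 asymptotically and smaller in the soft regime", {
  bil <- wrinkle_scan(10^seq(1, 3, length.out = 9), gr_over_gf = NULL)
  expect_equal(scan_slope(bil, c(10, 1000))$slope, 1 / 3, tolerance = 1e-3)
  tri_hi <- wrinkle_scan(10^seq(1, 3, length.out = 9), gr_over_gf = 0.1)
  expect_equal(scan_slope(tri_hi, c(10, 1000))$slope, 1 / 3, tolerance = 0.02)
  tri_lo <- wrinkle_scan(10^seq(log10(0.05), 0, length.out = 9),
                         gr_over_gf = 0.1)
  expect_lt(scan_slope(tri_lo, c(0.05, 1))$slope, 1 / 3 - 0.05)
})

test_that("residual stiffness is recovered from model-generated wavelengths", {
  ratios <- 10^seq(log10(0.02), 1, length.out = 8)
  ds <- gen_stiffness_dataset(0.1, ratios, noise_sigma = 0)
  fit <- fit_residual_stiffness(ds$data)
  expect_equal(fit$gr_over_gf, 0.1, tolerance = 1e-3)
  expect_false(fit$boundary)
  expect_s3_class(glance(fit), "tbl_df")
  expect_equal(tidy(fit)$estimate, fit$gr_over_gf)
})

test_that("residual fit tolerates multiplicative noise (seeded replicates)", {
  ratios <- 10^seq(log10(0.02), 1, length.out = 8)
  hits <- vapply(1:12, function(s) {
    ds <- gen_stiffness_dataset(0.1, ratios, noise_sigma = 0.05, seed = s)
    fit <- suppressWarnings(fit_residual_stiffness(ds$data))
    abs(fit$gr_over_gf / 0.1 - 1) < 0.3
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("degenerate fits are reported", {
  ratios <- 10^seq(log10(0.02), 1, length.out = 8)
  ds <- gen_stiffness_dataset(0.9, ratios, noise_sigma = 0)
  expect_warning(fit <- fit_residual_stiffness(ds$data, bracket = c(1e-3, 0.5)),
                 "boundary")
  expect_true(fit$boundary)
  expect_error(fit_residual_stiffness(ds$data[1:2, ]),
               class = "biofilmorph_domain_error")
})
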