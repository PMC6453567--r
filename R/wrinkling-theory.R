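#' Combined stiffness of the residual layer and substrate
#'
#' In the trilayer linear-stability model the film rests on a composite
#' foundation whose stiffness at wavenumber `n` is
#' \deqn{\tilde K(n) = \frac{4 G_s n}{n h_r (G_s/G_r - 1) + 2}.}
#' With `G_r = G_s` or `h_r = 0` this reduces to the classical half-space
#' foundation `2 G_s n`. The formula presumes a compliant interlayer: a stiff
#' residual layer (`G_r > G_s`) can drive the denominator non-positive at
#' large `n h_r`, which is outside model validity and raises an error rather
#' than being clipped.
#'
#' @param n Wavenumber (1/m), positive. Vectorised.
#' @param substrate_G,residual_G Shear moduli (Pa), positive.
#' @param residual_h Residual-layer thickness (m), non-negative.
#' @return The foundation stiffness (Pa/m).
#' @examples
#' composite_stiffness(5, 1, 1, 0.3) # bilayer limit: 2 * 1 * 5
#' @export
composite_stiffness <- function(n, substrate_G, residual_G, residual_h) {
  if (any(n <= 0)) abort("`n` must be positive.", class = "biofilmorph_domain_error")
  if (substrate_G <= 0 || residual_G <= 0)
    abort("Moduli must be positive.", class = "biofilmorph_domain_error")
  if (residual_h < 0)
    abort("`residual_h` must be non-negative.", class = "biofilmorph_domain_error")
  denom <- n * residual_h * (substrate_G / residual_G - 1) + 2
  if (any(denom <= 0))
    abort("Foundation stiffness denominator is non-positive: outside model validity (stiff residual layer at large n h_r).",
          class = "biofilmorph_validity_error")
  4 * substrate_G * n / denom
}

#' Longitudinal film stress at wavenumber n
#'
#' The sinusoidal-undulation ansatz gives the longitudinal stress required to
#' hold a wrinkle of wavenumber `n`:
#' \deqn{S(n) = \frac{G_f h_f^2 n^2}{3} + \frac{\tilde K(n)}{h_f n^2}.}
#' The first term is the film bending cost, the second the foundation
#' deformation cost; `S` diverges as `n` tends to 0 or infinity, so an
#' interior minimum (the critical wavenumber) always exists.
#'
#' @param n Wavenumber (1/m). Vectorised.
#' @param stack A [layer_stack()].
#' @return The stress `S(n)` (Pa).
#' @export
film_stress <- function(n, stack) {
  stopifnot(inherits(stack, "layer_stack"))
  Kt <- composite_stiffness(n, stack$substrate$G, stack$residual$G, stack$residual$h)
  stack$film$G * stack$film$h^2 * n^2 / 3 + Kt / (stack$film$h * n^2)
}

# analytic dS/dn; D = n h_r (G_s/G_r - 1) + 2, dK/dn = 8 G_s / D^2
film_stress_deriv <- function(n, stack) {
  Gs <- stack$substrate$G; Gr <- stack$residual$G
  hr <- stack$residual$h; Gf <- stack$film$G; hf <- stack$film$h
  D <- n * hr * (Gs / Gr - 1) + 2
  Kt <- 4 * Gs * n / D
  dK <- 8 * Gs / D^2
  2 * Gf * hf^2 * n / 3 + dK / (hf * n^2) - 2 * Kt / (hf * n^3)
}

#' Solve the trilayer wrinkling problem
#'
#' Minimises the film stress `S(n)` over wavenumber, giving the critical
#' wavenumber `n_cr`, wavelength `lambda_cr = 2 pi / n_cr`, critical stress
#' `S_cr = S(n_cr)` and critical mismatch strain `eps_cr = S_cr / (3 G_f)`.
#' The minimisation is a bracketed scalar search on `log n` over
#' `n h_f` in `[bracket[1], bracket[2]]`, polished by a root solve of the
#' analytic stationarity condition `dS/dn = 0`; the relative stationarity
#' residual `|dS/dn| n / S` of the returned solution is below 1e-8.
#'
#' @param stack A [layer_stack()].
#' @param bracket Search bracket for the dimensionless wavenumber `n h_f`
#'   (default `c(1e-3, 1e3)`).
#' @param strained_depth Depth of the strained substrate region used for the
#'   effective substrate modulus `G'_s = K(n_cr) h'_s`. Default `NULL` uses
#'   `1/n_cr`, the natural decay depth of a sinusoidal surface load.
#' @return An object of class `wrinkle_solution`: a list with `n_cr`,
#'   `lambda_cr`, `lambda_over_hf`, `S_cr`, `eps_cr`, `Gp_s` (effective
#'   substrate modulus), `stationarity` (relative residual) and the input
#'   `stack`.
#' @examples
#' sol <- solve_wrinkling(stack_from_ratios(100, gr_over_gf = 1/100))
#' sol$lambda_over_hf
#' @export
solve_wrinkling <- function(stack, bracket = c(1e-3, 1e3), strained_depth = NULL) {
  stopifnot(inherits(stack, "layer_stack"))
  hf <- stack$film$h
  lo <- bracket[1] / hf
  hi <- bracket[2] / hf
  # restrict to the validity region when the residual layer is stiffer than
  # the substrate (foundation denominator must stay positive)
  c_coef <- stack$residual$h * (stack$substrate$G / stack$residual$G - 1)
  if (c_coef < 0) hi <- min(hi, 0.999 * (-2 / c_coef))
  if (hi <= lo) abort("Empty validity bracket for the wavenumber search.",
                      class = "biofilmorph_solver_error")
  obj <- function(logn) film_stress(exp(logn), stack)
  opt <- stats::optimize(obj, c(log(lo), log(hi)), tol = 1e-10)
  n_cr <- exp(opt$minimum)
  if (n_cr < lo * 1.0001 || n_cr > hi * 0.9999) {
    # minimum at bracket edge: no interior minimum
    abort(sprintf("No interior stress minimum in bracket [%g, %g] (n h_f at edge: %g).",
                  lo * hf, hi * hf, n_cr * hf),
          class = "biofilmorph_solver_error")
  }
  # polish on the analytic stationarity condition
  dlo <- n_cr * 0.9; dhi <- n_cr * 1.1
  f_lo <- film_stress_deriv(dlo, stack); f_hi <- film_stress_deriv(dhi, stack)
  if (is.finite(f_lo) && is.finite(f_hi) && f_lo < 0 && f_hi > 0) {
    n_cr <- stats::uniroot(film_stress_deriv, c(dlo, dhi), stack = stack,
                           tol = .Machine$double.eps^0.75)$root
  }
  S_cr <- film_stress(n_cr, stack)
  res <- abs(film_stress_deriv(n_cr, stack)) * n_cr / S_cr
  sol <- structure(list(
    n_cr = n_cr,
    lambda_cr = 2 * pi / n_cr,
    lambda_over_hf = 2 * pi / n_cr / hf,
    S_cr = S_cr,
    eps_cr = S_cr / (3 * stack$film$G),
    stationarity = res,
    stack = stack
  ), class = "wrinkle_solution")
  sol$Gp_s <- effective_substrate_modulus(sol, stack, strained_depth)
  sol
}

#' @export
print.wrinkle_solution <- function(x, ...) {
  cat("<wrinkle_solution>\n")
  cat(sprintf("  n_cr = %.6g 1/m   lambda_cr = %.6g m (lambda/h_f = %.6g)\n",
              x$n_cr, x$lambda_cr, x$lambda_over_hf))
  cat(sprintf("  S_cr = %.6g Pa    eps_cr = %.6g    G'_s = %.6g Pa\n",
              x$S_cr, x$eps_cr, x$Gp_s))
  invisible(x)
}

#' @export
tidy.wrinkle_solution <- function(x, ...) {
  tibble(n_cr = x$n_cr, lambda_cr = x$lambda_cr,
         lambda_over_hf = x$lambda_over_hf, S_cr = x$S_cr,
         eps_cr = x$eps_cr, Gp_s = x$Gp_s)
}

#' Closed-form bilayer wrinkling wavelength
#'
#' For a film on a homogeneous substrate (no residual layer, or
#' `G_r = G_s`), the critical wavelength is
#' `lambda = 2 pi h_f (G_f / (3 G_s))^{1/3}`.
#'
#' @param film_G,substrate_G Shear moduli (Pa), positive.
#' @param film_h Film thickness (m), positive.
#' @return The wavelength (same units as `film_h`).
#' @examples
#' bilayer_wavelength(3, 1, 1) # 2 * pi
#' @export
bilayer_wavelength <- function(film_G, substrate_G, film_h) {
  if (any(c(film_G, substrate_G, film_h) <= 0))
    abort("All inputs must be positive.", class = "biofilmorph_domain_error")
  2 * pi * film_h * (film_G / (3 * substrate_G))^(1 / 3)
}

#' Classical bilayer critical strain
#'
#' The textbook small-strain bilayer result
#' `eps_cr = (1/4) (3 G_s / G_f)^{2/3}`, provided for comparison with the
#' convention `eps_cr = S_cr / (3 G_f)` used by [solve_wrinkling()]; the two
#' differ by a constant factor in the bilayer limit.
#'
#' @param gf_over_gs Stiffness contrast `G_f / G_s`.
#' @return The classical critical strain.
#' @export
bilayer_critical_strain_classical <- function(gf_over_gs) {
  if (any(gf_over_gs <= 0)) abort("`gf_over_gs` must be positive.",
                                  class = "biofilmorph_domain_error")
  0.25 * (3 / gf_over_gs)^(2 / 3)
}

#' Effective substrate modulus
#'
#' The composite foundation felt by the film can be summarised as an
#' effective substrate modulus `G'_s = K(n_cr) h'_s`, where `h'_s` is the
#' total depth of the strained region. The model does not fix `h'_s`; the
#' default is the sinusoidal decay depth `1/n_cr`.
#'
#' @param solution A `wrinkle_solution`.
#' @param stack The [layer_stack()] the solution was computed for.
#' @param strained_depth Depth `h'_s` (m), or `NULL` for `1/n_cr`.
#' @return The effective modulus (Pa).
#' @export
effective_substrate_modulus <- function(solution, stack, strained_depth = NULL) {
  hps <- strained_depth %||% (1 / solution$n_cr)
  if (hps <= 0) abort("`strained_depth` must be positive.",
                      class = "biofilmorph_domain_error")
  Kt <- composite_stiffness(solution$n_cr, stack$substrate$G,
                            stack$residual$G, stack$residual$h)
  Kt * hps
}

#' Normalised adhesion energy
#'
#' The dimensionless adhesion `Gamma* = Gamma / (h_f G'_s)` compares the
#' film-substrate adhesion energy with the elastic energy of deforming the
#' effective substrate. Small values (`Gamma* << 1`) favour delamination over
#' wrinkling; the biofilm system sits at order 0.01-1.
#'
#' @param Gamma Adhesion energy (J/m^2), non-negative.
#' @param film_h Film thickness (m), positive.
#' @param effective_G Effective substrate modulus `G'_s` (Pa), positive.
#' @return A list with `Gamma_star` and a qualitative `regime` label
#'   (`"delamination-prone"` for `Gamma* < 0.1`, else `"wrinkling-favoured"`).
#' @examples
#' normalized_adhesion(5e-3, 100e-6, 500)$Gamma_star # 0.1
#' @export
normalized_adhesion <- function(Gamma, film_h, effective_G) {
  if (Gamma < 0) abort("`Gamma` must be non-negative.",
                       class = "biofilmorph_domain_error")
  if (film_h <= 0 || effective_G <= 0)
    abort("`film_h` and `effective_G` must be positive.",
          class = "biofilmorph_domain_error")
  gs <- Gamma / (film_h * effective_G)
  list(Gamma_star = gs,
       regime = if (gs < 0.1) "delamination-prone" else "wrinkling-favoured")
}

#' Scan critical wavelength against stiffness contrast
#'
#' Solves the trilayer wrinkling problem over a set of `G_f/G_s` ratios,
#' keeping the film, residual-layer ratios and thicknesses of the template
#' fixed. Points where the solver fails are kept with `NA` and flagged.
#'
#' @param ratios Stiffness contrasts `G_f/G_s`, strictly increasing.
#' @param gr_over_gf,hr_over_hf Residual-layer ratios (see
#'   [stack_from_ratios()]). Use `gr_over_gf = NULL` for the bilayer model
#'   (`G_r = G_s` at every ratio).
#' @param h_f,G_f Film scale (defaults dimensionless).
#' @return A tibble of class `wrinkle_scan` with columns `gf_over_gs`,
#'   `lambda_over_hf`, `eps_cr`, `S_cr_over_Gf`, `converged`.
#' @examples
#' sc <- wrinkle_scan(10^seq(1, 3, length.out = 9), gr_over_gf = NULL)
#' @export
wrinkle_scan <- function(ratios, gr_over_gf = 0.1, hr_over_hf = 0.3,
                         h_f = 1, G_f = 1) {
  if (any(diff(ratios) <= 0)) abort("`ratios` must be strictly increasing.")
  rows <- purrr::map(ratios, function(r) {
    grf <- if (is.null(gr_over_gf)) 1 / r else gr_over_gf
    stack <- stack_from_ratios(r, gr_over_gf = grf, hr_over_hf = hr_over_hf,
                               G_f = G_f, h_f = h_f)
    sol <- tryCatch(solve_wrinkling(stack), error = function(e) NULL)
    if (is.null(sol)) {
      warn(sprintf("Wrinkling solver failed at G_f/G_s = %g; point flagged.", r))
      tibble(gf_over_gs = r, lambda_over_hf = NA_real_, eps_cr = NA_real_,
             S_cr_over_Gf = NA_real_, converged = FALSE)
    } else {
      tibble(gf_over_gs = r, lambda_over_hf = sol$lambda_over_hf,
             eps_cr = sol$eps_cr, S_cr_over_Gf = sol$S_cr / G_f,
             converged = TRUE)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("wrinkle_scan", class(out))
  out
}

#' Log-log slope of a wavelength scan
#'
#' Least-squares slope of `log(lambda/h_f)` against `log(G_f/G_s)` restricted
#' to an explicit window of ratios. In the asymptotic bilayer regime the
#' slope is 1/3; the window is always an explicit argument because the 1/3
#' law holds only asymptotically.
#'
#' @param scan A `wrinkle_scan` tibble.
#' @param window Length-2 numeric, inclusive `G_f/G_s` window for the fit.
#' @return A list with `slope`, `intercept`, `n_points`.
#' @export
scan_slope <- function(scan, window) {
  stopifnot(length(window) == 2)
  d <- dplyr::filter(scan, .data$converged,
                     .data$gf_over_gs >= window[1], .data$gf_over_gs <= window[2])
  if (nrow(d) < 5) abort("Need at least 5 converged points in the slope window.")
  fit <- stats::lm(log(lambda_over_hf) ~ log(gf_over_gs), data = d)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n_points = nrow(d))
}

#' Fit the residual-layer stiffness to wavelength data
#'
#' The residual-layer shear modulus is the one parameter of the trilayer
#' model that cannot be measured directly; it is recovered by least squares
#' against measured normalised wavelengths. The objective
#' `SSE(G_r/G_f) = sum (lambda_model/h_f - lambda_data/h_f)^2` is minimised
#' by bisection on the sign of its derivative over `log(G_r/G_f)`, with a
#' golden-section fallback when the coarse profile is not unimodal.
#'
#' @param data A data frame with columns `gf_over_gs` and `lambda_over_hf`
#'   (measured), at least 3 rows.
#' @param hr_over_hf Residual-to-film thickness ratio held fixed during the
#'   fit (default 0.3).
#' @param bracket Search bracket for `G_r/G_f`, within `(0, 1]`
#'   (default `c(1e-3, 1)`; the residual layer is softer than the film by
#'   construction).
#' @param tol Relative tolerance on the fitted ratio (default 1e-4).
#' @return An object of class `residual_fit`: list with `gr_over_gf`, `sse`,
#'   `iterations`, `boundary` (TRUE when the optimum sits at a bracket edge)
#'   and `method` ("bisection" or "golden-section").
#' @examples
#' sc <- wrinkle_scan(10^seq(-1, 1, length.out = 8), gr_over_gf = 0.1)
#' fit <- fit_residual_stiffness(sc)
#' fit$gr_over_gf
#' @export
fit_residual_stiffness <- function(data, hr_over_hf = 0.3,
                                   bracket = c(1e-3, 1), tol = 1e-4) {
  d <- dplyr::filter(as_tibble(data), is.finite(.data$lambda_over_hf))
  if (nrow(d) < 3) abort("Need at least 3 wavelength data points.",
                         class = "biofilmorph_domain_error")
  if (bracket[1] <= 0 || bracket[2] > 1 || bracket[1] >= bracket[2])
    abort("`bracket` must lie within (0, 1] and be increasing.")
  sse <- function(gr) {
    mod <- vapply(d$gf_over_gs, function(r) {
      stack <- stack_from_ratios(r, gr_over_gf = gr, hr_over_hf = hr_over_hf)
      tryCatch(solve_wrinkling(stack)$lambda_over_hf, error = function(e) NA_real_)
    }, 0)
    sum((mod - d$lambda_over_hf)^2, na.rm = TRUE)
  }
  lo <- log(bracket[1]); hi <- log(bracket[2])
  h_fd <- 1e-5
  dsse <- function(x) (sse(exp(x + h_fd)) - sse(exp(x - h_fd))) / (2 * h_fd)
  # coarse unimodality check on the derivative sign
  grid <- seq(lo, hi, length.out = 9)
  signs <- sign(vapply(grid, dsse, 0))
  changes <- sum(diff(signs[signs != 0]) != 0)
  iterations <- 0L
  if (changes <= 1 && signs[1] <= 0 && signs[length(signs)] >= 0) {
    a <- lo; b <- hi
    while ((b - a) > tol && iterations < 60L) {
      m <- (a + b) / 2
      if (dsse(m) > 0) b <- m else a <- m
      iterations <- iterations + 1L
    }
    x_opt <- (a + b) / 2
    method <- "bisection"
  } else {
    opt <- stats::optimize(function(x) sse(exp(x)), c(lo, hi), tol = tol / 2)
    x_opt <- opt$minimum
    iterations <- NA_integer_
    method <- "golden-section"
  }
  gr_opt <- exp(x_opt)
  boundary <- (x_opt - lo) < 2 * tol || (hi - x_opt) < 2 * tol
  if (boundary) warn("Residual-stiffness fit lies at the bracket boundary.")
  structure(list(gr_over_gf = gr_opt, sse = sse(gr_opt),
                 iterations = iterations, boundary = boundary,
                 method = method, hr_over_hf = hr_over_hf, data = d),
            class = "residual_fit")
}

#' @export
print.residual_fit <- function(x, ...) {
  cat(sprintf("<residual_fit> G_r/G_f = %.4g (SSE = %.4g, %s%s)\n",
              x$gr_over_gf, x$sse, x$method,
              if (x$boundary) ", boundary solution" else ""))
  invisible(x)
}

#' @export
tidy.residual_fit <- function(x, ...) {
  tibble(term = "gr_over_gf", estimate = x$gr_over_gf)
}

#' @export
glance.residual_fit <- function(x, ...) {
  tibble(gr_over_gf = x$gr_over_gf, sse = x$sse, n = nrow(x$data),
         boundary = x$boundary, method = x$method)
}

#' @export
autoplot.wrinkle_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$gf_over_gs,
                                       y = .data$lambda_over_hf)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(G[f] / G[s]),
                  y = expression(lambda[cr] / h[f]),
                  title = "Critical wrinkling wavelength vs stiffness contrast")
}
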