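#' Configuration for the plane-strain growth simulation
#'
#' Dimensionless configuration of the trilayer finite-element model. The film
#' thickness and shear modulus set the units (`h_f = 1`, `G_f = 1`); all
#' other quantities are ratios. Defaults follow the biofilm parameter set:
#' thick substrate (`h_s/h_f = 10`), soft residual layer (`G_r/G_f = 0.1`,
#' `h_r/h_f = 0.3`), growth increment 0.002, onset threshold 0.01 `h_f`,
#' Poisson ratio 0.45 in every layer.
#'
#' @param gf_over_gs Film-to-substrate stiffness contrast.
#' @param gr_over_gf Residual-to-film stiffness ratio.
#' @param hr_over_hf,hs_over_hf Thickness ratios.
#' @param nu Poisson ratio, one value for all layers, in `(0, 0.5)`.
#' @param L Domain length in units of `h_f`. Default `NULL` sizes the box to
#'   `10 *` the critical wavelength predicted by [solve_wrinkling()] for the
#'   same stack, which keeps finite-size effects small.
#' @param dg Growth increment per step.
#' @param g_max Maximum growth parameter (at most 1).
#' @param onset_threshold Wrinkle-onset threshold as a fraction of `h_f`
#'   applied to the surface deflection (peak deviation from the laterally
#'   averaged surface displacement).
#' @param perturbation_amplitude Amplitude of the symmetry-breaking surface
#'   perturbation, as a fraction of `h_f`.
#' @param seed Integer seed for the perturbation phases.
#' @param elements_per_hf Element rows through the film thickness.
#' @param aspect Target horizontal spacing in units of the predicted
#'   wavelength (`dx = lambda / aspect`); higher is finer.
#' @param steps_after_onset If not `NULL`, stop this many increments after
#'   onset is detected (the surface wavelength is measured 10 steps past
#'   onset, so values >= 10 retain full fidelity at reduced cost).
#' @param tol Projected-gradient tolerance of the energy minimiser, in units
#'   of `G_f h_f^2`.
#' @return A validated list of class `fem_config`.
#' @export
fem_config <- function(gf_over_gs = 10, gr_over_gf = 0.1, hr_over_hf = 0.3,
                       hs_over_hf = 10, nu = 0.45, L = NULL,
                       dg = 0.002, g_max = 1, onset_threshold = 0.01,
                       perturbation_amplitude = 1e-4, seed = 1L,
                       elements_per_hf = 4L, aspect = 16,
                       steps_after_onset = NULL, tol = 1e-8) {
  if (dg <= 0) abort("`dg` must be positive.", class = "biofilmorph_domain_error")
  if (g_max > 1 || g_max < 0) abort("`g_max` must lie in [0, 1].",
                                    class = "biofilmorph_domain_error")
  if (nu <= 0 || nu >= 0.5) abort("FEM requires 0 < nu < 0.5.",
                                  class = "biofilmorph_domain_error")
  if (hs_over_hf < 5) abort("Thick-substrate assumption requires hs/hf >= 5.",
                            class = "biofilmorph_domain_error")
  theory <- solve_wrinkling(stack_from_ratios(gf_over_gs, gr_over_gf, hr_over_hf))
  lambda <- theory$lambda_over_hf
  if (is.null(L)) L <- 10 * lambda
  if (L < 10 * lambda)
    warn(sprintf("L = %g is below 10 x predicted wavelength (%g); finite-size effects likely.",
                 L, 10 * lambda))
  structure(list(
    gf_over_gs = gf_over_gs, gr_over_gf = gr_over_gf,
    hr_over_hf = hr_over_hf, hs_over_hf = hs_over_hf, nu = nu,
    L = L, dg = dg, g_max = g_max, onset_threshold = onset_threshold,
    perturbation_amplitude = perturbation_amplitude, seed = as.integer(seed),
    elements_per_hf = as.integer(elements_per_hf), aspect = aspect,
    steps_after_onset = steps_after_onset, tol = tol,
    lambda_theory = lambda, eps_cr_theory = theory$eps_cr
  ), class = "fem_config")
}

#' Build the structured trilayer mesh
#'
#' Crossed-triangle structured mesh of the rectangle
#' `[0, L] x [0, h_s + h_r + h_f]`: each quad is split into four triangles
#' around its centroid. Layer interfaces conform exactly to element rows; the
#' film carries `elements_per_hf` uniform rows, the residual layer two, and
#' the substrate rows coarsen geometrically (ratio 2) with depth.
#'
#' @param config A [fem_config()].
#' @return A list of class `fem_mesh`: node coordinates `nodes` (n x 2,
#'   undeformed), triangle indices `tri` (m x 3, 1-based, positively
#'   oriented), per-element shape gradients `bx`, `by`, areas `area`, layer
#'   `label`, growth flag `grows`, Lame parameters `mu`, `lam`, plus node
#'   index vectors for the boundary conditions and the film surface.
#' @export
build_mesh <- function(config) {
  stopifnot(inherits(config, "fem_config"))
  hf <- 1
  hr <- config$hr_over_hf * hf
  hs <- config$hs_over_hf * hf
  L <- config$L
  n_f <- config$elements_per_hf
  if (hr <= 0) abort("Residual thickness must be positive for mesh rows (set hr_over_hf > 0).",
                     class = "biofilmorph_config_error")
  # row thicknesses bottom-up: substrate graded coarse->fine, residual, film
  dy_r <- hr / 2
  sub_rows <- dy_r * 2
  while (sum(sub_rows) < hs) sub_rows <- c(sub_rows, 2 * sub_rows[length(sub_rows)])
  sub_rows[length(sub_rows)] <- sub_rows[length(sub_rows)] - (sum(sub_rows) - hs)
  sub_rows <- rev(sub_rows)                       # coarse at bottom
  rows <- c(sub_rows, rep(dy_r, 2), rep(hf / n_f, n_f))
  band <- c(rep("substrate", length(sub_rows)), rep("residual", 2), rep("film", n_f))
  levels_y <- cumsum(c(0, rows))
  H <- levels_y[length(levels_y)]

  dx <- config$lambda_theory / config$aspect
  nx <- max(4L, as.integer(round(L / dx)))
  xs <- seq(0, L, length.out = nx + 1)
  ny <- length(rows)

  # grid nodes (column-major over x then y), then one centre node per quad
  gx <- rep(xs, times = ny + 1)
  gy <- rep(levels_y, each = nx + 1)
  grid_id <- function(i, j) (j - 1) * (nx + 1) + i  # i in 1..nx+1, j in 1..ny+1
  cx <- rep((xs[-1] + xs[-(nx + 1)]) / 2, times = ny)
  cy <- rep((levels_y[-1] + levels_y[-(ny + 1)]) / 2, each = nx)
  n_grid <- (nx + 1) * (ny + 1)
  nodes <- cbind(c(gx, cx), c(gy, cy))
  centre_id <- function(i, j) n_grid + (j - 1) * nx + i

  m <- 4L * nx * ny
  tri <- matrix(0L, m, 3)
  lab <- character(m)
  k <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      bl <- grid_id(i, j); br <- grid_id(i + 1, j)
      tl <- grid_id(i, j + 1); tr <- grid_id(i + 1, j + 1)
      cc <- centre_id(i, j)
      quad <- rbind(c(bl, br, cc), c(br, tr, cc), c(tr, tl, cc), c(tl, bl, cc))
      tri[k + 1:4, ] <- quad
      lab[k + 1:4] <- band[j]
      k <- k + 4L
    }
  }
  # shape-function gradients and areas
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  twoA <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  if (any(twoA <= 0)) abort("Mesh construction produced a non-positively oriented element.")
  bx <- cbind(y2 - y3, y3 - y1, y1 - y2) / twoA
  by <- cbind(x3 - x2, x1 - x3, x2 - x1) / twoA
  area <- twoA / 2

  G_of <- c(film = 1, residual = config$gr_over_gf,
            substrate = 1 / config$gf_over_gs)
  lame <- lame_parameters(G_of[lab], config$nu)
  grows <- as.integer(lab != "substrate")

  left <- which(abs(nodes[, 1]) < 1e-12)
  right <- which(abs(nodes[, 1] - L) < 1e-12)
  bottom <- which(abs(nodes[, 2]) < 1e-12)
  surface <- which(abs(nodes[, 2] - H) < 1e-12)
  surface <- surface[order(nodes[surface, 1])]

  structure(list(
    nodes = nodes, tri = tri, bx = bx, by = by, area = area,
    label = lab, grows = grows, mu = unname(lame$mu_e), lam = unname(lame$lambda_e),
    left = left, right = right, bottom = bottom, surface = surface,
    nx = nx, L = L, height = H, hf = hf,
    film_top = H, film_bottom = H - hf
  ), class = "fem_mesh")
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf("<fem_mesh> %d nodes, %d triangles, domain [0, %g] x [0, %g]\n",
              nrow(x$nodes), nrow(x$tri), x$L, x$height))
  invisible(x)
}
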