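# boundary conditions: u1 = 0 on the left/right walls, u2 = 0 on the bottom
free_dof_mask <- function(mesh) {
  n <- nrow(mesh$nodes)
  fixed <- c(mesh$left, mesh$right, n + mesh$bottom)
  mask <- rep(TRUE, 2 * n)
  mask[fixed] <- FALSE
  mask
}

#' Minimise the total energy at fixed growth
#'
#' Finds the displacement field minimising [total_energy()] subject to the
#' confinement boundary conditions (`u1 = 0` on the side walls, `u2 = 0` at
#' the bottom). The reduced problem on the free degrees of freedom is solved
#' by L-BFGS with the analytic gradient.
#'
#' @param u_init Initial displacement (`n x 2` matrix or `2n` vector)
#'   satisfying the boundary conditions.
#' @param mesh,config,g As in [total_energy()].
#' @param tol Projected-gradient max-norm tolerance (units `G_f h_f`);
#'   default from `config$tol`.
#' @param maxit Iteration cap.
#' @return A list with `u` (`n x 2` matrix), `energy`, `grad_norm`,
#'   `converged`.
#' @export
minimize_energy <- function(u_init, mesh, config, g, tol = NULL, maxit = 5000L) {
  stopifnot(inherits(mesh, "fem_mesh"))
  tol <- tol %||% config$tol
  uv <- as_u_vector(u_init, mesh)
  mask <- free_dof_mask(mesh)
  full <- uv
  fn <- function(x) {
    full[mask] <- x
    energy_grad_full(full, mesh, g)$energy
  }
  gr <- function(x) {
    full[mask] <- x
    energy_grad_full(full, mesh, g)$grad[mask]
  }
  e0 <- fn(uv[mask])
  # L-BFGS memory goes stale across the wrinkling bifurcation; restarting
  # from the current iterate recovers superlinear progress
  par <- uv[mask]
  for (attempt in 1:4) {
    opt <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 1e7, pgtol = tol))
    par <- opt$par
    if (opt$convergence == 0) break
  }
  full[mask] <- opt$par
  gnorm <- max(abs(energy_grad_full(full, mesh, g)$grad[mask]))
  if (opt$value > e0 + 1e-12 * max(1, abs(e0)))
    abort("Energy minimisation increased the energy.",
          class = "biofilmorph_solver_error")
  converged <- opt$convergence == 0 || gnorm <= tol
  if (!converged)
    abort(sprintf("Energy minimisation did not converge (grad norm %g, tol %g; optim code %d).",
                  gnorm, tol, opt$convergence),
          class = "biofilmorph_solver_error")
  n <- nrow(mesh$nodes)
  list(u = cbind(full[seq_len(n)], full[n + seq_len(n)]),
       energy = opt$value, grad_norm = gnorm, converged = converged)
}

# seeded multi-sine surface perturbation; phases drawn once per simulation
surface_perturbation <- function(mesh, config, phases, modes) {
  x <- mesh$nodes[mesh$surface, 1]
  w <- rowSums(vapply(seq_along(modes), function(i)
    sin(2 * pi * modes[i] * x / mesh$L + phases[i]), numeric(length(x))))
  w <- w / max(abs(w), 1e-12)
  config$perturbation_amplitude * mesh$hf * w
}

# deflection = peak deviation of the surface from its lateral mean
surface_deflection <- function(u2_surface) {
  max(abs(u2_surface - mean(u2_surface)))
}

#' Run the incremental growth simulation
#'
#' Steps the growth parameter `g` in increments of `config$dg`, at each step
#' minimising the total energy from the previous solution warm-started with a
#' small seeded multi-sine perturbation of the film surface (the flat branch
#' is a true equilibrium, so the wrinkled branch is only found off it).
#' Onset is the first step whose surface deflection (peak deviation from the
#' laterally averaged surface height) exceeds
#' `config$onset_threshold * h_f`.
#'
#' @param config A [fem_config()].
#' @param quiet Suppress progress messages.
#' @return An object of class `growth_sim`: list with `trajectory` (tibble
#'   `g`, `epsilon`, `max_deflection`, `Pi`), `onset_g`, `onset_strain`,
#'   `surface_profiles` (matrix, one row per step), `surface_x`, `u_final`,
#'   `mesh`, `config`.
#' @export
run_growth <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "fem_config"))
  mesh <- build_mesh(config)
  n <- nrow(mesh$nodes)
  gs <- if (config$g_max < config$dg) numeric(0) else
    seq(config$dg, config$g_max, by = config$dg)
  modes <- 3:12
  phases <- withr::with_seed(config$seed, runif(length(modes), 0, 2 * pi))
  pert <- surface_perturbation(mesh, config, phases, modes)

  u <- matrix(0, n, 2)
  traj <- vector("list", length(gs))
  profiles <- matrix(NA_real_, length(gs), length(mesh$surface))
  onset_g <- NA_real_
  onset_step <- NA_integer_
  last <- 0L
  for (k in seq_along(gs)) {
    g <- gs[k]
    u_start <- u
    u_start[mesh$surface, 2] <- u_start[mesh$surface, 2] + pert
    sol <- minimize_energy(u_start, mesh, config, g)
    u <- sol$u
    u2s <- u[mesh$surface, 2]
    defl <- surface_deflection(u2s)
    profiles[k, ] <- u2s
    traj[[k]] <- tibble(g = g, epsilon = growth_strain(g),
                        max_deflection = defl, Pi = sol$energy)
    last <- k
    if (!quiet && k %% 10 == 0)
      message(sprintf("g = %.3f  deflection = %.4g", g, defl))
    if (is.na(onset_g) && defl > config$onset_threshold * mesh$hf) {
      onset_g <- g
      onset_step <- k
    }
    if (!is.na(onset_g) && !is.null(config$steps_after_onset) &&
        k >= onset_step + config$steps_after_onset) break
  }
  trajectory <- dplyr::bind_rows(traj[seq_len(last)])
  structure(list(
    trajectory = trajectory,
    onset_g = onset_g,
    onset_strain = if (is.na(onset_g)) NA_real_ else growth_strain(onset_g),
    no_onset = is.na(onset_g),
    onset_step = onset_step,
    surface_profiles = profiles[seq_len(last), , drop = FALSE],
    surface_x = mesh$nodes[mesh$surface, 1],
    u_final = u, g_final = if (last > 0) gs[last] else 0,
    mesh = mesh, config = config
  ), class = "growth_sim")
}

#' @export
print.growth_sim <- function(x, ...) {
  cat("<growth_sim>\n")
  cat(sprintf("  steps: %d (g up to %g)\n", nrow(x$trajectory), x$g_final))
  if (x$no_onset) cat("  onset: none detected\n")
  else cat(sprintf("  onset: g = %g (strain %.4g)\n", x$onset_g, x$onset_strain))
  invisible(x)
}

#' @export
glance.growth_sim <- function(x, ...) {
  tibble(onset_g = x$onset_g, onset_strain = x$onset_strain,
         g_final = x$g_final, steps = nrow(x$trajectory),
         lambda_theory = x$config$lambda_theory,
         eps_cr_theory = x$config$eps_cr_theory)
}

#' Dominant surface wavelength of a growth simulation
#'
#' Measures the wrinkle wavelength from the simulated film surface by FFT of
#' the vertical surface displacement (mean removed): the wavelength is
#' `L / k` for the dominant nonzero mode `k`. By default the profile 10
#' steps after onset is used, mirroring the ring-counting image analysis.
#'
#' @param sim A `growth_sim`.
#' @param step Step index to analyse; default `onset_step + 10` (clamped to
#'   the last available step).
#' @return A list with `lambda` (units of `h_f`), `mode`, `step`.
#' @export
measure_surface_wavelength <- function(sim, step = NULL) {
  stopifnot(inherits(sim, "growth_sim"))
  if (nrow(sim$surface_profiles) == 0) abort("Simulation has no recorded steps.")
  step <- step %||% min(ifelse(is.na(sim$onset_step), nrow(sim$surface_profiles),
                               sim$onset_step + 10L), nrow(sim$surface_profiles))
  # drop the duplicated right-boundary sample (x = L is the period of x = 0)
  y <- sim$surface_profiles[step, -ncol(sim$surface_profiles)]
  y <- y - mean(y)
  p <- Mod(fft(y))^2
  half <- 2:floor(length(y) / 2)
  k <- half[which.max(p[half])] - 1L
  list(lambda = sim$mesh$L / k, mode = k, step = step)
}

#' @export
autoplot.growth_sim <- function(object, ...) {
  d <- object$trajectory
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epsilon, y = .data$max_deflection)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$config$onset_threshold,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$config$eps_cr_theory,
                        linetype = "dotted", colour = "red") +
    ggplot2::labs(x = "mismatch strain", y = "surface deflection / h_f",
                  title = "Growth trajectory",
                  subtitle = "dashed: onset threshold; dotted: linear-stability critical strain")
}

#' Film surface profile of a simulation step
#'
#' @param sim A `growth_sim`.
#' @param step Step index (default: last).
#' @return A tibble with `x` and vertical surface displacement `u2`.
#' @export
surface_profile <- function(sim, step = NULL) {
  step <- step %||% nrow(sim$surface_profiles)
  tibble(x = sim$surface_x, u2 = sim$surface_profiles[step, ])
}
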