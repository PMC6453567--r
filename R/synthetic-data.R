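# Seeded generators for every input the analysis pipeline consumes. Each is
# a pure function of (parameters, seed) and ships a machine-readable ground
# truth next to the generated artifact, so round-trip tests compare analysis
# output to truth rather than to hard-coded numbers.

#' Generate a radially striped colony transmission image
#'
#' Emulates the transmission image of a wrinkled/delaminated colony: a dark
#' disk on a bright background whose angular intensity is modulated with a
#' locally constant stripe spacing. At radius `r` the stripe count is
#' `N(r) = round(2 pi r / lambda)` (features bifurcate as `r` grows, keeping
#' the spacing within half a stripe of `lambda`); modulation is suppressed
#' where fewer than 3 stripes would fit (the disordered core).
#'
#' @param lambda Intrinsic stripe wavelength (mm). Must be at least 4 px.
#' @param R_f Colony radius (mm).
#' @param size Image side length in pixels.
#' @param pixel_size Pixel size (mm).
#' @param amplitude Modulation amplitude on the [0, 1] intensity scale; 0
#'   produces an unpatterned disk.
#' @param noise_sd Additive Gaussian intensity noise.
#' @param background,disk_level Background and mean disk intensity.
#' @param seed Integer seed.
#' @return A list with `image` (matrix in [0, 1]), and `truth` (list:
#'   `lambda`, `R_f`, `center` in pixel coordinates, `amplitude`,
#'   `noise_sd`, `pixel_size`).
#' @export
gen_radial_pattern_image <- function(lambda, R_f, size = 512L,
                                     pixel_size = 0.025, amplitude = 0.1,
                                     noise_sd = 0, background = 0.8,
                                     disk_level = 0.35, seed = 1L) {
  if (lambda < 4 * pixel_size)
    abort("`lambda` must be at least 4 pixels for the pixel grid.",
          class = "biofilmorph_domain_error")
  ctr <- (size - 1) / 2
  xs <- (0:(size - 1) - ctr) * pixel_size
  X <- matrix(xs, size, size, byrow = TRUE)   # x varies along columns
  Y <- matrix(xs, size, size)                 # y along rows
  R <- sqrt(X^2 + Y^2)
  TH <- atan2(Y, X)
  N <- round(2 * pi * R / lambda)
  mod <- ifelse(R <= R_f & N >= 3, amplitude * cos(N * TH), 0)
  img <- ifelse(R <= R_f, disk_level - mod, background)
  if (noise_sd > 0)
    img <- img + withr::with_seed(seed, matrix(rnorm(size^2, 0, noise_sd),
                                               size, size))
  img <- pmin(pmax(img, 0), 1)
  list(image = img,
       truth = list(lambda = lambda, R_f = R_f, center = c(x = ctr, y = ctr),
                    amplitude = amplitude, noise_sd = noise_sd,
                    pixel_size = pixel_size))
}

#' Generate an expanding colony contour series
#'
#' Emulates colony expansion with a velocity break: the mean radius grows
#' piecewise linearly with slopes `V1` then `V2`, breaking at the critical
#' time `t_c`; after `t_c` the boundary develops a petal modulation
#' `r(theta) = R(t) (1 + a(t) cos(k theta))` with `a` ramping linearly to
#' `a_max` at the final frame.
#'
#' @param times Frame times (hours), increasing.
#' @param R0 Initial radius (mm) at `t = 0`.
#' @param V1,V2 Expansion velocities before/after the break (mm/hr).
#' @param t_c Critical time (hours).
#' @param k Petal count.
#' @param a_max Final petal amplitude (0 keeps the colony circular).
#' @param n_points Boundary points per contour.
#' @param center Colony centre `c(x, y)` (mm).
#' @return A list with `contours` (list of tibbles `x`, `y`), `radii`
#'   (tibble `t`, `R`), and `truth` (list: `t_c`, `V1`, `V2`, `k`, `a_max`,
#'   `R0`, `center`).
#' @export
gen_colony_series <- function(times, R0 = 1, V1 = 0.2, V2 = 0.5, t_c = 40,
                              k = 6L, a_max = 0.15, n_points = 720L,
                              center = c(0, 0)) {
  if (any(diff(times) <= 0)) abort("`times` must be increasing.")
  R_of <- function(t) R0 + V1 * pmin(t, t_c) + V2 * pmax(t - t_c, 0)
  t_end <- max(times)
  a_of <- function(t) if (t_end > t_c)
    a_max * pmax(t - t_c, 0) / (t_end - t_c) else 0 * t
  theta <- 2 * pi * (seq_len(n_points) - 1) / n_points
  contours <- purrr::map(times, function(t) {
    r <- R_of(t) * (1 + a_of(t) * cos(k * theta))
    tibble(x = center[1] + r * cos(theta), y = center[2] + r * sin(theta))
  })
  list(contours = contours,
       radii = tibble(t = times, R = R_of(times)),
       truth = list(t_c = t_c, V1 = V1, V2 = V2, k = k, a_max = a_max,
                    R0 = R0, center = center))
}

#' Rasterise a contour into a binary mask
#'
#' @param contour Tibble `x`, `y` (physical units).
#' @param size Image side (pixels).
#' @param pixel_size Pixel size (same units as the contour).
#' @param origin Physical coordinates of pixel (0, 0).
#' @return Logical matrix: pixels whose centres lie inside the polygon.
#' @export
rasterize_contour <- function(contour, size, pixel_size, origin = NULL) {
  origin <- origin %||% c(-(size - 1) / 2 * pixel_size,
                          -(size - 1) / 2 * pixel_size)
  xs <- origin[1] + (0:(size - 1)) * pixel_size
  ys <- origin[2] + (0:(size - 1)) * pixel_size
  # polar point-in-polygon for star-shaped contours about their centroid
  cx <- mean(contour$x); cy <- mean(contour$y)
  th <- atan2(contour$y - cy, contour$x - cx)
  rr <- sqrt((contour$x - cx)^2 + (contour$y - cy)^2)
  o <- order(th)
  th_s <- th[o]; rr_s <- rr[o]
  th_pad <- c(th_s[length(th_s)] - 2 * pi, th_s, th_s[1] + 2 * pi)
  rr_pad <- c(rr_s[length(rr_s)], rr_s, rr_s[1])
  X <- matrix(xs, size, size, byrow = TRUE)
  Y <- matrix(ys, size, size)
  TH <- atan2(Y - cy, X - cx)
  RD <- sqrt((X - cx)^2 + (Y - cy)^2)
  Rb <- matrix(stats::approx(th_pad, rr_pad, xout = as.numeric(TH))$y,
               size, size)
  RD <= Rb
}

#' Generate a developing blister profile series
#'
#' Emulates side views of a blister over time: a wide low bump that narrows
#' and grows until its half-height width reaches exactly twice the film
#' thickness (walls in contact). Profiles are flat-topped generalised
#' Gaussians `z = H exp(-(|x| / w)^p)` with the wall-steepness exponent `p`
#' rising over the stages and `w` chosen so that the full width at half
#' maximum equals the stage's truth width exactly.
#'
#' @param h_f Film thickness (physical units).
#' @param stages Number of time points (at least 2).
#' @param W0 Initial width (default `8 h_f`).
#' @param H0,H_max Initial and final heights (defaults `0.5 h_f`, `4 h_f`).
#' @param n Samples per profile.
#' @param span Profile half-extent (default `2.5 W0`, leaving flat flanks).
#' @param baseline Baseline offset added to all profiles.
#' @return A list with `profiles` (list of tibbles `x`, `z`) and `truth`
#'   (tibble `stage`, `H`, `W`; `W` decreasing to `2 h_f`, `H` increasing).
#' @export
gen_blister_series <- function(h_f, stages = 5L, W0 = 8 * h_f,
                               H0 = 0.5 * h_f, H_max = 4 * h_f,
                               n = 801L, span = NULL, baseline = 0) {
  if (h_f <= 0) abort("`h_f` must be positive.", class = "biofilmorph_domain_error")
  if (stages < 2) abort("Need at least 2 stages.", class = "biofilmorph_domain_error")
  span <- span %||% (2.5 * W0)
  frac <- (seq_len(stages) - 1) / (stages - 1)
  W <- W0 + frac * (2 * h_f - W0)
  H <- H0 + frac * (H_max - H0)
  p <- 2 + frac * 10
  x <- seq(-span, span, length.out = n)
  profiles <- purrr::map(seq_len(stages), function(s) {
    w <- (W[s] / 2) / (log(2))^(1 / p[s])
    tibble(x = x, z = baseline + H[s] * exp(-(abs(x) / w)^p[s]))
  })
  list(profiles = profiles,
       truth = tibble(stage = seq_len(stages), H = H, W = W))
}

#' Generate a noisy wavelength-versus-stiffness dataset
#'
#' Emulates measured normalised wavelengths over a range of film/substrate
#' stiffness contrasts: the trilayer model is solved at each ratio with
#' `G_r = gr_true * G_f`, and multiplicative log-normal noise
#' `exp(N(0, sigma))` is applied. Ratios where the solver fails are dropped
#' and recorded.
#'
#' @param gr_true True residual-to-film stiffness ratio, in `(0, 1]`.
#' @param ratios Stiffness contrasts `G_f/G_s`.
#' @param noise_sigma Log-normal sigma (0 = noiseless).
#' @param seed Integer seed.
#' @param hr_over_hf Residual thickness ratio (default 0.3).
#' @return A list with `data` (tibble `gf_over_gs`, `lambda_over_hf`),
#'   `dropped` (ratios where the solver failed) and `truth` (list:
#'   `gr_true`, `noise_sigma`, `hr_over_hf`).
#' @export
gen_stiffness_dataset <- function(gr_true, ratios, noise_sigma = 0, seed = 1L,
                                  hr_over_hf = 0.3) {
  if (gr_true <= 0 || gr_true > 1)
    abort("`gr_true` must lie in (0, 1].", class = "biofilmorph_domain_error")
  lam <- vapply(ratios, function(r) {
    tryCatch(solve_wrinkling(stack_from_ratios(r, gr_over_gf = gr_true,
                                               hr_over_hf = hr_over_hf))$lambda_over_hf,
             error = function(e) NA_real_)
  }, 0)
  dropped <- ratios[is.na(lam)]
  keep <- !is.na(lam)
  noise <- if (noise_sigma > 0)
    withr::with_seed(seed, exp(rnorm(sum(keep), 0, noise_sigma))) else 1
  list(data = tibble(gf_over_gs = ratios[keep],
                     lambda_over_hf = lam[keep] * noise),
       dropped = dropped,
       truth = list(gr_true = gr_true, noise_sigma = noise_sigma,
                    hr_over_hf = hr_over_hf))
}
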