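# shoelace signed area of a closed polygon (tibble x, y; last != first)
signed_area <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(sqrt((xn - x)^2 + (yn - y)^2))
}

#' Extract the sub-pixel colony boundary
#'
#' Traces the colony outline as a smooth closed polygon: the binary mask is
#' blurred with a small Gaussian and the 0.5 iso-contour of the blurred field
#' is taken, giving sub-pixel vertices free of pixel staircase artefacts
#' while preserving corners at the blur scale (fixed in pixels).
#'
#' @param mask Logical or 0/1 matrix, a single connected object.
#' @param blur_sigma Gaussian blur standard deviation in pixels (default 1.1).
#' @param pixel_size Physical pixel size; output coordinates are multiplied
#'   by it.
#' @return A tibble with `x`, `y` (closed polygon, last vertex distinct from
#'   the first), ordered counter-clockwise in image coordinates.
#' @export
extract_contour <- function(mask, blur_sigma = 1.1, pixel_size = 1) {
  stopifnot(is.matrix(mask))
  m <- mask * 1
  lab <- EBImage::bwlabel(m)
  ncomp <- max(lab)
  if (ncomp == 0) abort("Mask is empty.", class = "biofilmorph_segmentation_error")
  if (ncomp > 1) abort("Mask is multiply connected (more than one object).",
                       class = "biofilmorph_segmentation_error")
  sm <- EBImage::gblur(m, sigma = blur_sigma)
  # contourLines indexes z[i, j] at (x[i], y[j]); our matrix is [y, x]
  cl <- grDevices::contourLines(x = 0:(nrow(m) - 1), y = 0:(ncol(m) - 1),
                                z = sm, levels = 0.5)
  if (length(cl) == 0) abort("No 0.5 iso-contour found.",
                             class = "biofilmorph_segmentation_error")
  areas <- vapply(cl, function(cc) abs(signed_area(cc$y, cc$x)), 0)
  cc <- cl[[which.max(areas)]]
  x <- cc$y; y <- cc$x  # back to (x = col, y = row) pixel coordinates
  if (length(x) > 1 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  if (signed_area(x, y) < 0) { x <- rev(x); y <- rev(y) }
  tibble(x = x * pixel_size, y = y * pixel_size)
}

#' Resample a closed contour to uniform arc length
#'
#' @param contour Tibble with `x`, `y` (closed polygon, no repeated first
#'   vertex).
#' @param n Number of output points (default 512).
#' @return A tibble with `x`, `y` of `n` points at equal arc-length spacing.
#' @export
resample_contour <- function(contour, n = 512) {
  x <- contour$x; y <- contour$y
  if (length(x) < 3) abort("Contour needs at least 3 points.")
  xc <- c(x, x[1]); yc <- c(y, y[1])
  seg <- sqrt(diff(xc)^2 + diff(yc)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  keep <- c(TRUE, diff(s) > 0)
  si <- seq(0, total, length.out = n + 1)[seq_len(n)]
  tibble(x = stats::approx(s[keep], xc[keep], xout = si)$y,
         y = stats::approx(s[keep], yc[keep], xout = si)$y)
}

# circular Gaussian smoothing of the coordinate sequences
smooth_contour <- function(contour, sigma = 2) {
  if (sigma <= 0) return(contour)
  n <- nrow(contour)
  half <- min(ceiling(3 * sigma), floor((n - 1) / 2))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  circ_filter <- function(v) {
    vp <- c(v[(n - half + 1):n], v, v[1:half])
    stats::filter(vp, k, sides = 2)[(half + 1):(half + n)]
  }
  tibble(x = as.numeric(circ_filter(contour$x)),
         y = as.numeric(circ_filter(contour$y)))
}

#' Contour shape metrics
#'
#' Perimeter `P`, area `A`, acircularity `alpha = P^2 / (4 pi A)` (1 for a
#' perfect circle, larger for petal-shaped outlines) and the mean radius
#' `<R_f>` (mean distance of boundary points from the colony centre).
#'
#' @param contour A closed-polygon tibble (`x`, `y`), e.g. from
#'   [extract_contour()], in physical units.
#' @param center Numeric `c(x, y)`; default is the polygon vertex centroid.
#' @param n Number of uniform arc-length points used for the measurements.
#' @return A one-row tibble: `P`, `A`, `alpha`, `R_f`.
#' @export
contour_metrics <- function(contour, center = NULL, n = 512) {
  rc <- resample_contour(contour, n)
  P <- polygon_perimeter(rc$x, rc$y)
  A <- abs(signed_area(rc$x, rc$y))
  if (A <= 0) abort("Contour encloses no area.")
  ctr <- center %||% c(mean(rc$x), mean(rc$y))
  tibble(P = P, A = A, alpha = P^2 / (4 * pi * A),
         R_f = mean(sqrt((rc$x - ctr[1])^2 + (rc$y - ctr[2])^2)))
}

#' Mask shape metrics
#'
#' Convenience wrapper: extracts the sub-pixel boundary of a mask and
#' computes [contour_metrics()].
#'
#' @inheritParams extract_contour
#' @param center Optional centre `c(x, y)` in physical units.
#' @return A one-row tibble: `P`, `A`, `alpha`, `R_f`.
#' @export
mask_metrics <- function(mask, center = NULL, pixel_size = 1, blur_sigma = 1.1) {
  contour_metrics(extract_contour(mask, blur_sigma, pixel_size), center)
}

#' Two-segment fit of the colony expansion curve
#'
#' The mean colony radius grows linearly until surface instabilities set in,
#' then faster; a continuous two-piece linear regression locates the
#' critical time `t_c` (breakpoint, chosen by grid search over interior
#' sample times minimising the SSE) and the mean expansion velocities before
#' and after it.
#'
#' @param series Data frame with columns `t` and `R` (mean radius), at least
#'   8 rows.
#' @param min_gap Number of samples excluded at each end of the breakpoint
#'   grid (default 2).
#' @return An object of class `expansion_fit`: list with `t_c`, `V_before`,
#'   `V_after`, `sse`, `break_detected`, `series`.
#' @export
expansion_fit <- function(series, min_gap = 2L) {
  d <- dplyr::arrange(as_tibble(series), .data$t)
  if (!all(c("t", "R") %in% names(d))) abort("`series` needs columns t, R.")
  if (nrow(d) < 8) abort("Need at least 8 time points.",
                         class = "biofilmorph_domain_error")
  n <- nrow(d)
  cand <- (1 + min_gap):(n - min_gap)
  fits <- purrr::map(cand, function(i) {
    tc <- d$t[i]
    X <- cbind(1, d$t, pmax(d$t - tc, 0))
    cf <- stats::lm.fit(X, d$R)
    list(tc = tc, sse = sum(cf$residuals^2), coef = cf$coefficients)
  })
  sses <- vapply(fits, `[[`, 0, "sse")
  best <- fits[[which.min(sses)]]
  lin <- stats::lm.fit(cbind(1, d$t), d$R)
  sse1 <- sum(lin$residuals^2)
  at_boundary <- which.min(sses) %in% c(1L, length(cand))
  no_improvement <- best$sse > (1 - 1e-6) * sse1
  break_detected <- !(at_boundary || no_improvement)
  structure(list(
    t_c = if (break_detected) best$tc else NA_real_,
    V_before = unname(best$coef[2]),
    V_after = unname(best$coef[2] + best$coef[3]),
    sse = best$sse, break_detected = break_detected, series = d
  ), class = "expansion_fit")
}

#' @export
print.expansion_fit <- function(x, ...) {
  if (!x$break_detected) cat("<expansion_fit> no break detected\n")
  else cat(sprintf("<expansion_fit> t_c = %g, V = %.4g -> %.4g\n",
                   x$t_c, x$V_before, x$V_after))
  invisible(x)
}

#' @export
tidy.expansion_fit <- function(x, ...) {
  tibble(term = c("t_c", "V_before", "V_after"),
         estimate = c(x$t_c, x$V_before, x$V_after))
}

#' @export
glance.expansion_fit <- function(x, ...) {
  tibble(t_c = x$t_c, V_before = x$V_before, V_after = x$V_after,
         sse = x$sse, break_detected = x$break_detected, n = nrow(x$series))
}

# weighted local quadratic derivatives along a closed resampled contour:
# returns x', x'', y', y'' per point (arc index as parameter)
local_quadratic_derivs <- function(v, window = 9L, sigma_w = 2) {
  n <- length(v)
  half <- (window - 1L) %/% 2L
  if (window > n) abort("Curvature window larger than the contour.",
                        class = "biofilmorph_domain_error")
  s <- (-half):half
  w <- exp(-s^2 / (2 * sigma_w^2))
  X <- cbind(1, s, s^2)
  # weighted least squares projection matrix rows for a1 (first deriv) and a2
  XtW <- t(X * w)
  H <- solve(XtW %*% X, XtW)  # 3 x window
  idx <- outer(seq_len(n), s, function(i, k) ((i + k - 1) %% n) + 1)
  V <- matrix(v[idx], n, window)
  d1 <- V %*% H[2, ]
  d2 <- 2 * (V %*% H[3, ])
  list(d1 = as.numeric(d1), d2 = as.numeric(d2))
}

#' Local contour curvature, normals and expansion velocity
#'
#' Boundary kinematics of an expanding colony: each closed contour is
#' resampled to uniform arc length and smoothed, local quadratic polynomials
#' (Gaussian-weighted window) give analytic first and second derivatives,
#' and the local curvature follows as
#' `kappa = (x' y'' - y' x'') / (x'^2 + y'^2)^{3/2}` with positive sign where
#' the boundary bulges outward. Local velocities connect each point to its
#' nearest neighbour on the later contour: `V = |r(t + dt) - r(t)| / dt`.
#'
#' @param contour_t,contour_t1 Closed-polygon tibbles (`x`, `y`) at times `t`
#'   and `t + dt`.
#' @param dt Time interval (hours).
#' @param n Resampling points (default 512).
#' @param smooth_sigma Gaussian contour smoothing in samples (default 2).
#' @param window,sigma_w Quadratic-fit window size (points) and Gaussian
#'   weight width.
#' @return A tibble of class `contour_kinematics` with `point_id`, `x`, `y`,
#'   `kappa`, `nx`, `ny` (outward normal), `v` (velocity).
#' @export
local_kinematics <- function(contour_t, contour_t1, dt, n = 512,
                             smooth_sigma = 2, window = 9L, sigma_w = 2) {
  if (dt <= 0) abort("`dt` must be positive.")
  c0 <- smooth_contour(resample_contour(contour_t, n), smooth_sigma)
  c1 <- smooth_contour(resample_contour(contour_t1, n), smooth_sigma)
  # orient counter-clockwise so that outward normals and convexity signs agree
  if (signed_area(c0$x, c0$y) < 0) c0 <- c0[rev(seq_len(n)), ]
  if (signed_area(c1$x, c1$y) < 0) c1 <- c1[rev(seq_len(n)), ]
  dx <- local_quadratic_derivs(c0$x, window, sigma_w)
  dy <- local_quadratic_derivs(c0$y, window, sigma_w)
  speed2 <- dx$d1^2 + dy$d1^2
  kappa <- (dx$d1 * dy$d2 - dy$d1 * dx$d2) / speed2^1.5
  sp <- sqrt(speed2)
  nx <- dy$d1 / sp
  ny <- -dx$d1 / sp
  # nearest-neighbour matching to the later contour
  nn <- vapply(seq_len(n), function(i) {
    d2 <- (c1$x - c0$x[i])^2 + (c1$y - c0$y[i])^2
    sqrt(min(d2))
  }, 0)
  out <- tibble(point_id = seq_len(n), x = c0$x, y = c0$y,
                kappa = kappa, nx = nx, ny = ny, v = nn / dt)
  class(out) <- c("contour_kinematics", class(out))
  out
}

#' @export
autoplot.contour_kinematics <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$kappa)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(title = "Boundary curvature", colour = expression(kappa))
}
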