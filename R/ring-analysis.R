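# bilinear interpolation of img at pixel-centred 0-based coordinates
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  if (any(x < 0 | x > nc - 1 | y < 0 | y > nr - 1))
    abort("Sampling circle exits the image bounds.",
          class = "biofilmorph_domain_error")
  j0 <- pmin(floor(x), nc - 2); i0 <- pmin(floor(y), nr - 2)
  fx <- x - j0; fy <- y - i0
  i0 <- i0 + 1; j0 <- j0 + 1  # to 1-based indices
  img[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    img[cbind(i0, j0 + 1)] * fx * (1 - fy) +
    img[cbind(i0 + 1, j0)] * (1 - fx) * fy +
    img[cbind(i0 + 1, j0 + 1)] * fx * fy
}

#' Sample an angular intensity profile on a ring
#'
#' @param img Numeric image matrix.
#' @param center Numeric `c(x, y)` in pixel coordinates.
#' @param r_px Ring radius in pixels.
#' @param M Number of equally spaced angular samples.
#' @return A tibble with `theta` and `intensity`.
#' @export
ring_profile <- function(img, center, r_px, M = 1024) {
  theta <- 2 * pi * (seq_len(M) - 1) / M
  tibble(theta = theta,
         intensity = bilinear_sample(img, center[1] + r_px * cos(theta),
                                     center[2] + r_px * sin(theta)))
}

# circular autocorrelation dominant period (samples); NA when none
autocorr_period <- function(y) {
  M <- length(y)
  y <- y - mean(y)
  ac <- Re(fft(Mod(fft(y))^2, inverse = TRUE)) / M
  ac <- ac / ac[1]
  lags <- 2:floor(M / 2)
  # first local maximum after the zero-lag peak
  for (k in lags) {
    if (k > 2 && ac[k] >= ac[k - 1] && ac[k] >= ac[k + 1] && ac[k] > 0.1)
      return(k - 1)
  }
  NA_real_
}

#' Count periodic features on a ring
#'
#' Counts radial stripes (wrinkles or blisters) crossing a circle of radius
#' `r` by Fourier analysis of the angular intensity profile: the feature
#' count `N` is the dominant FFT harmonic of the detrended profile, searched
#' from harmonic 3 upward (lower harmonics reflect centring/ellipticity, not
#' stripes). The count is cross-checked against the dominant circular
#' autocorrelation period; a disagreement of more than one harmonic flags
#' the sample.
#'
#' @param img Numeric image matrix (normalised or raw; the count is
#'   invariant under affine intensity rescaling).
#' @param center `c(x, y)` centre in pixel coordinates.
#' @param r Ring radius, in physical units if `pixel_size` is given.
#' @param M Angular samples (must be at least 8x the expected count).
#' @param pixel_size Physical size of one pixel (default 1 = `r` in pixels).
#' @param power_floor Dominant-harmonic power must exceed `power_floor` times
#'   the median harmonic power, otherwise the ring is flagged as having no
#'   periodic signal.
#' @return A list with `N` (count, `NA` when flagged), `flagged`, `reason`,
#'   `N_autocorr`.
#' @export
count_ring_features <- function(img, center, r, M = 1024, pixel_size = 1,
                                power_floor = 20) {
  prof <- ring_profile(img, center, r / pixel_size, M)
  y <- prof$intensity - mean(prof$intensity)
  if (sd(y) < 1e-9 * max(abs(prof$intensity), 1))
    return(list(N = NA_integer_, flagged = TRUE, reason = "no periodic signal",
                N_autocorr = NA_real_))
  p <- Mod(fft(y))^2
  harmonics <- 3:floor(M / 2)
  pw <- p[harmonics + 1]
  best <- which.max(pw)
  if (pw[best] < power_floor * median(pw))
    return(list(N = NA_integer_, flagged = TRUE, reason = "no periodic signal",
                N_autocorr = NA_real_))
  N <- harmonics[best]
  per <- autocorr_period(y)
  N_ac <- if (is.na(per)) NA_real_ else M / per
  flagged <- !is.na(N_ac) && abs(N - N_ac) > 1
  list(N = N, flagged = flagged,
       reason = if (flagged) "FFT/autocorrelation mismatch" else NA_character_,
       N_autocorr = N_ac)
}

#' Fit the intrinsic pattern wavelength
#'
#' The stripe count grows linearly with radius, `N(r) = 2 pi r / lambda`,
#' because stripes bifurcate to maintain constant spacing; pooling counts
#' from all frames and fitting the line through the origin gives the
#' intrinsic wavelength: `lambda = 2 pi sum(r N) / sum(N^2)`. The innermost
#' patterned radius per frame (`R_p`, where `N` drops to zero towards the
#' disordered core) is reported alongside.
#'
#' @param samples Data frame with columns `r` (radius, physical units), `t`
#'   (frame time), `N` (count; `NA` or zero = no pattern at that radius), and
#'   optionally `flagged` (flagged rows are excluded from the fit).
#' @return An object of class `wavelength_fit`: list with `lambda`, `sse`,
#'   `n_used`, `pattern` (FALSE when no positive counts exist), `R_p`
#'   (tibble per frame), `samples`.
#' @export
fit_wavelength <- function(samples) {
  d <- as_tibble(samples)
  if (!all(c("r", "N") %in% names(d))) abort("`samples` needs columns r, N.")
  if (!"t" %in% names(d)) d$t <- NA_real_
  if (!"flagged" %in% names(d)) d$flagged <- FALSE
  valid <- dplyr::filter(d, !.data$flagged, !is.na(.data$N))
  use <- dplyr::filter(valid, .data$N > 0)
  if (nrow(use) == 0)
    return(structure(list(lambda = NA_real_, sse = NA_real_, n_used = 0L,
                          pattern = FALSE, R_p = tibble(), samples = d),
                     class = "wavelength_fit"))
  if (nrow(valid) < 5 || length(unique(valid$r)) < 2)
    abort("Need at least 5 samples spanning at least 2 radii.",
          class = "biofilmorph_domain_error")
  lambda <- 2 * pi * sum(use$r * use$N) / sum(use$N^2)
  sse <- sum((use$N - 2 * pi * use$r / lambda)^2)
  rp <- d |>
    dplyr::group_by(.data$t) |>
    dplyr::group_modify(function(g, key) {
      zero <- g$r[!is.na(g$N) & g$N == 0]
      pos <- g$r[!is.na(g$N) & g$N > 0]
      rp <- if (length(pos) == 0) NA_real_
            else {
              inner_zero <- zero[zero < max(pos)]
              if (length(inner_zero)) max(inner_zero) else NA_real_
            }
      tibble(R_p = rp)
    }) |>
    dplyr::ungroup()
  structure(list(lambda = lambda, sse = sse, n_used = nrow(use),
                 pattern = TRUE, R_p = rp, samples = d),
            class = "wavelength_fit")
}

#' @export
print.wavelength_fit <- function(x, ...) {
  if (!x$pattern) cat("<wavelength_fit> no pattern\n")
  else cat(sprintf("<wavelength_fit> lambda = %.4g (n = %d, SSE = %.3g)\n",
                   x$lambda, x$n_used, x$sse))
  invisible(x)
}

#' @export
tidy.wavelength_fit <- function(x, ...) {
  tibble(term = "lambda", estimate = x$lambda)
}

#' @export
glance.wavelength_fit <- function(x, ...) {
  tibble(lambda = x$lambda, sse = x$sse, n_used = x$n_used, pattern = x$pattern)
}

# topographic prominence of local maxima on a circular profile
peak_prominences_circular <- function(y) {
  M <- length(y)
  at <- function(i) y[((i - 1) %% M) + 1]
  is_peak <- vapply(seq_len(M), function(i)
    at(i) > at(i - 1) && at(i) >= at(i + 1), TRUE)
  peaks <- which(is_peak)
  prom <- vapply(peaks, function(p) {
    h <- at(p)
    base <- function(dir) {
      lowest <- h
      for (s in 1:(M - 1)) {
        v <- at(p + dir * s)
        if (v > h) break
        if (v < lowest) lowest <- v
      }
      lowest
    }
    h - max(base(-1L), base(1L))
  }, 0)
  tibble(index = peaks, height = y[peaks], prominence = prom)
}

#' Peaks of the edge intensity profile
#'
#' Extracts the angular intensity profile on a circle near the colony edge
#' and locates the dips (dark features) as peaks of the negated profile,
#' treating the profile as periodic. Peaks with topographic prominence below
#' `min_prominence` are rejected as noise.
#'
#' @param img Numeric image matrix (normalised intensities).
#' @param center `c(x, y)` in pixel coordinates.
#' @param radius Circle radius (physical units given `pixel_size`); a common
#'   choice is 0.9x the mean colony radius.
#' @param M Angular samples.
#' @param min_prominence Minimum peak prominence (default 0.02, on the
#'   normalised intensity scale).
#' @param pixel_size Physical pixel size.
#' @return A tibble with `theta`, `height` (of `-I`), `prominence` for each
#'   accepted peak.
#' @export
edge_amplitude_peaks <- function(img, center, radius, M = 1024,
                                 min_prominence = 0.02, pixel_size = 1) {
  prof <- ring_profile(img, center, radius / pixel_size, M)
  pk <- peak_prominences_circular(-prof$intensity)
  pk <- dplyr::filter(pk, .data$prominence >= min_prominence)
  tibble(theta = prof$theta[pk$index], height = pk$height,
         prominence = pk$prominence)
}
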