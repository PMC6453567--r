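#' Blister height and width from a side-view profile
#'
#' A delaminated blister seen from the side is a single bump on a flat
#' baseline. The baseline is the mean height over the outer flank regions
#' (by default the outermost 10% of samples on each side), the height `H` is
#' the peak elevation above it, and the width `W` is measured at half
#' height, with sub-sample linear interpolation of the two crossings.
#'
#' @param profile Data frame with columns `x` and `z` (side-view height
#'   samples, covering the full blister with flat flanks on both sides).
#' @param flank_fraction Fraction of samples on each side used for the
#'   baseline (default 0.1).
#' @return A one-row tibble: `H`, `W`, `baseline`, `x_peak`.
#' @examples
#' x <- seq(-5, 5, length.out = 201)
#' blister_metrics(data.frame(x = x, z = exp(-x^2 / 2)))
#' @export
blister_metrics <- function(profile, flank_fraction = 0.1) {
  d <- dplyr::arrange(as_tibble(profile), .data$x)
  if (!all(c("x", "z") %in% names(d))) abort("`profile` needs columns x, z.")
  n <- nrow(d)
  k <- max(2L, floor(flank_fraction * n))
  baseline <- mean(c(d$z[1:k], d$z[(n - k + 1):n]))
  ipk <- which.max(d$z)
  if (ipk <= k || ipk > n - k)
    abort("No interior peak: profile is monotone or the blister is clipped.",
          class = "biofilmorph_domain_error")
  H <- d$z[ipk] - baseline
  if (H <= 0) abort("Peak does not rise above the baseline.",
                    class = "biofilmorph_domain_error")
  level <- baseline + H / 2
  cross_at <- function(i) {
    # linear interpolation between samples i and i+1
    d$x[i] + (level - d$z[i]) * (d$x[i + 1] - d$x[i]) / (d$z[i + 1] - d$z[i])
  }
  above <- d$z >= level
  left <- max(which(!above[1:(ipk - 1)]))
  right <- ipk - 1 + min(which(!above[ipk:n])) - 1
  x_left <- cross_at(left)
  x_right <- cross_at(right)
  tibble(H = H, W = x_right - x_left, baseline = baseline, x_peak = d$x[ipk])
}

#' Predicted sequence of interface events from the energy hierarchy
#'
#' Blister development creates and destroys interfaces, and the order of
#' events follows the interfacial energy hierarchy: delamination happens
#' first when the film-substrate adhesion `Gamma` is the smallest energy
#' (immediately, skipping wrinkling, when it is zero); a costly film-liquid
#' interface under the blister (`gamma_fl > gamma_fa`) drives the blister
#' walls into internal contact, after which neighbouring blisters merge to
#' shed film-air interface; the opposite hierarchy (`gamma_fa > gamma_fl`,
#' the matrix-mutant regime) favours lateral collapse of neighbouring
#' blisters instead.
#'
#' @param energies An [interfacial_energies()] object.
#' @return A tibble with columns `order`, `event`, `driver`; tied energies
#'   list the co-favoured events at the same rank.
#' @examples
#' interface_hierarchy(interfacial_energies(5, 49, 30))
#' @export
interface_hierarchy <- function(energies) {
  stopifnot(inherits(energies, "interfacial_energy_set"))
  G <- energies$Gamma; fl <- energies$gamma_fl; fa <- energies$gamma_fa
  if (G == fl && fl == fa) {
    return(tibble(order = c(1L, 1L, 1L),
                  event = c("delaminate", "internal_contact", "merge_peaks"),
                  driver = "tie: all interfacial energies equal"))
  }
  events <- list()
  if (G == 0) {
    events <- c(events, list(list(
      event = "delaminate_immediately",
      driver = "adhesion below detection limit: blisters skip the wrinkling state")))
  } else {
    events <- c(events, list(list(
      event = "delaminate",
      driver = sprintf("adhesion Gamma = %g is the smallest energy", G))))
  }
  if (fl > fa) {
    events <- c(events, list(
      list(event = "internal_contact",
           driver = sprintf("film-liquid interface costly (gamma_fl = %g > gamma_fa = %g)", fl, fa)),
      list(event = "merge_peaks",
           driver = "merging eliminates film-air interface")))
  } else if (fa > fl) {
    events <- c(events, list(
      list(event = "lateral_collapse",
           driver = sprintf("film-air interface costly (gamma_fa = %g > gamma_fl = %g)", fa, fl))))
  } else {
    events <- c(events, list(
      list(event = "internal_contact", driver = "tie: gamma_fl = gamma_fa"),
      list(event = "lateral_collapse", driver = "tie: gamma_fl = gamma_fa")))
  }
  tibble(order = seq_along(events),
         event = vapply(events, `[[`, "", "event"),
         driver = vapply(events, `[[`, "", "driver"))
}
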