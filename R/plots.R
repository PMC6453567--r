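#' @export
autoplot.wavelength_fit <- function(object, ...) {
  d <- dplyr::filter(object$samples, !is.na(.data$N))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$N)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$flagged)) +
    ggplot2::labs(x = "radius", y = "feature count N",
                  title = "Stripe count vs radius")
  if (object$pattern)
    p <- p + ggplot2::geom_abline(slope = 2 * pi / object$lambda, intercept = 0,
                                  colour = "red")
  p
}

#' @export
autoplot.expansion_fit <- function(object, ...) {
  d <- object$series
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$R)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (hr)", y = "mean radius",
                  title = "Colony expansion")
  if (object$break_detected)
    p <- p + ggplot2::geom_vline(xintercept = object$t_c, linetype = "dashed")
  p
}

#' Plot a blister side-view profile with its measured metrics
#'
#' @param profile Data frame with `x`, `z`.
#' @param metrics Optional result of [blister_metrics()]; computed if absent.
#' @return A ggplot object.
#' @export
plot_blister_profile <- function(profile, metrics = NULL) {
  metrics <- metrics %||% blister_metrics(profile)
  ggplot2::ggplot(as_tibble(profile), ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = metrics$baseline, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = metrics$baseline + metrics$H / 2,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "x", y = "z",
                  title = sprintf("Blister profile: H = %.3g, W = %.3g",
                                  metrics$H, metrics$W))
}
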