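#' @export
autoplot.cross_correlation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_s, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70", linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (s): positive = subject follows actor",
                  y = "normalized cross-correlation c(τ)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.entrainment_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$center_s, y = .data$com)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::labs(x = "time (s)",
                  y = "windowed entrainment CoM (s)\n> 0: actor leads, < 0: subject leads") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.motion_spectrum <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$power))
  if ("person" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$person))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::labs(x = "frequency (Hz)", y = "power") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dyad_energy <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("subject", "actor"),
                              names_to = "person", values_to = "energy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$energy,
                                     colour = .data$person)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "kinetic energy (px²/frame²)") +
    ggplot2::theme_minimal()
}

#' Feature-space view of the fitted classifier
#'
#' Plots the cohort in the (synchrony, entrainment) plane, coloured by
#' scenario label, with the P = 0.5 decision line `b*x + c*y = -log(a)`
#' and optional probability contours.
#'
#' @param model a fitted `dyad_classifier`.
#' @param contours probability levels to draw besides 0.5.
#' @return A ggplot object.
#' @export
plot_classifier <- function(model, contours = c(0.3, 0.7)) {
  stopifnot(inherits(model, "dyad_classifier"))
  df <- model$data
  # b*x + c*y = -log(a) + logit offset for each contour level
  iso_y <- function(x, level) {
    off <- log(level / (1 - level))
    (-log(model$a) - off - model$b * x) / model$c
  }
  xr <- range(df$x)
  grid <- tibble(x = seq(xr[1], xr[2], length.out = 50))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label)) +
    ggplot2::geom_line(data = dplyr::mutate(grid, y = iso_y(.data$x, 0.5)),
                       linetype = 2) +
    ggplot2::labs(x = "synchrony x = c(0)", y = "entrainment y = CoM (s)") +
    ggplot2::theme_minimal()
  for (lv in contours) {
    p <- p + ggplot2::geom_line(data = dplyr::mutate(grid, y = iso_y(.data$x, lv)),
                                linetype = 3, colour = "grey50")
  }
  p
}

#' @importFrom rlang .data
NULL
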