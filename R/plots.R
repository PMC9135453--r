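#' Plot a trajectory
#'
#' `type = "displacement"`: unwrapped x-displacement of each mobile
#' filament versus time (the gliding-assay readout).
#' `type = "solver"`: per-step constraint counts and BBPGD iterations.
#'
#' @param object An `fm_trajectory`.
#' @param type Panel selector.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fm_trajectory <- function(object, type = c("displacement",
                                                    "solver"), ...) {
  type <- match.arg(type)
  if (type == "displacement") {
    td <- tidy(object)
    td <- td[td$id %in% object$filaments$id[object$filaments$mobile], ]
    d0 <- td[td$time == min(td$time), c("id", "xu")]
    names(d0)[2] <- "x0"
    td <- dplyr::left_join(td, d0, by = "id")
    ggplot2::ggplot(td, ggplot2::aes(x = .data$time,
                                     y = .data$xu - .data$x0,
                                     group = .data$id)) +
      ggplot2::geom_line(alpha = 0.6) +
      ggplot2::labs(x = "time (s)", y = "x displacement (um)")
  } else {
    lg <- tidyr::pivot_longer(
      object$log[, c("time", "n_unilateral", "n_bilateral", "iterations")],
      -"time")
    ggplot2::ggplot(lg, ggplot2::aes(x = .data$time, y = .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~name, scales = "free_y") +
      ggplot2::labs(x = "time (s)", y = NULL)
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a radial distribution function
#'
#' @param rdf Tibble from [rdf_minus_ends()].
#' @param peaks Optional tibble from [rdf_peaks()] to mark.
#' @return A ggplot object.
#' @export
plot_rdf <- function(rdf, peaks = NULL) {
  p <- ggplot2::ggplot(rdf, ggplot2::aes(x = .data$r * 1000, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "r (nm)", y = "g(r)")
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = peaks$r * 1000,
                                 linetype = 3, colour = "red")
  }
  p
}

#' Plot straining-velocity samples against local polarity
#'
#' @param samples Tibble from [plane_straining_velocity()].
#' @return A ggplot object.
#' @export
plot_straining_velocity <- function(samples) {
  ggplot2::ggplot(samples, ggplot2::aes(x = .data$px_mean,
                                        y = .data$vx * 1000)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "local polarity Px", y = "Vx (nm/s)")
}

#' Plot collision and crosslinker pressure over time
#'
#' @param series Tibble from [stress_series()].
#' @return A ggplot object.
#' @export
plot_pressure <- function(series) {
  d <- tidyr::pivot_longer(series[, c("time", "pressure_col", "pressure_xl")],
                           -"time", names_prefix = "pressure_")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  colour = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "pressure (pN/um^2)",
                  colour = "constraints")
}
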