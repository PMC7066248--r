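#' Plot a simulated trajectory
#'
#' `autoplot()` renders either the population time series (prey in blue,
#' predator in red, time in months on the x axis) or the phase portrait
#' (prey density on x, predator density on y; closed loops indicate neutral
#' cycling).
#'
#' @param object An `mp_trajectory`.
#' @param kind `"time_series"` or `"phase_portrait"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mp_trajectory
#' @export
autoplot.mp_trajectory <- function(object,
                                   kind = c("time_series", "phase_portrait"),
                                   ...) {
  kind <- match.arg(kind)
  if (kind == "time_series") {
    long <- tidyr::pivot_longer(
      as_tibble(as.data.frame(object)[c("t", "x1", "x2")]),
      cols = c("x1", "x2"), names_to = "series", values_to = "density"
    )
    ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$density,
                                       colour = .data$series)) +
      ggplot2::geom_line(linewidth = 0.4) +
      ggplot2::scale_colour_manual(
        values = c(x1 = "blue", x2 = "red"),
        labels = c(x1 = "prey", x2 = "predator"), name = NULL
      ) +
      ggplot2::labs(x = "time (months)", y = "density (No./m^3)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(as_tibble(as.data.frame(object)),
                    ggplot2::aes(x = .data$x1, y = .data$x2)) +
      ggplot2::geom_path(linewidth = 0.4, colour = "grey30") +
      ggplot2::labs(x = "prey density (No./m^3)",
                    y = "predator density (No./m^3)") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Save a trajectory plot to file
#'
#' @inheritParams autoplot.mp_trajectory
#' @param traj An `mp_trajectory`.
#' @param path Output image path (format inferred from the extension).
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
plot_run <- function(traj, kind = c("time_series", "phase_portrait"), path,
                     width = 6, height = 4, dpi = 150) {
  p <- autoplot(traj, kind = kind)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}
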