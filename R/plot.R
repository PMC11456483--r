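# ggplot2 displays of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.condition_colors <- c(
  none = "grey50", S1 = "#D55E00", S2 = "#0072B2", S1S2 = "#009E73",
  S1S2_A1 = "#E69F00", S1S2_A2 = "#56B4E9",
  A1_only = "#CC79A7", A2_only = "#999999"
)

#' Plot population firing-rate time courses
#'
#' @param object A `trace_set`.
#' @param populations Labels to show (default `"1L5E"`).
#' @param window Optional time window, ms.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trace_set <- function(object, populations = "1L5E", window = NULL,
                               ...) {
  df <- tidy(object) |> filter(.data$population %in% populations)
  if (!is.null(window)) {
    df <- filter(df, .data$time_ms >= window[1], .data$time_ms <= window[2])
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms / 1000, .data$rate_hz)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~population, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "firing rate (Hz)",
                  title = paste("condition", object$condition)) +
    ggplot2::theme_minimal()
}

#' Compare oscillation envelopes across stimulus conditions
#'
#' Overlays the upper and lower envelopes of one population's firing rate
#' for each condition, the display used to read off the ordered pattern.
#'
#' @param traces Named list of `trace_set` objects.
#' @param population Population label.
#' @param window Time window, ms (default the final second).
#' @return A ggplot.
#' @export
plot_envelopes <- function(traces, population = "1L5E", window = NULL) {
  df <- purrr::imap_dfr(traces, function(tr, cc) {
    mutate(envelope(tr, population, window), condition = cc)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms / 1000,
                                   color = .data$condition)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower)) +
    ggplot2::scale_color_manual(values = .condition_colors) +
    ggplot2::labs(x = "time (s)", y = "firing rate (Hz)",
                  title = paste("envelopes of", population)) +
    ggplot2::theme_minimal()
}

#' Plot an amplitude spectrum
#'
#' @param object A `spectral_summary`.
#' @param ... Unused.
#' @return A ggplot with the 25 Hz beta/gamma boundary dashed.
#' @export
autoplot.spectral_summary <- function(object, ...) {
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(.data$freq_hz, .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 25, linetype = "dashed") +
    ggplot2::geom_point(data = object$peaks, color = "red") +
    ggplot2::labs(x = "frequency (Hz)", y = "amplitude",
                  title = paste(object$population, "under", object$condition)) +
    ggplot2::theme_minimal()
}

#' Plot a regime map over the heterogeneity plane
#'
#' @param object A `regime_map` from [sweep_plane()].
#' @param ... Unused.
#' @return A ggplot tile map colored by regime.
#' @export
autoplot.regime_map <- function(object, ...) {
  pal <- c(blue = "#4477AA", green = "#66BB66", red = "#CC4444",
           yellow = "#EEDD66", other = "grey80", failed = "black")
  ggplot2::ggplot(object, ggplot2::aes(.data$delta_e, .data$delta_i,
                                       fill = .data$region_color)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_point(data = filter(object, .data$concurrent %in% TRUE),
                        shape = 17, size = 2) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::labs(x = expression(Delta["back,E"]),
                  y = expression(Delta["back,I"]),
                  fill = "regime",
                  caption = "triangles: concurrent case") +
    ggplot2::theme_minimal()
}
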