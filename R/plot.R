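# ggplot2 helpers for the main result types (ggplot2 is in Suggests; the
# analysis itself never needs it).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("install ggplot2 to use the plotting helpers", call. = FALSE)
}

#' Plot the degradation series of one track
#'
#' Local (`L`), pre-birth (`P`) and corrected (`C`) differences over time,
#' with the smoothed corrected curve overlaid.
#'
#' @param series A [degradation_series()] object.
#' @param frame_interval_min Minutes per frame (for the time axis).
#' @return A ggplot object.
#' @export
plot_degradation_series <- function(series, frame_interval_min = 5) {
  need_ggplot()
  df <- series$data
  df$time_min <- (df$frame - df$frame[1]) * frame_interval_min
  long <- tibble::tibble(
    time_min = rep(df$time_min, 3),
    value = c(df$L, df$P, df$C),
    component = rep(c("local (L)", "pre-birth (P)", "corrected (C)"),
                    each = nrow(df)))
  sm <- tibble::tibble(time_min = df$time_min,
                       value = smooth_series(df$C))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = sm, ggplot2::aes(.data$time_min, .data$value),
                       inherit.aes = FALSE, linewidth = 1) +
    ggplot2::labs(x = "time since track start (min)",
                  y = "ECM fluorescence difference",
                  title = sprintf("track %d", series$track_id)) +
    ggplot2::theme_minimal()
}

#' Plot per-cell degradation percentages
#'
#' Overall percentage against maximum per-frame percentage, colored by
#' degrader status, with cutoff lines when supplied.
#'
#' @param per_cell The `per_cell` tibble from [analyze_population()].
#' @param cutoffs Optional `degrader_cutoffs`.
#' @return A ggplot object.
#' @export
plot_population_degradation <- function(per_cell, cutoffs = NULL) {
  need_ggplot()
  p <- ggplot2::ggplot(per_cell,
                       ggplot2::aes(.data$D_tot, .data$max_D_t,
                                    colour = .data$is_degrader)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "overall degradation (%)",
                  y = "max per-frame degradation (%)") +
    ggplot2::theme_minimal()
  if (!is.null(cutoffs))
    p <- p + ggplot2::geom_vline(xintercept = cutoffs$c_tot, linetype = 2) +
      ggplot2::geom_hline(yintercept = cutoffs$c_frame, linetype = 2)
  p
}
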