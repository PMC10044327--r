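#' Plot estimated vs measured wrench channels
#'
#' Overlays the measured wrench (blue) and the estimate (yellow) per
#' channel, faceted with forces above moments.
#'
#' @param measured,estimated Wrench tibbles with `time` and `Fx` .. `Mz`.
#' @param channels Channels to show (default all six).
#' @return A ggplot object.
#' @export
plot_wrench_comparison <- function(measured, estimated,
                                   channels = wrench_channels()) {
  long <- function(df, which) {
    df |>
      dplyr::select(dplyr::all_of(c("time", channels))) |>
      tidyr::pivot_longer(-"time", names_to = "channel",
                          values_to = "value") |>
      dplyr::mutate(series = which)
  }
  dat <- dplyr::bind_rows(long(measured, "measured"),
                          long(estimated, "estimated")) |>
    dplyr::mutate(channel = factor(.data$channel, levels = wrench_channels()))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$value,
                                    colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 3) +
    ggplot2::scale_colour_manual(
      values = c(measured = "#2166ac", estimated = "#e6b800")
    ) +
    ggplot2::labs(x = "Time [s]", y = "Force [N] / Moment [Nm]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_grf_lstm Training / validation loss curves.
#' @param object A `grf_lstm`.
#' @export
autoplot.grf_lstm <- function(object, ...) {
  dat <- object$log |>
    tidyr::pivot_longer(-"epoch", names_to = "series", values_to = "loss")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                    colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Epoch", y = "MSE (standardized targets)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_wrench Bar chart of per-axis percent RMSE.
#' @param object A `grf_eval`.
#' @export
autoplot.grf_eval <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(.data$axis, levels = wrench_channels()),
    y = .data$pct_rmse, fill = .data$group
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% RMSE", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
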