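#' Plot a colony trajectory
#'
#' Stage composition of the colony over time, one panel per tracked
#' generation, with the bust hour marked when the patch is exhausted within
#' the horizon.
#'
#' @param object A `colony_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.colony_trajectory <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$count > 0 | df$time_hr == 0, ]
  b <- detect_bust(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_hr, y = .data$count,
                                        fill = .data$stage)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::facet_wrap(~generation, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "hours since founding", y = "expected worms",
                  fill = "stage",
                  title = paste0(object$founder_number, " founder(s)")) +
    ggplot2::theme_minimal()
  if (!is.na(b$bust_hr)) {
    p <- p + ggplot2::geom_vline(xintercept = b$bust_hr, linetype = "dashed")
  }
  p
}

#' Plot population structure at one hour
#'
#' @param object A [structure_at()] summary.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.structure_summary <- function(object, ...) {
  df <- object[object$count > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$generation),
                                   y = .data$count, fill = .data$stage)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "generation", y = "expected worms",
                  title = paste0("population structure at hour ",
                                 attr(object, "hour"))) +
    ggplot2::theme_minimal()
}

#' Plot a dauer yield time course
#'
#' Mean plus/minus one standard deviation per post-bust timepoint, with the
#' peak highlighted.
#'
#' @param object A [yield_timecourse()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.yield_timecourse <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint_hr, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_peak), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "hours post bust", y = "dauer yield") +
    ggplot2::theme_minimal()
}

#' Plot the speed-versus-yield trade-off
#'
#' Mean time to bust against mean dauer yield, labelled by founder number.
#'
#' @param object A [tradeoff_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tradeoff_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_bust_hr,
                                   y = .data$mean_yield)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$founder_number),
                       vjust = -0.8) +
    ggplot2::labs(x = "mean time to bust (hr; left = faster)",
                  y = "mean dauer yield") +
    ggplot2::theme_minimal()
}
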