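# ggplot2 displays for the main result types.

#' Plot an INP spectrum
#'
#' Cumulative INP concentration per mL of well suspension against
#' temperature, log scale, censored points (all wells frozen) hollow.
#'
#' @param object An `inp_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot inp_spectrum
#' @export
autoplot.inp_spectrum <- function(object, ...) {
  df <- object %>% filter(.data$f_frozen > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temp_c,
                                   y = .data$c_inp_per_ml_suspension,
                                   shape = .data$censored)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Temperature (°C)",
                  y = expression(INP~mL^-1~suspension)) +
    ggplot2::theme_minimal()
}

#' Plot per-sample Shannon diversity
#'
#' @param object A `diversity_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diversity_result
#' @export
autoplot.diversity_result <- function(object, ...) {
  ggplot2::ggplot(object$shannon,
                  ggplot2::aes(x = .data$sample_id, y = .data$shannon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Shannon-Wiener H'") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Boxplot of percent G/C by detection group
#'
#' @param gc_table Output of [gc_detection_groups()].
#' @return A ggplot.
#' @export
plot_gc_groups <- function(gc_table) {
  ggplot2::ggplot(gc_table, ggplot2::aes(x = .data$group, y = .data$gc_percent)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "% G/C base content") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-event sea-time and loading fractions
#'
#' @param events The `$events` tibble of [event_summary()].
#' @return A ggplot.
#' @export
plot_event_fractions <- function(events) {
  long <- events %>%
    select("event", "sea_percent", "loading_percent") %>%
    tidyr::pivot_longer(-"event", names_to = "metric", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$event, y = .data$percent,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of trajectory points") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
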