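#' Plot an annual carbon budget
#'
#' Horizontal bar chart of budget rows, emissions and sinks side by side,
#' with the carbon credit in the subtitle.
#'
#' @param object a `carbon_budget`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @examples
#' autoplot(as_carbon_budget(reported_budget_2014()))
autoplot.carbon_budget <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$value,
    y = stats::reorder(.data$row, .data$value),
    fill = .data$column)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$column), scales = "free") +
    ggplot2::labs(
      x = "tC / yr", y = NULL, fill = NULL,
      title = "Annual island carbon budget",
      subtitle = sprintf(
        "emission %.0f, sink %.0f, carbon credit %.0f tC/yr",
        attr(object, "total_emission"), attr(object, "total_sink"),
        attr(object, "carbon_credit"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot stock trajectories
#'
#' Time series of the seven carbon stocks, one facet per stock (free y
#' scales: stocks span several orders of magnitude).
#'
#' @param object an `island_trajectory`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @examples
#' autoplot(run_model(config_calibrated()))
autoplot.island_trajectory <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(.data$type == "stock")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$name), scales = "free_y") +
    ggplot2::labs(x = "time (yr)", y = "stock (tC)",
                  title = "Carbon stock trajectories",
                  subtitle = object$config$name) +
    ggplot2::theme_minimal()
}
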