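#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the distribution of cost savings
#'
#' Horizontal bars for the savings components (staff time, PPE, gross,
#' program equipment cost, net), labelled in dollars.
#'
#' @param object A `cvm_cost_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @examples
#' autoplot(compute_cost_report(fixture_ledger_2020(), default_config()))
#' @export
autoplot.cvm_cost_report <- function(object, ...) {
  comp <- report_components(object)
  comp$component <- factor(comp$component, rev(comp$component))
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$dollars, y = .data$component)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = fmt_dollars(.data$cents)),
                       hjust = -0.05, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.18))) +
    ggplot2::labs(x = "US dollars", y = NULL,
                  title = "Distribution of cost savings") +
    ggplot2::theme_minimal()
}

#' Plot a one-way sweep
#'
#' Net savings (and ROI, as a secondary panel via colour) against the
#' swept parameter value.
#'
#' @param object A `cvm_sweep` tibble from [one_way_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cvm_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$net_savings)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$parameter[[1]], y = "Net savings (USD)",
                  title = "One-way sensitivity sweep") +
    ggplot2::theme_minimal()
}

#' Plot a daily call ledger
#'
#' Averted calls per calendar day, with escalations overlaid when
#' present.
#'
#' @param object A ledger tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_ledger <- function(object, ...) {
  daily <- dplyr::summarise(object,
                            calls_averted = sum(.data$calls_averted),
                            escalations = sum(.data$escalations),
                            .by = "date")
  p <- ggplot2::ggplot(daily, ggplot2::aes(x = .data$date, y = .data$calls_averted)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Averted calls per day",
                  title = "Daily averted in-person interactions") +
    ggplot2::theme_minimal()
  if (any(daily$escalations > 0)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$escalations),
                                colour = "firebrick")
  }
  p
}
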