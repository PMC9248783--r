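#' Plot melting curves
#'
#' Line plot of -dF/dT against temperature, one line per sample,
#' coloured by label when present.
#'
#' @param curves Curves tibble (`sample_id`, `temperature`, `dneg`).
#' @param value Curve column (default `"dneg"`).
#' @return A ggplot object.
#' @export
plot_melt_curves <- function(curves, value = "dneg") {
  colour <- if ("label" %in% names(curves)) "label" else "sample_id"
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$temperature, y = .data[[value]],
    group = .data$sample_id, colour = .data[[colour]])) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Temperature (°C)",
                  y = expression(-dF / dT ~ "(RFU/°C)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot difference curves
#'
#' The HRM difference plot: each curve's deviation from the reference
#' mean against temperature.
#'
#' @param diffs Difference tibble (`sample_id`, `temperature`,
#'   `delta`).
#' @return A ggplot object.
#' @export
plot_difference_curves <- function(diffs) {
  colour <- if ("label" %in% names(diffs)) "label" else "sample_id"
  ggplot2::ggplot(diffs, ggplot2::aes(
    x = .data$temperature, y = .data$delta,
    group = .data$sample_id, colour = .data[[colour]])) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3,
                        colour = "grey60") +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Temperature (°C)",
                  y = "Mean - curve (RFU/°C)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot hrm_library
#' @export
autoplot.hrm_library <- function(object, ...) {
  plot_melt_curves(mutate(object$curves, label = .data$sample_id),
                   value = object$value) +
    ggplot2::labs(title = "Reference library mean melting curves")
}

#' @method autoplot hrm_clusters
#' @export
autoplot.hrm_clusters <- function(object, ...) {
  dd <- left_join(object$diffs, object$assignments, by = "sample_id") |>
    mutate(group = factor(.data$group))
  ggplot2::ggplot(dd, ggplot2::aes(
    x = .data$temperature, y = .data[[object$value]],
    group = .data$sample_id, colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Temperature (°C)", y = object$value,
                  colour = "group",
                  title = paste0(object$n_groups, " melt group(s), cut = ",
                                 signif(object$cut, 3))) +
    ggplot2::theme_minimal()
}

#' @method autoplot hrm_assignments
#' @export
autoplot.hrm_assignments <- function(object, ...) {
  counts <- dplyr::count(as_tibble(object), .data$status, .data$best_label) |>
    mutate(best_label = ifelse(is.na(.data$best_label), "(none)",
                               .data$best_label))
  ggplot2::ggplot(counts, ggplot2::aes(
    x = .data$best_label, y = .data$n, fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "best label", y = "samples", fill = "status") +
    ggplot2::theme_minimal()
}
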