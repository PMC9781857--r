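#' Plot per-animal fGNG by group and timepoint
#'
#' Column-plus-jitter display of the cohort: group means as bars, animals as
#' points, split pre/post intervention — the standard presentation for a
#' small factorial tracer cohort. Values are shown in percent.
#'
#' @param results The `results` tibble of an `fgng_report` (or any data
#'   frame with `feeding`, `injury`, `timepoint`, `fgng`).
#' @return A ggplot object.
#' @export
plot_fgng_groups <- function(results) {
  results <- as_tibble(results)
  results$cell <- interaction(results$feeding, results$injury, sep = "-")
  means <- results |>
    group_by(.data$timepoint, .data$cell) |>
    summarise(fgng = mean(.data$fgng), .groups = "drop")
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$cell, y = 100 * .data$fgng,
                               fill = .data$cell)) +
    ggplot2::geom_col(data = means, width = 0.7, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 1.6) +
    ggplot2::facet_wrap(~timepoint) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "fractional gluconeogenesis (%)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_fgng_groups
#' @param object An `fgng_report`.
#' @param ... Unused.
#' @export
autoplot.fgng_report <- function(object, ...) {
  plot_fgng_groups(object$results)
}

#' Plot the feeding-state classification bands
#'
#' Shows where a set of fGNG values falls relative to the dietary-adequacy
#' bands: fed 0-15%, indeterminate 15-40%, unfed above 40%, with the
#' overfed warning sub-band at 0-10%.
#'
#' @param fgng Numeric vector of fGNG fractions.
#' @return A ggplot object.
#' @export
plot_feeding_bands <- function(fgng) {
  cls <- classify_feeding_state(fgng)
  bands <- tibble(
    state = factor(c("fed", "indeterminate", "unfed"),
                   levels = c("fed", "indeterminate", "unfed")),
    lo = c(0, 15, 40), hi = c(15, 40, 100))
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = bands,
                       ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                    ymin = 0, ymax = 1,
                                    fill = .data$state), alpha = 0.25) +
    ggplot2::geom_vline(xintercept = 10, linetype = 3) +
    ggplot2::geom_point(data = cls,
                        ggplot2::aes(x = 100 * .data$fgng, y = 0.5)) +
    ggplot2::scale_x_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "fractional gluconeogenesis (%)", y = NULL,
                  fill = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
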