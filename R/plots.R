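#' Forest plot of summary effects against equivalence bounds
#'
#' Summary SMDs with their 95% (thin) and 90% TOST (thick) intervals over
#' shaded equivalence regions, one shade per SESOI bound; the visual test of
#' equivalence is the thick interval sitting inside a shaded band.
#'
#' @param audit A `meta_audit`.
#' @return A ggplot object.
#' @export
plot_equivalence <- function(audit) {
  stopifnot(inherits(audit, "meta_audit"))
  eq1 <- audit$equivalence |>
    dplyr::filter(.data$bound == min(.data$bound)) |>
    dplyr::arrange(.data$smd) |>
    dplyr::mutate(meta_id = factor(.data$meta_id, levels = .data$meta_id))
  bands <- tibble::tibble(bound = sort(unique(audit$equivalence$bound),
                                       decreasing = TRUE))
  ggplot2::ggplot(eq1, ggplot2::aes(x = .data$smd, y = .data$meta_id)) +
    ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = -.data$bound, xmax = .data$bound,
                   alpha = factor(.data$bound)),
      ymin = -Inf, ymax = Inf, fill = "steelblue", inherit.aes = FALSE) +
    ggplot2::scale_alpha_manual(
      values = seq(0.15, 0.45, length.out = nrow(bands)),
      name = "SESOI bound",
      labels = rev(sprintf("%.2g", sort(bands$bound)))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_nhst_low, xmax = .data$ci_nhst_high),
      height = 0, linewidth = 0.4) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_tost_low, xmax = .data$ci_tost_high),
      height = 0, linewidth = 1.2) +
    ggplot2::geom_point(shape = 18, size = 2.5) +
    ggplot2::labs(x = "Summary standardized mean difference",
                  y = NULL,
                  title = "Summary effects with 95% and 90% TOST intervals")
}

#' Power-grid heatmap per meta-analysis
#'
#' Median constituent-study power for each meta-analysis across the assumed
#' true effect grid — the "firepower" display.
#'
#' @param audit A `meta_audit`.
#' @return A ggplot object.
#' @export
plot_power_grid <- function(audit) {
  stopifnot(inherits(audit, "meta_audit"))
  df <- audit$power |>
    dplyr::filter(.data$ref == "grid") |>
    dplyr::summarise(median_power = stats::median(.data$power),
                     .by = c("meta_id", "delta_star"))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$delta_star),
                                   y = .data$meta_id,
                                   fill = .data$median_power)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "Median power") +
    ggplot2::labs(x = "Assumed true effect size",
                  y = NULL, title = "Median study power per meta-analysis")
}

#' Power-by-year heatmap
#'
#' Median study power per publication year across the assumed true effect
#' grid.
#'
#' @param audit A `meta_audit`.
#' @return A ggplot object.
#' @export
plot_trend <- function(audit) {
  stopifnot(inherits(audit, "meta_audit"))
  df <- dplyr::filter(audit$trend, .data$ref == "grid")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$year),
                                   y = factor(.data$delta_star),
                                   fill = .data$median_power)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "Median power") +
    ggplot2::labs(x = "Publication year", y = "Assumed true effect size",
                  title = "Study power over time")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for audit objects
#'
#' @param object A `meta_audit`.
#' @param type One of `"equivalence"` (forest with bounds), `"power_grid"`,
#'   `"trend"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_audit <- function(object, type = c("equivalence", "power_grid",
                                                 "trend"), ...) {
  switch(match.arg(type),
         equivalence = plot_equivalence(object),
         power_grid = plot_power_grid(object),
         trend = plot_trend(object))
}
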