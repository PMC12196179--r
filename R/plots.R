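#' Plot a fitted dose-response curve
#'
#' Replicate viabilities with the fitted 4PL curve on a log10 concentration
#' axis; the fitted IC50 is marked.
#'
#' @param object a [fit_4pl()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  rng <- range(object$data$concentration)
  grid <- tibble::tibble(
    concentration = 10^seq(log10(rng[1]), log10(rng[2]), length.out = 200)
  )
  grid$viability <- predict(object, grid$concentration)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$concentration, .data$viability)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "concentration (µg/mL)", y = "viability (%)",
      title = sprintf("4PL fit: IC50 = %.3g µg/mL", object$ic50)
    ) +
    ggplot2::theme_minimal()
}

#' Annexin V / PI quadrant scatter plot
#'
#' @param events data frame with `annexin` and `pi` (log10 intensities).
#' @param annexin_gate,pi_gate gating thresholds.
#' @param max_points subsample cap for plotting (default 10000).
#' @return a ggplot object.
#' @export
plot_quadrants <- function(events, annexin_gate, pi_gate, max_points = 10000) {
  if (nrow(events) > max_points) {
    events <- events[sample.int(nrow(events), max_points), , drop = FALSE]
  }
  ggplot2::ggplot(events, ggplot2::aes(.data$annexin, .data$pi)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_vline(xintercept = annexin_gate, color = "red3") +
    ggplot2::geom_hline(yintercept = pi_gate, color = "red3") +
    ggplot2::labs(
      x = "Annexin V-FITC (log10 intensity)",
      y = "PI (log10 intensity)"
    ) +
    ggplot2::theme_minimal()
}

#' Enrichment bubble plot
#'
#' Gene-ratio versus term, sized by hit count and colored by adjusted
#' p-value, faceted by annotation category — the usual over-representation
#' display.
#'
#' @param result an [enrich()] result tibble.
#' @param top terms per category to show (default 10, by adjusted p).
#' @return a ggplot object.
#' @export
plot_enrichment <- function(result, top = 10) {
  shown <- result |>
    dplyr::group_by(.data$category) |>
    dplyr::slice_min(.data$p_adj, n = top, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot2::ggplot(
    shown,
    ggplot2::aes(.data$gene_ratio, stats::reorder(.data$term, -.data$p_adj))
  ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$k, color = .data$p_adj)) +
    ggplot2::scale_color_gradient(low = "red3", high = "blue3") +
    ggplot2::facet_wrap(ggplot2::vars(.data$category), scales = "free_y") +
    ggplot2::labs(x = "gene ratio (k/K)", y = NULL, size = "hits", color = "adj. p") +
    ggplot2::theme_minimal()
}

#' Docking-score heatmap
#'
#' @param scores long-format docking scores (`compound`, `target`, `score`).
#' @return a ggplot object.
#' @export
plot_docking_heatmap <- function(scores) {
  scores <- validate_docking_long(scores)
  ggplot2::ggplot(scores, ggplot2::aes(.data$target, .data$compound)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$score)) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$score)), size = 2.6) +
    ggplot2::scale_fill_gradient(
      low = "firebrick", high = "lightyellow",
      name = "kcal/mol"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Centrality distribution plot with hub thresholds
#'
#' @param table a [centralities()] tibble.
#' @param thresholds optional named list (`bc_min`, `cc_min`, `dc_min`) to
#'   mark, e.g. from [tier2_screen()].
#' @return a ggplot object.
#' @export
plot_centralities <- function(table, thresholds = NULL) {
  long <- tidyr::pivot_longer(table, c("dc", "bc", "cc"),
    names_to = "metric", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free") +
    ggplot2::labs(x = NULL, y = "nodes") +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    vl <- tibble::tibble(
      metric = c("bc", "cc", "dc"),
      value = c(thresholds$bc_min, thresholds$cc_min, thresholds$dc_min)
    )
    p <- p + ggplot2::geom_vline(
      data = vl, ggplot2::aes(xintercept = .data$value),
      linetype = "dashed", color = "red3"
    )
  }
  p
}
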