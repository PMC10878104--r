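# ggplot2 helpers for the main result types.

#' Heatmap of per-species accuracy by database
#'
#' @param accuracy An `accuracy_tbl` from [score_accuracy()].
#' @return A ggplot: species x database tiles filled by accuracy, faceted
#'   by region and method.
#' @export
plot_accuracy <- function(accuracy) {
  ggplot(accuracy, aes(x = .data$database, y = .data$species,
                       fill = .data$accuracy)) +
    geom_tile() +
    facet_grid(~ .data$region + .data$method) +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "accuracy") +
    theme_minimal()
}

#' Stacked-bar community profiles
#'
#' @param profiles Long profile tibble (`sample_id`, `species`,
#'   `abundance`, optionally `region` for faceting).
#' @return A ggplot of stacked relative abundances per sample.
#' @export
plot_profile <- function(profiles) {
  p <- ggplot(profiles, aes(x = .data$sample_id, y = .data$abundance,
                            fill = .data$species)) +
    geom_col() +
    labs(x = NULL, y = "relative abundance", fill = NULL) +
    theme_minimal()
  if ("region" %in% names(profiles)) p <- p + facet_wrap(~ .data$region)
  p
}

#' @describeIn pcoa Scatter of the first two principal coordinates.
#' @param object An `amplibench_pcoa`.
#' @export
autoplot.amplibench_pcoa <- function(object, ...) {
  co <- object$coordinates
  if (ncol(co) < 3) co$Axis2 <- 0
  pe <- round(100 * object$proportion_explained, 1)
  ggplot(co, aes(x = .data$Axis1, y = .data$Axis2)) +
    geom_point() +
    labs(x = paste0("Axis 1 (", pe[1], "%)"),
         y = paste0("Axis 2 (", ifelse(length(pe) > 1, pe[2], 0), "%)")) +
    theme_minimal()
}

#' @describeIn run_evaluation Mean accuracy per pipeline, bars by database.
#' @param object An `evaluation_result`.
#' @export
autoplot.evaluation_result <- function(object, ...) {
  ggplot(object$summary,
         aes(x = .data$database, y = .data$mean_accuracy,
             fill = .data$database)) +
    geom_col() +
    facet_grid(.data$subset ~ .data$region + .data$method) +
    labs(x = NULL, y = "mean species accuracy") +
    theme_minimal()
}
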