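#' Plot the fitness trajectory of a masking run
#'
#' @param object A `masking_result`.
#' @param ... Unused.
#' @return A ggplot of per-generation best fitness.
#' @export
autoplot.masking_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$generation, y = .data$best_fitness)) +
    ggplot2::geom_step(colour = "#2c7fb8") +
    ggplot2::labs(x = "Generation", y = "Best fitness",
                  title = sprintf("Gene masking (%s), best fitness %.4f, %d genes retained",
                                  toupper(object$provenance$classifier),
                                  object$best$fitness, object$best$retained)) +
    ggplot2::theme_minimal()
}

#' Plot the shrinkage profile of a shrunken-centroid model
#'
#' Shows how many genes survive shrinkage as the threshold delta grows — the
#' curve is non-increasing and hits zero beyond `max(|d_ik|)`.
#'
#' @param object A `shrunken_centroid_model`.
#' @param deltas Delta grid; defaults to 50 points from 0 to just past
#'   `max(|d_ik|)`.
#' @param ... Unused.
#' @return A ggplot of surviving-gene count against delta.
#' @export
autoplot.shrunken_centroid_model <- function(object, deltas = NULL, ...) {
  if (is.null(deltas)) {
    deltas <- seq(0, max(abs(object$d_ik)) * 1.05, length.out = 50L)
  }
  delta_sweep(object, deltas) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$delta, y = .data$n_surviving)) +
    ggplot2::geom_step(colour = "#d95f02") +
    ggplot2::labs(x = expression(Delta), y = "Genes surviving shrinkage") +
    ggplot2::theme_minimal()
}

#' Plot a gene-occurrence report
#'
#' @param report Tibble from [occurrence_report()].
#' @param top_n Show at most this many genes (default 25).
#' @return A ggplot bar chart of per-gene occurrence across qualifying runs.
#' @export
plot_occurrence <- function(report, top_n = 25L) {
  report |>
    dplyr::slice_head(n = top_n) |>
    dplyr::mutate(gene_id = stats::reorder(.data$gene_id, .data$occurrence)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$occurrence, y = .data$gene_id)) +
    ggplot2::geom_col(fill = "#1b9e77") +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Occurrence among qualifying runs", y = NULL) +
    ggplot2::theme_minimal()
}
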