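#' Tidy a masking result into its fitness trajectory
#'
#' @param x A `masking_result` from [evolve()] or [shrink_then_mask()].
#' @param ... Unused.
#' @return Tibble with columns `generation` and `best_fitness`.
#' @export
tidy.masking_result <- function(x, ...) {
  tibble::tibble(generation = seq_along(x$history), best_fitness = x$history)
}

#' One-row summary of a masking result
#'
#' @param x A `masking_result`.
#' @param ... Unused.
#' @return Tibble with the best mask's fitness, accuracy and gene counts.
#' @export
glance.masking_result <- function(x, ...) {
  tibble::tibble(
    fitness = x$best$fitness,
    cv_accuracy = x$best$cv_accuracy,
    retained = x$best$retained,
    eliminated = x$best$eliminated,
    generations = length(x$history),
    best_generation = x$provenance$best_generation,
    classifier = x$provenance$classifier,
    alpha = x$provenance$config$alpha,
    seed = x$provenance$seed
  )
}

#' Tidy a shrunken-centroid model into per-gene statistics
#'
#' @param x A `shrunken_centroid_model`.
#' @param ... Unused.
#' @return Long tibble with one row per gene and class: the raw and shrunken
#'   standardized distances, centroids, pooled SD, and a `survives` flag.
#' @export
tidy.shrunken_centroid_model <- function(x, ...) {
  surv <- logical(length(x$gene_ids))
  surv[surviving_genes(x)] <- TRUE
  tibble::tibble(
    gene_id = rep(x$gene_ids, times = length(x$class_set)),
    class = rep(x$class_set, each = length(x$gene_ids)),
    centroid = as.vector(x$centroids),
    d = as.vector(x$d_ik),
    d_shrunk = as.vector(x$d_shrunk),
    shrunken_centroid = as.vector(x$shrunken_centroids),
    s_i = rep(unname(x$s_i), times = length(x$class_set)),
    survives = rep(surv, times = length(x$class_set))
  )
}

#' One-row summary of a shrunken-centroid model
#'
#' @param x A `shrunken_centroid_model`.
#' @param ... Unused.
#' @return Tibble with `delta`, `s0`, gene counts and class count.
#' @export
glance.shrunken_centroid_model <- function(x, ...) {
  tibble::tibble(
    delta = x$delta,
    s0 = x$s0,
    n_genes = length(x$gene_ids),
    n_surviving = length(surviving_genes(x)),
    n_classes = length(x$class_set)
  )
}

#' Tidy a tuning report
#'
#' @param x A `tuning_report` from [grid_search()].
#' @param ... Unused.
#' @return The per-cell summary tibble (selection order: best cell first).
#' @export
tidy.tuning_report <- function(x, ...) x$cells

#' One-row summary of a tuning report (the selected cell)
#'
#' @param x A `tuning_report`.
#' @param ... Unused.
#' @return One-row tibble: the winning `{alpha, cr, mr}` and its summaries.
#' @export
glance.tuning_report <- function(x, ...) x$selected
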