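#' Fit a nearest-centroid classifier
#'
#' Computes the per-class centroid of every gene (the class mean profile) and
#' the overall centroid across all samples. Prediction assigns a sample to
#' the class whose centroid is nearest in Euclidean distance.
#'
#' @param data An [expression_dataset()] in which every class has at least one
#'   sample.
#' @return An object of class `centroid_model`: list with `centroids`
#'   (genes x classes matrix), `overall_centroid`, `class_set`, `gene_ids`,
#'   `n_k` (per-class sample counts) and `n`.
#' @examples
#' ds <- simulate_expression(synthetic_spec(seed = 1))
#' fit <- fit_centroids(ds$data)
#' table(predict(fit, ds$data), ds$data$labels)
#' @export
fit_centroids <- function(data) {
  stopifnot(inherits(data, "expression_dataset"))
  classes <- data$class_set
  n_k <- as.integer(table(data$labels)[classes])
  if (any(n_k == 0L)) stop("every class needs >= 1 sample", call. = FALSE)
  cents <- vapply(classes, function(k) {
    rowMeans(data$values[, data$labels == k, drop = FALSE])
  }, numeric(n_genes(data)))
  cents <- matrix(cents, nrow = n_genes(data),
                  dimnames = list(data$gene_ids, classes))
  structure(
    list(centroids = cents,
         overall_centroid = rowMeans(data$values),
         class_set = classes, gene_ids = data$gene_ids,
         n_k = stats::setNames(n_k, classes), n = n_samples(data)),
    class = "centroid_model"
  )
}

#' @export
print.centroid_model <- function(x, ...) {
  cat(sprintf("<%s> %d genes, classes: %s\n", class(x)[1L],
              length(x$gene_ids), paste(x$class_set, collapse = ", ")))
  if (inherits(x, "shrunken_centroid_model")) {
    cat(sprintf("  delta = %g, surviving genes: %d / %d\n", x$delta,
                length(surviving_genes(x)), length(x$gene_ids)))
  }
  invisible(x)
}

# Nearest-centroid argmin over a set of centroids; ties go to the
# lowest class index (class_set is sorted, so this is deterministic).
nearest_class <- function(centroids, x, class_set) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  # argmin_k ||x - c_k||^2 = argmax_k (2 x.c_k - ||c_k||^2); ||x||^2 constant
  cross <- crossprod(x, centroids)              # samples x classes
  sq <- colSums(centroids^2)
  scores <- sweep(2 * cross, 2L, sq, `-`)
  idx <- max.col(scores, ties.method = "first")
  factor(class_set[idx], levels = class_set)
}

#' Predict classes with a nearest-centroid model
#'
#' @param object A `centroid_model` from [fit_centroids()].
#' @param newdata An [expression_dataset()], or a numeric matrix / vector with
#'   genes in rows matching the model's gene order.
#' @param ... Unused.
#' @return Factor of predicted classes (levels = the model's `class_set`).
#' @export
predict.centroid_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "expression_dataset")) newdata$values else newdata
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (nrow(x) != length(object$gene_ids)) {
    stop(sprintf("sample has %d genes but the model expects %d",
                 nrow(x), length(object$gene_ids)), call. = FALSE)
  }
  nearest_class(object$centroids, x, object$class_set)
}

#' Classification accuracy
#'
#' Proportion of exact matches between predicted and true class labels.
#'
#' @param predicted,truth Equal-length class vectors (factor or character).
#' @return Fraction in \[0, 1\].
#' @export
classification_accuracy <- function(predicted, truth) {
  if (length(predicted) == 0L || length(predicted) != length(truth)) {
    stop("predicted and truth must be non-empty and of equal length",
         call. = FALSE)
  }
  mean(as.character(predicted) == as.character(truth))
}
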