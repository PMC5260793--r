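#' Construct an expression dataset
#'
#' Bundles a genes-by-samples expression matrix with per-sample class labels.
#' This is the container every classifier and masking function in the package
#' operates on. Values are unitless (assumed preprocessed/normalised upstream);
#' classes are ordered lexicographically so that centroid column `k` always
#' refers to the same class across fits and serialised models.
#'
#' @param values Numeric matrix, genes in rows and samples in columns. Row
#'   names are used as gene identifiers (generated as `g1..gd` when absent);
#'   column names as sample identifiers.
#' @param labels Character or factor vector of per-sample class labels, one
#'   per column of `values`.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (the matrix), `gene_ids`, `sample_ids`, `labels` (factor) and
#'   `class_set` (sorted distinct classes, the factor levels).
#'
#' @examples
#' x <- matrix(rnorm(20), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' ds <- expression_dataset(x, c("A", "A", "B", "B"))
#' n_genes(ds)
#' n_samples(ds)
#' @export
expression_dataset <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (length(labels) != ncol(values)) {
    stop(sprintf("dimension mismatch: %d matrix columns but %d labels",
                 ncol(values), length(labels)), call. = FALSE)
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stop("expression values must all be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop(sprintf("duplicated gene identifier(s): %s",
                 paste(head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  sample_ids <- colnames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  class_set <- sort(unique(labels))
  labels <- factor(labels, levels = class_set)
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         labels = labels, class_set = class_set),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples, %d classes (%s)\n",
              n_genes(x), n_samples(x), length(x$class_set),
              paste(x$class_set, collapse = ", ")))
  invisible(x)
}

#' Number of genes / samples in an expression dataset
#'
#' @param data An [expression_dataset()].
#' @return Integer count.
#' @export
n_genes <- function(data) nrow(data$values)

#' @rdname n_genes
#' @export
n_samples <- function(data) ncol(data$values)

#' Subset an expression dataset by sample index
#'
#' Keeps all genes; used internally for cross-validation folds.
#'
#' @param data An [expression_dataset()].
#' @param idx Integer vector of sample (column) indices.
#' @return An `expression_dataset` with the selected samples.
#' @keywords internal
#' @export
subset_samples <- function(data, idx) {
  expression_dataset(data$values[, idx, drop = FALSE],
                     as.character(data$labels[idx]))
}

#' Construct a gene mask
#'
#' A gene mask is a binary chromosome over the gene dimension: bit 1 keeps the
#' corresponding gene, bit 0 removes it from the dataset before a classifier
#' is trained.
#'
#' @param bits Vector coercible to integer containing only 0s and 1s.
#' @return Integer vector of class `gene_mask`.
#' @examples
#' m <- gene_mask(c(1, 0, 0, 1, 1))
#' mask_eliminated(m)  # 2 genes dropped
#' @export
gene_mask <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) == 0L) stop("mask must have length >= 1", call. = FALSE)
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("mask bits must all be 0 or 1", call. = FALSE)
  }
  structure(bits, class = "gene_mask")
}

#' Mask bit counts
#'
#' `mask_eliminated()` counts zero bits (genes removed); `mask_retained()`
#' counts one bits (genes kept).
#'
#' @param mask A [gene_mask()] or plain 0/1 vector.
#' @return Integer count.
#' @export
mask_eliminated <- function(mask) sum(as.integer(mask) == 0L)

#' @rdname mask_eliminated
#' @export
mask_retained <- function(mask) sum(as.integer(mask) == 1L)

#' @export
print.gene_mask <- function(x, ...) {
  cat(sprintf("<gene_mask> length %d, %d retained / %d eliminated\n",
              length(x), mask_retained(x), mask_eliminated(x)))
  cat(paste(as.integer(x), collapse = ""), "\n")
  invisible(x)
}

#' Apply a gene mask to a dataset
#'
#' Returns the dataset restricted to the genes whose mask bit is 1, in the
#' original gene order. Samples and labels are unchanged. An all-zero mask
#' yields a degenerate 0-gene dataset (still carrying all samples); downstream
#' fitness evaluation assigns such masks zero accuracy.
#'
#' @param data An [expression_dataset()].
#' @param mask A [gene_mask()] (or 0/1 vector) of length `n_genes(data)`.
#' @return An `expression_dataset` with `mask_retained(mask)` genes.
#' @examples
#' x <- matrix(1:10, nrow = 5,
#'             dimnames = list(paste0("f", 1:5), c("s1", "s2")))
#' ds <- expression_dataset(x, c("A", "B"))
#' apply_mask(ds, gene_mask(c(1, 0, 0, 1, 1)))$gene_ids  # f1 f4 f5
#' @export
apply_mask <- function(data, mask) {
  mask <- as.integer(mask)
  if (length(mask) != n_genes(data)) {
    stop(sprintf("mask length %d does not match gene dimension %d",
                 length(mask), n_genes(data)), call. = FALSE)
  }
  if (!all(mask %in% c(0L, 1L))) stop("mask bits must be 0/1", call. = FALSE)
  keep <- mask == 1L
  out <- data
  out$values <- data$values[keep, , drop = FALSE]
  out$gene_ids <- data$gene_ids[keep]
  out
}
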