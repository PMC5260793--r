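#' Stratified k-fold partition
#'
#' Splits sample indices into k disjoint folds, stratified by class: each
#' class's samples are shuffled and dealt across folds so per-class
#' proportions are approximately preserved and overall fold sizes differ by at
#' most one. Deterministic given `seed` (the global RNG state is untouched).
#'
#' @param labels Per-sample class labels.
#' @param k Number of folds (>= 2). Every class must have at least `k`
#'   samples, otherwise some training split could lose a class entirely.
#' @param seed RNG seed for the within-class shuffles.
#' @return List of `k` integer index vectors (disjoint, union = all samples).
#' @export
kfold_partition <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  tab <- table(labels)
  if (any(tab < k)) {
    small <- names(tab)[tab < k]
    stop(sprintf("class(es) %s have fewer than k = %d samples; use a smaller k",
                 paste(small, collapse = ", "), k), call. = FALSE)
  }
  folds <- vector("list", k)
  sizes <- integer(k)
  withr::with_seed(as.integer(seed), {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      base <- length(idx) %/% k
      rem <- length(idx) %% k
      # extras go to the currently smallest folds, keeping overall sizes
      # within one of each other; ties by fold index for determinism
      extra_folds <- order(sizes, seq_len(k))[seq_len(rem)]
      counts <- rep(base, k)
      counts[extra_folds] <- counts[extra_folds] + 1L
      pos <- 0L
      for (f in seq_len(k)) {
        if (counts[f] > 0L) {
          folds[[f]] <- c(folds[[f]], idx[pos + seq_len(counts[f])])
          pos <- pos + counts[f]
        }
      }
      sizes <- sizes + counts
    }
  })
  lapply(folds, sort)
}

#' Genetic-algorithm configuration for gene masking
#'
#' Collects every tunable of a gene-masking run. The defaults are the
#' standard configuration for this method: population 105, 50000 generations,
#' roulette-wheel selection, crossover rate 0.85, mutation rate 0.10, one
#' elite individual, and 5-fold cross-validation. `alpha` is the accuracy-to-
#' elimination ratio weighting cross-validated accuracy against the fraction
#' of genes eliminated in the fitness
#' \deqn{F = \alpha \cdot \mathrm{accuracy} + (1-\alpha) \cdot
#'       \mathrm{eliminated}/d.}
#'
#' @param population_size Number of chromosomes per generation.
#' @param generations Number of generations to evolve.
#' @param crossover_rate Probability that a selected pair is recombined by
#'   one-point crossover (otherwise the parents are cloned).
#' @param mutation_rate Mutation rate; its meaning depends on
#'   `mutation_mode`.
#' @param mutation_mode `"per_individual"` (default): with probability
#'   `mutation_rate` an offspring has exactly one uniformly chosen bit
#'   flipped. `"per_bit"`: every bit flips independently with probability
#'   `mutation_rate` (a literal reading that is highly disruptive for long
#'   chromosomes). The chosen mode is recorded in run provenance.
#' @param num_elite Number of best chromosomes copied unchanged into the next
#'   generation (must be < `population_size`).
#' @param alpha Accuracy-to-elimination ratio in (0, 1].
#' @param folds Cross-validation folds k (default 5).
#' @param classifier `"ncc"` (nearest centroid) or `"nscc"` (nearest shrunken
#'   centroid with shrinkage `delta`, refit inside every training fold).
#' @param delta Shrinkage amount used when `classifier = "nscc"`.
#' @param init_prob Probability that an initial-population bit is 1.
#' @param seed RNG seed for the evolutionary search.
#' @param cv_seed Seed for the stratified CV partition; defaults to
#'   `seed + 1`. The partition is drawn once per run, independently of the GA
#'   stream, and reused for every mask so fitness comparisons are noise-free.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 105L, generations = 50000L,
                      crossover_rate = 0.85, mutation_rate = 0.10,
                      mutation_mode = c("per_individual", "per_bit"),
                      num_elite = 1L, alpha = 0.9, folds = 5L,
                      classifier = c("ncc", "nscc"), delta = 0,
                      init_prob = 0.5, seed = 1L, cv_seed = NULL) {
  mutation_mode <- match.arg(mutation_mode)
  classifier <- match.arg(classifier)
  stopifnot(population_size >= 2, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            num_elite >= 0, alpha > 0, alpha <= 1, folds >= 2,
            delta >= 0, init_prob > 0, init_prob <= 1)
  if (num_elite >= population_size) {
    stop("num_elite must be smaller than population_size", call. = FALSE)
  }
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         mutation_mode = mutation_mode, num_elite = as.integer(num_elite),
         alpha = alpha, folds = as.integer(folds), classifier = classifier,
         delta = delta, init_prob = init_prob, seed = as.integer(seed),
         cv_seed = if (is.null(cv_seed)) as.integer(seed) + 1L
                   else as.integer(cv_seed)),
    class = "ga_config"
  )
}

# Per-fold sufficient statistics for the compiled CV evaluator: class sums
# and sums of squares of the training split plus the held-out matrix.
build_cv_precomp <- function(data, folds) {
  classes <- data$class_set
  K <- length(classes)
  lab_int <- as.integer(data$labels)
  all_idx <- seq_len(n_samples(data))
  lapply(folds, function(test_idx) {
    train_idx <- setdiff(all_idx, test_idx)
    xt <- data$values[, train_idx, drop = FALSE]
    lt <- lab_int[train_idx]
    sums <- matrix(0, nrow = n_genes(data), ncol = K)
    ssq <- matrix(0, nrow = n_genes(data), ncol = K)
    counts <- integer(K)
    for (k in seq_len(K)) {
      sel <- lt == k
      counts[k] <- sum(sel)
      if (counts[k] > 0L) {
        xk <- xt[, sel, drop = FALSE]
        sums[, k] <- rowSums(xk)
        ssq[, k] <- rowSums(xk * xk)
      }
    }
    if (any(counts == 0L)) {
      stop("a training split lost a class entirely; use stratified folds",
           call. = FALSE)
    }
    list(sums = sums, ssq = ssq, counts = counts,
         x_test = data$values[, test_idx, drop = FALSE],
         y_test = lab_int[test_idx])
  })
}

# Batch CV accuracy for a population of masks via the compiled evaluator.
cv_accuracy_batch <- function(masks, precomp, config) {
  cls <- if (config$classifier == "nscc") 1L else 0L
  cpp_cv_accuracy(masks, precomp, cls, config$delta)
}

#' Cross-validated accuracy of a masked dataset
#'
#' Applies the mask, then for each stratified fold fits the configured
#' classifier on the remaining k-1 folds and scores the held-out fold; the
#' unweighted mean of the k fold accuracies is returned. An all-zero mask
#' scores 0 (no features, no classifier), as does any fold whose shrunken
#' model retains no genes.
#'
#' @param data An [expression_dataset()].
#' @param mask A [gene_mask()] of length `n_genes(data)`.
#' @param config A [ga_config()]; `folds`, `cv_seed`, `classifier` and
#'   `delta` are used.
#' @return Mean fold accuracy in \[0, 1\].
#' @export
cv_accuracy <- function(data, mask, config = ga_config()) {
  mask <- as.integer(mask)
  if (length(mask) != n_genes(data)) {
    stop("mask length must equal the gene dimension", call. = FALSE)
  }
  if (sum(mask) == 0L) return(0)
  folds <- kfold_partition(data$labels, config$folds, config$cv_seed)
  masked <- apply_mask(data, mask)
  all_idx <- seq_len(n_samples(data))
  accs <- vapply(folds, function(test_idx) {
    train <- subset_samples(masked, setdiff(all_idx, test_idx))
    x_test <- masked$values[, test_idx, drop = FALSE]
    truth <- as.character(masked$labels[test_idx])
    if (config$classifier == "nscc") {
      fit <- fit_shrunken_centroids(train, delta = config$delta)
      if (length(surviving_genes(fit)) == 0L) return(0)
      classification_accuracy(predict(fit, x_test), truth)
    } else {
      classification_accuracy(predict(fit_centroids(train), x_test), truth)
    }
  }, numeric(1L))
  mean(accs)
}

#' Weighted fitness of a gene mask
#'
#' The fitness driving the genetic search is the weighted sum of
#' cross-validated accuracy and the eliminated-gene fraction:
#' `fitness = alpha * accuracy + (1 - alpha) * eliminated / total`.
#'
#' @inheritParams cv_accuracy
#' @return A `fitness_record`: list with `mask`, `cv_accuracy`, `eliminated`,
#'   `retained` and `fitness`.
#' @examples
#' # accuracy 0.95, alpha 0.9, 15 of 20 genes eliminated -> 0.930
#' 0.9 * 0.95 + (1 - 0.9) * 15 / 20
#' @export
mask_fitness <- function(data, mask, config = ga_config()) {
  acc <- cv_accuracy(data, mask, config)
  new_fitness_record(mask, acc, length(mask), config$alpha)
}

new_fitness_record <- function(mask, acc, d, alpha) {
  mask <- gene_mask(mask)
  elim <- mask_eliminated(mask)
  structure(
    list(mask = mask, cv_accuracy = acc, eliminated = elim,
         retained = d - elim,
         fitness = alpha * acc + (1 - alpha) * elim / d),
    class = "fitness_record"
  )
}

#' @export
print.fitness_record <- function(x, ...) {
  cat(sprintf(
    "<fitness_record> fitness %.4f (cv accuracy %.4f, eliminated %d/%d)\n",
    x$fitness, x$cv_accuracy, x$eliminated, x$eliminated + x$retained))
  invisible(x)
}
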