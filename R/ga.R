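#' Roulette-wheel selection
#'
#' Draws population indices with probability proportional to fitness. When
#' every fitness is zero the draw falls back to uniform so a selection always
#' exists. Uses the current RNG state.
#'
#' @param fitness Non-negative fitness vector.
#' @param n Number of independent draws.
#' @return Integer vector of `n` population indices.
#' @export
select_roulette <- function(fitness, n = 1L) {
  if (any(fitness < 0)) stop("fitness values must be non-negative", call. = FALSE)
  if (sum(fitness) == 0) {
    sample.int(length(fitness), n, replace = TRUE)
  } else {
    sample.int(length(fitness), n, replace = TRUE, prob = fitness)
  }
}

#' One-point crossover of two masks
#'
#' Picks a cut point uniformly in `1..d-1` and swaps the tails of the two
#' parent chromosomes. Length-1 chromosomes are returned unchanged.
#'
#' @param a,b Parent masks (equal length).
#' @param cut Optional fixed cut point (for reproducible examples/tests);
#'   drawn uniformly when `NULL`.
#' @return List of two child [gene_mask()]s.
#' @examples
#' crossover_one_point(gene_mask(c(1,1,1,1)), gene_mask(c(0,0,0,0)), cut = 2)
#' @export
crossover_one_point <- function(a, b, cut = NULL) {
  a <- as.integer(a); b <- as.integer(b)
  d <- length(a)
  if (length(b) != d) stop("parents must have equal length", call. = FALSE)
  if (d < 2L) return(list(gene_mask(a), gene_mask(b)))
  if (is.null(cut)) cut <- sample.int(d - 1L, 1L)
  if (cut < 1L || cut >= d) stop("cut must lie in 1..d-1", call. = FALSE)
  head_idx <- seq_len(cut)
  c1 <- c(a[head_idx], b[-head_idx])
  c2 <- c(b[head_idx], a[-head_idx])
  list(gene_mask(c1), gene_mask(c2))
}

#' Mutate a mask
#'
#' Negates chromosome bits at random locations. Two modes:
#' `"per_individual"` flips exactly one uniformly chosen bit with probability
#' `rate` (and otherwise leaves the mask untouched); `"per_bit"` flips every
#' bit independently with probability `rate`. Uses the current RNG state.
#'
#' @param mask A [gene_mask()].
#' @param rate Mutation rate in \[0, 1\].
#' @param mode `"per_individual"` (default) or `"per_bit"`.
#' @return The mutated [gene_mask()].
#' @export
mutate_mask <- function(mask, rate, mode = c("per_individual", "per_bit")) {
  mode <- match.arg(mode)
  bits <- as.integer(mask)
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]", call. = FALSE)
  if (rate == 0) return(gene_mask(bits))
  if (mode == "per_individual") {
    if (runif(1L) < rate) {
      pos <- sample.int(length(bits), 1L)
      bits[pos] <- 1L - bits[pos]
    }
  } else {
    flip <- runif(length(bits)) < rate
    bits[flip] <- 1L - bits[flip]
  }
  gene_mask(bits)
}

# Order of a generation: best first (fitness desc, then fewer retained genes,
# then column index) — used for elitism and best-of-generation bookkeeping.
generation_order <- function(fitness, retained) {
  order(-fitness, retained, seq_along(fitness))
}

#' Evolve a gene mask by genetic search
#'
#' Runs the full gene-masking loop: an initial random population of binary
#' masks is evaluated with the cross-validated weighted fitness, the
#' `num_elite` best chromosomes are copied unchanged into the next
#' generation, and the remainder is filled with offspring of roulette-selected
#' parent pairs that undergo one-point crossover (with probability
#' `crossover_rate`) and mutation. The stratified CV partition is drawn once
#' and reused for every mask, so fitness differences between masks reflect
#' the masks alone. Fitness values are cached by chromosome, which makes
#' revisited masks free. Fully reproducible given the config's seed.
#'
#' @param data An [expression_dataset()].
#' @param config A [ga_config()].
#' @return A `masking_result`: list with `best` (the best-ever
#'   `fitness_record`; ties resolved towards fewer retained genes, then the
#'   earlier generation), `history` (per-generation best fitness,
#'   non-decreasing when `num_elite >= 1`), `retained_gene_ids` and
#'   `provenance` (config, dataset dimensions, classifier settings).
#' @examples
#' \donttest{
#' sim <- simulate_expression(synthetic_spec(n_classes = 2,
#'   samples_per_class = 10, n_informative = 2, n_noise = 18, seed = 7))
#' cfg <- ga_config(population_size = 30, generations = 60, alpha = 0.5,
#'                  seed = 7)
#' res <- evolve(sim$data, cfg)
#' res$best
#' }
#' @export
evolve <- function(data, config = ga_config()) {
  stopifnot(inherits(data, "expression_dataset"), inherits(config, "ga_config"))
  d <- n_genes(data)
  if (d < 1L) stop("dataset has no genes", call. = FALSE)
  folds <- kfold_partition(data$labels, config$folds, config$cv_seed)
  precomp <- build_cv_precomp(data, folds)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  P <- config$population_size
  E <- config$num_elite
  alpha <- config$alpha

  eval_accuracy <- function(pop) {
    keys <- character(ncol(pop))
    for (j in seq_len(ncol(pop))) keys[j] <- intToUtf8(pop[, j] + 48L)
    miss <- keys[!vapply(keys, function(k) !is.null(cache[[k]]), logical(1L))]
    miss <- unique(miss)
    if (length(miss) > 0L) {
      cols <- match(miss, keys)
      sub <- pop[, cols, drop = FALSE]
      res <- numeric(length(cols))
      nz <- colSums(sub) > 0L
      if (any(nz)) {
        res[nz] <- cv_accuracy_batch(sub[, nz, drop = FALSE], precomp, config)
      }
      for (i in seq_along(miss)) cache[[miss[i]]] <- res[i]
    }
    vapply(keys, function(k) cache[[k]], numeric(1L), USE.NAMES = FALSE)
  }

  history <- numeric(config$generations)
  best <- NULL
  best_gen <- NA_integer_

  withr::with_seed(config$seed, {
    pop <- matrix(as.integer(runif(d * P) < config$init_prob), nrow = d)
    for (g in seq_len(config$generations)) {
      acc <- eval_accuracy(pop)
      elim <- d - colSums(pop)
      fitness <- alpha * acc + (1 - alpha) * elim / d
      ord <- generation_order(fitness, d - elim)
      top <- ord[1L]
      history[g] <- fitness[top]
      if (is.null(best) || fitness[top] > best$fitness ||
          (fitness[top] == best$fitness && (d - elim[top]) < best$retained)) {
        best <- new_fitness_record(pop[, top], acc[top], d, alpha)
        best_gen <- g
      }
      if (g == config$generations) break
      n_off <- P - E
      n_pairs <- (n_off + 1L) %/% 2L
      parents <- select_roulette(fitness, 2L * n_pairs)
      offspring <- matrix(0L, nrow = d, ncol = 2L * n_pairs)
      for (p in seq_len(n_pairs)) {
        pa <- pop[, parents[2L * p - 1L]]
        pb <- pop[, parents[2L * p]]
        if (d >= 2L && runif(1L) < config$crossover_rate) {
          cut <- sample.int(d - 1L, 1L)
          head_idx <- seq_len(cut)
          offspring[, 2L * p - 1L] <- c(pa[head_idx], pb[-head_idx])
          offspring[, 2L * p] <- c(pb[head_idx], pa[-head_idx])
        } else {
          offspring[, 2L * p - 1L] <- pa
          offspring[, 2L * p] <- pb
        }
      }
      if (config$mutation_rate > 0) {
        if (config$mutation_mode == "per_individual") {
          hit <- runif(2L * n_pairs) < config$mutation_rate
          for (j in which(hit)) {
            pos <- sample.int(d, 1L)
            offspring[pos, j] <- 1L - offspring[pos, j]
          }
        } else {
          flip <- matrix(runif(d * 2L * n_pairs) < config$mutation_rate,
                         nrow = d)
          offspring[flip] <- 1L - offspring[flip]
        }
      }
      pop <- cbind(pop[, ord[seq_len(E)], drop = FALSE],
                   offspring[, seq_len(n_off), drop = FALSE])
    }
  })

  new_masking_result(best, history, best_gen, data, config)
}

new_masking_result <- function(best, history, best_gen, data, config,
                               extra_provenance = list()) {
  structure(
    list(best = best,
         history = history,
         retained_gene_ids = data$gene_ids[as.integer(best$mask) == 1L],
         provenance = c(list(config = config, seed = config$seed,
                             n_genes = n_genes(data),
                             n_samples = n_samples(data),
                             classifier = config$classifier,
                             delta = config$delta,
                             best_generation = best_gen),
                        extra_provenance)),
    class = "masking_result"
  )
}

#' @export
print.masking_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<masking_result> %s, %d generations\n",
    "  best fitness %.4f (cv accuracy %.4f), retained %d / %d genes\n"),
    toupper(x$provenance$classifier), length(x$history),
    x$best$fitness, x$best$cv_accuracy, x$best$retained,
    x$best$retained + x$best$eliminated))
  invisible(x)
}

#' Exhaustive search over all masks (small problems)
#'
#' Enumerates every non-empty mask over up to 16 genes and returns the one
#' with maximal fitness; used as an independent optimum oracle for the
#' genetic search. Ties are broken towards fewer retained genes, then the
#' lexicographically smallest bitstring.
#'
#' @inheritParams evolve
#' @param max_genes Refusal bound on the gene dimension (default 16, i.e. at
#'   most 65535 candidate masks).
#' @return The optimal `fitness_record`.
#' @export
exhaustive_mask_search <- function(data, config = ga_config(),
                                   max_genes = 16L) {
  d <- n_genes(data)
  if (d > max_genes) {
    stop(sprintf("exhaustive search enumerates 2^d masks; d = %d exceeds the bound %d",
                 d, max_genes), call. = FALSE)
  }
  folds <- kfold_partition(data$labels, config$folds, config$cv_seed)
  precomp <- build_cv_precomp(data, folds)
  n_masks <- 2L^d - 1L
  best <- NULL
  chunk <- 4096L
  for (start in seq(1L, n_masks, by = chunk)) {
    ms <- start:min(start + chunk - 1L, n_masks)
    pop <- vapply(ms, function(m) as.integer(intToBits(m))[seq_len(d)],
                  integer(d))
    pop <- matrix(pop, nrow = d)
    acc <- cv_accuracy_batch(pop, precomp, config)
    fitness <- config$alpha * acc +
      (1 - config$alpha) * (d - colSums(pop)) / d
    ord <- order(-fitness, colSums(pop),
                 vapply(seq_along(ms), function(j)
                   intToUtf8(pop[, j] + 48L), character(1L)))
    top <- ord[1L]
    cand <- new_fitness_record(pop[, top], acc[top], d, config$alpha)
    cand_key <- intToUtf8(pop[, top] + 48L)
    if (is.null(best) || cand$fitness > best$fitness ||
        (cand$fitness == best$fitness &&
         (cand$retained < best$retained ||
          (cand$retained == best$retained && cand_key < best_key)))) {
      best <- cand
      best_key <- cand_key
    }
  }
  best
}

#' Shrink a dataset, then run gene masking on the survivors
#'
#' The two-stage workflow for large gene dimensions: nearest-shrunken-centroid
#' statistics are fitted once on the full dataset, shrinkage at `delta`
#' removes the genes with little deviation from the overall centroid, and the
#' genetic search is run on the surviving genes only (the chromosome length
#' becomes the survivor count). The returned result is expressed in the
#' original gene space: the best mask is padded with zeros for the genes
#' shrinkage removed, and the surviving gene identifiers are recorded in the
#' provenance.
#'
#' @inheritParams evolve
#' @param delta Shrinkage amount for the pre-masking reduction.
#' @return A `masking_result` whose `best$mask` has length `n_genes(data)`.
#'   Note `best$fitness` and `best$eliminated` refer to the chromosome the GA
#'   actually searched (the shrunken dataset).
#' @export
shrink_then_mask <- function(data, delta, config = ga_config()) {
  model <- fit_shrunken_centroids(data, delta = delta)
  surv <- surviving_genes(model)
  if (length(surv) == 0L) {
    stop(sprintf("no gene survives shrinkage at delta = %g; use a smaller delta",
                 delta), call. = FALSE)
  }
  keep <- integer(n_genes(data))
  keep[surv] <- 1L
  reduced <- apply_mask(data, keep)
  res <- evolve(reduced, config)
  full_mask <- integer(n_genes(data))
  full_mask[surv[as.integer(res$best$mask) == 1L]] <- 1L
  res$best$mask <- gene_mask(full_mask)
  res$retained_gene_ids <- data$gene_ids[full_mask == 1L]
  res$provenance$shrinkage_delta <- delta
  res$provenance$surviving_gene_ids <- data$gene_ids[surv]
  res$provenance$n_genes <- n_genes(data)
  res
}

#' Gene occurrence across qualifying masking runs
#'
#' Because the genetic search is stochastic, repeated runs that reach the same
#' accuracy need not select the same genes. This report filters a collection
#' of runs to those meeting an accuracy floor and a retained-gene ceiling and
#' tabulates, for each gene, the fraction of qualifying runs in which it was
#' retained.
#'
#' @param results List of `masking_result` objects.
#' @param max_genes Retained-gene ceiling for a run to qualify (default 15).
#' @param min_accuracy Cross-validated accuracy floor (default 1.0).
#' @return A tibble with columns `gene_id`, `n_selected`, `n_runs`,
#'   `occurrence` (fraction) and `percentage` (occurrence * 100, rounded to
#'   2 decimals), sorted by decreasing occurrence. Empty (with a warning) if
#'   no run qualifies.
#' @export
occurrence_report <- function(results, max_genes = 15L, min_accuracy = 1.0) {
  if (length(results) == 0L) stop("need at least one result", call. = FALSE)
  ok <- vapply(results, function(r) {
    r$best$cv_accuracy >= min_accuracy &&
      length(r$retained_gene_ids) <= max_genes
  }, logical(1L))
  empty <- tibble::tibble(gene_id = character(), n_selected = integer(),
                          n_runs = integer(), occurrence = numeric(),
                          percentage = numeric())
  if (!any(ok)) {
    warning(sprintf("no run meets accuracy >= %g with <= %d genes",
                    min_accuracy, max_genes), call. = FALSE)
    return(empty)
  }
  qual <- results[ok]
  ids <- unlist(lapply(qual, `[[`, "retained_gene_ids"))
  counts <- table(ids)
  tibble::tibble(
    gene_id = names(counts),
    n_selected = as.integer(counts),
    n_runs = length(qual),
    occurrence = as.integer(counts) / length(qual),
    percentage = round(100 * as.integer(counts) / length(qual), 2L)
  ) |>
    dplyr::arrange(dplyr::desc(.data$occurrence), .data$gene_id)
}
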