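# Fixtures are built in code; nothing is read from disk.

# Small Gaussian dataset with no planted structure.
random_dataset <- function(d = 10, per_class = 5, K = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- per_class * K
    x <- matrix(rnorm(d * n), nrow = d,
                dimnames = list(paste0("g", seq_len(d)),
                                paste0("s", seq_len(n))))
    expression_dataset(x, rep(paste0("C", seq_len(K)), each = per_class))
  })
}

# Planted dataset where every informative gene is necessary for perfect
# classification: one marker per class for K-1 classes, the K-th class is
# the unmarked all-baseline profile. Dropping any marker collapses its class
# onto the unmarked one.
necessary_marker_dataset <- function(K = 4, per_class = 10, n_noise = 47,
                                     effect = 6, seed = 1) {
  sim <- simulate_expression(synthetic_spec(
    n_classes = K, samples_per_class = per_class,
    n_informative = K - 1, n_noise = n_noise,
    effect_size = effect, seed = seed))
  sim
}

# Two perfectly separated constant-profile classes on every gene.
separable_dataset <- function(d = 1, per_class = 10, gap = 10, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * per_class
    x <- matrix(rnorm(d * n, sd = 0.1), nrow = d)
    x[, seq_len(per_class)] <- x[, seq_len(per_class)] + gap
    rownames(x) <- paste0("g", seq_len(d))
    colnames(x) <- paste0("s", seq_len(n))
    expression_dataset(x, rep(c("A", "B"), each = per_class))
  })
}

quick_config <- function(...) {
  ga_config(population_size = 20L, generations = 30L, folds = 5L, ...)
}

# Independent brute-force shrinkage statistics: plain loops, no shared code
# with the implementation.
oracle_shrunken_stats <- function(data) {
  x <- data$values
  labels <- as.character(data$labels)
  classes <- sort(unique(labels))
  d <- nrow(x); n <- ncol(x); K <- length(classes)
  cent <- matrix(0, d, K)
  overall <- numeric(d)
  for (i in seq_len(d)) overall[i] <- sum(x[i, ]) / n
  n_k <- integer(K)
  for (k in seq_len(K)) {
    idx <- which(labels == classes[k])
    n_k[k] <- length(idx)
    for (i in seq_len(d)) cent[i, k] <- sum(x[i, idx]) / length(idx)
  }
  s2 <- numeric(d)
  for (i in seq_len(d)) {
    tot <- 0
    for (k in seq_len(K)) {
      for (j in which(labels == classes[k])) {
        tot <- tot + (x[i, j] - cent[i, k])^2
      }
    }
    s2[i] <- tot / (n - K)
  }
  s <- sqrt(s2)
  s_sorted <- sort(s)
  s0 <- s_sorted[(d + 1) %/% 2]
  m_k <- sqrt(1 / n_k - 1 / n)
  d_ik <- matrix(0, d, K)
  for (k in seq_len(K)) {
    for (i in seq_len(d)) {
      den <- m_k[k] * (s[i] + s0)
      d_ik[i, k] <- if (den > 0) (cent[i, k] - overall[i]) / den else 0
    }
  }
  list(classes = classes, centroids = cent, overall = overall, n_k = n_k,
       m_k = m_k, s = s, s0 = s0, d_ik = d_ik)
}

# Independent cross-validation oracle: explicit fold loop with hand-computed
# class means and distances.
oracle_cv_accuracy <- function(data, mask, k, cv_seed) {
  folds <- kfold_partition(data$labels, k, cv_seed)
  keep <- which(as.integer(mask) == 1L)
  if (length(keep) == 0L) return(0)
  labels <- as.character(data$labels)
  classes <- sort(unique(labels))
  accs <- numeric(length(folds))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(labels), test_idx)
    cent <- sapply(classes, function(cl) {
      cols <- intersect(train_idx, which(labels == cl))
      rowMeans(data$values[keep, cols, drop = FALSE])
    })
    cent <- matrix(cent, nrow = length(keep))
    correct <- 0
    for (t in test_idx) {
      dists <- apply(cent, 2, function(cc)
        sum((data$values[keep, t] - cc)^2))
      pred <- classes[which.min(dists)]
      if (pred == labels[t]) correct <- correct + 1
    }
    accs[f] <- correct / length(test_idx)
  }
  mean(accs)
}
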