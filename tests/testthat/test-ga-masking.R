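test_that("stratified k-fold partitions are disjoint, balanced and seeded", {
  labels <- rep(c("A", "B"), each = 10)
  folds <- kfold_partition(labels, 5, seed = 2)
  expect_length(folds, 5)
  expect_equal(sort(unlist(folds)), 1:20)
  for (f in folds) {
    expect_length(f, 4)
    expect_equal(sum(labels[f] == "A"), 2)  # strata preserved
  }

  expect_identical(kfold_partition(labels, 5, seed = 2), folds)
  expect_false(identical(kfold_partition(labels, 5, seed = 3), folds))

  expect_error(kfold_partition(rep(c("A", "B"), c(3, 17)), 5, 1),
               "fewer than k")
  expect_error(kfold_partition(labels, 1, 1), "k must be")
})

test_that("fold sizes differ by at most one across class layouts", {
  withr::with_seed(6, {
    for (n in seq(8, 50, by = 7)) {
      for (k in 2:5) {
        if (n < 2 * k) next
        sizes_a <- seq(k, n - k)
        n_a <- sizes_a[sample.int(length(sizes_a), 1)]
        labels <- rep(c("A", "B"), c(n_a, n - n_a))
        folds <- kfold_partition(labels, k, seed = n + k)
        sizes <- lengths(folds)
        expect_lte(max(sizes) - min(sizes), 1)
        expect_equal(sort(unlist(folds)), seq_len(n))
      }
    }
  })
})

test_that("cross-validated accuracy handles separable, degenerate and random
           masks, and matches an independent fold-by-fold oracle", {
  sep <- separable_dataset(d = 1, per_class = 10)
  cfg <- quick_config(seed = 1)
  expect_equal(cv_accuracy(sep, gene_mask(1), cfg), 1.0)
  expect_equal(cv_accuracy(sep, gene_mask(0), cfg), 0.0)

  ds <- random_dataset(d = 10, per_class = 10, K = 2, seed = 12)
  withr::with_seed(5, {
    for (r in 1:8) {
      m <- gene_mask(rbinom(10, 1, 0.6))
      expect_equal(cv_accuracy(ds, m, cfg),
                   oracle_cv_accuracy(ds, m, cfg$folds, cfg$cv_seed),
                   tolerance = 1e-12)
    }
  })
})

test_that("the compiled population evaluator agrees with the reference
           cross-validation for both classifiers", {
  sim <- simulate_expression(synthetic_spec(n_classes = 3,
    samples_per_class = 8, n_informative = 3, n_noise = 12,
    effect_size = 4, seed = 6))
  ds <- sim$data
  for (cls in c("ncc", "nscc")) {
    cfg <- quick_config(seed = 2, classifier = cls, delta = 0.6)
    folds <- kfold_partition(ds$labels, cfg$folds, cfg$cv_seed)
    pre <- genemask:::build_cv_precomp(ds, folds)
    withr::with_seed(77, {
      masks <- matrix(rbinom(15 * 25, 1, 0.5), nrow = 15)
    })
    masks <- masks[, colSums(masks) > 0, drop = FALSE]
    fast <- genemask:::cv_accuracy_batch(masks, pre, cfg)
    slow <- apply(masks, 2, function(m) cv_accuracy(ds, m, cfg))
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("fitness is the weighted accuracy/elimination sum", {
  rec <- genemask:::new_fitness_record(
    gene_mask(c(rep(0, 15), rep(1, 5))), acc = 0.95, d = 20, alpha = 0.9)
  expect_equal(rec$fitness, 0.930)
  expect_equal(rec$eliminated, 15)

  # alpha = 1: fitness is pure accuracy
  rec1 <- genemask:::new_fitness_record(gene_mask(c(0, 1)), 0.8, 2, 1)
  expect_equal(rec1$fitness, 0.8)

  # all-ones mask: elimination term vanishes
  sep <- separable_dataset(d = 2, per_class = 10)
  cfg <- quick_config(alpha = 0.7, seed = 1)
  rec2 <- mask_fitness(sep, gene_mask(c(1, 1)), cfg)
  expect_equal(rec2$fitness, 0.7 * rec2$cv_accuracy)
  expect_true(rec2$fitness >= 0 && rec2$fitness <= 1)
})

test_that("roulette selection is fitness-proportional", {
  expect_error(select_roulette(c(1, -0.5)), "non-negative")

  withr::with_seed(8, {
    expect_true(all(select_roulette(c(1, 0), 200) == 1L))

    draws <- select_roulette(c(3, 1), 1e5)
    p <- mean(draws == 1L)
    expect_lt(abs(p - 0.75), 0.01)

    # all-equal fitness: uniform (chi-square gof)
    draws <- select_roulette(rep(2, 4), 1e5)
    expect_gt(stats::chisq.test(table(factor(draws, 1:4)))$p.value, 1e-4)

    # all-zero fitness: uniform fallback still selects everything
    draws <- select_roulette(rep(0, 3), 1e4)
    expect_setequal(unique(draws), 1:3)
  })
})

test_that("one-point crossover swaps tails and conserves positionwise bits", {
  out <- crossover_one_point(gene_mask(c(1, 1, 1, 1)),
                             gene_mask(c(0, 0, 0, 0)), cut = 2)
  expect_equal(as.integer(out[[1]]), c(1L, 1L, 0L, 0L))
  expect_equal(as.integer(out[[2]]), c(0L, 0L, 1L, 1L))

  a <- gene_mask(c(1, 0, 1, 0, 1))
  same <- crossover_one_point(a, a, cut = 3)
  expect_identical(as.integer(same[[1]]), as.integer(a))

  withr::with_seed(9, {
    for (r in 1:10) {
      pa <- gene_mask(rbinom(8, 1, 0.5)); pb <- gene_mask(rbinom(8, 1, 0.5))
      kids <- crossover_one_point(pa, pb)
      for (i in 1:8) {
        expect_setequal(c(kids[[1]][i], kids[[2]][i]), c(pa[i], pb[i]))
      }
    }
  })

  # length-1 chromosomes pass through unchanged
  out1 <- crossover_one_point(gene_mask(1), gene_mask(0))
  expect_equal(as.integer(out1[[1]]), 1L)
})

test_that("mutation flips bits at the configured rate", {
  m <- gene_mask(rep(1, 10))
  expect_identical(as.integer(mutate_mask(m, 0)), rep(1L, 10))
  expect_identical(as.integer(mutate_mask(m, 1, mode = "per_bit")),
                   rep(0L, 10))

  withr::with_seed(10, {
    # per-bit: total flips over trials within 3 sigma of Binomial(n*d, p)
    p <- 0.2; d <- 25; trials <- 400
    flips <- sum(vapply(seq_len(trials), function(i) {
      sum(as.integer(mutate_mask(gene_mask(rep(0, d)), p, "per_bit")))
    }, numeric(1)))
    expected <- trials * d * p
    expect_lt(abs(flips - expected), 3 * sqrt(trials * d * p * (1 - p)))

    # per-individual: flips exactly 0 or 1 bits, hitting at rate ~ MR
    hits <- vapply(seq_len(trials), function(i) {
      sum(as.integer(mutate_mask(gene_mask(rep(0, d)), 0.3)))
    }, numeric(1))
    expect_true(all(hits %in% c(0, 1)))
    expect_lt(abs(mean(hits) - 0.3), 3 * sqrt(0.3 * 0.7 / trials))
  })
})

test_that("evolution improves monotonically under elitism, is reproducible
           bit-for-bit, and recovers a planted subset", {
  sim <- simulate_expression(synthetic_spec(n_classes = 2,
    samples_per_class = 10, n_informative = 3, n_noise = 37,
    effect_size = 8, seed = 14))
  cfg <- ga_config(population_size = 50, generations = 200, alpha = 0.5,
                   seed = 4, classifier = "ncc")
  res <- evolve(sim$data, cfg)

  expect_true(all(diff(res$history) >= 0))
  expect_equal(res$best$fitness, max(res$history))
  expect_equal(res$best$cv_accuracy, 1.0)
  # the retained set is a sufficient informative subset: no noise genes,
  # at least one planted marker (any marker separates the two classes)
  expect_gte(sum(grepl("^inf", res$retained_gene_ids)), 1)
  expect_equal(sum(grepl("^noise", res$retained_gene_ids)), 0)

  res2 <- evolve(sim$data, cfg)
  expect_identical(as.integer(res$best$mask), as.integer(res2$best$mask))
  expect_identical(res$history, res2$history)
  expect_identical(glance(res), glance(res2))

  # different seed generically explores differently
  cfg3 <- ga_config(population_size = 50, generations = 200, alpha = 0.5,
                    seed = 5, classifier = "ncc")
  expect_false(identical(res$history, evolve(sim$data, cfg3)$history))

  expect_error(ga_config(population_size = 2, num_elite = 2), "num_elite")
})

test_that("exhaustive search returns the enumerated optimum with the
           documented tie rules", {
  # d = 1, separable: only candidate mask [1]
  sep1 <- separable_dataset(d = 1, per_class = 10)
  cfg <- quick_config(alpha = 0.5, seed = 1)
  opt1 <- exhaustive_mask_search(sep1, cfg)
  expect_equal(as.integer(opt1$mask), 1L)

  # 2 genes: gene 1 separates perfectly, gene 2 is noise -> optimum [1,0]
  withr::with_seed(15, {
    g1 <- c(rep(1, 10), rep(3, 10)) + rnorm(20, sd = 1e-3)
    g2 <- rnorm(20)
    x <- rbind(g1 = g1, g2 = g2)
    colnames(x) <- paste0("s", 1:20)
  })
  ds2 <- expression_dataset(x, rep(c("A", "B"), each = 10))
  opt2 <- exhaustive_mask_search(ds2, cfg)
  expect_equal(as.integer(opt2$mask), c(1L, 0L))
  expect_equal(opt2$cv_accuracy, 1.0)
  expect_equal(opt2$fitness, 0.75)

  # optimum dominates every enumerated mask
  ds <- random_dataset(d = 6, per_class = 8, K = 2, seed = 16)
  opt <- exhaustive_mask_search(ds, cfg)
  for (m in 1:(2^6 - 1)) {
    bits <- as.integer(intToBits(m))[1:6]
    expect_gte(opt$fitness + 1e-12, mask_fitness(ds, bits, cfg)$fitness)
  }

  expect_error(exhaustive_mask_search(random_dataset(d = 20, seed = 1), cfg),
               "exceeds")
})

test_that("shrink-then-mask restricts the search to shrinkage survivors and
           maps the result back to original identifiers", {
  sim <- necessary_marker_dataset(K = 4, per_class = 10, n_noise = 57,
                                  effect = 6, seed = 18)
  ds <- sim$data
  cfg <- ga_config(population_size = 40, generations = 150, alpha = 0.9,
                   seed = 6, classifier = "nscc", delta = 1)
  res <- shrink_then_mask(ds, delta = 1, cfg)

  surv_ids <- res$provenance$surviving_gene_ids
  expect_true(all(res$retained_gene_ids %in% surv_ids))
  expect_true(all(surv_ids %in% ds$gene_ids))
  expect_length(res$best$mask, n_genes(ds))
  expect_equal(ds$gene_ids[as.integer(res$best$mask) == 1L],
               res$retained_gene_ids)
  expect_equal(res$best$cv_accuracy, 1.0)
  # every planted marker is necessary here, so all survive the search
  expect_true(all(paste0("inf", 1:3) %in% res$retained_gene_ids))

  expect_error(shrink_then_mask(ds, delta = 1e6, cfg), "smaller delta")
})

test_that("shrink-then-mask at delta 0 reduces to plain evolution when every
           gene survives", {
  ds <- random_dataset(d = 12, per_class = 8, K = 2, seed = 19)
  cfg <- quick_config(alpha = 0.5, seed = 7, classifier = "nscc", delta = 0)
  a <- shrink_then_mask(ds, delta = 0, cfg)
  b <- evolve(ds, cfg)
  expect_identical(as.integer(a$best$mask), as.integer(b$best$mask))
  expect_identical(a$history, b$history)
})

test_that("occurrence reporting counts retained genes across qualifying runs", {
  fake_run <- function(ids, acc) {
    structure(list(
      best = list(cv_accuracy = acc, fitness = acc, retained = length(ids),
                  eliminated = 10 - length(ids)),
      retained_gene_ids = ids,
      history = 1, provenance = list()), class = "masking_result")
  }
  runs <- c(
    lapply(1:7, function(i) {
      ids <- c("gA", if (i <= 3) "gB")
      fake_run(ids, 1.0)
    }),
    list(fake_run(c("gC"), 0.9),                       # accuracy filter
         fake_run(paste0("x", 1:20), 1.0))             # size filter
  )
  rep_tbl <- occurrence_report(runs, max_genes = 15, min_accuracy = 1.0)
  expect_equal(rep_tbl$n_runs[1], 7L)
  expect_equal(rep_tbl$occurrence[rep_tbl$gene_id == "gA"], 1.0)
  expect_equal(rep_tbl$percentage[rep_tbl$gene_id == "gB"], 42.86)
  expect_false("gC" %in% rep_tbl$gene_id)
  expect_false("x1" %in% rep_tbl$gene_id)
  expect_true(all(diff(rep_tbl$occurrence) <= 0))

  expect_warning(empty <- occurrence_report(list(fake_run("g", 0.5))),
                 "no run")
  expect_equal(nrow(empty), 0)
})
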