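#' Specify a synthetic class-structured expression dataset
#'
#' Describes a planted-truth simulation emulating the structure of microarray
#' classification problems: many more genes than samples, a small set of
#' informative genes whose class-conditional means differ, and Gaussian noise
#' everywhere. Noise genes are drawn class-independently from
#' `N(0, noise_sd^2)`; each informative gene additionally receives a mean
#' offset of `effect_size * noise_sd` in one designated class, assigned
#' round-robin across classes so every class is separable.
#'
#' @param n_classes Number of classes K.
#' @param samples_per_class Integer vector (recycled to K) of class sizes.
#' @param n_informative Number of informative genes.
#' @param n_noise Number of pure-noise genes.
#' @param effect_size Mean shift of an informative gene in its designated
#'   class, in units of `noise_sd`.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param seed RNG seed making the generated matrix reproducible.
#' @return A `synthetic_spec` list.
#' @examples
#' spec <- synthetic_spec(n_classes = 4, samples_per_class = 10,
#'                        n_informative = 5, n_noise = 95,
#'                        effect_size = 6, seed = 1)
#' sim <- simulate_expression(spec)
#' sim$data
#' sim$informative   # indices of the planted genes
#' @export
synthetic_spec <- function(n_classes = 2, samples_per_class = 10,
                           n_informative = 3, n_noise = 37,
                           effect_size = 6, noise_sd = 1, seed = 1L) {
  stopifnot(n_classes >= 1, n_informative >= 0, n_noise >= 0,
            n_informative + n_noise >= 1, effect_size >= 0, noise_sd > 0)
  samples_per_class <- rep_len(as.integer(samples_per_class), n_classes)
  if (any(samples_per_class < 1L)) {
    stop("every class needs >= 1 sample", call. = FALSE)
  }
  structure(
    list(n_classes = as.integer(n_classes),
         samples_per_class = samples_per_class,
         n_informative = as.integer(n_informative),
         n_noise = as.integer(n_noise),
         effect_size = effect_size, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Simulate an expression dataset with planted informative genes
#'
#' @param spec A [synthetic_spec()].
#' @return List with `data` (an [expression_dataset()]; informative genes
#'   come first, named `inf*`, then noise genes `noise*`), `informative`
#'   (integer indices of the planted genes) and `informative_class` (the
#'   designated class of each informative gene).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d <- spec$n_informative + spec$n_noise
  n <- sum(spec$samples_per_class)
  classes <- paste0("C", seq_len(spec$n_classes))
  labels <- rep(classes, times = spec$samples_per_class)
  withr::with_seed(spec$seed, {
    values <- matrix(rnorm(d * n, sd = spec$noise_sd), nrow = d, ncol = n)
  })
  inf_idx <- seq_len(spec$n_informative)
  inf_class <- classes[((inf_idx - 1L) %% spec$n_classes) + 1L]
  for (g in inf_idx) {
    in_class <- labels == inf_class[g]
    values[g, in_class] <- values[g, in_class] + spec$effect_size * spec$noise_sd
  }
  gene_ids <- c(sprintf("inf%d", inf_idx),
                sprintf("noise%d", seq_len(spec$n_noise)))
  colnames(values) <- sprintf("s%d", seq_len(n))
  rownames(values) <- gene_ids
  list(data = expression_dataset(values, labels),
       informative = inf_idx,
       informative_class = inf_class)
}

#' Dataset-shaped simulation profiles
#'
#' Returns a [synthetic_spec()] whose dimensions mimic the published
#' microarray training sets commonly used to benchmark centroid classifiers:
#' `"srbct"` (small round blue cell tumours: 2308 genes, 4 classes, 63
#' training samples), `"mll"` (mixed-lineage leukaemia: 12582 genes, 3
#' classes, 57 samples) and `"lc"` (lung cancer: 12533 genes, 2 classes, 32
#' samples). A `scale` factor shrinks the gene dimension (and the planted
#' informative set) proportionally for smoke tests; classes and sample counts
#' are unchanged.
#'
#' @param profile One of `"srbct"`, `"mll"`, `"lc"`.
#' @param scale Positive factor applied to the gene dimension.
#' @param effect_size,seed Passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @examples
#' fixture_profile("srbct", scale = 0.1)  # ~231 genes, K = 4
#' @export
fixture_profile <- function(profile = c("srbct", "mll", "lc"), scale = 1,
                            effect_size = 6, seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(scale > 0)
  shape <- switch(profile,
    srbct = list(d = 2308L, K = 4L, sizes = c(23L, 20L, 12L, 8L), inf = 40L),
    mll   = list(d = 12582L, K = 3L, sizes = c(20L, 17L, 20L), inf = 60L),
    lc    = list(d = 12533L, K = 2L, sizes = c(16L, 16L), inf = 40L)
  )
  d <- max(shape$K, as.integer(round(shape$d * scale)))
  n_inf <- min(d, max(shape$K, as.integer(round(shape$inf * scale))))
  synthetic_spec(n_classes = shape$K, samples_per_class = shape$sizes,
                 n_informative = n_inf, n_noise = d - n_inf,
                 effect_size = effect_size, seed = seed)
}
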