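#' Fit a nearest-shrunken-centroid classifier
#'
#' Computes the shrinkage statistics underlying the nearest shrunken centroid
#' classifier and (optionally) applies soft-threshold shrinkage by `delta`.
#' For every gene i and class k the standardized distance of the class
#' centroid from the overall centroid is
#' \deqn{d_{ik} = \frac{\bar x_{ik} - \bar x_i}{m_k (s_i + s_0)}}
#' with \eqn{m_k^2 = 1/n_k - 1/n}, \eqn{s_i} the pooled within-class standard
#' deviation (divisor n - K) and \eqn{s_0} the median of the \eqn{s_i}
#' (lower median for an even number of genes, a deterministic convention).
#' Shrinkage replaces \eqn{d_{ik}} with the soft-thresholded
#' \eqn{d'_{ik} = \mathrm{sign}(d_{ik})(|d_{ik}| - \Delta)_+} and rebuilds
#' shrunken centroids \eqn{\bar x'_{ik} = \bar x_i + m_k (s_i + s_0) d'_{ik}}.
#' Genes whose \eqn{d'_{ik}} vanish for every class carry no class information
#' and are dropped at prediction time.
#'
#' @param data An [expression_dataset()] with at least two classes and more
#'   samples than classes (`n > K`, so the pooled-variance divisor is
#'   positive).
#' @param delta Non-negative shrinkage amount. `delta = 0` performs no
#'   shrinkage: predictions then coincide with [fit_centroids()].
#' @return An object of class `shrunken_centroid_model` (inherits
#'   `centroid_model`) with fields `centroids`, `overall_centroid`,
#'   `class_set`, `gene_ids`, `n_k`, `n`, `m_k`, `s_i`, `s0`, `d_ik`, `delta`,
#'   `d_shrunk` and `shrunken_centroids`.
#' @examples
#' ds <- simulate_expression(synthetic_spec(seed = 1))
#' fit <- fit_shrunken_centroids(ds$data, delta = 2)
#' length(surviving_genes(fit))
#' @export
fit_shrunken_centroids <- function(data, delta = 0) {
  stopifnot(inherits(data, "expression_dataset"))
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  base <- fit_centroids(data)
  K <- length(base$class_set)
  n <- base$n
  if (K < 2L) stop("shrinkage statistics need at least 2 classes", call. = FALSE)
  if (n <= K) {
    stop(sprintf("need n > K for the pooled variance (n = %d, K = %d)", n, K),
         call. = FALSE)
  }
  m_k <- sqrt(1 / base$n_k - 1 / n)
  # pooled within-class variance, divisor n - K
  dev2 <- (data$values - base$centroids[, as.integer(data$labels), drop = FALSE])^2
  s_i <- sqrt(rowSums(dev2) / (n - K))
  s0 <- lower_median(s_i)
  if (s0 == 0 && all(s_i == 0)) {
    stop("all pooled within-class SDs are zero; standardized distances undefined",
         call. = FALSE)
  }
  denom <- outer(s_i + s0, m_k)            # genes x classes
  d_ik <- (base$centroids - base$overall_centroid) / denom
  d_ik[denom == 0] <- 0                    # constant gene guard: no information
  model <- structure(
    c(base, list(m_k = m_k, s_i = stats::setNames(s_i, data$gene_ids), s0 = s0,
                 d_ik = d_ik, delta = 0, d_shrunk = d_ik,
                 shrunken_centroids = base$centroids)),
    class = c("shrunken_centroid_model", "centroid_model")
  )
  if (delta > 0) model <- shrink_centroids(model, delta)
  model
}

# lower median: for an even count take the smaller of the two middle values
lower_median <- function(x) unname(sort(x)[(length(x) + 1L) %/% 2L])

#' Apply soft-threshold shrinkage to a fitted model
#'
#' Re-applies shrinkage at a new `delta` using the stored statistics; the
#' statistics themselves (`m_k`, `s_i`, `s0`, `d_ik`) are unchanged, so
#' shrinking is cheap and can be swept over a delta grid.
#'
#' @param model A `shrunken_centroid_model`.
#' @param delta Non-negative shrinkage amount.
#' @return The model with `d_shrunk`, `shrunken_centroids` and `delta`
#'   updated.
#' @export
shrink_centroids <- function(model, delta) {
  stopifnot(inherits(model, "shrunken_centroid_model"))
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  d_shrunk <- sign(model$d_ik) * pmax(abs(model$d_ik) - delta, 0)
  denom <- outer(model$s_i + model$s0, model$m_k)
  model$d_shrunk <- d_shrunk
  model$shrunken_centroids <- model$overall_centroid + denom * d_shrunk
  model$delta <- delta
  model
}

#' Genes surviving shrinkage
#'
#' A gene survives when its shrunken standardized distance is nonzero for at
#' least one class; all other genes have been pulled entirely onto the overall
#' centroid and carry no class information.
#'
#' @param model A `shrunken_centroid_model`.
#' @return Integer vector of surviving gene indices (possibly empty).
#' @export
surviving_genes <- function(model) {
  stopifnot(inherits(model, "shrunken_centroid_model"))
  unname(which(rowSums(model$d_shrunk != 0) > 0))
}

#' @describeIn fit_shrunken_centroids Predict with the shrunken centroids.
#'   The nearest-centroid rule is applied to the shrunken centroids over the
#'   surviving genes only (genes shrunk to the overall centroid contribute an
#'   identical offset to every class, so the argmin is unchanged; restricting
#'   is purely a speed-up). Errors if no gene survives.
#' @param object A `shrunken_centroid_model`.
#' @param newdata An [expression_dataset()] or matrix/vector with genes in the
#'   model's row order.
#' @param ... Unused.
#' @export
predict.shrunken_centroid_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "expression_dataset")) newdata$values else newdata
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (nrow(x) != length(object$gene_ids)) {
    stop(sprintf("sample has %d genes but the model expects %d",
                 nrow(x), length(object$gene_ids)), call. = FALSE)
  }
  surv <- surviving_genes(object)
  if (length(surv) == 0L) {
    stop("degenerate model: no gene survives shrinkage at this delta",
         call. = FALSE)
  }
  nearest_class(object$shrunken_centroids[surv, , drop = FALSE],
                x[surv, , drop = FALSE], object$class_set)
}

#' Survivor counts across a shrinkage grid
#'
#' Sweeps `delta` over a grid and counts the genes surviving shrinkage at each
#' value — the shrinkage profile of a dataset. The count is non-increasing in
#' `delta` and reaches zero once `delta` exceeds `max(|d_ik|)`.
#'
#' @param data An [expression_dataset()] (or an already fitted
#'   `shrunken_centroid_model`).
#' @param deltas Numeric vector of shrinkage amounts.
#' @return A tibble with columns `delta` and `n_surviving`.
#' @export
delta_sweep <- function(data, deltas) {
  model <- if (inherits(data, "shrunken_centroid_model")) data
           else fit_shrunken_centroids(data)
  tibble::tibble(
    delta = deltas,
    n_surviving = vapply(deltas, function(d) {
      length(surviving_genes(shrink_centroids(model, d)))
    }, integer(1L))
  )
}
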