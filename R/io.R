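#' Read an expression matrix and its sample labels
#'
#' Reads a delimited expression matrix (first column = gene identifier, one
#' column per sample by default) together with a two-column labels file
#' (sample identifier, class) and returns a validated [expression_dataset()].
#' Labels are reordered to match the matrix's sample order, so the two files
#' may list samples differently.
#'
#' @param matrix_path Path to the expression matrix (TSV or CSV, header row).
#' @param labels_path Path to the labels file (same delimiter; two columns:
#'   sample id, class; a header row is required).
#' @param format `"tsv"` (default) or `"csv"`.
#' @param orientation `"genes_rows"` (default, the microarray convention) or
#'   `"genes_cols"` for a transposed matrix whose first column is the sample
#'   identifier.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, labels_path,
                            format = c("tsv", "csv"),
                            orientation = c("genes_rows", "genes_cols")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(matrix_path, col_types = readr::cols(), progress = FALSE,
                show_col_types = FALSE)
  if (ncol(raw) < 2L) stop("matrix file needs an id column plus >= 1 data column",
                           call. = FALSE)
  ids <- as.character(raw[[1L]])
  body <- raw[-1L]
  # locate non-numeric cells before coercion so the error can name coordinates
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric cell at row %d ('%s'), column '%s': '%s'",
                     bad[1L], ids[bad[1L]], names(body)[j], col[bad[1L]]),
             call. = FALSE)
      }
      body[[j]] <- as.numeric(col)
    }
  }
  mat <- as.matrix(body)
  if (orientation == "genes_cols") {
    mat <- t(mat)
    tmp <- ids
    ids <- colnames(raw)[-1L]
    dimnames(mat) <- list(ids, tmp)
  } else {
    rownames(mat) <- ids
  }
  if (anyDuplicated(rownames(mat))) {
    dup <- unique(rownames(mat)[duplicated(rownames(mat))])
    stop(sprintf("duplicated gene identifier(s): %s",
                 paste(head(dup, 5L), collapse = ", ")), call. = FALSE)
  }

  lab_raw <- reader(labels_path, col_types = readr::cols(), progress = FALSE,
                    show_col_types = FALSE)
  if (ncol(lab_raw) < 2L) stop("labels file needs two columns: sample id, class",
                               call. = FALSE)
  lab_map <- stats::setNames(as.character(lab_raw[[2L]]),
                             as.character(lab_raw[[1L]]))
  missing <- setdiff(colnames(mat), names(lab_map))
  if (length(missing) > 0L) {
    stop(sprintf("labels file is missing sample(s): %s",
                 paste(head(missing, 5L), collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(lab_map), colnames(mat))
  if (length(extra) > 0L) {
    stop(sprintf("labels file has sample(s) absent from the matrix: %s",
                 paste(head(extra, 5L), collapse = ", ")), call. = FALSE)
  }
  expression_dataset(mat, unname(lab_map[colnames(mat)]))
}

#' Write an expression dataset to delimited text
#'
#' Values are written with 17 significant digits so that a read/write
#' round-trip reproduces doubles exactly.
#'
#' @param data An [expression_dataset()].
#' @param matrix_path,labels_path Output paths.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return Invisibly, `data`.
#' @export
write_expression <- function(data, matrix_path, labels_path,
                             format = c("tsv", "csv")) {
  format <- match.arg(format)
  writer <- if (format == "tsv") readr::write_tsv else readr::write_csv
  df <- tibble::as_tibble(data$values, .name_repair = "minimal")
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(),
                                        ~ sprintf("%.17g", .x)))
  df <- dplyr::bind_cols(tibble::tibble(gene_id = data$gene_ids), df)
  writer(df, matrix_path)
  writer(tibble::tibble(sample_id = data$sample_ids,
                        class = as.character(data$labels)),
         labels_path)
  invisible(data)
}

#' Save / load a gene mask
#'
#' The on-disk format is one line of 0/1 characters (the chromosome), followed
#' by one retained gene identifier per line for human inspection. Round trips
#' are bit-exact.
#'
#' @param mask A [gene_mask()].
#' @param gene_ids Gene identifiers, same length as `mask`.
#' @param path File path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns a
#'   list with elements `mask` (a `gene_mask`) and `retained_ids`.
#' @export
write_mask <- function(mask, gene_ids, path) {
  mask <- gene_mask(mask)
  if (length(gene_ids) != length(mask)) {
    stop("gene_ids length must equal mask length", call. = FALSE)
  }
  lines <- c(paste(as.integer(mask), collapse = ""),
             gene_ids[as.integer(mask) == 1L])
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty mask file", call. = FALSE)
  chars <- strsplit(lines[[1L]], "")[[1L]]
  if (!all(chars %in% c("0", "1"))) {
    bad <- setdiff(unique(chars), c("0", "1"))
    stop(sprintf("malformed mask bit character(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  mask <- gene_mask(as.integer(chars))
  retained <- lines[-1L]
  retained <- retained[nzchar(retained)]
  if (length(retained) != mask_retained(mask)) {
    stop("mask file inconsistent: retained id count does not match one-bits",
         call. = FALSE)
  }
  list(mask = mask, retained_ids = retained)
}

#' Serialise / deserialise a shrunken-centroid model
#'
#' Writes a plain-text dump: a header with the class order, delta, s0 and the
#' per-class scales m_k, followed by a TSV table of per-gene statistics
#' (overall centroid, pooled SD, raw and shrunken centroids per class).
#' All numbers use 17 significant digits, so load(save(m)) reproduces the
#' model to double precision.
#'
#' @param model A `shrunken_centroid_model` from [fit_shrunken_centroids()].
#' @param path File path.
#' @return `write_shrunken_model()` returns `path` invisibly;
#'   `read_shrunken_model()` returns a `shrunken_centroid_model`.
#' @export
write_shrunken_model <- function(model, path) {
  stopifnot(inherits(model, "shrunken_centroid_model"))
  g17 <- function(x) sprintf("%.17g", x)
  K <- length(model$class_set)
  hdr <- c(paste0("#classes\t", paste(model$class_set, collapse = "\t")),
           paste0("#delta\t", g17(model$delta)),
           paste0("#s0\t", g17(model$s0)),
           paste0("#m_k\t", paste(g17(model$m_k), collapse = "\t")))
  tab <- cbind(model$gene_ids, g17(model$overall_centroid), g17(model$s_i),
               matrix(g17(model$centroids), ncol = K),
               matrix(g17(model$shrunken_centroids), ncol = K))
  header_row <- paste(c("gene_id", "overall", "s_i",
                        paste0("centroid_", model$class_set),
                        paste0("shrunken_", model$class_set)),
                      collapse = "\t")
  writeLines(c(hdr, header_row, apply(tab, 1L, paste, collapse = "\t")), path)
  invisible(path)
}

#' @rdname write_shrunken_model
#' @export
read_shrunken_model <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stopifnot(fields[[1L]][1L] == "#classes")
  class_set <- fields[[1L]][-1L]
  delta <- as.numeric(fields[[2L]][2L])
  s0 <- as.numeric(fields[[3L]][2L])
  m_k <- as.numeric(fields[[4L]][-1L])
  K <- length(class_set)
  body <- fields[-(1:5)]
  d <- length(body)
  gene_ids <- vapply(body, `[[`, "", 1L)
  num <- t(vapply(body, function(f) as.numeric(f[-1L]), numeric(2L + 2L * K)))
  overall <- num[, 1L]
  s_i <- num[, 2L]
  centroids <- num[, 2L + seq_len(K), drop = FALSE]
  shrunk <- num[, 2L + K + seq_len(K), drop = FALSE]
  dimnames(centroids) <- dimnames(shrunk) <- list(gene_ids, class_set)
  names(m_k) <- class_set
  # reconstruct the standardized distances from the stored centroids
  denom <- outer(s_i + s0, m_k)
  d_ik <- (centroids - overall) / denom
  d_ik[denom == 0] <- 0
  d_shrunk <- (shrunk - overall) / denom
  d_shrunk[denom == 0] <- 0
  structure(
    list(centroids = centroids, overall_centroid = stats::setNames(overall, gene_ids),
         class_set = class_set, gene_ids = gene_ids,
         m_k = m_k, s_i = stats::setNames(s_i, gene_ids), s0 = s0,
         d_ik = d_ik, delta = delta, d_shrunk = d_shrunk,
         shrunken_centroids = shrunk),
    class = c("shrunken_centroid_model", "centroid_model")
  )
}
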