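# tf-idf association weights: acupoints are the terms, diagnosis patterns the
# documents. tf is the raw co-occurrence count, idf down-weights acupoints
# used across many patterns, and each document's weight vector is
# L2-normalized so document length drops out.

idf_values <- function(df, n_docs, variant) {
  switch(variant,
    classic = log(n_docs / df),
    log10 = log10(n_docs / df),
    smoothed = log(n_docs / df) + 1,
    stop("unknown idf variant: ", variant, call. = FALSE)
  )
}

# Core weight computation on a plain counts matrix; kept free of S3 wrapping
# so the permutation loop can call it directly.
tfidf_weights <- function(counts, idf_variant = "classic") {
  df <- colSums(counts > 0)
  n_docs <- nrow(counts)
  idf <- ifelse(df > 0, idf_values(pmax(df, 1), n_docs, idf_variant), 0)
  w <- sweep(counts, 2L, idf, `*`)
  norms <- sqrt(rowSums(w^2))
  nz <- norms > 0
  w[nz, ] <- w[nz, , drop = FALSE] / norms[nz]
  w
}

#' Compute tf-idf association weights
#'
#' `weight[d, t] = tf[d, t] * idf(t)`, followed by L2 normalization of each
#' document (diagnosis) row; rows with no positive entry stay all-zero. The
#' default idf is the classic `ln(N / df_t)` with `N` the number of
#' documents and `df_t` the number of documents containing term `t`; under
#' it an acupoint present in every document scores 0 everywhere. `"log10"`
#' only rescales (L2 normalization makes it equivalent to classic);
#' `"smoothed"` (`ln(N / df) + 1`) keeps ubiquitous terms at positive
#' weight, which changes what survives the reporting threshold.
#'
#' @param mat A `cooccurrence_matrix` from [build_matrix()].
#' @param idf_variant `"classic"` (default), `"log10"`, or `"smoothed"`.
#' @return A `tfidf_matrix`: list with `weights`, `tf`, `df`, `n_docs`,
#'   `idf_variant`.
#' @export
compute_tfidf <- function(mat, idf_variant = c("classic", "log10", "smoothed")) {
  stopifnot(inherits(mat, "cooccurrence_matrix"))
  idf_variant <- match.arg(idf_variant)
  counts <- mat$counts
  structure(list(
    weights = tfidf_weights(counts, idf_variant),
    tf = counts,
    df = colSums(counts > 0),
    n_docs = nrow(counts),
    idf_variant = idf_variant
  ), class = "tfidf_matrix")
}

#' @export
print.tfidf_matrix <- function(x, ...) {
  cat("tf-idf matrix (", x$idf_variant, " idf): ", nrow(x$weights),
      " diagnosis documents x ", ncol(x$weights), " acupoint terms\n",
      sep = "")
  invisible(x)
}

#' Thresholded association table
#'
#' Rows `(diagnosis, acupoint, weight)` with weight strictly above
#' `min_value` (default 0.1, the conventional reporting cut for these
#' weights), sorted by weight descending with ties broken by canonical code
#' order.
#'
#' @param tfidf A `tfidf_matrix`.
#' @param min_value Strict lower bound on reported weights.
#' @return Tibble with columns `diagnosis`, `acupoint`, `weight`.
#' @export
threshold_associations <- function(tfidf, min_value = 0.1) {
  stopifnot(inherits(tfidf, "tfidf_matrix"), min_value >= 0)
  w <- tfidf$weights
  idx <- which(w > min_value, arr.ind = TRUE)
  out <- tibble::tibble(
    diagnosis = rownames(w)[idx[, 1]],
    acupoint = colnames(w)[idx[, 2]],
    weight = w[idx]
  )
  ord <- order(-out$weight, code_order(out$diagnosis), code_order(out$acupoint))
  out[ord, ]
}

#' Write the tf-idf weight matrix as a heatmap-ready CSV
#'
#' One row per diagnosis, one column per acupoint plus a leading `diagnosis`
#' label column; weights are written at full precision and round-trip
#' exactly. Optionally also renders a heatmap image when `image` is given
#' (requires the pheatmap package).
#'
#' @param tfidf A `tfidf_matrix`.
#' @param path CSV output path.
#' @param image Optional image file path (png/pdf) for a rendered heatmap.
#' @return The CSV path, invisibly.
#' @export
heatmap_matrix <- function(tfidf, path, image = NULL) {
  stopifnot(inherits(tfidf, "tfidf_matrix"))
  w <- tfidf$weights
  out <- tibble::as_tibble(as.data.frame(w))
  out <- tibble::add_column(out, diagnosis = rownames(w), .before = 1)
  readr::write_csv(out, path, progress = FALSE)
  if (!is.null(image)) {
    if (!requireNamespace("pheatmap", quietly = TRUE)) {
      stop("the pheatmap package is needed for image output", call. = FALSE)
    }
    pheatmap::pheatmap(w, cluster_rows = FALSE, cluster_cols = FALSE,
                       filename = image)
  }
  invisible(path)
}

#' Read back a heatmap CSV as a weight matrix
#'
#' @param path CSV written by [heatmap_matrix()].
#' @return Numeric matrix with diagnosis rownames.
#' @export
read_heatmap_csv <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    diagnosis = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$diagnosis
  m
}
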