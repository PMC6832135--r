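# Permutation null for tf-idf association weights. Pair instances are
# shuffled by permuting the acupoint column against the fixed diagnosis
# column, which preserves both marginal frequency vectors exactly; after
# each shuffle the contingency matrix and tf-idf weights are recomputed and
# per-cell exceedance counters updated (one-sided, upper tail).

#' Randomly permute the acupoint labels of a pair list
#'
#' The acupoint column becomes a uniform random permutation of its original
#' multiset against the fixed diagnosis column, so the diagnosis and
#' acupoint marginal totals of the rebuilt contingency matrix are exactly
#' those of the input.
#'
#' @param pairs Pair list (columns `diagnosis`, `acupoint`).
#' @return The pair list with `acupoint` permuted.
#' @export
permute_pairs <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("empty pair list", call. = FALSE)
  }
  pairs$acupoint <- pairs$acupoint[sample.int(nrow(pairs))]
  pairs
}

#' Permutation null distribution of tf-idf weights
#'
#' Runs `n_perm` marginal-preserving permutations; after each one the
#' contingency matrix and tf-idf weights are recomputed and each cell's
#' exceedance counter is incremented when the permuted weight is at least
#' the observed weight (ties count as exceedances, making the p-value
#' conservative). Counters are updated streaming, so memory does not grow
#' with `n_perm`. p-values use the add-one estimator
#' `(1 + exceed) / (1 + n_perm)`, bounded below by `1/(1 + n_perm)`.
#'
#' With `unit = "record"` the diagnosis labels are instead reassigned among
#' whole records (all of a record's points move together), a coarser null
#' that preserves the acupoint column exactly and the per-record diagnosis
#' assignment counts. With `pooled = TRUE` each observed weight is compared
#' against the pooled null of all cells rather than its own cell's null.
#'
#' @param pairs Pair list from [extract_pairs()].
#' @param n_perm Number of permutations B (default 10,000, the conventional
#'   choice).
#' @param seed RNG seed; identical `(pairs, n_perm, seed)` gives identical
#'   p-values. R's Mersenne-Twister generator is fixed for the permutation
#'   draws, so integer permutations reproduce across platforms.
#' @param idf_variant Passed to the tf-idf computation.
#' @param unit `"pair"` (default; shuffle pair instances) or `"record"`.
#' @param pooled Compare each cell against the pooled null of all cells.
#' @param alpha Significance level stored for downstream reporting.
#' @return A `permutation_result`: list with `observed` (the observed
#'   `tfidf_matrix`), `n_perm`, `exceed` (matrix), `p_values` (matrix),
#'   `alpha`, `seed`, `unit`, `pooled`.
#' @export
null_distribution <- function(pairs, n_perm = 10000L, seed = NULL,
                              idf_variant = "classic",
                              unit = c("pair", "record"),
                              pooled = FALSE, alpha = 0.05) {
  stopifnot(n_perm >= 1L)
  unit <- match.arg(unit)
  mat <- build_matrix(pairs)
  observed <- compute_tfidf(mat, idf_variant)
  w_obs <- observed$weights
  nd <- nrow(w_obs)
  na <- ncol(w_obs)
  di <- match(pairs$diagnosis, rownames(w_obs))
  ai <- match(pairs$acupoint, colnames(w_obs))
  n_pairs <- nrow(pairs)
  if (unit == "pair") {
    # canonicalize instance order so results depend on the pair multiset,
    # not on how the input rows happen to be ordered
    ord <- order(di, ai)
    di <- di[ord]
    ai <- ai[ord]
  }
  if (unit == "record") {
    refs <- pairs$record_ref
    if (is.null(refs)) stop("record-level permutation needs record_ref", call. = FALSE)
    rec_index <- match(refs, unique(refs))
    rec_diag <- di[!duplicated(rec_index)]
  }
  exceed <- matrix(0L, nd, na, dimnames = dimnames(w_obs))
  obs_vec <- as.vector(w_obs)
  if (pooled) {
    pooled_exceed <- numeric(nd * na)
  }
  with_seed_if(seed, {
    for (b in seq_len(n_perm)) {
      if (unit == "pair") {
        ai_b <- ai[sample.int(n_pairs)]
        di_b <- di
      } else {
        di_b <- rec_diag[sample.int(length(rec_diag))][rec_index]
        ai_b <- ai
      }
      counts_b <- matrix(tabulate(di_b + (ai_b - 1L) * nd, nbins = nd * na),
                         nd, na)
      w_b <- tfidf_weights(counts_b, idf_variant)
      exceed <- exceed + (w_b >= w_obs)
      if (pooled) {
        sv <- sort(as.vector(w_b))
        # permuted values >= each observed value, over the whole matrix
        pooled_exceed <- pooled_exceed +
          (length(sv) - findInterval(obs_vec, sv, left.open = TRUE))
      }
    }
  })
  p <- if (pooled) {
    matrix((1 + pooled_exceed) / (1 + as.numeric(n_perm) * nd * na),
           nd, na, dimnames = dimnames(w_obs))
  } else {
    (1 + exceed) / (1 + n_perm)
  }
  structure(list(
    observed = observed, n_perm = as.integer(n_perm), exceed = exceed,
    p_values = p, alpha = alpha, seed = seed, unit = unit, pooled = pooled
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test:", x$n_perm, "permutations (", x$unit,
      "level );", sum(x$p_values <= x$alpha), "cells with p <=", x$alpha, "\n")
  invisible(x)
}

#' Significant diagnosis-acupoint associations
#'
#' Cells whose (optionally multiplicity-adjusted) permutation p-value is at
#' most `alpha`, sorted by p-value then canonical code order. No adjustment
#' is applied by default; `"benjamini-hochberg"` (alias `"BH"`) applies the
#' false-discovery-rate step-up procedure over all cells.
#'
#' @param result A `permutation_result`.
#' @param alpha Significance level (defaults to the one stored in `result`).
#' @param correction `"none"`, `"benjamini-hochberg"`, or `"BH"`.
#' @return Tibble with columns `diagnosis`, `acupoint`, `weight`, `p_value`,
#'   `p_adjusted`.
#' @export
significant_associations <- function(result, alpha = result$alpha,
                                     correction = c("none",
                                                    "benjamini-hochberg",
                                                    "BH")) {
  stopifnot(inherits(result, "permutation_result"))
  correction <- match.arg(correction)
  p <- result$p_values
  p_adj <- if (correction == "none") {
    p
  } else {
    matrix(stats::p.adjust(as.vector(p), method = "BH"),
           nrow(p), ncol(p), dimnames = dimnames(p))
  }
  idx <- which(p_adj <= alpha, arr.ind = TRUE)
  out <- tibble::tibble(
    diagnosis = rownames(p)[idx[, 1]],
    acupoint = colnames(p)[idx[, 2]],
    weight = result$observed$weights[idx],
    p_value = p[idx],
    p_adjusted = p_adj[idx]
  )
  ord <- order(out$p_value, code_order(out$diagnosis), code_order(out$acupoint))
  out[ord, ]
}

#' Long-format p-value table
#'
#' @param result A `permutation_result`.
#' @return Tibble with one row per matrix cell: `diagnosis`, `acupoint`,
#'   `weight`, `exceed`, `p_value`, ordered canonically.
#' @export
pvalue_table <- function(result) {
  stopifnot(inherits(result, "permutation_result"))
  p <- result$p_values
  d <- rep(rownames(p), times = ncol(p))
  a <- rep(colnames(p), each = nrow(p))
  out <- tibble::tibble(
    diagnosis = d, acupoint = a,
    weight = as.vector(result$observed$weights),
    exceed = as.vector(result$exceed),
    p_value = as.vector(p)
  )
  out[order(code_order(out$diagnosis), code_order(out$acupoint)), ]
}
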