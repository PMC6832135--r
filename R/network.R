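# Diagnosis x acupoint contingency matrix, thresholded bipartite network and
# eigenvector centrality.

#' Build the diagnosis x acupoint co-occurrence matrix
#'
#' `counts[d, a]` is the number of pair instances `(d, a)`. Rows and columns
#' are in canonical code order.
#'
#' @param pairs Pair list from [extract_pairs()] (columns `diagnosis`,
#'   `acupoint`).
#' @return A `cooccurrence_matrix`: list with `counts` (integer matrix),
#'   `row_totals`, `col_totals`.
#' @export
build_matrix <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("empty pair list", call. = FALSE)
  }
  d_levels <- sort_codes(unique(pairs$diagnosis))
  a_levels <- sort_codes(unique(pairs$acupoint))
  di <- match(pairs$diagnosis, d_levels)
  ai <- match(pairs$acupoint, a_levels)
  counts <- matrix(
    tabulate(di + (ai - 1L) * length(d_levels),
             nbins = length(d_levels) * length(a_levels)),
    nrow = length(d_levels), ncol = length(a_levels),
    dimnames = list(diagnosis = d_levels, acupoint = a_levels)
  )
  new_cooccurrence_matrix(counts)
}

new_cooccurrence_matrix <- function(counts) {
  structure(list(
    counts = counts,
    row_totals = rowSums(counts),
    col_totals = colSums(counts)
  ), class = "cooccurrence_matrix")
}

#' Assemble a co-occurrence matrix from explicit counts
#'
#' Convenience constructor for printed contingency counts (e.g. frequency
#' tables from the literature) so [frequency_table()] arithmetic can be run
#' without the underlying pair list.
#'
#' @param counts Named integer matrix (diagnosis rows, acupoint columns).
#' @return A `cooccurrence_matrix`.
#' @export
cooccurrence_from_counts <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            !is.null(rownames(counts)), !is.null(colnames(counts)))
  new_cooccurrence_matrix(counts)
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat("Co-occurrence matrix:", nrow(x$counts), "diagnosis patterns x",
      ncol(x$counts), "acupoints;", sum(x$counts), "pair instances\n")
  invisible(x)
}

# Round half away from zero (commercial rounding), as used for printed
# percentage tables; base round() rounds half to even.
round_half_up <- function(x, digits = 1L) {
  scale <- 10^digits
  trunc(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale * sign(x)
}

#' Per-diagnosis top-k acupoint frequency table
#'
#' For each diagnosis, the `top_k` most frequent acupoints with raw counts
#' and percentages of the diagnosis's pair total, percentage rounded half-up
#' to one decimal. Ties in count are broken by canonical acupoint order.
#'
#' @param mat A `cooccurrence_matrix`.
#' @param top_k Number of acupoints per diagnosis (default 5).
#' @return Tibble with columns `diagnosis`, `row_total`, `rank`, `acupoint`,
#'   `count`, `percent`.
#' @export
frequency_table <- function(mat, top_k = 5L) {
  stopifnot(inherits(mat, "cooccurrence_matrix"), top_k >= 1L)
  counts <- mat$counts
  rows <- lapply(rownames(counts), function(d) {
    cnt <- counts[d, ]
    ord <- order(-cnt, code_order(colnames(counts)))
    k <- min(top_k, sum(cnt > 0))
    if (k == 0L) return(NULL)
    sel <- ord[seq_len(k)]
    tibble::tibble(
      diagnosis = d,
      row_total = unname(mat$row_totals[d]),
      rank = seq_len(k),
      acupoint = colnames(counts)[sel],
      count = unname(cnt[sel]),
      percent = round_half_up(100 * unname(cnt[sel]) / mat$row_totals[d], 1L)
    )
  })
  dplyr::bind_rows(rows)
}

#' Build the thresholded bipartite diagnosis-acupoint network
#'
#' Directed edges run from each diagnosis pattern to its associated
#' acupoints, weighted by the co-occurrence count; an edge is included iff
#' its count strictly exceeds `min_cooccurrence` (set `inclusive = TRUE` for
#' `>=`). Nodes left without any edge are removed.
#'
#' @param mat A `cooccurrence_matrix`.
#' @param min_cooccurrence Count threshold (default 10, strict).
#' @param inclusive Use `>=` instead of `>`.
#' @return An [igraph::igraph] with vertex attributes `name` and `type`
#'   (`"diagnosis"`/`"acupoint"`) and edge attribute `weight`. May have zero
#'   edges.
#' @export
build_network <- function(mat, min_cooccurrence = 10, inclusive = FALSE) {
  stopifnot(inherits(mat, "cooccurrence_matrix"), min_cooccurrence >= 0)
  counts <- mat$counts
  keep <- if (inclusive) counts >= min_cooccurrence else counts > min_cooccurrence
  idx <- which(keep, arr.ind = TRUE)
  d_names <- rownames(counts)[idx[, 1]]
  a_names <- colnames(counts)[idx[, 2]]
  vertices <- data.frame(
    name = c(sort_codes(unique(d_names)), sort_codes(unique(a_names))),
    stringsAsFactors = FALSE
  )
  vertices$type <- c(rep("diagnosis", length(unique(d_names))),
                     rep("acupoint", length(unique(a_names))))
  edges <- data.frame(from = d_names, to = a_names,
                      weight = counts[keep], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = vertices)
  igraph::graph_attr(g, "min_cooccurrence") <- min_cooccurrence
  igraph::graph_attr(g, "inclusive") <- inclusive
  g
}

# Power iteration for the Perron vector of a non-negative symmetric matrix.
# Bipartite adjacency spectra are symmetric about 0, so plain iteration on A
# oscillates; iterating on A/max(A) + I keeps the eigenvectors, makes the
# Perron eigenvalue strictly dominant, and is invariant to uniform weight
# scaling.
power_iteration <- function(A, tol = 1e-10, max_iter = 10000L) {
  n <- nrow(A)
  if (n == 1L) return(list(vector = 1, value = 0))
  s <- max(A)
  if (s <= 0) stop("component without positive edge weight", call. = FALSE)
  B <- A / s + diag(n)
  x <- rep(1 / sqrt(n), n)
  delta_prev <- Inf
  for (i in seq_len(max_iter)) {
    y <- as.vector(B %*% x)
    y <- y / sqrt(sum(y^2))
    delta <- max(abs(y - x))
    # successive changes contract geometrically with ratio r, so the
    # remaining distance to the limit is about delta * r / (1 - r); stop on
    # that estimate rather than on the raw step size
    r <- delta / delta_prev
    err_est <- if (is.finite(delta_prev) && r < 1) delta * r / (1 - r) else Inf
    if (delta == 0 || (delta < 1e-5 && err_est < tol)) {
      x <- abs(y)
      return(list(vector = x, value = as.vector(x %*% A %*% x)))
    }
    delta_prev <- delta
    x <- y
  }
  warning("power iteration did not converge within ", max_iter, " iterations")
  x <- abs(x)
  list(vector = x, value = as.vector(x %*% A %*% x))
}

#' Eigenvector centrality of the diagnosis-acupoint network
#'
#' Scores are the principal (Perron) eigenvector of the symmetrized weighted
#' adjacency matrix, computed by power iteration (tolerance `1e-10`, at most
#' 10,000 iterations). The directed diagnosis-to-acupoint edges are treated
#' as undirected: acupoints have zero out-degree, so directed eigenvector
#' centrality would be degenerate. On a disconnected network the Perron
#' vector is computed per connected component and the components are placed
#' on one global scale by weighting each component's vector by the ratio of
#' its spectral radius to the largest spectral radius; the final scores are
#' divided by the global maximum, so the top node of the dominant component
#' scores 1 whenever the network has at least one edge and satellite
#' components score proportionally lower.
#'
#' @param network Graph from [build_network()] (or any weighted igraph).
#' @param tol,max_iter Power-iteration controls.
#' @return Named numeric vector of scores in \[0, 1\], one per vertex.
#' @export
eigenvector_centrality <- function(network, tol = 1e-10, max_iter = 10000L) {
  if (igraph::ecount(network) == 0L) {
    stop("cannot compute centrality on a network with no edges", call. = FALSE)
  }
  g <- igraph::as_undirected(network, mode = "collapse",
                             edge.attr.comb = list(weight = "sum", "ignore"))
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  comp <- igraph::components(g)
  scores <- numeric(igraph::vcount(g))
  lambda <- numeric(comp$no)
  for (cid in seq_len(comp$no)) {
    idx <- which(comp$membership == cid)
    pi <- power_iteration(A[idx, idx, drop = FALSE], tol = tol,
                          max_iter = max_iter)
    lambda[cid] <- pi$value
    scores[idx] <- (pi$vector / max(pi$vector)) * pi$value
  }
  scores <- scores / max(scores)
  names(scores) <- igraph::V(g)$name
  scores
}

#' Export a network for Gephi
#'
#' Writes GEXF (the Gephi native exchange format) or GraphML, with node
#' `type` and `centrality` attributes and edge weights, re-importable
#' losslessly via [import_network()]. Centrality is computed on the fly when
#' the graph does not carry a `centrality` vertex attribute (and the graph
#' has edges).
#'
#' @param network Graph from [build_network()].
#' @param path Output file path.
#' @param format `"gexf"` (default) or `"graphml"`.
#' @return The path, invisibly.
#' @export
export_network <- function(network, path, format = c("gexf", "graphml")) {
  format <- match.arg(format)
  g <- network
  if (!("centrality" %in% igraph::vertex_attr_names(g))) {
    cent <- if (igraph::ecount(g) > 0L) {
      eigenvector_centrality(g)
    } else {
      stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
    }
    igraph::V(g)$centrality <- unname(cent[igraph::V(g)$name])
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  write_gexf(g, path)
}

write_gexf <- function(g, path) {
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", mode = "static",
                               defaultedgetype = "directed")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "type",
                      type = "string")
  xml2::xml_add_child(attrs, "attribute", id = "1", title = "centrality",
                      type = "double")
  nodes <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(igraph::vcount(g))) {
    nd <- xml2::xml_add_child(nodes, "node",
                              id = igraph::V(g)$name[i],
                              label = igraph::V(g)$name[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = igraph::V(g)$type[i])
    xml2::xml_add_child(av, "attvalue", `for` = "1",
                        value = format(igraph::V(g)$centrality[i],
                                       digits = 17, scientific = FALSE))
  }
  edges <- xml2::xml_add_child(graph, "edges")
  el <- igraph::as_data_frame(g, what = "edges")
  for (i in seq_len(nrow(el))) {
    xml2::xml_add_child(edges, "edge", id = as.character(i - 1L),
                        source = el$from[i], target = el$to[i],
                        weight = format(el$weight[i], digits = 17,
                                        scientific = FALSE))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Re-import an exported network
#'
#' @param path File written by [export_network()].
#' @param format `"gexf"` or `"graphml"`; guessed from the extension when
#'   missing.
#' @return An igraph with `name`, `type`, `centrality` vertex attributes and
#'   `weight` edge attribute.
#' @export
import_network <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "gexf"
  }
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  node_els <- xml2::xml_find_all(doc, ".//nodes/node")
  vertices <- data.frame(
    name = xml2::xml_attr(node_els, "id"),
    type = xml2::xml_attr(
      xml2::xml_find_first(node_els, "./attvalues/attvalue[@for='0']"), "value"),
    centrality = as.numeric(xml2::xml_attr(
      xml2::xml_find_first(node_els, "./attvalues/attvalue[@for='1']"), "value")),
    stringsAsFactors = FALSE
  )
  edge_els <- xml2::xml_find_all(doc, ".//edges/edge")
  edges <- data.frame(
    from = xml2::xml_attr(edge_els, "source"),
    to = xml2::xml_attr(edge_els, "target"),
    weight = as.numeric(xml2::xml_attr(edge_els, "weight")),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}
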