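# Independent oracles and fixture builders shared across the suite.

# Plain-loop tf-idf, kept deliberately naive and separate from the package's
# vectorized implementation.
oracle_tfidf <- function(counts, variant = "classic") {
  n_docs <- nrow(counts)
  w <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (t in seq_len(ncol(counts))) {
    df <- sum(counts[, t] > 0)
    if (df == 0) next
    idf <- switch(variant,
                  classic = log(n_docs / df),
                  log10 = log10(n_docs / df),
                  smoothed = log(n_docs / df) + 1)
    for (d in seq_len(n_docs)) w[d, t] <- counts[d, t] * idf
  }
  for (d in seq_len(n_docs)) {
    nrm <- sqrt(sum(w[d, ]^2))
    if (nrm > 0) w[d, ] <- w[d, ] / nrm
  }
  w
}

# Dense eigen-decomposition centrality oracle: Perron vector per connected
# component, components weighted by spectral radius, global max 1.
oracle_centrality <- function(g) {
  gu <- igraph::as_undirected(g, mode = "collapse",
                              edge.attr.comb = list(weight = "sum", "ignore"))
  A <- igraph::as_adjacency_matrix(gu, attr = "weight", sparse = FALSE)
  comp <- igraph::components(gu)
  scores <- numeric(nrow(A))
  for (cid in seq_len(comp$no)) {
    idx <- which(comp$membership == cid)
    if (length(idx) == 1L) next
    e <- eigen(A[idx, idx, drop = FALSE], symmetric = TRUE)
    v <- abs(e$vectors[, 1])
    scores[idx] <- v / max(v) * e$values[1]
  }
  scores <- scores / max(scores)
  names(scores) <- igraph::V(gu)$name
  scores
}

# Random weighted bipartite diagnosis-acupoint graph with <= max_nodes nodes.
random_bipartite_graph <- function(seed, max_nodes = 50L) {
  withr::with_seed(seed, {
    nd <- sample(2:10, 1L)
    na <- sample(2:(max_nodes - nd), 1L)
    repeat {
      keep <- matrix(stats::runif(nd * na) < 0.3, nd, na)
      if (any(keep)) break
    }
    idx <- which(keep, arr.ind = TRUE)
    edges <- data.frame(
      from = paste0("d", idx[, 1]),
      to = paste0("a", idx[, 2]),
      weight = stats::runif(nrow(idx), 1, 20)
    )
    vertices <- data.frame(
      name = c(unique(edges$from), unique(edges$to)),
      type = c(rep("diagnosis", length(unique(edges$from))),
               rep("acupoint", length(unique(edges$to))))
    )
    igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
  })
}

# Top-5 frequency rows printed for the five most frequent diagnosis patterns
# in the virtual-diagnosis study, used as an arithmetic fixture.
table2_fixture <- function() {
  tibble::tribble(
    ~diagnosis, ~row_total, ~acupoint, ~count, ~percent,
    "U61", 460, "ST36", 32, 7.0,
    "U61", 460, "ST35", 27, 5.9,
    "U61", 460, "LI4",  26, 5.7,
    "U61", 460, "SP6",  25, 5.4,
    "U61", 460, "SP10", 21, 4.6,
    "U62", 432, "LI4",  38, 8.8,
    "U62", 432, "ST36", 37, 8.6,
    "U62", 432, "LR3",  36, 8.3,
    "U62", 432, "KI3",  25, 5.8,
    "U62", 432, "SP6",  21, 4.9,
    "U71", 424, "KI3",  40, 9.4,
    "U71", 424, "SP6",  25, 5.9,
    "U71", 424, "KI7",  18, 4.2,
    "U71", 424, "BL23", 16, 3.8,
    "U71", 424, "LI4",  15, 3.5,
    "U65", 397, "LR3",  49, 12.3,
    "U65", 397, "LI4",  38, 9.6,
    "U65", 397, "CV17", 26, 6.5,
    "U65", 397, "GV20", 24, 6.0,
    "U65", 397, "SP6",  24, 6.0,
    "U63", 378, "ST36", 39, 10.3,
    "U63", 378, "LI4",  33, 8.7,
    "U63", 378, "CV12", 32, 8.5,
    "U63", 378, "PC6",  24, 6.3,
    "U63", 378, "ST40", 21, 5.6
  )
}

# Contingency matrix carrying the fixture counts, padded with filler acupoint
# columns (counts <= 14, below every row's fifth-ranked count) so each row
# total matches the printed diagnosis total without disturbing the top five.
table2_matrix <- function() {
  fix <- table2_fixture()
  diags <- unique(fix$diagnosis)
  points <- unique(fix$acupoint)
  totals <- tapply(fix$row_total, fix$diagnosis, unique)[diags]
  listed <- tapply(fix$count, fix$diagnosis, sum)[diags]
  n_fill <- max(ceiling((totals - listed) / 14))
  fillers <- setdiff(load_acupoint_registry(), points)[seq_len(n_fill)]
  counts <- matrix(0L, length(diags), length(points) + n_fill,
                   dimnames = list(diags, c(points, fillers)))
  for (i in seq_len(nrow(fix))) {
    counts[fix$diagnosis[i], fix$acupoint[i]] <- fix$count[i]
  }
  for (d in diags) {
    rem <- totals[[d]] - listed[[d]]
    k <- ceiling(rem / 14)
    fill <- c(rep(14L, k - 1L), rem - 14L * (k - 1L))
    counts[d, fillers[seq_len(k)]] <- as.integer(fill)
  }
  cooccurrence_from_counts(counts)
}

# Two-document toy: D1 = {A:2, B:1}, D2 = {B:3, C:1}, with acupoint stand-in
# codes LU1 (A), LU2 (B), LU3 (C).
toy_tfidf_matrix <- function() {
  counts <- matrix(c(2L, 0L, 1L, 3L, 0L, 1L), nrow = 2,
                   dimnames = list(c("U61", "U62"), c("LU1", "LU2", "LU3")))
  cooccurrence_from_counts(counts)
}

# Tiny coded record set for preprocessing tests.
tiny_records <- function() {
  tibble::tibble(
    doctor_id = c("d1", "d2"),
    case_id = c(1L, 1L),
    diagnosis = c("U61", "U61"),
    acupoints = list(c("LI4", "ST36"), c("ST36", "SP10", "ST35"))
  )
}

# Null cohort for calibration studies: 40 diagnosis codes spread over the 10
# case profiles, every diagnosis sharing one near-uniform 60-point acupoint
# distribution; the sparse regime keeps the tf-idf permutation null
# essentially atomless away from zero.
null_cohort_config <- function(seed) {
  dx <- sprintf("U%02d", 20:59)
  cp <- dplyr::bind_rows(lapply(1:10, function(cs) {
    tibble::tibble(case_id = cs,
                   diagnosis = dx[(cs - 1L) * 4L + 1:4],
                   prob = 0.25)
  }))
  pool <- load_acupoint_registry()[seq(1L, 355L, by = 6L)][1:60]
  pp <- tibble::tibble(
    diagnosis = rep(dx, each = 60L),
    acupoint = rep(pool, times = length(dx)),
    weight = 1 / 60
  )
  cohort_config(n_doctors = 80L, n_cases = 10L,
                case_profiles = cp, pattern_profiles = pp, seed = seed)
}

# All permutations of 1..n (recursive insertion), for exact enumeration
# oracles on tiny inputs.
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# Planted pattern-specific acupoints with elevated weight (0.25 each, three
# times the per-point common-pool weight) under high-prevalence diagnosis
# patterns in the default generator profiles. The kidney pattern (U71) is
# deliberately absent: its six specific points share the common-pool
# per-point weight, emulating a diffuse multi-point pattern rather than an
# elevated planted signal.
core_planted_pairs <- function() {
  tibble::tribble(
    ~diagnosis, ~acupoint,
    "U61", "ST35",
    "U61", "SP10",
    "U62", "KI3",
    "U62", "CV4",
    "U65", "CV17",
    "U65", "GV20",
    "U63", "ST40",
    "U63", "GB20",
    "U30", "GV3",
    "U30", "BL25"
  )
}
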