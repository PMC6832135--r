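test_that("the co-occurrence matrix counts pair instances directly", {
  pairs <- tibble::tibble(
    diagnosis = c("U61", "U61", "U61", "U62"),
    acupoint = c("LI4", "LI4", "ST36", "LI4")
  )
  mat <- build_matrix(pairs)
  expect_equal(mat$counts["U61", "LI4"], 2L)
  expect_equal(mat$counts["U61", "ST36"], 1L)
  expect_equal(mat$counts["U62", "LI4"], 1L)
  expect_equal(mat$counts["U62", "ST36"], 0L)
  expect_equal(unname(mat$row_totals), c(3L, 1L))
  expect_equal(unname(mat$col_totals), c(3L, 1L))
  expect_error(build_matrix(pairs[0, ]), "empty")
})

test_that("total counts are conserved and invariant to pair order", {
  rec <- generate_cohort(cohort_config(n_doctors = 10L, seed = 41))
  pairs <- extract_pairs(rec)
  mat <- build_matrix(pairs)
  expect_equal(sum(mat$counts), nrow(pairs))
  expect_equal(unname(mat$row_totals), unname(rowSums(mat$counts)))
  expect_equal(unname(mat$col_totals), unname(colSums(mat$counts)))
  mat2 <- build_matrix(pairs[withr::with_seed(1, sample.int(nrow(pairs))), ])
  expect_identical(mat2$counts, mat$counts)
})

test_that("frequency percentages reproduce printed-table arithmetic", {
  freq <- frequency_table(table2_matrix(), top_k = 5L)
  fix <- table2_fixture()
  merged <- dplyr::inner_join(fix, freq, by = c("diagnosis", "acupoint"),
                              suffix = c(".fix", ".got"))
  expect_equal(nrow(merged), nrow(fix))
  expect_equal(merged$count.got, merged$count.fix)
  expect_equal(merged$percent.got, merged$percent.fix)
  expect_equal(merged$row_total.got, merged$row_total.fix)
})

test_that("percentages round half-up to one decimal", {
  counts <- matrix(c(5L, 75L), 1, 2, dimnames = list("U61", c("LI4", "ST36")))
  freq <- frequency_table(cooccurrence_from_counts(counts), top_k = 2L)
  # 5/80 = 6.25% -> 6.3 under half-up (banker's rounding would give 6.2)
  expect_equal(freq$percent[freq$acupoint == "LI4"], 6.3)
  expect_equal(freq$percent[freq$acupoint == "ST36"], 93.8)
  counts0 <- matrix(c(0L, 10L), 1, 2, dimnames = list("U61", c("LI4", "ST36")))
  freq0 <- frequency_table(cooccurrence_from_counts(counts0), top_k = 2L)
  expect_false("LI4" %in% freq0$acupoint)  # zero-count points not listed
})

test_that("the edge threshold is strict and monotone", {
  counts <- matrix(c(10L, 11L, 3L, 25L), 2, 2,
                   dimnames = list(c("U61", "U62"), c("LI4", "ST36")))
  mat <- cooccurrence_from_counts(counts)
  net <- build_network(mat, min_cooccurrence = 10)
  el <- igraph::as_data_frame(net)
  expect_equal(nrow(el), 2L)  # only the 11 and 25 cells
  expect_setequal(el$weight, c(11, 25))
  expect_false("LI4" %in% igraph::V(net)$name[igraph::V(net)$type == "acupoint"] &&
                 any(el$weight == 10))

  inc <- build_network(mat, min_cooccurrence = 10, inclusive = TRUE)
  expect_equal(igraph::ecount(inc), 3L)

  empty <- build_network(mat, min_cooccurrence = 25)
  expect_equal(igraph::ecount(empty), 0L)
  expect_equal(igraph::vcount(empty), 0L)

  for (thr in c(0, 5, 12, 20)) {
    lo <- igraph::ecount(build_network(mat, thr))
    hi <- igraph::ecount(build_network(mat, thr + 1))
    expect_lte(hi, lo)
  }
})

test_that("star-graph centrality matches the closed form", {
  edges <- data.frame(from = paste0("d", 1:4), to = "ST36", weight = 1)
  vertices <- data.frame(name = c(paste0("d", 1:4), "ST36"),
                         type = c(rep("diagnosis", 4), "acupoint"))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = vertices)
  cent <- eigenvector_centrality(g)
  expect_equal(unname(cent["ST36"]), 1, tolerance = 1e-9)
  expect_equal(unname(cent[paste0("d", 1:4)]), rep(0.5, 4), tolerance = 1e-9)

  single <- igraph::graph_from_data_frame(
    data.frame(from = "d1", to = "LI4", weight = 7), directed = TRUE,
    vertices = data.frame(name = c("d1", "LI4"),
                          type = c("diagnosis", "acupoint")))
  expect_equal(unname(eigenvector_centrality(single)), c(1, 1),
               tolerance = 1e-9)
})

test_that("power iteration matches the dense eigen oracle on random graphs", {
  for (s in 1:20) {
    g <- random_bipartite_graph(1000L + s)
    cent <- eigenvector_centrality(g)
    oracle <- oracle_centrality(g)
    expect_lt(max(abs(cent[names(oracle)] - oracle)), 1e-8)
  }
})

test_that("centrality is invariant to relabeling and uniform weight scaling", {
  g <- random_bipartite_graph(77L)
  cent <- eigenvector_centrality(g)

  g2 <- g
  igraph::V(g2)$name <- paste0("x_", igraph::V(g)$name)
  cent2 <- eigenvector_centrality(g2)
  expect_equal(unname(cent2[paste0("x_", names(cent))]), unname(cent),
               tolerance = 1e-9)

  g3 <- g
  igraph::E(g3)$weight <- igraph::E(g)$weight * 13.7
  cent3 <- eigenvector_centrality(g3)
  expect_equal(unname(cent3[names(cent)]), unname(cent), tolerance = 1e-8)

  expect_error(eigenvector_centrality(
    igraph::make_empty_graph(n = 2)), "no edges")
})

test_that("exports are schema-sane and round-trip losslessly", {
  counts <- matrix(c(12L, 0L, 11L, 15L), 2, 2,
                   dimnames = list(c("U61", "U62"), c("LI4", "ST36")))
  net <- build_network(cooccurrence_from_counts(counts), 10)

  gexf <- withr::local_tempfile(fileext = ".gexf")
  export_network(net, gexf, "gexf")
  doc <- xml2::read_xml(gexf)
  xml2::xml_ns_strip(doc)
  expect_equal(length(xml2::xml_find_all(doc, ".//nodes/node")), 4L)
  expect_equal(length(xml2::xml_find_all(doc, ".//edges/edge")), 3L)

  back <- import_network(gexf)
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  el0 <- igraph::as_data_frame(net)[, c("from", "to", "weight")]
  el1 <- igraph::as_data_frame(back)[, c("from", "to", "weight")]
  expect_equal(el1[order(el1$from, el1$to), ], el0[order(el0$from, el0$to), ],
               ignore_attr = TRUE)
  cent <- eigenvector_centrality(net)
  expect_equal(unname(igraph::V(back)$centrality),
               unname(cent[igraph::V(back)$name]), tolerance = 1e-12)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back2 <- import_network(gml)
  el2 <- igraph::as_data_frame(back2)[, c("from", "to", "weight")]
  expect_equal(el2[order(el2$from, el2$to), ], el0[order(el0$from, el0$to), ],
               ignore_attr = TRUE)
  expect_setequal(igraph::V(back2)$type, igraph::V(net)$type)
})
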