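# One-command driver: generation/ingestion -> preprocessing -> network ->
# tf-idf -> permutation test -> report bundle.

#' Configure a pipeline run
#'
#' Defaults mirror the conventional analysis settings: co-occurrence edges
#' kept when the count exceeds 10, associations reported when the tf-idf
#' weight exceeds 0.1, 10,000 permutations, alpha 0.05, no multiplicity
#' correction.
#'
#' @param input `"synthetic"` (generate a cohort), or a path to a coded or
#'   raw cohort CSV.
#' @param input_kind `"synthetic"`, `"coded"`, or `"raw"`; inferred as
#'   `"synthetic"` when `input` is NULL, `"coded"` otherwise.
#' @param cohort A [cohort_config()] for synthetic input (default config
#'   when omitted; its seed is overridden by `seed`).
#' @param synonyms Synonym table (or path to its CSV) for raw input.
#' @param min_cooccurrence,inclusive Network edge threshold, see
#'   [build_network()].
#' @param tfidf_threshold Association reporting threshold, see
#'   [threshold_associations()].
#' @param idf_variant idf flavour, see [compute_tfidf()].
#' @param n_perm,alpha,correction,perm_unit,pooled Permutation-test settings,
#'   see [null_distribution()] and [significant_associations()].
#' @param seed Master seed: drives cohort generation and the permutation
#'   test.
#' @param out_dir Output directory (created if needed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, input_kind = NULL, cohort = NULL,
                            synonyms = NULL, min_cooccurrence = 10,
                            inclusive = FALSE, tfidf_threshold = 0.1,
                            idf_variant = "classic", n_perm = 10000L,
                            alpha = 0.05, correction = "none",
                            perm_unit = "pair", pooled = FALSE,
                            seed = NULL, out_dir = tempfile("acupairs_run_")) {
  if (is.null(input_kind)) {
    input_kind <- if (is.null(input)) "synthetic" else "coded"
  }
  input_kind <- match.arg(input_kind, c("synthetic", "coded", "raw"))
  stopifnot(min_cooccurrence >= 0, tfidf_threshold >= 0, n_perm >= 1)
  if (is.character(synonyms)) synonyms <- read_synonym_table(synonyms)
  if (input_kind == "synthetic" && is.null(cohort)) cohort <- cohort_config()
  structure(list(
    input = input, input_kind = input_kind, cohort = cohort,
    synonyms = synonyms, min_cooccurrence = min_cooccurrence,
    inclusive = inclusive, tfidf_threshold = tfidf_threshold,
    idf_variant = idf_variant, n_perm = as.integer(n_perm), alpha = alpha,
    correction = correction, perm_unit = perm_unit, pooled = pooled,
    seed = seed, out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `cohort`
#' block mirrors [cohort_config()] scalar arguments.
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$cohort)) {
    vals$cohort <- do.call(cohort_config, vals$cohort)
  }
  over <- list(...)
  vals[names(over)] <- over
  do.call(pipeline_config, vals)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Per-case diagnosis prevalence table
#'
#' For each case, how often each diagnosis was assigned, as a percentage of
#' the case's records (rounded half-up to one decimal), most frequent first.
#'
#' @param records Coded records with `case_id` and `diagnosis`.
#' @return Tibble with columns `case_id`, `diagnosis`, `n`, `percent`.
#' @export
case_prevalence <- function(records) {
  out <- dplyr::count(records, .data$case_id, .data$diagnosis, name = "n")
  out <- dplyr::mutate(dplyr::group_by(out, .data$case_id),
                       percent = round_half_up(100 * .data$n / sum(.data$n), 1L))
  out <- dplyr::arrange(dplyr::ungroup(out), .data$case_id, -.data$n,
                        .data$diagnosis)
  out
}

#' Run the full association pipeline
#'
#' Chains input acquisition, cleaning, pair extraction, the co-occurrence
#' network with eigenvector centrality, tf-idf association scoring, and the
#' permutation significance test, writing a report bundle to
#' `config$out_dir`:
#'
#' * `cleaning_report.json`, `pairs.csv`
#' * `case_prevalence.csv`, `frequency_table.csv` (top-5 acupoints per
#'   diagnosis)
#' * `network.gexf`, `centrality.csv`
#' * `tfidf_heatmap.csv`, `associations.csv`
#' * `pvalues.csv`, `significant.csv`
#' * `run_metadata.json` (all parameters, seed, package version)
#'
#' Reruns with an identical configuration produce bit-identical CSV/JSON
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)

  raw <- pipeline_stage("input", switch(config$input_kind,
    synthetic = {
      cc <- config$cohort
      if (!is.null(config$seed)) cc$seed <- config$seed
      generate_cohort(cc)
    },
    coded = read_cohort_csv(config$input),
    raw = read_cohort_csv(config$input)
  ))
  cleaned <- pipeline_stage("preprocess",
                            clean_records(raw, table = config$synonyms))
  records <- cleaned$records
  pairs <- pipeline_stage("preprocess", extract_pairs(records))
  write_cleaning_report(cleaned$report, path("cleaning_report.json"))
  write_pairs_csv(pairs, path("pairs.csv"))

  readr::write_csv(case_prevalence(records), path("case_prevalence.csv"),
                   progress = FALSE)
  mat <- pipeline_stage("network", build_matrix(pairs))
  readr::write_csv(frequency_table(mat, top_k = 5L),
                   path("frequency_table.csv"), progress = FALSE)
  net <- pipeline_stage("network",
                        build_network(mat, config$min_cooccurrence,
                                      config$inclusive))
  cent <- if (igraph::ecount(net) > 0L) {
    eigenvector_centrality(net)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  if (length(cent) > 0L) {
    igraph::V(net)$centrality <- unname(cent[igraph::V(net)$name])
  }
  pipeline_stage("network", export_network(net, path("network.gexf"), "gexf"))
  cent_tab <- tibble::tibble(
    node = igraph::V(net)$name,
    type = igraph::V(net)$type,
    centrality = if (length(cent) > 0L) unname(cent[igraph::V(net)$name]) else numeric(0)
  )
  readr::write_csv(cent_tab[order(-cent_tab$centrality, cent_tab$node), ],
                   path("centrality.csv"), progress = FALSE)

  tfidf <- pipeline_stage("tfidf", compute_tfidf(mat, config$idf_variant))
  heatmap_matrix(tfidf, path("tfidf_heatmap.csv"))
  readr::write_csv(threshold_associations(tfidf, config$tfidf_threshold),
                   path("associations.csv"), progress = FALSE)

  perm <- pipeline_stage("permtest",
    null_distribution(pairs, n_perm = config$n_perm, seed = config$seed,
                      idf_variant = config$idf_variant,
                      unit = config$perm_unit, pooled = config$pooled,
                      alpha = config$alpha))
  readr::write_csv(pvalue_table(perm), path("pvalues.csv"), progress = FALSE)
  readr::write_csv(
    significant_associations(perm, config$alpha, config$correction),
    path("significant.csv"), progress = FALSE)

  meta <- list(
    package = "acupairs",
    version = as.character(utils::packageVersion("acupairs")),
    input_kind = config$input_kind,
    min_cooccurrence = config$min_cooccurrence,
    inclusive = config$inclusive,
    tfidf_threshold = config$tfidf_threshold,
    idf_variant = config$idf_variant,
    n_perm = config$n_perm,
    alpha = config$alpha,
    correction = config$correction,
    perm_unit = config$perm_unit,
    pooled = config$pooled,
    seed = config$seed
  )
  jsonlite::write_json(meta, path("run_metadata.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  artifacts <- c("cleaning_report.json", "pairs.csv", "case_prevalence.csv",
                 "frequency_table.csv", "network.gexf", "centrality.csv",
                 "tfidf_heatmap.csv", "associations.csv", "pvalues.csv",
                 "significant.csv", "run_metadata.json")
  invisible(list(
    records = records, report = cleaned$report, pairs = pairs, matrix = mat,
    network = net, centrality = cent, tfidf = tfidf, permutation = perm,
    paths = stats::setNames(file.path(config$out_dir, artifacts), artifacts)
  ))
}
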