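# Raw rows -> validated coded records -> diagnosis-acupoint pair list.
# Everything downstream (contingency matrix, network, tf-idf, permutation
# test) consumes the pair list produced here.

#' Clean raw prescription rows into coded records
#'
#' Normalizes every diagnosis and acupoint term against the controlled
#' vocabularies (via the synonym table for free-text terms), drops acupoints
#' that do not resolve to one of the 361 codes on the 14 meridians (counting
#' drops by reason), collapses duplicate acupoints within a record, and drops
#' records left with no valid diagnosis or no valid acupoints. All losses are
#' recorded in the returned cleaning report.
#'
#' @param raw Tibble with columns `doctor_id`, `case_id`, `diagnosis`,
#'   `acupoints` (`;`-separated string, or list-column of codes), as read by
#'   [read_cohort_csv()].
#' @param table Synonym table (see [read_synonym_table()]) or `NULL`.
#' @param collapse_duplicates Collapse repeated acupoints within a record
#'   (default `TRUE`: a prescription is a set of points).
#' @return List with elements `records` (tibble `doctor_id, case_id,
#'   record_ref, diagnosis, acupoints` list-column) and `report` (a
#'   `cleaning_report`).
#' @export
clean_records <- function(raw, table = NULL, collapse_duplicates = TRUE) {
  needed <- c("doctor_id", "case_id", "diagnosis", "acupoints")
  missing_col <- setdiff(needed, names(raw))
  if (length(missing_col) > 0L) {
    stop("raw records lack column(s): ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  }
  raw <- tibble::as_tibble(raw)
  n_in <- nrow(raw)
  point_lists <- if (is.list(raw$acupoints)) {
    raw$acupoints
  } else {
    strsplit(as.character(raw$acupoints), ";", fixed = TRUE)
  }
  bad_row <- vapply(point_lists, function(p) {
    length(p) == 0L || any(trimws(p) == "")
  }, logical(1)) | is.na(raw$diagnosis) | trimws(raw$diagnosis) == ""
  if (any(bad_row)) {
    stop("malformed record row(s): ", paste(which(bad_row), collapse = ", "),
         call. = FALSE)
  }

  dx <- normalize_diagnosis(raw$diagnosis, table)
  drop_reasons <- c()
  kept <- vector("list", n_in)
  keep_row <- logical(n_in)
  dropped_records <- 0L
  for (i in seq_len(n_in)) {
    if (dx$status[i] != "ok") {
      dropped_records <- dropped_records + 1L
      next
    }
    pts <- normalize_acupoint(point_lists[[i]], table)
    rej <- pts$reason[pts$status != "ok"]
    for (r in rej) {
      drop_reasons[r] <- sum(drop_reasons[r], 1L, na.rm = TRUE)
    }
    codes <- pts$code[pts$status == "ok"]
    if (collapse_duplicates) codes <- unique(codes)
    if (length(codes) == 0L) {
      dropped_records <- dropped_records + 1L
      next
    }
    keep_row[i] <- TRUE
    kept[[i]] <- sort_codes(codes)
  }

  records <- tibble::tibble(
    doctor_id = as.character(raw$doctor_id[keep_row]),
    case_id = raw$case_id[keep_row],
    record_ref = paste0(raw$doctor_id[keep_row], ":", raw$case_id[keep_row],
                        ":", which(keep_row)),
    diagnosis = dx$code[keep_row],
    acupoints = kept[keep_row]
  )
  n_points <- vapply(records$acupoints, length, integer(1))
  pairs <- extract_pairs(records)
  report <- structure(list(
    n_input_records = n_in,
    n_kept_records = nrow(records),
    n_dropped_records = dropped_records,
    n_dropped_points = as.list(drop_reasons),
    n_pair_instances = sum(n_points),
    n_unique_pairs = nrow(unique(pairs[, c("diagnosis", "acupoint")]))
  ), class = "cleaning_report")
  list(records = records, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:\n")
  cat("  records in/kept/dropped:", x$n_input_records, "/", x$n_kept_records,
      "/", x$n_dropped_records, "\n")
  if (length(x$n_dropped_points) > 0L) {
    cat("  points dropped:",
        paste(names(x$n_dropped_points), unlist(x$n_dropped_points),
              sep = "=", collapse = ", "), "\n")
  } else {
    cat("  points dropped: none\n")
  }
  cat("  pair instances:", x$n_pair_instances,
      " unique pairs:", x$n_unique_pairs, "\n")
  invisible(x)
}

#' Extract diagnosis-acupoint pair instances
#'
#' One row per (record, acupoint): the unit of counting and of permutation.
#' Ordering is record order, then canonical acupoint code order within a
#' record, so the output is stable.
#'
#' @param records Coded records (tibble with `diagnosis`, list-column
#'   `acupoints`, and optionally `record_ref`).
#' @return Tibble with columns `diagnosis`, `acupoint`, `record_ref`.
#' @export
#' @examples
#' recs <- tibble::tibble(diagnosis = "U61",
#'                        acupoints = list(c("ST36", "LI4")),
#'                        record_ref = "r1")
#' extract_pairs(recs)  # LI4 row first (canonical order)
extract_pairs <- function(records) {
  n_points <- vapply(records$acupoints, length, integer(1))
  refs <- if ("record_ref" %in% names(records)) {
    records$record_ref
  } else {
    paste0("r", seq_len(nrow(records)))
  }
  tibble::tibble(
    diagnosis = rep(records$diagnosis, n_points),
    acupoint = unlist(lapply(records$acupoints, sort_codes), use.names = FALSE),
    record_ref = rep(refs, n_points)
  )
}

#' Write a pair list to CSV
#'
#' @param pairs Tibble from [extract_pairs()].
#' @param path File path.
#' @export
write_pairs_csv <- function(pairs, path) {
  readr::write_csv(pairs, path, progress = FALSE)
  invisible(path)
}

#' Write a cleaning report to JSON
#'
#' @param report A `cleaning_report` from [clean_records()].
#' @param path File path.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
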