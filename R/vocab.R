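# Controlled vocabularies: WHO standard acupoint codes on the 14 meridians and
# ICD-10-style diagnosis codes (Korean-medicine pattern U codes U20-U99 and
# symptom R codes).

# Highest point number on each of the 14 meridians (12 organ meridians plus
# the Conception Vessel CV and Governing Vessel GV); 361 codes in total.
MERIDIAN_LIMITS <- c(
  LU = 11L, LI = 20L, ST = 45L, SP = 21L, HT = 9L, SI = 19L, BL = 67L,
  KI = 27L, PC = 9L, TE = 23L, GB = 44L, LR = 14L, CV = 24L, GV = 28L
)

#' The WHO standard acupoint registry
#'
#' Enumerates every acupoint code on the 14 meridians (the 12 organ meridians
#' plus the Conception Vessel and Governing Vessel), `"LU1"` through `"GV28"`.
#' Points off these meridians (auricular points, anatomical trigger points,
#' extra points) are outside the registry and are rejected by
#' [normalize_acupoint()].
#'
#' @return Character vector of the 361 registry codes in canonical order
#'   (meridian alphabetical, then point number).
#' @export
#' @examples
#' reg <- load_acupoint_registry()
#' length(reg)        # 361
#' "ST36" %in% reg    # TRUE
load_acupoint_registry <- function() {
  meridians <- names(MERIDIAN_LIMITS)[order(names(MERIDIAN_LIMITS))]
  unlist(lapply(meridians, function(m) {
    paste0(m, seq_len(MERIDIAN_LIMITS[[m]]))
  }), use.names = FALSE)
}

#' Test whether strings are valid registry acupoint codes
#'
#' @param x Character vector of candidate codes (already canonical form:
#'   upper-case meridian prefix immediately followed by the point number).
#' @return Logical vector.
#' @export
is_acupoint_code <- function(x) {
  m <- regmatches(x, regexec("^([A-Z]{2})([0-9]{1,2})$", x))
  vapply(m, function(parts) {
    if (length(parts) != 3L) return(FALSE)
    mer <- parts[[2]]
    num <- as.integer(parts[[3]])
    mer %in% names(MERIDIAN_LIMITS) && num >= 1L && num <= MERIDIAN_LIMITS[[mer]]
  }, logical(1))
}

#' Test whether strings are valid diagnosis codes
#'
#' Valid codes are the Korean-medicine pattern codes `U20`--`U99` and symptom
#' codes `R00`--`R99`.
#'
#' @param x Character vector of candidate codes.
#' @return Logical vector.
#' @export
is_diagnosis_code <- function(x) {
  ok <- grepl("^[UR][0-9]{2}$", x)
  num <- suppressWarnings(as.integer(substr(x, 2, 3)))
  ok & ifelse(substr(x, 1, 1) == "U", !is.na(num) & num >= 20L, ok)
}

#' Family of a diagnosis code
#'
#' @param code Character vector of valid diagnosis codes.
#' @return `"U-pattern"` for U codes, `"R-symptom"` for R codes.
#' @export
diagnosis_family <- function(code) {
  ifelse(substr(code, 1, 1) == "R", "R-symptom", "U-pattern")
}

# Canonical form of a raw acupoint-like string: trim, upper-case, drop internal
# whitespace, rewrite the SJ (San Jiao) meridian alias to WHO-standard TE.
canonicalize_point_string <- function(raw) {
  x <- toupper(gsub("[[:space:]]+", "", raw))
  sub("^SJ([0-9])", "TE\\1", x)
}

#' An empty synonym table
#'
#' @return Zero-row tibble with columns `raw_term`, `code`, `kind`.
#' @export
empty_synonym_table <- function() {
  tibble::tibble(raw_term = character(), code = character(), kind = character())
}

#' Read a synonym table from CSV
#'
#' The CSV maps free-text terms to registry codes and must have a header
#' `raw_term,code,kind` with `kind` one of `"acupoint"` or `"diagnosis"`.
#' Every target code is validated against the corresponding registry; an
#' invalid target is an error, so a loaded table is always closed over the
#' registries.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return Tibble with columns `raw_term`, `code`, `kind`.
#' @export
read_synonym_table <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_synonym_table(tab)
}

#' Validate a synonym table
#'
#' @param tab Data frame with columns `raw_term`, `code`, `kind`.
#' @return The table as a tibble, with codes canonicalized.
#' @export
validate_synonym_table <- function(tab) {
  needed <- c("raw_term", "code", "kind")
  if (!all(needed %in% names(tab))) {
    stop("synonym table must have columns raw_term, code, kind", call. = FALSE)
  }
  tab <- tibble::as_tibble(tab[needed])
  if (!all(tab$kind %in% c("acupoint", "diagnosis"))) {
    stop("synonym table 'kind' must be 'acupoint' or 'diagnosis'", call. = FALSE)
  }
  is_acu <- tab$kind == "acupoint"
  tab$code[is_acu] <- canonicalize_point_string(tab$code[is_acu])
  tab$code[!is_acu] <- toupper(trimws(tab$code[!is_acu]))
  bad <- (is_acu & !is_acupoint_code(tab$code)) |
    (!is_acu & !is_diagnosis_code(tab$code))
  if (any(bad)) {
    stop("synonym table targets outside the registries: ",
         paste(unique(tab$code[bad]), collapse = ", "), call. = FALSE)
  }
  tab
}

# Shared normalization driver. Returns tibble(raw, code, status, reason).
normalize_terms <- function(raw, table, kind) {
  if (length(raw) == 0L) {
    return(tibble::tibble(raw = character(), code = character(),
                          status = character(), reason = character()))
  }
  trimmed <- trimws(raw)
  if (any(is.na(trimmed) | trimmed == "")) {
    stop("empty term passed to normalize_", kind, call. = FALSE)
  }
  code <- rep(NA_character_, length(raw))
  status <- rep("rejected", length(raw))
  reason <- rep(NA_character_, length(raw))

  if (kind == "acupoint") {
    cand <- canonicalize_point_string(trimmed)
    ok <- is_acupoint_code(cand)
    looks_coded <- grepl("^[A-Z]{2}[0-9]{1,2}$", cand) &
      substr(cand, 1, 2) %in% names(MERIDIAN_LIMITS)
  } else {
    cand <- toupper(gsub("[[:space:]]+", "", trimmed))
    ok <- is_diagnosis_code(cand)
    looks_coded <- grepl("^[A-Z][0-9]{2}$", cand) & substr(cand, 1, 1) %in% c("U", "R")
  }
  code[ok] <- cand[ok]
  status[ok] <- "ok"
  reason[looks_coded & !ok] <- "out-of-range"

  # table lookup for what did not resolve canonically (case-insensitive)
  todo <- which(!ok & !looks_coded)
  if (length(todo) > 0L && !is.null(table) && nrow(table) > 0L) {
    sub <- table[table$kind == kind, , drop = FALSE]
    hit <- match(tolower(trimmed[todo]), tolower(sub$raw_term))
    found <- !is.na(hit)
    code[todo[found]] <- sub$code[hit[found]]
    status[todo[found]] <- "ok"
    todo <- todo[!found]
  }
  if (length(todo) > 0L) {
    non_meridian <- grepl("auricul|trigger|ashi|ear point", tolower(trimmed[todo]))
    reason[todo] <- ifelse(non_meridian, "non-meridian", "unmapped")
  }
  tibble::tibble(raw = raw, code = code, status = status, reason = reason)
}

#' Normalize raw acupoint terms to WHO standard codes
#'
#' Canonical code strings (`"ST36"`, `"st 36"`, the `SJ` alias for the TE
#' meridian) resolve without a table entry; anything else is looked up
#' case-insensitively in the synonym table. Terms that resolve to nothing are
#' rejected with a reason tag rather than raising, so preprocessing can count
#' and log drops: `"out-of-range"` for a meridian code beyond the meridian's
#' highest point, `"non-meridian"` for recognisable off-meridian terms
#' (auricular points, trigger points, Ashi points), `"unmapped"` otherwise.
#'
#' @param raw Character vector of raw terms; empty strings are an error.
#' @param table Synonym table (see [read_synonym_table()]) or `NULL`.
#' @return Tibble with columns `raw`, `code` (NA when rejected), `status`
#'   (`"ok"`/`"rejected"`), `reason`.
#' @export
#' @examples
#' normalize_acupoint(c("ST36", "st 36", "SJ5", "ST46"))
normalize_acupoint <- function(raw, table = NULL) {
  normalize_terms(raw, table, "acupoint")
}

#' Normalize raw diagnosis terms to ICD-10-style codes
#'
#' Canonical `U20`--`U99` and `R00`--`R99` codes pass through; other terms are
#' looked up in the synonym table. `U00`--`U19` are rejected as
#' `"out-of-range"` (the Korean-medicine pattern block starts at U20).
#'
#' @inheritParams normalize_acupoint
#' @return Tibble with columns `raw`, `code`, `family` (`"U-pattern"` or
#'   `"R-symptom"`, NA when rejected), `status`, `reason`.
#' @export
#' @examples
#' normalize_diagnosis(c("U61", "U19"))
normalize_diagnosis <- function(raw, table = NULL) {
  out <- normalize_terms(raw, table, "diagnosis")
  out$family <- ifelse(out$status == "ok", diagnosis_family(out$code), NA_character_)
  out[, c("raw", "code", "family", "status", "reason")]
}

#' Canonical ordering of codes
#'
#' Orders acupoint codes by (meridian, point number) and diagnosis codes by
#' (letter, number), so e.g. `ST4` sorts before `ST36`. This is the ordering
#' used for matrix rows/columns and for tie-breaking throughout the package.
#'
#' @param codes Character vector of valid codes (all acupoints or all
#'   diagnoses).
#' @return Integer permutation, as from [order()].
#' @export
code_order <- function(codes) {
  prefix <- sub("[0-9]+$", "", codes)
  num <- as.integer(sub("^[A-Z]+", "", codes))
  order(prefix, num)
}

#' @rdname code_order
#' @return `sort_codes()`: the codes sorted canonically.
#' @export
sort_codes <- function(codes) {
  codes[code_order(codes)]
}
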