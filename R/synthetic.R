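# Seeded generator of virtual-diagnosis cohorts. Emulates a study design in
# which N doctors each diagnose the same set of standardized cases and
# prescribe 3-5 acupoints per case: every case has its own categorical
# diagnosis distribution, and every diagnosis has its own acupoint weight
# profile mixing a pool of commonly used points with pattern-specific points.

# Acupoints prescribed across essentially all diagnosis patterns.
COMMON_POOL <- c("ST36", "LI4", "LR3", "SP6", "CV12", "PC6")

#' Default per-case diagnosis profiles
#'
#' Ten case profiles. Each case has a modal diagnosis whose probability
#' matches the prevalence of the leading diagnosis observed for that case in
#' the virtual-diagnosis study (0.199--0.406), plus four alternative
#' diagnoses splitting the remaining mass with decaying weights 4:3:2:1.
#'
#' @return Tibble with columns `case_id`, `diagnosis`, `prob`; probabilities
#'   sum to 1 within each case.
#' @export
default_case_profiles <- function() {
  modal <- list(
    list(1L,  "U63", 0.406, c("R42", "U60", "U62", "U68")),
    list(2L,  "U73", 0.285, c("U68", "U66", "U60", "R10")),
    list(3L,  "U65", 0.278, c("U66", "U67", "U60", "R42")),
    list(4L,  "U61", 0.403, c("U30", "U62", "U60", "U52")),
    list(5L,  "U62", 0.238, c("U60", "U61", "U24", "U57")),
    list(6L,  "U71", 0.386, c("U76", "U62", "U52", "R10")),
    list(7L,  "U65", 0.307, c("U67", "U66", "U51", "U57")),
    list(8L,  "U30", 0.338, c("R10", "U52", "U61", "U60")),
    list(9L,  "U61", 0.199, c("U62", "U60", "U24", "R42")),
    list(10L, "U62", 0.397, c("U60", "U61", "U71", "U69"))
  )
  rows <- lapply(modal, function(m) {
    rest <- (1 - m[[3]]) * c(4, 3, 2, 1) / 10
    tibble::tibble(case_id = m[[1]],
                   diagnosis = c(m[[2]], m[[4]]),
                   prob = c(m[[3]], rest))
  })
  dplyr::bind_rows(rows)
}

#' Default per-diagnosis acupoint profiles
#'
#' For every diagnosis used by [default_case_profiles()], an acupoint weight
#' table mixing the common pool (ST36, LI4, LR3, SP6, CV12, PC6) with
#' pattern-specific points: e.g. ST35 and SP10 for blood disorder (U61), KI3,
#' KI7 and BL23 for kidney disease (U71), CV17 and GV20 for liver excess
#' (U65), ST40 for the fluid-and-humour pattern (U63). A fraction
#' `common_weight` of the probability mass is split equally over the common
#' pool; the rest is split equally over the specific points.
#'
#' @param common_weight Fraction of acupoint probability mass on the common
#'   pool, in \[0, 1\] (default 0.5).
#' @return Tibble with columns `diagnosis`, `acupoint`, `weight`; weights sum
#'   to 1 within each diagnosis.
#' @export
default_pattern_profiles <- function(common_weight = 0.5) {
  stopifnot(common_weight >= 0, common_weight <= 1)
  specific <- list(
    U61 = c("ST35", "SP10"),
    U62 = c("KI3", "CV4"),
    U71 = c("KI3", "KI7", "BL23", "BL31", "BL32", "LU8"),
    U65 = c("CV17", "GV20"),
    U63 = c("ST40", "GB20"),
    U73 = c("ST21", "BL21"),
    U30 = c("GV3", "BL25"),
    U60 = c("CV6", "BL20"),
    U66 = c("HT7", "BL15"),
    U67 = c("HT8", "PC7"),
    U68 = c("SP3", "ST25"),
    U76 = c("BL40", "BL28"),
    U52 = c("BL60", "SI3"),
    U24 = c("HT3", "LI11"),
    U51 = c("LU9", "LU7"),
    U57 = c("LU9", "LU5"),
    U69 = c("LU9", "LU1"),
    R42 = c("GB20", "TE17"),
    R10 = c("GB30", "GB34")
  )
  rows <- lapply(names(specific), function(d) {
    sp <- specific[[d]]
    tibble::tibble(
      diagnosis = d,
      acupoint = c(COMMON_POOL, sp),
      weight = c(rep(common_weight / length(COMMON_POOL), length(COMMON_POOL)),
                 rep((1 - common_weight) / length(sp), length(sp)))
    )
  })
  dplyr::bind_rows(rows)
}

#' Configure a virtual-diagnosis cohort
#'
#' Bundles and validates everything [generate_cohort()] needs. The defaults
#' describe a cohort of 80 doctors each prescribing 3--5 acupoints for 10
#' standardized cases, with case diagnosis distributions and per-diagnosis
#' acupoint profiles as in [default_case_profiles()] and
#' [default_pattern_profiles()].
#'
#' @param n_doctors Number of participating doctors (default 80).
#' @param n_cases Number of cases presented to every doctor (default 10).
#' @param points_min,points_max Inclusive range of distinct acupoints per
#'   prescription (default 3--5).
#' @param case_profiles Tibble `case_id, diagnosis, prob`; per-case
#'   probabilities must sum to 1 within 1e-9.
#' @param pattern_profiles Tibble `diagnosis, acupoint, weight`; every
#'   diagnosis in `case_profiles` needs a profile with at least `points_max`
#'   distinct positively weighted acupoints.
#' @param common_weight Passed to [default_pattern_profiles()] when
#'   `pattern_profiles` is not supplied.
#' @param multi_pattern If `TRUE`, a doctor may report a second diagnosis
#'   pattern for a case (drawn from the same case profile); each record still
#'   carries one diagnosis, so a (doctor, case) may then yield two records.
#' @param second_pattern_prob Probability of a second pattern per (doctor,
#'   case) when `multi_pattern` is on.
#' @param seed RNG seed for [generate_cohort()]; `NULL` uses the session RNG.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_doctors = 80L, n_cases = 10L,
                          points_min = 3L, points_max = 5L,
                          case_profiles = default_case_profiles(),
                          pattern_profiles = NULL,
                          common_weight = 0.5,
                          multi_pattern = FALSE,
                          second_pattern_prob = 0.15,
                          seed = NULL) {
  if (is.null(pattern_profiles)) {
    pattern_profiles <- default_pattern_profiles(common_weight)
  }
  stopifnot(n_doctors >= 1L, n_cases >= 1L,
            points_min >= 1L, points_max >= points_min)
  case_profiles <- tibble::as_tibble(case_profiles)
  pattern_profiles <- tibble::as_tibble(pattern_profiles)
  if (!all(seq_len(n_cases) %in% case_profiles$case_id)) {
    stop("case_profiles must cover case_id 1..n_cases", call. = FALSE)
  }
  case_profiles <- case_profiles[case_profiles$case_id <= n_cases, ]
  sums <- tapply(case_profiles$prob, case_profiles$case_id, sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("case profile probabilities must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (!all(is_diagnosis_code(case_profiles$diagnosis))) {
    stop("case profile references an unregistered diagnosis code", call. = FALSE)
  }
  if (!all(is_acupoint_code(pattern_profiles$acupoint))) {
    stop("pattern profile references an unregistered acupoint code", call. = FALSE)
  }
  missing_prof <- setdiff(unique(case_profiles$diagnosis),
                          unique(pattern_profiles$diagnosis))
  if (length(missing_prof) > 0L) {
    stop("no pattern profile for diagnosis: ",
         paste(missing_prof, collapse = ", "), call. = FALSE)
  }
  pos <- pattern_profiles[pattern_profiles$weight > 0, ]
  n_pos <- tapply(pos$acupoint, pos$diagnosis, function(a) length(unique(a)))
  if (any(n_pos < points_max)) {
    stop("every pattern profile needs >= points_max acupoints with positive weight",
         call. = FALSE)
  }
  structure(list(
    n_doctors = as.integer(n_doctors), n_cases = as.integer(n_cases),
    points_min = as.integer(points_min), points_max = as.integer(points_max),
    case_profiles = case_profiles, pattern_profiles = pattern_profiles,
    multi_pattern = isTRUE(multi_pattern),
    second_pattern_prob = second_pattern_prob,
    seed = seed
  ), class = "cohort_config")
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Generate a virtual-diagnosis cohort
#'
#' Draws one prescription record per (doctor, case): the diagnosis comes from
#' the case's categorical profile, the number of acupoints is uniform on
#' `points_min..points_max`, and the acupoints themselves are drawn without
#' replacement with probability proportional to the diagnosis's pattern
#' profile weights (sequential draws with renormalization). Identical
#' `(config, seed)` gives byte-identical output.
#'
#' @param config A [cohort_config()].
#' @return Tibble with columns `doctor_id`, `case_id`, `diagnosis`, and the
#'   list-column `acupoints` (distinct codes in canonical order).
#' @export
#' @examples
#' records <- generate_cohort(cohort_config(seed = 1))
#' nrow(records)  # 800
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed_if(config$seed, {
    profs <- split(config$case_profiles, config$case_profiles$case_id)
    pat <- split(config$pattern_profiles, config$pattern_profiles$diagnosis)
    rows <- vector("list", config$n_doctors * config$n_cases)
    k <- 0L
    for (d in seq_len(config$n_doctors)) {
      doctor <- sprintf("D%03d", d)
      for (cs in seq_len(config$n_cases)) {
        pr <- profs[[as.character(cs)]]
        n_diag <- 1L
        if (config$multi_pattern &&
            stats::runif(1) < config$second_pattern_prob) {
          n_diag <- 2L
        }
        dx <- sample(pr$diagnosis, n_diag, replace = FALSE,
                     prob = pr$prob)
        for (one in dx) {
          pp <- pat[[one]]
          pp <- pp[pp$weight > 0, ]
          n_pts <- sample(config$points_min:config$points_max, 1L)
          pts <- sample(pp$acupoint, n_pts, replace = FALSE, prob = pp$weight)
          k <- k + 1L
          rows[[k]] <- list(doctor_id = doctor, case_id = cs,
                            diagnosis = one, acupoints = sort_codes(pts))
        }
      }
    }
    rows <- rows[seq_len(k)]
    tibble::tibble(
      doctor_id = vapply(rows, `[[`, character(1), "doctor_id"),
      case_id = vapply(rows, `[[`, integer(1), "case_id"),
      diagnosis = vapply(rows, `[[`, character(1), "diagnosis"),
      acupoints = lapply(rows, `[[`, "acupoints")
    )
  })
}

# Off-meridian terms occasionally present in free-text prescriptions; used to
# exercise the preprocessing filter.
NON_MERIDIAN_TERMS <- c("auricular Shenmen", "trigger point upper trapezius",
                        "Ashi point")

#' Degrade coded records to free-text-style raw rows
#'
#' Re-expresses a coded cohort the way free-text survey data would look:
#' each code is replaced by one of its synonyms from the table at rate
#' `noise_rate` (codes without synonyms stay canonical), and a fraction
#' `inject_rate` of records gains one off-meridian term (auricular/trigger
#' point) to exercise the preprocessing filter. Cleaning the result with the
#' same synonym table recovers the coded records exactly.
#'
#' @param records Coded records as from [generate_cohort()].
#' @param table Synonym table used for the reverse (code to term) lookup.
#' @param noise_rate Per-code probability of synonym substitution, in \[0,1\].
#' @param inject_rate Per-record probability of gaining one off-meridian term.
#' @param seed RNG seed; `NULL` uses the session RNG.
#' @return Tibble with columns `doctor_id`, `case_id`, `diagnosis`,
#'   `acupoints` (`;`-separated raw strings).
#' @export
degrade_to_raw_text <- function(records, table = empty_synonym_table(),
                                noise_rate = 0, inject_rate = 0, seed = NULL) {
  stopifnot(noise_rate >= 0, noise_rate <= 1, inject_rate >= 0, inject_rate <= 1)
  table <- validate_synonym_table(table)
  syn_of <- function(code, kind) {
    hits <- table$raw_term[table$kind == kind & table$code == code]
    if (length(hits) == 0L) code else sample(hits, 1L)
  }
  with_seed_if(seed, {
    diag_raw <- vapply(records$diagnosis, function(d) {
      if (stats::runif(1) < noise_rate) syn_of(d, "diagnosis") else d
    }, character(1), USE.NAMES = FALSE)
    acu_raw <- vapply(seq_len(nrow(records)), function(i) {
      pts <- vapply(records$acupoints[[i]], function(a) {
        if (stats::runif(1) < noise_rate) syn_of(a, "acupoint") else a
      }, character(1), USE.NAMES = FALSE)
      if (stats::runif(1) < inject_rate) {
        pts <- c(pts, sample(NON_MERIDIAN_TERMS, 1L))
      }
      paste(pts, collapse = ";")
    }, character(1))
    tibble::tibble(doctor_id = records$doctor_id, case_id = records$case_id,
                   diagnosis = diag_raw, acupoints = acu_raw)
  })
}

#' Write / read cohort CSV
#'
#' The on-disk dialect has columns `doctor_id,case_id,diagnosis,acupoints`
#' with the acupoints `;`-separated; it serves both the coded and the raw
#' (free-text) flavour.
#'
#' @param records Tibble with an `acupoints` list-column (coded) or character
#'   column (raw).
#' @param path File path.
#' @return `read_cohort_csv()` returns the tibble with `acupoints` as a
#'   character column; pass it to [clean_records()].
#' @export
write_cohort_csv <- function(records, path) {
  out <- records
  if (is.list(out$acupoints)) {
    out$acupoints <- vapply(out$acupoints, paste, character(1), collapse = ";")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    doctor_id = readr::col_character(),
    case_id = readr::col_integer(),
    diagnosis = readr::col_character(),
    acupoints = readr::col_character()
  ), progress = FALSE)
}
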