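# Cohort tables: a validated tibble with one row per patient, plus
# provenance (source path, filter log). All downstream modules (index
# computation, calibration, evaluation) consume this representation only.

COHORT_SCHEMA_VERSION <- "km-cohort v1"

VESSEL_LEVELS <- c("CCA", "ICA", "carotid_T", "M1", "M2", "M3", "combined")

COHORT_COLUMNS <- c(
  "id", "age", "sex", "occluded_vessel", "nihss",
  "v_core", "v_penumbra", "v_mip", "v_mtt",
  "thrombectomy", "mtici", "rtpa", "onset_to_groin_hours",
  "mls_max_mm", "dhc", "death_7d", "exclusion_flags"
)

cohort_col_types <- function() {
  readr::cols(
    id = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character(),
    occluded_vessel = readr::col_character(),
    nihss = readr::col_integer(),
    v_core = readr::col_double(),
    v_penumbra = readr::col_double(),
    v_mip = readr::col_double(),
    v_mtt = readr::col_double(),
    thrombectomy = readr::col_logical(),
    mtici = readr::col_character(),
    rtpa = readr::col_logical(),
    onset_to_groin_hours = readr::col_double(),
    mls_max_mm = readr::col_double(),
    dhc = readr::col_logical(),
    death_7d = readr::col_logical(),
    exclusion_flags = readr::col_character()
  )
}

#' Construct a validated cohort from a patient table
#'
#' @param data A data frame with the canonical cohort columns (see
#'   [read_cohort()] for the schema). Missing values: `mtici` is `NA` for
#'   patients without thrombectomy, `onset_to_groin_hours` is `NA` when the
#'   onset is unknown, `mls_max_mm` is `NA` when no follow-up measurement
#'   exists (distinct from a measured 0 mm shift).
#' @param source Provenance string (e.g. the source file path).
#' @param filter_log Optional list recording applied filters.
#' @return A `km_cohort`, a tibble subclass.
#' @export
km_cohort <- function(data, source = NA_character_, filter_log = list()) {
  tbl <- tibble::as_tibble(data)
  missing_cols <- setdiff(COHORT_COLUMNS, names(tbl))
  if (length(missing_cols))
    km_stop(paste0("cohort is missing columns: ",
                   paste(missing_cols, collapse = ", ")))
  tbl <- tbl[COHORT_COLUMNS]
  tbl$exclusion_flags[is.na(tbl$exclusion_flags)] <- ""
  validate_cohort_rows(tbl)
  structure(tbl, class = c("km_cohort", class(tibble::tibble())),
            source = source, filter_log = filter_log)
}

# Row-level validation with row-numbered diagnostics; collects all problems
# before failing so a malformed file is reported in one pass.
validate_cohort_rows <- function(tbl) {
  problems <- character(0)
  bad <- function(rows, what) {
    if (any(rows, na.rm = TRUE))
      problems <<- c(problems, sprintf("row %d: %s", which(rows), what))
  }
  dup <- duplicated(tbl$id)
  bad(dup, "duplicate patient id")
  bad(is.na(tbl$id) | tbl$id == "", "empty patient id")
  for (v in c("v_core", "v_penumbra", "v_mip", "v_mtt"))
    bad(!is.finite(tbl[[v]]) | tbl[[v]] < 0, paste("invalid", v))
  bad(tbl$v_mip <= 0, "v_mip must be positive")
  bad(tbl$v_mtt > tbl$v_mip + 1e-9, "v_mtt exceeds v_mip")
  bad(tbl$v_core + tbl$v_penumbra > tbl$v_mtt + 1e-9,
      "v_core + v_penumbra exceeds v_mtt")
  bad(tbl$thrombectomy & is.na(tbl$mtici),
      "mtici missing despite thrombectomy")
  bad(!tbl$thrombectomy & !is.na(tbl$mtici),
      "mtici present without thrombectomy")
  bad(!is.na(tbl$mtici) & !tbl$mtici %in% MTICI_LEVELS, "unknown mTICI code")
  bad(!is.na(tbl$onset_to_groin_hours) & tbl$onset_to_groin_hours < 0,
      "negative onset_to_groin_hours")
  bad(!is.na(tbl$mls_max_mm) & tbl$mls_max_mm < 0, "negative mls_max_mm")
  bad(!is.na(tbl$occluded_vessel) &
        !tbl$occluded_vessel %in% VESSEL_LEVELS, "unknown occluded_vessel")
  flags <- strsplit(tbl$exclusion_flags, ";", fixed = TRUE)
  bad(vapply(flags, function(f) length(setdiff(f, EXCLUSION_REASONS)) > 0,
             logical(1)),
      "unknown exclusion flag")
  if (length(problems))
    km_stop(paste0("invalid cohort:\n  ",
                   paste(utils::head(problems, 20), collapse = "\n  ")))
  invisible(tbl)
}

#' Read a cohort CSV
#'
#' The file format is UTF-8 comma-separated with a versioned first line
#' (`# km-cohort v1`) followed by a header row and one row per patient.
#' Blank fields are missing values, never zeros. `exclusion_flags` holds a
#' semicolon-separated subset of `large_hemorrhage`,
#' `iatrogenic_bleed_gt20ml`, `ctp_technical_failure`,
#' `no_followup_imaging`; an empty field means the patient is included.
#'
#' @param path Path to the cohort CSV.
#' @return A `km_cohort`.
#' @seealso [write_cohort()], [apply_inclusion_filters()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) km_stop(paste("no such file:", path))
  first <- readLines(path, n = 1L)
  if (!identical(trimws(sub("^#", "", first)), COHORT_SCHEMA_VERSION))
    km_stop(sprintf("unrecognized cohort schema line '%s' (expected '# %s')",
                    first, COHORT_SCHEMA_VERSION))
  tbl <- readr::read_csv(path, skip = 1L, col_types = cohort_col_types(),
                         na = c("", "NA"), progress = FALSE)
  prob <- readr::problems(tbl)
  if (nrow(prob))
    km_stop(paste0("malformed cohort rows:\n  ",
                   paste(sprintf("row %d: %s", prob$row, prob$expected),
                         collapse = "\n  ")))
  km_cohort(tbl, source = path)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: emits the versioned schema line, the header
#' and the patient rows, with missing values as empty fields.
#'
#' @param cohort A `km_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "km_cohort"))
  writeLines(paste0("# ", COHORT_SCHEMA_VERSION), path)
  readr::write_csv(tibble::as_tibble(cohort)[COHORT_COLUMNS], path,
                   na = "", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Apply the inclusion/exclusion filters
#'
#' Removes every patient carrying at least one exclusion flag and tallies
#' the exclusions by reason. A patient with several flags is counted once,
#' under the first flagged reason in the fixed order large hemorrhage,
#' iatrogenic bleed, CT-perfusion technical failure, missing follow-up
#' imaging. Counts are conserved: included + sum of tally = input size.
#'
#' @param cohort A `km_cohort`.
#' @return A list with `included` (a `km_cohort`), `excluded` (a tibble) and
#'   `tally` (named integer vector over the four reasons).
#' @export
apply_inclusion_filters <- function(cohort) {
  stopifnot(inherits(cohort, "km_cohort"))
  tbl <- tibble::as_tibble(cohort)
  flags <- strsplit(tbl$exclusion_flags, ";", fixed = TRUE)
  primary <- vapply(flags, function(f) {
    hit <- EXCLUSION_REASONS[EXCLUSION_REASONS %in% f]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  excluded <- !is.na(primary)
  tally <- table(factor(primary[excluded], levels = EXCLUSION_REASONS))
  tally <- stats::setNames(as.integer(tally), EXCLUSION_REASONS)
  log_entry <- list(filter = "inclusion", input = nrow(tbl),
                    included = sum(!excluded), tally = as.list(tally))
  list(
    included = km_cohort(tbl[!excluded, ], source = attr(cohort, "source"),
                         filter_log = c(attr(cohort, "filter_log"),
                                        list(log_entry))),
    excluded = tbl[excluded, ],
    tally = tally
  )
}

#' Export a cohort's filter log as JSON
#'
#' Writes the provenance of all filters applied to the cohort (input sizes,
#' per-reason exclusion tallies) for audit.
#'
#' @param cohort A `km_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(cohort, path) {
  stopifnot(inherits(cohort, "km_cohort"))
  jsonlite::write_json(
    list(source = attr(cohort, "source"),
         n = nrow(cohort),
         filters = attr(cohort, "filter_log")),
    path, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Compute indices, scores and risk classes for a whole cohort
#'
#' Vectorized counterpart of [km_index()] / [kmt_index()]: appends the
#' weighting factor `n`, (for KMT) the time factor `t`, the `index`, the
#' integer `score` and the `risk_class` to the cohort table. Identical,
#' value for value, to looping the single-patient functions over the rows.
#'
#' @param cohort A `km_cohort` (or any data frame with the cohort columns).
#' @param params An [index_params()].
#' @param variant `"km"` (default) or `"kmt"` (time-weighted).
#' @param literal_grouping Passed to [kmt_index()]; ignored for `"km"`.
#' @return A tibble: the cohort columns plus `n`, `t`, `index`, `score`,
#'   `risk_class`.
#' @export
cohort_indices <- function(cohort, params = index_params(),
                           variant = c("km", "kmt"),
                           literal_grouping = FALSE) {
  variant <- match.arg(variant)
  tbl <- tibble::as_tibble(cohort)
  lam <- if (variant == "km") params$lambda_lysis else params$lambda_lysis_time
  n <- ifelse(tbl$thrombectomy,
              unname(params$n_base[tbl$mtici]),
              params$n_no_thrombectomy)
  n <- n * ifelse(tbl$rtpa, lam, 1)
  h <- tbl$onset_to_groin_hours
  t <- ifelse(is.na(h), 1L, ifelse(h <= 4.5, 3L, ifelse(h <= 8, 2L, 1L)))
  if (variant == "km") {
    num <- n * (params$m_ratio * tbl$v_core + tbl$v_penumbra) + tbl$v_mtt
    t <- NA_integer_
  } else if (literal_grouping) {
    num <- params$m_ratio * n^t * (tbl$v_core + tbl$v_penumbra) + tbl$v_mtt
  } else {
    num <- params$m_ratio * n^t * tbl$v_core + n^t * tbl$v_penumbra +
      tbl$v_mtt
  }
  idx <- num / tbl$v_mip
  score <- km_score_vec(idx)
  tbl$n <- n
  tbl$t <- t
  tbl$index <- idx
  tbl$score <- score
  tbl$risk_class <- risk_class_vec(score)
  tbl
}

# Vectorized score/class used by cohort-level code; semantics identical to
# km_score() / risk_class().
km_score_vec <- function(index) {
  as.integer(ifelse(index < 1.005, 0L,
                    ifelse(index >= 1.195, 20L,
                           floor(100 * (index - 1) + 0.5))))
}

risk_class_vec <- function(score) {
  cls <- cut(score, breaks = c(-1, 2, 7, 13, 20), labels = RISK_CLASSES)
  factor(as.character(cls), levels = RISK_CLASSES)
}

#' @export
print.km_cohort <- function(x, ...) {
  src <- attr(x, "source")
  cat(sprintf("KM cohort: %d patients%s\n", nrow(x),
              if (is.na(src)) "" else paste0(" (", src, ")")))
  NextMethod()
}
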