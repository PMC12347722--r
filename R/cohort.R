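#' Cohort data frames
#'
#' A cohort is a tibble with one row per subject and columns
#' `subject_id` (unique character id), up to three postoperative biomarker
#' columns — `strem1_post` (sTREM-1, pg/mL), `crp_post` (C-reactive
#' protein, mg/dL), `wbc_post` (white blood cell count, cells/uL) — and a
#' binary `sepsis` outcome (0 = no sepsis, 1 = sepsis within 48 h of
#' surgery). Marker values must be strictly positive and non-missing.
#'
#' `validate_cohort()` checks these invariants and returns the cohort
#' invisibly (as a tibble), raising an informative error on the first
#' violation. Cohorts recovered from a published ROC coordinate table
#' carry only the marker the table was computed from, so the set of
#' required marker columns is an argument.
#'
#' @param cohort A data frame of subject records.
#' @param markers Character vector of marker columns that must be present
#'   and valid. Defaults to any of the three canonical markers found in
#'   the data; at least one is required.
#' @param require_both_classes If `TRUE`, additionally require at least
#'   one septic and one non-septic subject (needed by ROC analysis).
#' @return The validated cohort as a tibble, invisibly.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_params(n = 10), seed = 1)
#' validate_cohort(cohort)
validate_cohort <- function(cohort,
                            markers = intersect(cohort_marker_columns(), names(cohort)),
                            require_both_classes = FALSE) {
  if (!is.data.frame(cohort)) {
    abort("`cohort` must be a data frame.")
  }
  cohort <- tibble::as_tibble(cohort)
  required <- c("subject_id", markers, "sepsis")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "cohort is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (length(markers) == 0) {
    abort("cohort must contain at least one marker column (strem1_post, crp_post, wbc_post).")
  }
  if (nrow(cohort) == 0) {
    abort("cohort has no records")
  }
  ids <- as.character(cohort$subject_id)
  if (anyNA(ids) || any(!nzchar(ids))) {
    abort("subject_id must be non-missing and non-empty.")
  }
  if (anyDuplicated(ids) > 0) {
    dup <- ids[duplicated(ids)][1]
    abort(paste0("duplicate subject_id: '", dup, "'"))
  }
  for (m in markers) {
    x <- cohort[[m]]
    if (!is.numeric(x)) {
      abort(paste0("column '", m, "' must be numeric."))
    }
    bad <- which(is.na(x) | x <= 0)
    if (length(bad) > 0) {
      abort(paste0(
        "column '", m, "' must be strictly positive and non-missing; ",
        "violated at row ", bad[1], " (value ",
        if (is.na(x[bad[1]])) "NA" else format(x[bad[1]]), ")"
      ))
    }
  }
  s <- cohort$sepsis
  bad <- which(is.na(s) | !(s %in% c(0, 1)))
  if (length(bad) > 0) {
    abort(paste0("sepsis must be 0 or 1; violated at row ", bad[1]))
  }
  if (require_both_classes && length(unique(s)) < 2) {
    abort("ROC undefined without both classes: cohort needs septic and non-septic subjects.")
  }
  invisible(cohort)
}

cohort_marker_columns <- function() c("strem1_post", "crp_post", "wbc_post")

#' Read and write cohort CSV files
#'
#' Cohort files are plain comma-separated UTF-8 text with a header row and
#' `.` as decimal separator. The `sepsis` column may be coded 0/1 or as
#' the strings `"With"`/`"Without"`, which are normalized to 1/0 on read.
#' Empty cells in an analysis column are an error: there is no
#' missing-data procedure in this pipeline.
#'
#' @param path Path to a CSV file.
#' @param markers Marker columns required in the file (see
#'   [validate_cohort()]).
#' @return `read_cohort()` returns a validated cohort tibble with row
#'   order preserved; `write_cohort()` writes `cohort` to `path` and
#'   returns it invisibly, so that `read_cohort(write_cohort(...))` is the
#'   identity on all fields.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' cohort <- simulate_cohort(simulation_params(n = 5), seed = 1)
#' write_cohort(cohort, path)
#' identical(read_cohort(path)$subject_id, cohort$subject_id)
read_cohort <- function(path, markers = cohort_marker_columns()) {
  if (!file.exists(path)) {
    abort(paste0("cohort file not found: '", path, "'"))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("subject_id", markers, "sepsis")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "cohort file is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(raw) == 0) {
    abort("cohort has no records")
  }
  out <- raw
  for (m in intersect(cohort_marker_columns(), names(raw))) {
    x <- suppressWarnings(as.numeric(raw[[m]]))
    bad <- which(is.na(x) & !is.na(raw[[m]]))
    if (length(bad) > 0) {
      abort(paste0("column '", m, "' is non-numeric at row ", bad[1],
                   " (value '", raw[[m]][bad[1]], "')"))
    }
    out[[m]] <- x
  }
  out$sepsis <- normalize_sepsis(raw$sepsis)
  out$subject_id <- as.character(raw$subject_id)
  validate_cohort(out, markers = markers)
  out
}

normalize_sepsis <- function(x) {
  x <- trimws(as.character(x))
  mapped <- dplyr::case_when(
    x %in% c("0", "Without", "without") ~ 0,
    x %in% c("1", "With", "with") ~ 1,
    TRUE ~ NA_real_
  )
  bad <- which(is.na(mapped))
  if (length(bad) > 0) {
    abort(paste0("sepsis must be 0/1 or With/Without; violated at row ", bad[1],
                 " (value '", x[bad[1]], "')"))
  }
  mapped
}

#' @rdname read_cohort
#' @param cohort A validated cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  markers <- intersect(cohort_marker_columns(), names(cohort))
  validate_cohort(cohort, markers = markers)
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(cohort)
}
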