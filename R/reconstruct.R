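#' Published ROC coordinate table for postoperative sTREM-1
#'
#' The coordinate grid (cutoff, sensitivity, specificity) of the ROC
#' analysis of postoperative sTREM-1 versus sepsis in the reference
#' pediatric post-cardiac-surgery cohort (n = 32), transcribed verbatim
#' from the published table — including its two typographical errors: a
#' non-monotone specificity of 0.470 at cutoff 467.30 and a specificity of
#' 0.787 (instead of 15/19 = 0.789) at the highlighted cutoff 283.50.
#' Pass the table through [repair_roc_coordinates()] /
#' [reconstruct_cohort()] to obtain the corrected curve and the labeled
#' cohort it encodes.
#'
#' @return A tibble with columns `cutoff` (pg/mL), `sensitivity`,
#'   `specificity`, as printed.
#' @export
#' @examples
#' coords <- strem1_roc_coordinates()
#' nrow(coords)
strem1_roc_coordinates <- function() {
  path <- system.file("extdata", "strem1_roc_coordinates.csv",
                      package = "sepsisbn", mustWork = TRUE)
  readr::read_csv(path, col_types = "ddd", progress = FALSE)
}

#' Repair a printed ROC coordinate table
#'
#' Printed coordinate tables carry rounding (3 decimals) and occasional
#' typographical errors. This routine restores an exactly monotone,
#' integer-step table in three stages:
#' \enumerate{
#'   \item entries breaking monotonicity (sensitivity must be
#'     non-increasing, specificity non-decreasing in the cutoff) are
#'     identified as the complement of the longest monotone subsequence of
#'     each column;
#'   \item the case/control class sizes are inferred from the conforming
#'     entries as the smallest denominator `d` such that all but at most
#'     one entry lie within `tol` of an integer multiple of `1/d`;
#'   \item every entry is snapped to the nearest multiple of `1/d`;
#'     monotonicity violators are replaced by the value interpolated in
#'     count space between their monotone neighbours (rounded to the
#'     nearest count). All changed entries are logged.
#' }
#' The result is validated: strictly ascending cutoffs, monotone columns,
#' first row (Se 1, Sp 0) and last row (Se 0, Sp 1). A table admitting no
#' such completion (for instance one whose specificity column decreases
#' throughout) is an error.
#'
#' @param coords A data frame with columns `cutoff`, `sensitivity`,
#'   `specificity`, cutoffs strictly ascending.
#' @param tol Matching tolerance between a printed proportion and `k/d`;
#'   default `1e-3`, the rounding radius of a 3-decimal table.
#' @param max_denominator Largest class size searched; default 1000.
#' @return The repaired table as a tibble, with attributes `n_pos`,
#'   `n_neg` (inferred class sizes) and `repairs` (a tibble logging each
#'   changed entry: `row`, `column`, `printed`, `repaired`, `reason`).
#' @export
repair_roc_coordinates <- function(coords, tol = 1e-3, max_denominator = 1000) {
  coords <- check_coordinates(coords)
  se <- coords$sensitivity
  sp <- coords$specificity

  v_se <- monotone_violators(-se)
  v_sp <- monotone_violators(sp)
  if (sum(v_se) > length(se) / 3 || sum(v_sp) > length(sp) / 3) {
    abort("coordinate table is irreparable: too many monotonicity violations.")
  }

  n_pos <- infer_denominator(se[!v_se], tol, max_denominator, max_misfit = 1)
  n_neg <- infer_denominator(sp[!v_sp], tol, max_denominator, max_misfit = 1)
  if (is.na(n_pos) || is.na(n_neg)) {
    abort("coordinate table is irreparable: no class size <= max_denominator fits the printed steps.")
  }

  rep_se <- repair_column(se, n_pos, v_se, decreasing = TRUE, tol = tol)
  rep_sp <- repair_column(sp, n_neg, v_sp, decreasing = FALSE, tol = tol)

  out <- tibble::tibble(
    cutoff = coords$cutoff,
    sensitivity = rep_se$values,
    specificity = rep_sp$values
  )
  if (any(diff(out$sensitivity) > 0) || any(diff(out$specificity) < 0)) {
    abort("coordinate table is irreparable: no monotone integer-step completion found.")
  }
  if (out$sensitivity[1] != 1 || out$specificity[1] != 0 ||
      out$sensitivity[nrow(out)] != 0 || out$specificity[nrow(out)] != 1) {
    abort("repaired table must start at (Se 1, Sp 0) and end at (Se 0, Sp 1).")
  }
  repairs <- dplyr::bind_rows(
    dplyr::mutate(rep_se$log, column = "sensitivity"),
    dplyr::mutate(rep_sp$log, column = "specificity")
  )
  structure(out, n_pos = n_pos, n_neg = n_neg,
            repairs = repairs[c("row", "column", "printed", "repaired", "reason")])
}

check_coordinates <- function(coords) {
  coords <- tibble::as_tibble(coords)
  need <- c("cutoff", "sensitivity", "specificity")
  missing_cols <- setdiff(need, names(coords))
  if (length(missing_cols) > 0) {
    abort(paste0("coordinate table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(coords) < 2) abort("coordinate table needs at least two rows.")
  if (any(diff(coords$cutoff) <= 0)) abort("cutoffs must be strictly ascending.")
  rng <- c(coords$sensitivity, coords$specificity)
  if (anyNA(rng) || any(rng < 0 | rng > 1)) {
    abort("sensitivity and specificity must be proportions in [0, 1].")
  }
  coords[need]
}

# indices NOT on a longest non-decreasing subsequence (classic O(n^2) DP;
# coordinate tables are tens of rows)
monotone_violators <- function(y) {
  n <- length(y)
  len <- integer(n); prev <- integer(n)
  for (i in seq_len(n)) {
    len[i] <- 1L; prev[i] <- 0L
    for (j in seq_len(i - 1)) {
      if (y[j] <= y[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  keep <- logical(n)
  i <- which.max(len)
  while (i > 0) {
    keep[i] <- TRUE
    i <- prev[i]
  }
  !keep
}

infer_denominator <- function(x, tol, max_denominator, max_misfit = 0) {
  for (d in seq_len(max_denominator)) {
    misfit <- sum(abs(x * d - round(x * d)) > d * tol)
    if (misfit <= max_misfit) return(d)
  }
  NA_integer_
}

repair_column <- function(x, d, violators, decreasing, tol) {
  k <- round(x * d)
  log <- tibble::tibble(row = integer(), printed = numeric(),
                        repaired = numeric(), reason = character())
  snapped <- which(!violators & abs(x * d - k) > d * tol)
  for (i in snapped) {
    log <- tibble::add_row(log, row = i, printed = x[i], repaired = k[i] / d,
                           reason = "snapped to nearest integer step")
  }
  for (i in which(violators)) {
    lo <- if (i == 1) k[i] else k[i - 1]
    hi <- if (i == length(k)) k[i] else k[i + 1]
    k[i] <- round((lo + hi) / 2)
    log <- tibble::add_row(log, row = i, printed = x[i], repaired = k[i] / d,
                           reason = "monotonicity repair (count-space interpolation)")
  }
  list(values = k / d, log = log)
}

#' Infer case/control counts from a monotone coordinate table
#'
#' The sensitivity column of an empirical ROC curve steps in multiples of
#' `1/n_pos` and the specificity column in multiples of `1/n_neg`, so the
#' class sizes are recoverable from the printed proportions: each is the
#' smallest denominator `d` such that every entry lies within `tol` of an
#' integer multiple of `1/d`. Run [repair_roc_coordinates()] first if the
#' table may contain typographical errors.
#'
#' @inheritParams repair_roc_coordinates
#' @return A named list with integer elements `n_pos` and `n_neg`.
#' @export
#' @examples
#' coords <- repair_roc_coordinates(strem1_roc_coordinates())
#' infer_class_sizes(coords)
infer_class_sizes <- function(coords, tol = 1e-3, max_denominator = 1000) {
  coords <- check_coordinates(coords)
  n_pos <- infer_denominator(coords$sensitivity, tol, max_denominator)
  n_neg <- infer_denominator(coords$specificity, tol, max_denominator)
  if (is.na(n_pos) || is.na(n_neg)) {
    abort(paste0("no class size <= ", max_denominator,
                 " makes every printed proportion an integer step."))
  }
  list(n_pos = n_pos, n_neg = n_neg)
}

#' Recover a labeled cohort from an ROC coordinate table
#'
#' Inverts a printed coordinate table into per-subject marker values with
#' sepsis labels. Between consecutive cutoffs, each drop of `1/n_pos` in
#' sensitivity corresponds to one septic subject and each rise of
#' `1/n_neg` in specificity to one non-septic subject; all subjects of an
#' interval share one marker value (reproducing ties when a case and a
#' control step occur together). Interior intervals place that value at
#' the arithmetic midpoint of the two cutoffs; the first and last
#' intervals use `first cutoff + 1` and `last cutoff - 1`, matching the
#' `min - 1` / `max + 1` end-cutoff convention of [compute_roc()], so
#' `compute_roc()` on the reconstruction reproduces the table's Se/Sp
#' columns exactly. The true raw marker values are not recoverable — only
#' their order statistics relative to the cutoff grid — and the recovered
#' cohort carries the thresholded marker and the outcome only.
#'
#' @param coords A coordinate table (`cutoff`, `sensitivity`,
#'   `specificity`).
#' @param repair If `TRUE` (default), pass the table through
#'   [repair_roc_coordinates()] first; set to `FALSE` for a table already
#'   known to be exact.
#' @param marker Name of the marker column in the output cohort.
#' @inheritParams repair_roc_coordinates
#' @return A cohort tibble (`subject_id` `"S001"`... in marker order,
#'   the marker column, `sepsis`) with attribute `reconstruction`, a list
#'   holding `n_pos`, `n_neg`, the repair log, and `ties` (marker values
#'   shared by a case and a control). Retrieve it with
#'   [reconstruction_report()].
#' @export
#' @examples
#' cohort <- reconstruct_cohort(strem1_roc_coordinates())
#' table(cohort$sepsis)
#' reconstruction_report(cohort)$n_pos
reconstruct_cohort <- function(coords, repair = TRUE, marker = "strem1_post",
                               tol = 1e-3, max_denominator = 1000) {
  if (repair) {
    coords <- repair_roc_coordinates(coords, tol = tol,
                                     max_denominator = max_denominator)
    n_pos <- attr(coords, "n_pos")
    n_neg <- attr(coords, "n_neg")
    repairs <- attr(coords, "repairs")
  } else {
    coords <- check_coordinates(coords)
    sizes <- infer_class_sizes(coords, tol = tol,
                               max_denominator = max_denominator)
    n_pos <- sizes$n_pos
    n_neg <- sizes$n_neg
    repairs <- tibble::tibble(row = integer(), column = character(),
                              printed = numeric(), repaired = numeric(),
                              reason = character())
  }
  k_se <- round(coords$sensitivity * n_pos)
  k_sp <- round(coords$specificity * n_neg)
  if (max(abs(coords$sensitivity * n_pos - k_se),
          abs(coords$specificity * n_neg - k_sp)) > 1e-6) {
    abort("non-integer event counts after repair; table is inconsistent.")
  }
  m <- nrow(coords)
  values <- numeric(0)
  labels <- numeric(0)
  ties <- numeric(0)
  for (i in seq_len(m - 1)) {
    d_case <- k_se[i] - k_se[i + 1]
    d_ctrl <- k_sp[i + 1] - k_sp[i]
    if (d_case < 0 || d_ctrl < 0) {
      abort("non-monotone step encountered; run repair_roc_coordinates() first.")
    }
    if (d_case + d_ctrl == 0) next
    v <- if (i == 1) {
      min(coords$cutoff[1] + 1, (coords$cutoff[1] + coords$cutoff[2]) / 2)
    } else if (i == m - 1) {
      max(coords$cutoff[m] - 1, (coords$cutoff[m - 1] + coords$cutoff[m]) / 2)
    } else {
      (coords$cutoff[i] + coords$cutoff[i + 1]) / 2
    }
    if (d_case > 0 && d_ctrl > 0) ties <- c(ties, v)
    values <- c(values, rep(v, d_case + d_ctrl))
    labels <- c(labels, rep(1, d_case), rep(0, d_ctrl))
  }
  if (sum(labels == 1) != n_pos || sum(labels == 0) != n_neg) {
    abort("event decomposition does not conserve class sizes; table is inconsistent.")
  }
  cohort <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_along(values)),
    !!marker := values,
    sepsis = labels
  )
  validate_cohort(cohort, markers = marker)
  structure(cohort,
            reconstruction = list(n_pos = n_pos, n_neg = n_neg,
                                  repairs = repairs, ties = ties))
}

#' @rdname reconstruct_cohort
#' @param cohort A cohort returned by `reconstruct_cohort()`.
#' @export
reconstruction_report <- function(cohort) {
  rep <- attr(cohort, "reconstruction")
  if (is.null(rep)) abort("no reconstruction report attached to this cohort.")
  rep
}
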