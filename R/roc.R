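#' Construct an empirical ROC curve for one biomarker
#'
#' Builds the full coordinate grid of an empirical ROC curve for a
#' continuous marker against the binary sepsis outcome. The cutoff grid is
#' the union of `min(marker) - 1`, the midpoints of consecutive distinct
#' observed values, and `max(marker) + 1`, so the first row is always
#' (sensitivity 1, specificity 0) and the last (0, 1). A subject is
#' test-positive when `marker >= cutoff` (with `direction = "greater"`,
#' the default, meaning higher values indicate sepsis); sensitivity and
#' specificity are the empirical proportions among septic and non-septic
#' subjects.
#'
#' @param cohort A cohort tibble (see [validate_cohort()]) with at least
#'   one septic and one non-septic subject.
#' @param marker Name of the marker column to threshold (default
#'   `"strem1_post"`).
#' @param outcome Name of the 0/1 outcome column (default `"sepsis"`).
#' @param direction `"greater"` if large marker values indicate the
#'   positive class, `"less"` for the reverse (the marker is negated
#'   internally and cutoffs reported on the original scale).
#' @return A tibble of class `roc_curve` with columns `cutoff`,
#'   `sensitivity`, `specificity`, and attributes `n_pos`, `n_neg`,
#'   `marker`, `direction`.
#' @seealso [auroc()], [youden_optimal()], [tidy.roc_curve()]
#' @export
#' @examples
#' cohort <- reconstruct_cohort(strem1_roc_coordinates())
#' roc <- compute_roc(cohort)
#' glance(roc)
compute_roc <- function(cohort, marker = "strem1_post", outcome = "sepsis",
                        direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!marker %in% names(cohort)) {
    abort(paste0("marker column '", marker, "' not found in cohort."))
  }
  cohort <- tibble::as_tibble(cohort)
  if (!identical(outcome, "sepsis")) cohort$sepsis <- cohort[[outcome]]
  validate_cohort(cohort, markers = marker, require_both_classes = TRUE)

  x <- cohort[[marker]]
  if (direction == "less") x <- -x
  y <- cohort$sepsis
  v <- sort(unique(x))
  cutoffs <- c(v[1] - 1,
               if (length(v) > 1) (head(v, -1) + tail(v, -1)) / 2,
               v[length(v)] + 1)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  sens <- vapply(cutoffs, function(ct) sum(x >= ct & y == 1) / n_pos, numeric(1))
  spec <- vapply(cutoffs, function(ct) sum(x < ct & y == 0) / n_neg, numeric(1))
  out <- tibble::tibble(
    cutoff = if (direction == "less") -cutoffs else cutoffs,
    sensitivity = sens,
    specificity = spec
  )
  new_roc_curve(out, n_pos = n_pos, n_neg = n_neg,
                marker = marker, direction = direction)
}

new_roc_curve <- function(data, n_pos, n_neg, marker = NA_character_,
                          direction = "greater") {
  structure(
    tibble::as_tibble(data),
    n_pos = n_pos, n_neg = n_neg, marker = marker, direction = direction,
    class = c("roc_curve", class(tibble::tibble()))
  )
}

#' Number of positive / negative subjects behind an ROC curve
#'
#' @param roc An object of class `roc_curve`.
#' @return An integer count.
#' @export
n_pos <- function(roc) attr(roc, "n_pos")

#' @rdname n_pos
#' @export
n_neg <- function(roc) attr(roc, "n_neg")

#' Area under the ROC curve with a Hanley-McNeil confidence interval
#'
#' `auroc()` computes the trapezoidal area under the empirical (1 -
#' specificity, sensitivity) polyline, which for an empirical ROC curve
#' equals the Mann-Whitney concordance statistic (probability that a
#' random septic subject has a higher marker value than a random
#' non-septic one, ties counted 1/2). The standard error and
#' normal-approximation interval come from [auroc_ci()].
#'
#' @param roc An `roc_curve` object.
#' @param level Confidence level, in (0, 1); default 0.95.
#' @return A one-row tibble with columns `auc`, `se`, `ci_low`, `ci_high`,
#'   `level`, `n_pos`, `n_neg`.
#' @export
auroc <- function(roc, level = 0.95) {
  stopifnot(inherits(roc, "roc_curve"))
  fpr <- 1 - roc$specificity
  tpr <- roc$sensitivity
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  ci <- auroc_ci(auc, n_pos(roc), n_neg(roc), level = level)
  dplyr::mutate(ci, n_pos = n_pos(roc), n_neg = n_neg(roc))
}

#' Hanley-McNeil standard error and confidence interval for an AUC
#'
#' Distribution-free standard error for an empirical AUC `A` estimated
#' from `n_pos` cases and `n_neg` controls, using
#' `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`:
#' `se^2 = (A(1-A) + (n_pos-1)(Q1 - A^2) + (n_neg-1)(Q2 - A^2)) /
#' (n_pos * n_neg)`. The interval is the normal approximation
#' `A +/- z * se`, clipped to `[0, 1]`. For a degenerate `A` of exactly 0
#' or 1 the standard error is 0 and a warning is issued.
#'
#' @param auc Estimated area under the curve, in `[0, 1]`.
#' @param n_pos,n_neg Case and control counts (each >= 2 for a meaningful
#'   interval).
#' @param level Confidence level, default 0.95.
#' @return A one-row tibble with `auc`, `se`, `ci_low`, `ci_high`, `level`.
#' @export
#' @examples
#' auroc_ci(0.761, 13, 19)
auroc_ci <- function(auc, n_pos, n_neg, level = 0.95) {
  stopifnot(length(auc) == 1, auc >= 0, auc <= 1,
            n_pos >= 1, n_neg >= 1, level > 0, level < 1)
  if (auc %in% c(0, 1)) {
    warn("AUC is degenerate (0 or 1); returning a zero-width interval.")
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    auc = auc, se = se,
    ci_low = max(0, auc - z * se),
    ci_high = min(1, auc + z * se),
    level = level
  )
}

#' Youden-optimal cutoff of an ROC curve
#'
#' Scans every cutoff of the curve and returns the row maximizing the
#' Youden index J = sensitivity + specificity - 1, together with the
#' positive and negative likelihood ratios at that cutoff (full-precision;
#' see [likelihood_ratios()] for the printed-value rounding mode). Ties in
#' J are broken toward the smallest cutoff, which favors sensitivity in a
#' screening setting.
#'
#' @param roc An `roc_curve` object.
#' @return A one-row tibble with `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`, `plr`, `nlr`.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$sensitivity + roc$specificity - 1
  i <- which(j == max(j))[1]
  lr <- likelihood_ratios(roc$sensitivity[i], roc$specificity[i])
  tibble::tibble(
    cutoff = roc$cutoff[i],
    sensitivity = roc$sensitivity[i],
    specificity = roc$specificity[i],
    youden_j = j[i],
    plr = lr$plr,
    nlr = lr$nlr
  )
}

#' Positive and negative likelihood ratios
#'
#' PLR = Se / (1 - Sp) is the factor by which a positive test raises the
#' odds of sepsis; NLR = (1 - Se) / Sp is the corresponding factor for a
#' negative test. Division by zero yields `Inf` (a perfect-specificity
#' cutoff has an infinite PLR), kept in-band rather than raised as an
#' error. With `round_inputs = 3`, Se and Sp are first rounded to three
#' decimals — the convention used when likelihood ratios are quoted from a
#' coordinate table printed to three decimals.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @param round_inputs Number of decimals to round Se and Sp to before
#'   forming the ratios, or `NULL` (default) for full precision.
#' @return A one-row tibble with `plr` and `nlr`.
#' @export
#' @examples
#' likelihood_ratios(10 / 13, 15 / 19, round_inputs = 3)
likelihood_ratios <- function(sensitivity, specificity, round_inputs = NULL) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  se <- sensitivity
  sp <- specificity
  if (!is.null(round_inputs)) {
    se <- round(se, round_inputs)
    sp <- round(sp, round_inputs)
  }
  plr <- ifelse(sp == 1, ifelse(se == 0, NaN, Inf), se / (1 - sp))
  nlr <- ifelse(sp == 0, ifelse(se == 1, NaN, Inf), (1 - se) / sp)
  # 0/0 corners are undefined tests, not infinities
  tibble::tibble(plr = as.numeric(plr), nlr = as.numeric(nlr))
}

#' @describeIn compute_roc Per-cutoff coordinate table with Youden index
#'   and likelihood ratios.
#' @param x,object An `roc_curve` object.
#' @param ... Unused.
#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) {
  lr <- likelihood_ratios(x$sensitivity, x$specificity)
  tibble::tibble(
    cutoff = x$cutoff,
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    youden_j = x$sensitivity + x$specificity - 1,
    plr = lr$plr,
    nlr = lr$nlr
  )
}

#' @describeIn compute_roc One-row AUC summary (see [auroc()]).
#' @param level Confidence level for the AUC interval.
#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, level = 0.95, ...) {
  auroc(x, level = level)
}

#' @describeIn compute_roc ROC curve plot in the unit square with the
#'   Youden-optimal point marked.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  opt <- youden_optimal(object)
  a <- auroc(object)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = opt, colour = "red", size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC: %s (AUC %.3f, %g%% CI %.3f-%.3f)",
                      attr(object, "marker") %||% "marker",
                      a$auc, 100 * a$level, a$ci_low, a$ci_high),
      subtitle = sprintf("Youden-optimal cutoff %.2f (Se %.3f, Sp %.3f, J %.2f)",
                         opt$cutoff, opt$sensitivity, opt$specificity,
                         opt$youden_j)
    ) +
    ggplot2::theme_minimal()
}
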