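#' Stratification scheme for the biomarker nodes
#'
#' Maps each continuous marker to the discrete states of its network
#' node. Each marker has an ordered vector of interior break points; a
#' value `x` falls in the lowest state with `x <= break`, and above the
#' last break in the top state (the lower state is always inclusive of
#' its boundary). State labels are generated from the breaks
#' (`"<=70"`, `">70"`, or `"(70,140]"` for middle strata) so evidence can
#' be named unambiguously. The defaults are the two-state splits used by
#' the sepsis network: CRP at 70 mg/dL, WBC at 14,000 cells/uL, sTREM-1
#' at its Youden-optimal cutoff 283.53 pg/mL.
#'
#' @param crp_breaks,wbc_breaks,strem1_breaks Numeric vectors of strictly
#'   increasing positive interior break points.
#' @return A named list of class `stratification_scheme`; one element per
#'   variable with fields `breaks` and `labels`, plus the outcome labels
#'   `c("Without", "With")`.
#' @export
#' @examples
#' scheme <- stratification_scheme()
#' scheme$strem1_post$labels
stratification_scheme <- function(crp_breaks = 70, wbc_breaks = 14000,
                                  strem1_breaks = 283.53) {
  mk <- function(breaks, var) {
    breaks <- as.numeric(breaks)
    if (length(breaks) < 1 || anyNA(breaks) || any(breaks <= 0) ||
        any(diff(breaks) <= 0)) {
      abort(paste0("breaks for ", var,
                   " must be strictly increasing positive values."))
    }
    labels <- c(
      paste0("<=", format(breaks[1], scientific = FALSE, trim = TRUE)),
      if (length(breaks) > 1) {
        sprintf("(%s,%s]",
                format(head(breaks, -1), scientific = FALSE, trim = TRUE),
                format(tail(breaks, -1), scientific = FALSE, trim = TRUE))
      },
      paste0(">", format(breaks[length(breaks)], scientific = FALSE, trim = TRUE))
    )
    list(breaks = breaks, labels = labels)
  }
  structure(
    list(
      crp_post = mk(crp_breaks, "crp_post"),
      wbc_post = mk(wbc_breaks, "wbc_post"),
      strem1_post = mk(strem1_breaks, "strem1_post"),
      sepsis = list(labels = c("Without", "With"))
    ),
    class = "stratification_scheme"
  )
}

scheme_parents <- function(scheme) setdiff(names(scheme), "sepsis")

#' Discretize cohort markers into network node states
#'
#' Adds one factor column per marker present in the cohort
#' (`crp_state`, `wbc_state`, `strem1_state`) holding the node state of
#' each subject under `scheme`, plus `sepsis_state`
#' (`"Without"`/`"With"`). Marker values exactly on a break fall in the
#' lower state.
#'
#' @param cohort A cohort tibble (see [validate_cohort()]).
#' @param scheme A [stratification_scheme()].
#' @return The cohort with state columns appended.
#' @export
#' @examples
#' simulate_cohort(simulation_params(n = 5), seed = 1) |> stratify()
stratify <- function(cohort, scheme = stratification_scheme()) {
  stopifnot(inherits(scheme, "stratification_scheme"))
  markers <- intersect(scheme_parents(scheme), names(cohort))
  cohort <- validate_cohort(cohort, markers = markers)
  out <- cohort
  for (m in markers) {
    s <- scheme[[m]]
    idx <- findInterval(out[[m]], s$breaks, left.open = TRUE) + 1L
    col <- sub("_post$", "_state", m)
    out[[col]] <- factor(s$labels[idx], levels = s$labels)
  }
  out$sepsis_state <- factor(scheme$sepsis$labels[out$sepsis + 1L],
                             levels = scheme$sepsis$labels)
  out
}

#' Fit the sepsis conditional probability table from stratified data
#'
#' Estimates `P(sepsis | CRP state, WBC state, sTREM-1 state)` for every
#' parent-state combination by relative frequency, optionally with a
#' symmetric pseudo-count: `p = (n_with + alpha) / (n + 2 * alpha)`. With
#' `alpha = 0`, a combination observed in no subject gets the uniform
#' (0.5, 0.5) column and is flagged `"zero_count"` rather than silently
#' dividing 0 by 0 — with 32 subjects over 8 cells some columns are
#' guaranteed to be sparse.
#'
#' @param data A stratified cohort: output of [stratify()] or of
#'   [simulate_from_cpt()] (must carry the `*_state` columns and
#'   `sepsis_state`).
#' @param scheme The [stratification_scheme()] defining the state space.
#' @param alpha Pseudo-count, a non-negative real; default 0 (raw
#'   frequencies).
#' @return A tibble of class `sepsis_cpt` with one row per parent
#'   combination: state columns, `n`, `n_with`, `p_with`, `p_without`,
#'   `flag` (`"ok"`, `"zero_count"`, or `"not_printed"` for transcribed
#'   tables with unavailable columns).
#' @export
#' @examples
#' simulate_cohort(simulation_params(n = 200), seed = 1) |>
#'   stratify() |>
#'   fit_cpt()
fit_cpt <- function(data, scheme = stratification_scheme(), alpha = 0) {
  stopifnot(inherits(scheme, "stratification_scheme"), alpha >= 0)
  state_cols <- c("crp_state", "wbc_state", "strem1_state")
  missing_cols <- setdiff(c(state_cols, "sepsis_state"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("data is not stratified; missing column(s): ",
                 paste(missing_cols, collapse = ", "),
                 ". Run stratify() first."))
  }
  if (nrow(data) == 0) abort("cohort has no records")

  grid <- cpt_state_grid(scheme)
  counts <- data |>
    dplyr::count(.data$crp_state, .data$wbc_state, .data$strem1_state,
                 name = "n") |>
    dplyr::left_join(
      data |>
        dplyr::filter(.data$sepsis_state == "With") |>
        dplyr::count(.data$crp_state, .data$wbc_state, .data$strem1_state,
                     name = "n_with"),
      by = state_cols
    )
  out <- grid |>
    dplyr::left_join(counts, by = state_cols) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      n_with = dplyr::coalesce(.data$n_with, 0L),
      p_with = dplyr::if_else(
        .data$n + 2 * alpha > 0,
        (.data$n_with + alpha) / (.data$n + 2 * alpha),
        0.5
      ),
      p_without = 1 - .data$p_with,
      flag = dplyr::if_else(.data$n == 0 & alpha == 0, "zero_count", "ok")
    )
  new_sepsis_cpt(out, scheme = scheme, alpha = alpha)
}

cpt_state_grid <- function(scheme) {
  tidyr::expand_grid(
    crp_state = factor(scheme$crp_post$labels, levels = scheme$crp_post$labels),
    wbc_state = factor(scheme$wbc_post$labels, levels = scheme$wbc_post$labels),
    strem1_state = factor(scheme$strem1_post$labels,
                          levels = scheme$strem1_post$labels)
  )
}

new_sepsis_cpt <- function(data, scheme, alpha = 0) {
  data <- tibble::as_tibble(data)
  known <- !is.na(data$p_with)
  if (any(abs(data$p_with[known] + data$p_without[known] - 1) > 1e-12)) {
    abort("CPT columns must sum to 1.")
  }
  if (any(data$p_with[known] < 0 | data$p_with[known] > 1)) {
    abort("CPT probabilities must lie in [0, 1].")
  }
  n_expected <- prod(vapply(scheme[scheme_parents(scheme)],
                            function(s) length(s$labels), numeric(1)))
  if (nrow(data) != n_expected) {
    abort(paste0("CPT must have one row per parent combination (",
                 n_expected, ")."))
  }
  structure(data, scheme = scheme, alpha = alpha,
            class = c("sepsis_cpt", class(tibble::tibble())))
}

#' @method tidy sepsis_cpt
#' @export
tidy.sepsis_cpt <- function(x, ...) {
  tibble::as_tibble(x)
}

#' The published conditional probability table for the sepsis node
#'
#' The CPT transcribed from the published model, which prints the sepsis
#' distribution for four of the eight parent-state combinations: the
#' all-low and all-high CRP/WBC columns, each for both sTREM-1 strata.
#' The four unprinted combinations carry `NA` probabilities and are
#' flagged `"not_printed"`; posterior queries that need them raise an
#' error. Subject counts behind the printed percentages were not
#' published, so `n` and `n_with` are `NA`.
#'
#' @return A `sepsis_cpt` tibble (see [fit_cpt()]).
#' @export
#' @examples
#' printed_sepsis_cpt()
printed_sepsis_cpt <- function() {
  path <- system.file("extdata", "sepsis_cpt.yaml", package = "sepsisbn",
                      mustWork = TRUE)
  read_cpt_yaml(path)
}

read_cpt_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  scheme <- stratification_scheme(
    crp_breaks = spec$scheme$crp_breaks,
    wbc_breaks = spec$scheme$wbc_breaks,
    strem1_breaks = spec$scheme$strem1_breaks
  )
  cols <- dplyr::bind_rows(lapply(spec$columns, tibble::as_tibble))
  grid <- cpt_state_grid(scheme)
  out <- grid |>
    dplyr::left_join(
      dplyr::mutate(
        cols,
        crp_state = factor(.data$crp_state, levels = scheme$crp_post$labels),
        wbc_state = factor(.data$wbc_state, levels = scheme$wbc_post$labels),
        strem1_state = factor(.data$strem1_state,
                              levels = scheme$strem1_post$labels)
      ),
      by = c("crp_state", "wbc_state", "strem1_state")
    ) |>
    dplyr::mutate(
      n = NA_integer_, n_with = NA_integer_,
      p_without = 1 - .data$p_with,
      flag = dplyr::if_else(is.na(.data$p_with), "not_printed", "ok")
    )
  new_sepsis_cpt(out, scheme = scheme)
}

#' Assemble the sepsis Bayesian network
#'
#' The network structure is fixed: three discrete root nodes (CRP, WBC,
#' sTREM-1 states) each with a directed edge into the binary SEPSIS
#' child, quantified by `cpt`. Root priors are not part of the published
#' model; by default they are the empirical state frequencies of `data`
#' when supplied, and uniform otherwise. Full-evidence posteriors do not
#' depend on the priors.
#'
#' @param cpt A `sepsis_cpt` (from [fit_cpt()] or [printed_sepsis_cpt()]).
#' @param priors Optional named list (`crp_post`, `wbc_post`,
#'   `strem1_post`) of probability vectors over each root's states, each
#'   summing to 1.
#' @param data Optional stratified cohort from which to take empirical
#'   priors.
#' @return An object of class `sepsis_bn`: a list with elements `scheme`,
#'   `cpt`, `priors`.
#' @export
#' @examples
#' bn <- sepsis_bn(printed_sepsis_cpt())
#' posterior(bn, crp = ">70", wbc = ">14000", strem1 = ">283.53")
sepsis_bn <- function(cpt, priors = NULL, data = NULL) {
  stopifnot(inherits(cpt, "sepsis_cpt"))
  scheme <- attr(cpt, "scheme")
  parents <- scheme_parents(scheme)
  if (is.null(priors)) {
    priors <- lapply(setNames(parents, parents), function(v) {
      labels <- scheme[[v]]$labels
      if (!is.null(data)) {
        col <- sub("_post$", "_state", v)
        if (!col %in% names(data)) {
          abort(paste0("data lacks column '", col, "' needed for empirical priors."))
        }
        tab <- table(factor(data[[col]], levels = labels))
        as.numeric(tab) / sum(tab)
      } else {
        rep(1 / length(labels), length(labels))
      }
    })
  }
  for (v in parents) {
    p <- priors[[v]]
    labels <- scheme[[v]]$labels
    if (is.null(p) || length(p) != length(labels) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-12) {
      abort(paste0("prior for ", v, " must be a probability vector over ",
                   length(labels), " states summing to 1."))
    }
    names(priors[[v]]) <- labels
  }
  structure(list(scheme = scheme, cpt = cpt, priors = priors[parents]),
            class = "sepsis_bn")
}

#' @export
print.sepsis_bn <- function(x, ...) {
  cat("Sepsis Bayesian network: crp_post, wbc_post, strem1_post -> sepsis\n")
  cat("CPT (", nrow(x$cpt), " parent combinations):\n", sep = "")
  print(tibble::as_tibble(x$cpt), n = nrow(x$cpt))
  invisible(x)
}

#' Posterior probability of sepsis given biomarker evidence
#'
#' Exact inference by enumeration over the parent-state space (at most a
#' handful of combinations, so no approximation is needed). Evidence may
#' fix any subset of the three roots; because the roots are independent a
#' priori, the posterior is the prior-weighted average of the CPT over
#' the unobserved parents:
#' `P(With | e) = sum_u [ prod_v pi_v(u_v) ] * CPT(e, u)`,
#' which with full evidence reduces to the CPT cell itself. Evidence on
#' the SEPSIS node is rejected — it is the query target.
#'
#' @param bn A [sepsis_bn()] object.
#' @param crp,wbc,strem1 Optional state labels (see the scheme's
#'   `labels`) fixing the corresponding root node.
#' @param evidence Alternatively, a named character vector such as
#'   `c(crp_post = ">70")`; full variable names or the short forms
#'   `crp`/`wbc`/`strem1` are accepted.
#' @return The posterior probability `P(sepsis = With | evidence)`, a
#'   single number in `[0, 1]`.
#' @export
#' @examples
#' bn <- sepsis_bn(printed_sepsis_cpt())
#' posterior(bn, crp = "<=70", wbc = "<=14000", strem1 = ">283.53")
posterior <- function(bn, crp = NULL, wbc = NULL, strem1 = NULL,
                      evidence = NULL) {
  stopifnot(inherits(bn, "sepsis_bn"))
  ev <- c(
    if (!is.null(crp)) c(crp_post = crp),
    if (!is.null(wbc)) c(wbc_post = wbc),
    if (!is.null(strem1)) c(strem1_post = strem1),
    evidence
  )
  if (!is.null(ev)) {
    names(ev) <- sub("^crp$", "crp_post",
                     sub("^wbc$", "wbc_post",
                         sub("^strem1$", "strem1_post", names(ev))))
  }
  if (any(names(ev) %in% c("sepsis", "sepsis_state"))) {
    abort("evidence on the SEPSIS node is not allowed: it is the query target.")
  }
  parents <- scheme_parents(bn$scheme)
  unknown <- setdiff(names(ev), parents)
  if (length(unknown) > 0) {
    abort(paste0("unknown evidence variable(s): ",
                 paste(unknown, collapse = ", ")))
  }
  for (v in names(ev)) {
    if (!ev[[v]] %in% bn$scheme[[v]]$labels) {
      abort(paste0("'", ev[[v]], "' is not a state of ", v, " (states: ",
                   paste(bn$scheme[[v]]$labels, collapse = ", "), ")."))
    }
  }
  cpt <- bn$cpt
  state_of <- list(crp_post = cpt$crp_state, wbc_post = cpt$wbc_state,
                   strem1_post = cpt$strem1_state)
  keep <- rep(TRUE, nrow(cpt))
  for (v in names(ev)) keep <- keep & (state_of[[v]] == ev[[v]])
  free <- setdiff(parents, names(ev))
  w <- rep(1, nrow(cpt))
  for (v in free) w <- w * bn$priors[[v]][as.character(state_of[[v]])]
  w <- w[keep]
  p <- cpt$p_with[keep]
  used <- w > 0
  if (any(is.na(p[used]))) {
    abort("posterior requires CPT columns that are not available (flagged not_printed).")
  }
  sum(w[used] * p[used])
}

#' Full joint distribution of the network
#'
#' Enumerates all parent-state combinations crossed with both SEPSIS
#' states and multiplies priors by the CPT:
#' `P(crp, wbc, strem1, sepsis) = pi(crp) pi(wbc) pi(strem1) *
#' P(sepsis | parents)`. The result sums to 1 and serves as an
#' independent conditioning oracle for [posterior()].
#'
#' @param bn A [sepsis_bn()] object with a fully specified CPT.
#' @return A tibble with the state columns, `sepsis_state`, and `prob`.
#' @export
enumerate_joint <- function(bn) {
  stopifnot(inherits(bn, "sepsis_bn"))
  cpt <- bn$cpt
  if (anyNA(cpt$p_with)) {
    abort("enumerate_joint() requires a fully specified CPT.")
  }
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(cpt), "crp_state", "wbc_state",
                  "strem1_state", "p_with", "p_without"),
    cols = c("p_with", "p_without"),
    names_to = "sepsis_state", values_to = "p_cond"
  ) |>
    dplyr::mutate(sepsis_state = factor(
      dplyr::if_else(.data$sepsis_state == "p_with", "With", "Without"),
      levels = bn$scheme$sepsis$labels
    ))
  prior_w <- bn$priors$crp_post[as.character(long$crp_state)] *
    bn$priors$wbc_post[as.character(long$wbc_state)] *
    bn$priors$strem1_post[as.character(long$strem1_state)]
  dplyr::mutate(long, prob = unname(prior_w) * .data$p_cond,
                p_cond = NULL)
}

#' @describeIn sepsis_bn Posterior sepsis probability for each row of a
#'   cohort, using the subject's available stratified markers as full or
#'   partial evidence.
#' @param object A `sepsis_bn` object.
#' @param newdata A cohort (raw or already stratified).
#' @param ... Unused.
#' @export
predict.sepsis_bn <- function(object, newdata, ...) {
  state_cols <- c(crp_post = "crp_state", wbc_post = "wbc_state",
                  strem1_post = "strem1_state")
  if (!any(state_cols %in% names(newdata))) {
    newdata <- stratify(newdata, object$scheme)
  }
  present <- state_cols[state_cols %in% names(newdata)]
  vapply(seq_len(nrow(newdata)), function(i) {
    ev <- vapply(present, function(col) as.character(newdata[[col]][i]),
                 character(1))
    names(ev) <- names(present)
    posterior(object, evidence = ev)
  }, numeric(1))
}

#' Write / read a fitted network as YAML
#'
#' Serializes the scheme breaks, root priors and CPT columns of a
#' `sepsis_bn` to a human-readable YAML file, and reads it back.
#'
#' @param bn A `sepsis_bn` object.
#' @param path File path.
#' @return `write_sepsis_bn()` returns `bn` invisibly; `read_sepsis_bn()`
#'   returns the reconstructed `sepsis_bn`.
#' @export
write_sepsis_bn <- function(bn, path) {
  stopifnot(inherits(bn, "sepsis_bn"))
  cpt <- tibble::as_tibble(bn$cpt)
  cols <- lapply(seq_len(nrow(cpt)), function(i) {
    list(
      crp_state = as.character(cpt$crp_state[i]),
      wbc_state = as.character(cpt$wbc_state[i]),
      strem1_state = as.character(cpt$strem1_state[i]),
      p_with = if (is.na(cpt$p_with[i])) NULL else cpt$p_with[i]
    )
  })
  out <- list(
    scheme = list(
      crp_breaks = bn$scheme$crp_post$breaks,
      wbc_breaks = bn$scheme$wbc_post$breaks,
      strem1_breaks = bn$scheme$strem1_post$breaks
    ),
    priors = lapply(bn$priors, function(p) as.list(p)),
    columns = cols
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(bn)
}

#' @rdname write_sepsis_bn
#' @export
read_sepsis_bn <- function(path) {
  spec <- yaml::read_yaml(path)
  cpt <- read_cpt_yaml(path)
  priors <- lapply(spec$priors, function(p) unlist(p))
  sepsis_bn(cpt, priors = priors)
}
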