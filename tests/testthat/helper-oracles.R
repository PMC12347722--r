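# Independent oracles and generators used across the suite.

# Random cohort with both classes present.
random_cohort <- function(n, tie_prob = 0.3) {
  repeat {
    sepsis <- rbinom(n, 1, 0.4)
    if (length(unique(sepsis)) == 2) break
  }
  # draw from a small value pool to provoke ties (incl. case-control ties)
  pool <- round(rlnorm(max(3, n %/% 2), meanlog = 5.5, sdlog = 0.5), 2)
  x <- ifelse(runif(n) < tie_prob, sample(pool, n, replace = TRUE),
              round(rlnorm(n, meanlog = 5.5, sdlog = 0.5), 2))
  tibble::tibble(
    subject_id = sprintf("R%03d", seq_len(n)),
    strem1_post = x,
    sepsis = as.numeric(sepsis)
  )
}

# Brute-force confusion-matrix scan at one threshold (marker >= cutoff
# is test-positive).
oracle_se_sp <- function(x, y, cutoff) {
  list(
    se = sum(x >= cutoff & y == 1) / sum(y == 1),
    sp = sum(x < cutoff & y == 0) / sum(y == 0)
  )
}

# Pairwise-concordance AUC: exhaustive enumeration over case-control
# pairs, ties counted 1/2.
oracle_auc_pairs <- function(x, y) {
  xp <- x[y == 1]
  xn <- x[y == 0]
  s <- 0
  for (a in xp) s <- s + sum(a > xn) + 0.5 * sum(a == xn)
  s / (length(xp) * length(xn))
}

# Random fully specified network (2x2x2) with random priors.
random_bn <- function() {
  scheme <- stratification_scheme()
  grid <- tidyr::expand_grid(
    crp_state = factor(scheme$crp_post$labels, levels = scheme$crp_post$labels),
    wbc_state = factor(scheme$wbc_post$labels, levels = scheme$wbc_post$labels),
    strem1_state = factor(scheme$strem1_post$labels,
                          levels = scheme$strem1_post$labels)
  )
  p <- runif(nrow(grid))
  cpt_data <- dplyr::mutate(grid, n = NA_integer_, n_with = NA_integer_,
                            p_with = p, p_without = 1 - p, flag = "ok")
  bn_cpt <- new_cpt_for_test(cpt_data, scheme)
  rp <- function(k) { w <- runif(k) + 0.05; w / sum(w) }
  sepsis_bn(bn_cpt, priors = list(
    crp_post = rp(2), wbc_post = rp(2), strem1_post = rp(2)
  ))
}

# Minimal constructor mirroring the exported CPT contract, for tests
# that need an arbitrary generating table.
new_cpt_for_test <- function(data, scheme) {
  structure(tibble::as_tibble(data), scheme = scheme, alpha = 0,
            class = c("sepsis_cpt", class(tibble::tibble())))
}

# Condition the enumerated joint on evidence: the independent inference
# oracle for posterior().
oracle_posterior_from_joint <- function(joint, evidence) {
  keep <- rep(TRUE, nrow(joint))
  cols <- c(crp_post = "crp_state", wbc_post = "wbc_state",
            strem1_post = "strem1_state")
  for (v in names(evidence)) keep <- keep & (joint[[cols[[v]]]] == evidence[[v]])
  sub <- joint[keep, ]
  sum(sub$prob[sub$sepsis_state == "With"]) / sum(sub$prob)
}

# All 27 evidence subsets (each variable unobserved or fixed to one of
# its two states).
all_evidence_subsets <- function(scheme) {
  opts <- lapply(c("crp_post", "wbc_post", "strem1_post"),
                 function(v) c(NA, scheme[[v]]$labels))
  names(opts) <- c("crp_post", "wbc_post", "strem1_post")
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    e <- unlist(grid[i, ])
    e[!is.na(e)]
  })
}
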