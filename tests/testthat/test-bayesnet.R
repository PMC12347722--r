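test_that("stratification follows the node boundaries, lower state inclusive", {
  scheme <- stratification_scheme()
  cohort <- tibble::tibble(
    subject_id = sprintf("s%d", 1:6),
    strem1_post = c(283.53, 283.54, 100, 904.04, 283.53, 120),
    crp_post = c(63.28, 70, 70.01, 208.7, 4.9, 71),
    wbc_post = c(14000, 14001, 6280, 44792, 13999, 14000),
    sepsis = c(0, 1, 0, 1, 0, 1)
  )
  out <- stratify(cohort, scheme)
  expect_equal(as.character(out$strem1_state),
               c("<=283.53", ">283.53", "<=283.53", ">283.53",
                 "<=283.53", "<=283.53"))
  expect_equal(as.character(out$crp_state),
               c("<=70", "<=70", ">70", ">70", "<=70", ">70"))
  expect_equal(as.character(out$wbc_state),
               c("<=14000", ">14000", "<=14000", ">14000",
                 "<=14000", "<=14000"))
  expect_equal(as.character(out$sepsis_state),
               c("Without", "With", "Without", "With", "Without", "With"))
  expect_error(stratify(dplyr::mutate(cohort, crp_post = -crp_post), scheme),
               "crp_post")
})

test_that("a three-stratum CRP scheme is expressible", {
  scheme <- stratification_scheme(crp_breaks = c(70, 138))
  expect_equal(scheme$crp_post$labels, c("<=70", "(70,138]", ">138"))
  cohort <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    crp_post = c(50, 100, 200),
    strem1_post = c(1, 1, 1), wbc_post = c(1, 1, 1),
    sepsis = c(0, 0, 1)
  )
  out <- stratify(cohort, scheme)
  expect_equal(as.character(out$crp_state), c("<=70", "(70,138]", ">138"))
  cpt <- fit_cpt(out, scheme)
  expect_equal(nrow(cpt), 12) # 3 x 2 x 2 columns
})

test_that("CPT estimation is direct relative frequency with zero-count policy", {
  scheme <- stratification_scheme()
  # 3 With / 1 Without in the all-high cell, nothing elsewhere
  data <- tibble::tibble(
    subject_id = sprintf("s%d", 1:4),
    crp_post = rep(100, 4), wbc_post = rep(20000, 4),
    strem1_post = rep(400, 4),
    sepsis = c(1, 1, 1, 0)
  ) |> stratify(scheme)
  cpt <- fit_cpt(data, scheme)
  hi <- dplyr::filter(cpt, crp_state == ">70", wbc_state == ">14000",
                      strem1_state == ">283.53")
  expect_equal(hi$p_with, 0.75)
  expect_equal(hi$p_without, 0.25)
  expect_equal(hi$flag, "ok")
  empty <- dplyr::filter(cpt, flag == "zero_count")
  expect_equal(nrow(empty), 7)
  expect_true(all(empty$p_with == 0.5))
  # smoothing pulls toward 1/2 and unflags empty cells
  cpt_s <- fit_cpt(data, scheme, alpha = 1)
  hi_s <- dplyr::filter(cpt_s, crp_state == ">70", wbc_state == ">14000",
                        strem1_state == ">283.53")
  expect_equal(hi_s$p_with, (3 + 1) / (4 + 2))
  expect_true(all(cpt_s$flag == "ok"))
  # every column sums to one
  expect_true(all(abs(cpt$p_with + cpt$p_without - 1) < 1e-12))
  expect_error(fit_cpt(data[0, ], scheme), "no records")
})

test_that("full-evidence posteriors equal the CPT cells exactly", {
  bn <- sepsis_bn(printed_sepsis_cpt())
  expect_identical(
    posterior(bn, crp = ">70", wbc = ">14000", strem1 = ">283.53"), 1)
  expect_identical(
    posterior(bn, crp = ">70", wbc = ">14000", strem1 = "<=283.53"), 0.67)
  expect_identical(
    posterior(bn, crp = "<=70", wbc = "<=14000", strem1 = ">283.53"), 0.2)
  expect_identical(
    posterior(bn, crp = "<=70", wbc = "<=14000", strem1 = "<=283.53"), 0)
  # all-high evidence dominates every other printed full-evidence posterior
  expect_true(all(
    posterior(bn, crp = ">70", wbc = ">14000", strem1 = ">283.53") >=
      c(0.67, 0.2, 0)
  ))
})

test_that("queries touching unprinted CPT columns are refused", {
  bn <- sepsis_bn(printed_sepsis_cpt())
  expect_error(posterior(bn, crp = ">70", wbc = "<=14000",
                         strem1 = ">283.53"),
               "not available")
  expect_error(posterior(bn), "not available") # marginal needs all columns
  expect_error(enumerate_joint(bn), "fully specified")
})

test_that("evidence is validated", {
  bn <- sepsis_bn(printed_sepsis_cpt())
  expect_error(posterior(bn, evidence = c(sepsis = "With")), "query target")
  expect_error(posterior(bn, crp = "banana"), "not a state")
  expect_error(posterior(bn, evidence = c(age = "old")), "unknown evidence")
})

test_that("the joint distribution normalizes and matches uniform intuition", {
  scheme <- stratification_scheme()
  uniform_cpt <- new_cpt_for_test(
    dplyr::mutate(tidyr::expand_grid(
      crp_state = factor(scheme$crp_post$labels, levels = scheme$crp_post$labels),
      wbc_state = factor(scheme$wbc_post$labels, levels = scheme$wbc_post$labels),
      strem1_state = factor(scheme$strem1_post$labels,
                            levels = scheme$strem1_post$labels)
    ), n = NA_integer_, n_with = NA_integer_, p_with = 0.5, p_without = 0.5,
    flag = "ok"),
    scheme
  )
  bn <- sepsis_bn(uniform_cpt) # uniform priors by default
  joint <- enumerate_joint(bn)
  expect_equal(nrow(joint), 16)
  expect_true(all(abs(joint$prob - 1 / 16) < 1e-12))
  expect_equal(sum(joint$prob), 1, tolerance = 1e-12)
})

test_that("posterior() agrees with joint-distribution conditioning on
           random networks for every evidence subset", {
  withr::with_seed(47, {
    subsets <- all_evidence_subsets(stratification_scheme())
    expect_equal(length(subsets), 27)
    for (i in 1:100) {
      bn <- random_bn()
      joint <- enumerate_joint(bn)
      expect_equal(sum(joint$prob), 1, tolerance = 1e-12)
      for (ev in subsets) {
        expect_equal(posterior(bn, evidence = ev),
                     oracle_posterior_from_joint(joint, ev),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("predict() maps cohort rows through stratified full evidence", {
  cohort <- simulate_cohort(simulation_params(n = 300), seed = 8)
  strat <- stratify(cohort)
  cpt <- fit_cpt(strat)
  bn <- sepsis_bn(cpt, data = strat)
  p <- predict(bn, cohort)
  expect_equal(length(p), nrow(cohort))
  expect_true(all(p >= 0 & p <= 1))
  # a subject's prediction is the CPT cell of their stratum
  i <- 1
  expect_equal(p[i], posterior(bn,
    crp = as.character(strat$crp_state[i]),
    wbc = as.character(strat$wbc_state[i]),
    strem1 = as.character(strat$strem1_state[i])))
})

test_that("a fitted network round-trips through YAML", {
  cohort <- simulate_cohort(simulation_params(n = 200), seed = 12)
  strat <- stratify(cohort)
  bn <- sepsis_bn(fit_cpt(strat), data = strat)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sepsis_bn(bn, path)
  back <- read_sepsis_bn(path)
  expect_equal(back$cpt$p_with, bn$cpt$p_with, tolerance = 1e-12)
  for (v in c("crp_post", "wbc_post", "strem1_post")) {
    expect_equal(unname(back$priors[[v]]), unname(bn$priors[[v]]),
                 tolerance = 1e-12)
  }
  expect_equal(posterior(back), posterior(bn), tolerance = 1e-12)
})
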