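test_that("ROC coordinates match a brute-force confusion-matrix scan", {
  withr::with_seed(7, {
    for (i in 1:10) {
      cohort <- random_cohort(20)
      roc <- compute_roc(cohort)
      for (k in seq_len(nrow(roc))) {
        ref <- oracle_se_sp(cohort$strem1_post, cohort$sepsis, roc$cutoff[k])
        expect_identical(roc$sensitivity[k], ref$se)
        expect_identical(roc$specificity[k], ref$sp)
      }
      # endpoints and monotonicity
      expect_equal(roc$sensitivity[1], 1)
      expect_equal(roc$specificity[1], 0)
      expect_equal(roc$sensitivity[nrow(roc)], 0)
      expect_equal(roc$specificity[nrow(roc)], 1)
      expect_true(all(diff(roc$sensitivity) <= 0))
      expect_true(all(diff(roc$specificity) >= 0))
      # step granularity: k/n_pos and m/n_neg
      expect_true(all(abs(roc$sensitivity * n_pos(roc) -
                            round(roc$sensitivity * n_pos(roc))) < 1e-9))
      expect_true(all(abs(roc$specificity * n_neg(roc) -
                            round(roc$specificity * n_neg(roc))) < 1e-9))
    }
  })
})

test_that("perfectly separated classes give the three-corner curve", {
  cohort <- tibble::tibble(
    subject_id = c("a", "b", "c", "d"),
    strem1_post = c(10, 10, 1, 1),
    sepsis = c(1, 1, 0, 0)
  )
  roc <- compute_roc(cohort)
  expect_equal(nrow(roc), 3)
  expect_equal(roc$sensitivity, c(1, 1, 0))
  expect_equal(roc$specificity, c(0, 1, 1))
  expect_warning(a <- auroc(roc), "degenerate")
  expect_equal(a$auc, 1)
  opt <- youden_optimal(roc)
  expect_equal(opt$youden_j, 1)
  expect_equal(opt$cutoff, 5.5) # separating midpoint
})

test_that("single-class cohorts are rejected", {
  cohort <- tibble::tibble(subject_id = c("a", "b"),
                           strem1_post = c(1, 2), sepsis = c(1, 1))
  expect_error(compute_roc(cohort), "without both classes")
})

test_that("trapezoidal AUC equals exhaustive pairwise concordance", {
  withr::with_seed(13, {
    for (i in 1:25) {
      cohort <- random_cohort(sample(5:40, 1))
      roc <- compute_roc(cohort)
      expect_equal(suppressWarnings(auroc(roc)$auc),
                   oracle_auc_pairs(cohort$strem1_post, cohort$sepsis),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with pROC on random cohorts", {
  skip_if_not_installed("pROC")
  withr::with_seed(17, {
    for (i in 1:5) {
      cohort <- random_cohort(30)
      ref <- as.numeric(pROC::auc(pROC::roc(
        cohort$sepsis, cohort$strem1_post,
        direction = "<", levels = c(0, 1), quiet = TRUE
      )))
      expect_equal(auroc(compute_roc(cohort))$auc, ref, tolerance = 1e-12)
    }
  })
})

test_that("flipping all labels maps AUC to its complement", {
  withr::with_seed(19, {
    for (i in 1:10) {
      cohort <- random_cohort(25)
      flipped <- dplyr::mutate(cohort, sepsis = 1 - sepsis)
      expect_equal(auroc(compute_roc(flipped))$auc,
                   1 - auroc(compute_roc(cohort))$auc, tolerance = 1e-12)
    }
  })
})

test_that("strictly increasing marker transforms leave AUC and J unchanged", {
  withr::with_seed(23, {
    for (f in list(function(x) 3 * x + 7, exp, function(x) x^3)) {
      cohort <- random_cohort(25)
      tr <- dplyr::mutate(cohort, strem1_post = f(strem1_post / 100))
      expect_equal(auroc(compute_roc(tr))$auc,
                   auroc(compute_roc(cohort))$auc, tolerance = 1e-12)
      expect_equal(youden_optimal(compute_roc(tr))$youden_j,
                   youden_optimal(compute_roc(cohort))$youden_j,
                   tolerance = 1e-12)
    }
  })
})

test_that("Hanley-McNeil interval matches direct formula evaluation", {
  withr::with_seed(29, {
    for (i in 1:10) {
      A <- runif(1, 0.05, 0.95)
      n1 <- sample(2:50, 1)
      n2 <- sample(2:50, 1)
      res <- auroc_ci(A, n1, n2)
      q1 <- A / (2 - A)
      q2 <- 2 * A^2 / (1 + A)
      se_ref <- sqrt((A * (1 - A) + (n1 - 1) * (q1 - A^2) +
                        (n2 - 1) * (q2 - A^2)) / (n1 * n2))
      expect_equal(res$se, se_ref, tolerance = 1e-15)
      expect_true(res$ci_low <= A && A <= res$ci_high)
      expect_true(res$ci_low >= 0 && res$ci_high <= 1)
    }
  })
  # symmetry about 1/2 for an uninformative AUC
  res <- auroc_ci(0.5, 10, 10)
  expect_equal(res$ci_low + res$ci_high, 1, tolerance = 1e-12)
  expect_warning(auroc_ci(1, 5, 5), "degenerate")
})

test_that("Youden optimum equals an exhaustive row scan, smallest-cutoff ties", {
  withr::with_seed(31, {
    for (i in 1:10) {
      roc <- compute_roc(random_cohort(20))
      opt <- youden_optimal(roc)
      j <- roc$sensitivity + roc$specificity - 1
      expect_equal(opt$youden_j, max(j), tolerance = 1e-12)
      expect_equal(opt$cutoff, min(roc$cutoff[j == max(j)]))
    }
  })
})

test_that("likelihood ratios handle rounding mode, exact fractions, and zeros", {
  # printed-convention mode: 3-decimal pre-rounding
  lr <- likelihood_ratios(10 / 13, 15 / 19, round_inputs = 3)
  expect_equal(lr$plr, 0.769 / 0.211, tolerance = 1e-12)
  expect_equal(round(lr$plr, 5), 3.64455)
  expect_equal(round(lr$nlr, 6), 0.292776)
  # full precision differs: exact rational value 190/52
  lr_exact <- likelihood_ratios(10 / 13, 15 / 19)
  expect_equal(lr_exact$plr, 190 / 52, tolerance = 1e-12)
  # boundary behaviour
  expect_equal(likelihood_ratios(1, 0.5)$nlr, 0)
  expect_equal(likelihood_ratios(0.8, 1)$plr, Inf)
  expect_equal(likelihood_ratios(0.8, 0)$nlr, Inf)
})

test_that("tidy/glance/autoplot expose the curve in broom style", {
  roc <- compute_roc(reconstruct_cohort(strem1_roc_coordinates()))
  td <- tidy(roc)
  expect_true(all(c("cutoff", "sensitivity", "specificity", "youden_j",
                    "plr", "nlr") %in% names(td)))
  expect_equal(td$youden_j, td$sensitivity + td$specificity - 1)
  gl <- glance(roc)
  expect_equal(nrow(gl), 1)
  expect_true(gl$ci_low <= gl$auc && gl$auc <= gl$ci_high)
  expect_s3_class(autoplot(roc), "ggplot")
})
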