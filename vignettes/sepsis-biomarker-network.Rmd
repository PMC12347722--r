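---
title: "Methods: ROC analysis, cohort reconstruction, and the sepsis Bayesian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROC analysis, cohort reconstruction, and the sepsis Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisbn)
```

This vignette documents the statistical methods in `sepsisbn`, the
choices behind their defaults, and the limits of what the package's
tests demonstrate.

## The clinical problem

Children undergoing surgical correction of congenital heart disease are
at high risk of postoperative sepsis, and the standard inflammatory
markers — C-reactive protein (CRP) and the white blood cell count
(WBC) — are individually neither sensitive nor specific enough for early
detection. sTREM-1 (soluble triggering receptor expressed on myeloid
cells-1) is a circulating marker of the innate immune response with
better discrimination in several infection settings. The analysis
implemented here evaluates postoperative sTREM-1 as a single diagnostic
marker (ROC analysis), then combines the three markers in a discrete
Bayesian network whose target node is the binary sepsis outcome recorded
within 48 h of surgery.

## Empirical ROC analysis

`compute_roc()` builds the full empirical coordinate grid. Two
conventions matter and are applied uniformly:

* **Positivity rule.** A subject is test-positive when
  `marker >= cutoff` (sepsis is associated with high values; use
  `direction = "less"` for markers oriented the other way). This makes
  the lowest cutoff classify everyone positive (Se 1, Sp 0).
* **Cutoff grid.** `min − 1`, the midpoints of consecutive distinct
  observed values, and `max + 1`. Any cutoff strictly between two
  observed values yields the same confusion matrix, so midpoints are a
  canonical, reproducible choice; the two sentinel end cutoffs pin the
  (1, 0) and (0, 1) corners.

The AUC is the trapezoidal area over the (1 − Sp, Se) polyline. For an
empirical curve this equals the Mann–Whitney concordance with ties
counted 1/2; the test suite asserts that identity to 1e−12 against an
exhaustive scan over all case–control pairs, and cross-checks the value
against pROC. Two further invariants are tested as properties: flipping
all outcome labels maps A to 1 − A, and any strictly increasing marker
transform leaves A and the maximal Youden index unchanged.

The confidence interval uses the Hanley–McNeil distribution-free
standard error (Q₁ = A/(2 − A), Q₂ = 2A²/(1 + A)) with a normal
approximation, clipped to [0, 1]. Small-sample ROC software differs in
the exact SE variant; for 13 cases and 19 controls at A = 0.761 the
alternatives agree to roughly ±0.01 per bound, which is the tolerance
the acceptance test uses. A degenerate A of exactly 0 or 1 yields a
zero-width interval with a warning rather than an error.

`youden_optimal()` scans all rows for the maximum of J = Se + Sp − 1;
ties are broken toward the **smallest** cutoff. The tie-break is a
design choice: it is deterministic and, in a screening context, prefers
the more sensitive of two equally informative cutoffs. The reference
table has a unique maximizer, so the choice does not affect the shipped
results.

`likelihood_ratios()` has a `round_inputs` mode that first rounds Se and
Sp to a given number of decimals. The default is full precision; the
3-decimal mode exists because published tables print proportions to
three decimals, and quoted likelihood ratios (e.g. 0.769/0.211) are
computed from those printed values. With exact fractions 10/13 and
15/19, the full-precision PLR is 190/52 ≈ 3.654, while the 3-decimal
mode gives 3.64455 — both are correct answers to different questions,
and the package keeps them distinct. Division by zero returns an
in-band `Inf` (a perfect-specificity cutoff genuinely has an infinite
PLR); 0/0 corners return `NaN`.

## Recovering a cohort from a printed coordinate table

A published empirical ROC coordinate table over-determines the cohort
that produced it: sensitivities move in steps of 1/n₁ and specificities
in steps of 1/n₀, and each interval between consecutive cutoffs contains
exactly the subjects implied by those steps. `reconstruct_cohort()`
inverts the table:

1. **Monotonicity repair** (`repair_roc_coordinates()`). Printed tables
   can contain typographical errors. Violating entries are identified as
   the complement of the longest monotone subsequence of each column —
   the minimal set of entries whose removal restores monotonicity. This
   is done *before* class-size inference, because a corrupted entry can
   otherwise draw the denominator search to a spurious large value.
2. **Class-size inference** (`infer_class_sizes()`). Each class size is
   the smallest denominator d ≤ 1000 such that every (conforming) entry
   is within 1e−3 — the rounding radius of a 3-decimal table — of an
   integer multiple of 1/d. During repair, at most one non-violating
   entry per column may miss this test (it is then snapped to the
   nearest step and logged); the exported `infer_class_sizes()` applies
   the strict all-entries criterion.
3. **Repair values.** A violating entry is replaced by the count-space
   interpolation of its monotone neighbours, rounded to the nearest
   integer count. When the neighbours differ by two steps this choice is
   not forced by monotonicity alone (either neighbour's count, or the
   value between them, would be consistent); interpolation is the
   package's deterministic tie-break and distributes one event to each
   adjacent interval, the least-assuming completion.
4. **Event placement.** Between consecutive cutoffs, Δ(Se)·n₁ case and
   Δ(Sp)·n₀ control events share one marker value (reproducing ties
   between a case and a control). Interior intervals use the midpoint of
   the two cutoffs; the first and last intervals use `first cutoff + 1`
   and `last cutoff − 1`, mirroring the `min − 1`/`max + 1` grid
   convention so that `compute_roc()` on the reconstruction reproduces
   the printed Se/Sp columns *exactly*, row for row. That round trip,
   and conservation of both class sizes, are asserted as properties on
   randomly generated cohorts.

In the shipped table the repair stage changes two entries: the
non-monotone specificity 0.470 (restored to 18/19 ≈ 0.947 by
count-space interpolation between 17/19 and 19/19) and the off-grid
0.787 (snapped to 15/19 ≈ 0.789). The printed J column of such tables
is never read — J is always recomputed from Se and Sp.

What reconstruction cannot do: recover the raw marker values (only
their order statistics relative to the cutoff grid survive printing) or
any column the table does not carry (the recovered cohort has the
thresholded marker and the outcome only). Cutoff *coordinates* reported
downstream are therefore grid midpoints, while cutoff *statistics* (Se,
Sp, J, PLR, NLR, AUC) are exact.

## The Bayesian network

The structure is fixed: three root nodes — CRP, WBC and sTREM-1 states —
each with a directed edge into the binary SEPSIS child. Discretization
(`stratification_scheme()`) uses two states per marker by default:

| node | boundary | default states |
|---|---|---|
| CRP_POST | 70 mg/dL | `<=70`, `>70` |
| WBC_POST | 14,000 cells/µL | `<=14000`, `>14000` |
| sTREM-1_POST | 283.53 pg/mL (the Youden-optimal cutoff) | `<=283.53`, `>283.53` |

The lower state is inclusive of its boundary, uniformly. The published
node table leaves the CRP interval 71–138 mg/dL unassigned between its
two printed strata and elsewhere describes three CRP strata; the package
defaults to a clean two-state split at 70 (giving the 2×2×2 = 8-column
CPT that matches the published probabilities) and accepts arbitrary
break vectors, so a three-stratum CRP scheme (e.g. breaks at 70 and 138,
12 columns) is expressible when wanted.

`fit_cpt()` estimates each column by relative frequency,
(n_with + α)/(n + 2α) with pseudo-count α (default 0, i.e. the raw
frequency distribution). With 32 subjects spread over 8 columns, empty
columns are expected; under α = 0 they are set to the uninformative
(0.5, 0.5) and flagged `zero_count` so downstream users can distinguish
"estimated" from "unobserved".

`posterior()` performs exact inference by enumeration. The roots are
independent a priori, so conditioning on evidence E gives

P(With | E) = Σ over unobserved parent states u of Π π_v(u_v) · CPT(E, u),

which under full evidence is the CPT cell itself. Root priors are not
part of the published model; defaults are the empirical state
frequencies of the fitted data (uniform when no data are supplied), and
full-evidence queries are prior-independent. `enumerate_joint()` builds
the full 16-state joint by a separate code path; the suite checks
posterior() against conditioning of that joint, to 1e−12, for all 27
evidence subsets on 100 randomly parameterized networks. No
approximate inference exists anywhere: the state space is 8
combinations and exactness is free.

The packaged CPT transcribes the four published columns (the all-low
and all-high CRP/WBC combinations for both sTREM-1 strata); the four
unpublished columns are `NA`, flagged `not_printed`, and any query
touching them errors rather than guessing. Whether the original model
applied smoothing or expert adjustment is unstated; raw frequencies are
assumed (α = 0).

## The synthetic cohort generator

`simulate_cohort()` exists so every stage is testable without any data
download, and for parameter-recovery experiments. The generating model:
labels Bernoulli(0.41); each marker lognormal conditional on the label,
with `meanlog`/`sdlog` solved analytically so the arithmetic mean and SD
are matched exactly (`lognormal_moments()`); markers conditionally
independent given the label. The lognormal family was chosen because all
three markers are positive and right-skewed — overall CRP has SD ≈ mean
(63.25 vs 63.28 mg/dL), which a normal distribution cannot produce
without truncating negative mass.

sTREM-1 group parameters are the published ones (394.58 ± 211.91 vs
239.93 ± 100.88 pg/mL). Group-wise CRP and WBC parameters are *not*
published — only overall moments are — so the defaults
(CRP 110 ± 70 septic vs 30 ± 30; WBC 24,000 ± 12,000 vs 13,500 ± 6,000)
are a synthetic choice fixed once: their prevalence-0.41 mixtures
reproduce the published overall moments to within a few percent, and
stratified draws produce a CPT qualitatively like the published one
(all-high column near 1). They are documented as synthetic and should
not be read as estimates of the real group distributions.

`simulate_from_cpt()` draws parent combinations from the root priors
(uniform over available columns by default) and the sepsis state from
the CPT column, for recovery tests of `fit_cpt()`.

What the generator does **not** emulate: correlation among markers
within outcome groups (none is reported, independence is assumed),
demographic covariates, preoperative measurements, or temporal
dynamics. Tests passing on synthetic data therefore demonstrate the
correctness of the estimators under the stated generating model, not
the clinical performance of the markers on new patients.

## Numerical and scale choices

* Proportion-to-fraction matching tolerance 1e−3 (3-decimal printing);
  integer-consistency of reconstructed event counts checked at 1e−6;
  probability normalization checks at 1e−12.
* Denominator search capped at 1000; class sizes beyond that are not
  plausibly recoverable from a 3-decimal table anyway.
* Seeds: every stochastic function takes an explicit `seed` and uses a
  scoped RNG (`withr::with_seed`), leaving the caller's RNG state
  untouched; identical inputs give byte-identical cohorts.
* Test problem sizes: pairwise-concordance oracles run on cohorts of
  up to 40 subjects (exhaustive enumeration stays trivial); moment
  checks use 100,000 draws; CPT recovery uses 50,000 draws (expected
  12,500 per sampled column, giving ±0.02 sup-norm headroom at
  binomial noise ≈ 0.004); inference equivalence uses 100 random
  networks × 27 evidence subsets. These sizes make the Monte-Carlo
  assertions sharp while keeping the default suite fast.

## Known limitations

* The reference cohort is small (n = 32, 13 septic); the Hanley–McNeil
  normal approximation is rough at this size and the CPT's printed
  extreme cells (0% and 100%) rest on very few subjects per column —
  the package reproduces them, it does not endorse them as stable
  estimates.
* Reconstruction recovers order statistics only; any analysis depending
  on raw marker magnitudes (e.g. refitting the lognormal model to the
  recovered cohort) is out of reach by construction.
* The network assumes a priori independent roots and a fixed structure;
  no structure learning, no inter-marker edges, no continuous nodes.
* The unpublished half of the CPT cannot be recovered; queries needing
  it must refit from data.
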