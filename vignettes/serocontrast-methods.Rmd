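---
title: "Methods: contrast-score serology classification with stability selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrast-score serology classification with stability selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serocontrast)
```

## The measurement model

Peptide-array serology measures serum IgG binding to an immobilised peptide
library as relative fluorescence units (RFU). Unlike expression arrays, the
biology is nearly discrete: a given serum binds only a small fraction of
peptides (on the order of 10^3 out of several hundred thousand) at levels
roughly 50-fold above background, so the pooled RFU distribution is bimodal
and positively skewed, and per-peptide intensities carry little usable
information beyond "bound" versus "not bound". `serocontrast` therefore
dichotomises first and runs all statistics on binary patient-positive
calls.

**Positivity rule.** A sample is patient-positive for a peptide when
strictly more than `rfu_threshold` RFU (default 20,000) is observed in at
least `min_positive_replicates` (default 2) of its replicate arrays
(default 4). The strict inequality is a deliberate reading of "over": the
boundary value itself is negative, and the threshold is configurable when a
different background level warrants it. Pairs with missing replicates are
called on the replicates present with the required count unchanged, which
can only lose positives — the conservative direction for a screen.

**Prevalence filter.** Peptides patient-positive in fewer than
`min_prevalence` (default 3) samples of the analysis cohort are excluded
before testing; a 2×2 test on a peptide seen once or twice is pure noise.
The filter is deliberately cohort-scoped: response and adverse-event
cohorts differ in membership, so each defines its own peptide universe from
the same calls. A global "seen in at least one sample anywhere" pre-filter
is the same function with `min_prevalence = 1` over all samples.

## Stability selection

For a two-group contrast, each candidate peptide's 2×2 table (positive /
negative × group) is tested with the uncorrected Pearson chi-square

$$X^2 = \frac{(ad-bc)^2\,N}{(a+b)(c+d)(a+c)(b+d)}, \qquad
p = P(\chi^2_1 \ge X^2),$$

on each of `n_iterations` (default 100) random subsamples of
`subsample_fraction` (default 0.8) of the cohort, drawn without
replacement. Peptides significant at `p_threshold` (default 0.05) in at
least `recurrence_threshold` (default 70) iterations are retained.
Recurrence across subsamples — not multiple-testing correction — is the
error control: a peptide must owe its association to the cohort, not to a
handful of samples.

Numerical conventions, all chosen for a screening context:

* **No continuity correction** by default. The Yates correction is
  conservative in small tables and screening favours the liberal filter;
  `correct = TRUE` toggles it.
* **Zero-margin tables score p = 1**, not NaN: a peptide positive in nobody
  (or everybody) in a subsample is uninformative there and must simply fail
  that iteration.
* **Subsample size is `floor(fraction · n)`** — deterministic, erring
  toward smaller subsamples.
* **Unstratified draws**: one draw from the pooled cohort, so a subsample
  can (rarely) empty a pole; every table then has a zero margin, the
  iteration contributes nothing, and a warning is logged.
* **Seed policy**: the master seed spawns one seed per iteration up front,
  so extending `n_iterations` adds iterations without changing earlier
  draws, and recurrence is bit-reproducible across platforms (integer
  counting happens only after the p-value comparison).

**Direction assignment.** A retained peptide is coded +1 if more samples of
the positive pole are positive for it over the full cohort, −1 if the
negative pole has more. Equal counts leave no majority group, so tied
peptides are dropped with a warning rather than coded arbitrarily.

A note on null behaviour: iterations are resamples of one cohort, so their
test outcomes are strongly positively correlated. A truly non-differential
peptide whose full-cohort table happens to reach p < 0.05 (probability
about the test level) will usually stay significant in most 80%
subsamples. The per-peptide false-retention probability is therefore on the
order of 1–2%, not the naive binomial tail $P(\mathrm{Bin}(100, 0.05) \ge
70)$; it is the upstream prevalence filter, which removes the great
majority of null peptides outright, that keeps the pipeline-level null
admission rate near zero (measured below 10^-4 in the recovery
experiments).

## Scoring and the indeterminate class

A sample's contrast score is the sum of the codes of the model peptides it
binds; unbound peptides contribute zero, so the score decomposes exactly as
(positives on +1 peptides) − (positives on −1 peptides) and is an integer
bounded by the model size. No normalisation by model size is applied — the
procedure sums raw ±1 codes. Positive scores predict the positive pole,
negative the negative pole. A zero score — no model peptide bound, or
balanced binding — is **indeterminate**: the classifier abstains rather
than guesses.

When every retained peptide associates with one pole (the typical outcome
for adverse-event contrasts), the two-sided score cannot go negative and
the model switches to **unidirectional** scoring: a sample binding at least
`unidirectional_threshold` model peptides (default 1, exposed because a
threshold is a tunable) is predicted to that pole and everything else
defaults to the opposite pole, with no indeterminates. `assign_directions()`
chooses the mode automatically from the code signs; either mode can be
forced. For adverse-event evaluation the package scores the full annotated
cohort against the final model; scoring only resampling holdouts is the
documented alternative, but the full-cohort convention matches how such
models are reported and keeps evaluation deterministic given the model.

## Evaluation conventions

Reports are built on the 2×3 confusion table (observed group × predicted
positive / predicted negative / indeterminate). `coverage` is the fraction
classified; `accuracy_classified` is accuracy among the classified — the
convention under which an abstaining classifier's headline numbers are
quoted — and `accuracy_overall` (indeterminates counted as errors) is
emitted alongside for transparency. Sensitivity and specificity treat the
positive pole as the positive class and exclude indeterminates from the
denominators, except under unidirectional scoring where below-threshold
samples are real (negative-pole) predictions and count fully. Printed
percentages are rendered to one decimal; machine output keeps full
precision.

Published confusion tables for this kind of pipeline are occasionally
internally inconsistent with their accompanying prose (e.g. a 2×2 table
whose counts imply 77.8% sensitivity and 95.2% specificity alongside text
quoting 87.5% and 91%). `serocontrast` always computes metrics from counts
and leaves reconciling prose to the reader; the package never stores a
metric it cannot reconstruct from its own table, and a reconstruction
identity is enforced in the test suite.

## The synthetic generator

`simulate_cohort()` generates what the analysis assumes, not what an array
scanner produces:

* **Background**: lognormal with median ≈ 400 RFU (`background_log_mean =
  log(400)`, `background_log_sd = 0.5`) — the ~50-fold separation below a
  20,000 RFU threshold. No distributional form is canonical here; lognormal
  is the least-parameter positively-skewed choice.
* **Bound signal**: uniform on 25,000–60,000 RFU, clipped at the 16-bit
  saturation of 65,535 — comfortably above threshold without modelling
  affinity.
* **Replicates**: multiplicative lognormal jitter at `replicate_cv = 0.15`;
  at that noise level ≥ 99% of truly bound pairs pass the 2-of-4 rule
  (verified by Monte-Carlo in the tests). `replicate_dropout_rate` can fail
  bound replicates to background to stress the consensus rule.
* **Sparsity**: every peptide binds each sample at `baseline_positive_rate
  = 0.003`; planted peptides bind at `prevalence_in_group = 0.5` in their
  associated group and `prevalence_out_group = 0.03` elsewhere. Planted
  response-associated peptides exist for both poles (markers of response
  and of progression), while planted adverse-event peptides are one-sided,
  and the three sets are disjoint — mirroring the qualitative structure the
  analysis is designed around.
* **Annotations**: default stratum sizes reproduce the reference cohort's
  margins — 74 samples (1 CR, 25 PR, 13 SD, 27 PD, 8 under six weeks of
  treatment), 18/42/14 symptomatic/asymptomatic/unknown irAE grades, 26
  combination-therapy samples among the 66 evaluable (hence 40 monotherapy),
  9 evaluable SCLC, 2 EGFR-mutant PD samples. Category assignments are
  mutually independent given these counts, so the short-treatment and
  irAE-unknown subsets overlap at random — the filters are treated as
  independent. The default array is desk-scale (5,000 peptides); full-scale
  generation works but nothing in the tests needs it.

What passing tests on this generator do **not** show: robustness to
spatial artefacts, batch effects between slides, antibody cross-reactivity
between similar peptides, or intensity-dependent noise — none of which are
simulated. The generator validates the statistics pipeline, not the assay.

`recovery_experiment()` runs the full pipeline per seed (simulate, call,
filter, select, code, score a generated holdout excluded from selection)
and reports planted-marker recall, null-peptide admission (admitted model
peptides over all non-planted peptides on the array) and holdout
accuracy/coverage. At the default 25 + 25 samples with 30 planted peptides
per pole, mean recall across 20 seeds is ≈ 0.96 with null admission below
10^-4 and holdout accuracy ≈ 1 — these are the figures the acceptance
script recomputes.

## Problem sizes and runtime

Unit tests run on arrays of a few hundred peptides and cohorts of 20–80
samples; the recovery suite uses 5,000-peptide arrays over 20 seeds. A full
fit at 5,000 peptides × 74 samples × 4 replicates takes well under a second
on one core after simulation, so the whole suite completes in tens of
seconds. These sizes were chosen as the smallest at which the binomial and
chi-square power calculations say the planted effects are comfortably
detectable; they are the package's own defaults, and scale up unchanged.

## Known limitations

* Labels are taken as given: no RECIST computation, no survival modelling,
  no probabilistic calibration of scores — the classifier is discrete by
  design and reports no margins of confidence.
* The chi-square screen is marginal per peptide; correlated peptides are
  selected or rejected independently, and the contrast score weights them
  equally.
* Two independently seeded selection runs on the same cohort agree closely
  but not exactly (the recurrence cut is sharp at 70); comparing two runs'
  peptide sets by Jaccard overlap is supported via `model_overlap()`, but
  no universal agreement threshold is defined.
* With no deposited raw data for the reference cohort, model *content*
  (which peptides) is only meaningful on synthetic data; what is
  reproducible exactly are the evaluation metrics implied by published
  confusion tables and cohort arithmetic, which is what the acceptance
  script checks.
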