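test_that("chisq_2x2 matches hand-derived values and conventions", {
  expect_equal(chisq_2x2(5, 5, 5, 5)$statistic, 0)
  expect_equal(chisq_2x2(5, 5, 5, 5)$p_value, 1)

  res <- chisq_2x2(10, 10, 0, 20)
  expect_equal(res$statistic, 40 / 3, tolerance = 1e-12)
  expect_equal(res$p_value, 2.607296e-4, tolerance = 1e-6)

  # zero positive margin -> uninformative by convention
  res <- chisq_2x2(0, 20, 0, 20)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  expect_error(chisq_2x2(0, 0, 0, 0), "degenerate")
  expect_error(chisq_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("chisq_2x2 agrees with the expected-count oracle and chisq.test on random tables", {
  set.seed(20)
  tabs <- matrix(rpois(400, 8), ncol = 4)
  # keep tables with both margins non-zero so all three routes are defined
  ok <- (tabs[, 1] + tabs[, 2]) > 0 & (tabs[, 3] + tabs[, 4]) > 0 &
    (tabs[, 1] + tabs[, 3]) > 0 & (tabs[, 2] + tabs[, 4]) > 0
  tabs <- tabs[ok, ]
  got <- chisq_2x2(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
  for (i in seq_len(nrow(tabs))) {
    tab <- matrix(tabs[i, ], 2, byrow = TRUE)
    # independent oracle 1: sum((O - E)^2 / E)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got$statistic[i], sum((tab - e)^2 / e), tolerance = 1e-10)
    # independent oracle 2: stats::chisq.test without continuity correction
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value[i], ref$p.value, tolerance = 1e-10)
  }
  # Yates correction toggle against the base implementation
  ref <- suppressWarnings(stats::chisq.test(matrix(c(8, 4, 2, 9), 2), correct = TRUE))
  got <- chisq_2x2(8, 2, 4, 9, correct = TRUE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
})

make_selection_fixture <- function(seed, n_pos = 20, n_neg = 20,
                                   prev_pos = 0.6, prev_neg = 0.0,
                                   n_null = 5, prev_null = 0.3) {
  set.seed(seed)
  n <- n_pos + n_neg
  m <- cbind(
    planted = c(runif(n_pos) < prev_pos, runif(n_neg) < prev_neg),
    matrix(runif(n * n_null) < prev_null, n,
           dimnames = list(NULL, paste0("null", seq_len(n_null))))
  )
  rownames(m) <- sprintf("S%02d", seq_len(n))
  list(pos = positivity_from_matrix(m), cohort = toy_cohort(n_pos, n_neg))
}

test_that("a strongly differential peptide recurs above threshold; balanced peptides do not", {
  for (seed in c(11, 12, 13)) {
    fx <- make_selection_fixture(seed)
    rec <- resample_select(fx$pos, fx$cohort, colnames(fx$pos)[-1], seed = seed)
    expect_equal(rec$peptide_id, colnames(fx$pos)[-1])
    expect_gte(rec$recurrence[rec$peptide_id == "planted"], 70)
    expect_true(all(rec$recurrence[rec$peptide_id != "planted"] < 70))
  }
})

test_that("degenerate resampling reduces to the full-cohort test indicator", {
  fx <- make_selection_fixture(21)
  peps <- colnames(fx$pos)[-1]
  rec <- resample_select(fx$pos, fx$cohort, peps,
                         subsample_fraction = 1, n_iterations = 1, seed = 5)
  m <- positivity_matrix(fx$pos)
  is_pos <- fx$cohort$label == "non_progressor"
  a <- colSums(m[is_pos, peps, drop = FALSE])
  c_ <- colSums(m[!is_pos, peps, drop = FALSE])
  full <- chisq_2x2(a, sum(is_pos) - a, c_, sum(!is_pos) - c_)
  expect_equal(rec$recurrence, as.integer(full$p_value < 0.05))
})

test_that("selection is deterministic in the seed and stable under added iterations", {
  fx <- make_selection_fixture(31)
  peps <- colnames(fx$pos)[-1]
  r1 <- resample_select(fx$pos, fx$cohort, peps, seed = 123)
  r2 <- resample_select(fx$pos, fx$cohort, peps, seed = 123)
  expect_identical(r1, r2)
  r3 <- resample_select(fx$pos, fx$cohort, peps, seed = 124)
  expect_false(identical(r1$recurrence, r3$recurrence))
  # extending the iteration count only adds iterations: recurrence can only grow
  r150 <- resample_select(fx$pos, fx$cohort, peps, n_iterations = 150, seed = 123)
  expect_true(all(r150$recurrence >= r1$recurrence))
})

test_that("swapping pole labels leaves recurrence unchanged and negates codes", {
  fx <- make_selection_fixture(41)
  peps <- colnames(fx$pos)[-1]
  r_a <- resample_select(fx$pos, fx$cohort, peps, seed = 9)
  r_b <- resample_select(fx$pos, swap_poles(fx$cohort), peps, seed = 9)
  expect_equal(r_a$recurrence, r_b$recurrence)

  retained <- r_a[r_a$recurrence >= 70, ]
  m_a <- assign_directions(fx$pos, fx$cohort, retained)
  m_b <- assign_directions(fx$pos, swap_poles(fx$cohort), retained)
  expect_equal(m_b$code, -m_a$code)
})

test_that("directional assignment follows the positive-count majority and drops ties", {
  m <- cbind(resp10 = c(rep(TRUE, 10), rep(FALSE, 10)),
             minor  = c(rep(TRUE, 3), rep(FALSE, 7), rep(TRUE, 7), rep(FALSE, 3)),
             tied   = rep(c(TRUE, FALSE), 10))
  rownames(m) <- sprintf("S%02d", 1:20)
  pos <- positivity_from_matrix(m)
  cohort <- toy_cohort(10, 10)
  expect_warning(model <- assign_directions(pos, cohort, colnames(m)), "tie|equal")
  expect_equal(model$code[model$peptide_id == "resp10"], 1L)
  expect_equal(model$code[model$peptide_id == "minor"], -1L)
  expect_false("tied" %in% model$peptide_id)
  expect_error(assign_directions(pos, cohort, character(0)), "empty")
})

test_that("one-sided retained sets switch to unidirectional scoring under auto mode", {
  m <- cbind(a = c(rep(TRUE, 8), rep(FALSE, 12)),
             b = c(rep(TRUE, 7), rep(FALSE, 13)))
  rownames(m) <- sprintf("S%02d", 1:20)
  pos <- positivity_from_matrix(m)
  model <- assign_directions(pos, toy_cohort(10, 10), colnames(m))
  expect_equal(attr(model, "scoring_mode"), "unidirectional")
  expect_error(
    assign_directions(pos, toy_cohort(10, 10),
                      tibble::tibble(peptide_id = "a", recurrence = 70L),
                      scoring_mode = "bidirectional"),
    NA)
})

test_that("emptied-pole subsamples warn and count nothing", {
  m <- cbind(p = c(TRUE, rep(FALSE, 9)))
  rownames(m) <- sprintf("S%02d", 1:10)
  pos <- positivity_from_matrix(m)
  cohort <- toy_cohort(1, 9) # one-sample pole often absent from 80% draws
  expect_warning(
    rec <- resample_select(pos, cohort, "p", n_iterations = 50, seed = 3),
    "empty pole")
  expect_true(rec$recurrence <= 50)
})
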