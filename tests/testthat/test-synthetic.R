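# Small configuration used throughout: keeps generator tests well under a
# second each while preserving the default rates and signal structure.
small_config <- function(...) {
  sim_config_balanced(n_per_group = 10, n_peptides = 400,
                      n_informative_pos = 8, n_informative_neg = 8,
                      n_informative_irae = 4, ...)
}

test_that("generation is bit-stable under a fixed seed and leaves the caller's RNG alone", {
  a <- simulate_cohort(small_config(), seed = 99)
  set.seed(1); before <- runif(1)
  b <- simulate_cohort(small_config(), seed = 99)
  expect_identical(tibble::as_tibble(a$binding), tibble::as_tibble(b$binding))
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth, b$truth)
  set.seed(1); expect_identical(runif(1), before)
  c_ <- simulate_cohort(small_config(), seed = 100)
  expect_false(identical(tibble::as_tibble(a$binding), tibble::as_tibble(c_$binding)))
})

test_that("generated RFU respect the saturation range and are bimodal", {
  sim <- simulate_cohort(sim_config_balanced(n_per_group = 8, n_peptides = 600),
                         seed = 3)
  rfu <- sim$binding$rfu
  expect_true(all(rfu >= 0 & rfu <= 65535))
  # valley test: background mode (median ~400) and bound mode (>= 25000)
  # leave almost nothing in the mid band
  mid <- mean(rfu > 5000 & rfu <= 20000)
  low <- mean(rfu <= 5000)
  high <- mean(rfu > 20000)
  expect_lt(mid, 0.005)
  expect_gt(low, 0.9)
  expect_gt(high, 0.001)
})

test_that("planted sets are disjoint and respect config counts", {
  sim <- simulate_cohort(small_config(), seed = 5)
  tr <- sim$truth
  expect_length(tr$planted_pos, 8)
  expect_length(tr$planted_neg, 8)
  expect_length(tr$planted_irae, 4)
  all_planted <- c(tr$planted_pos, tr$planted_neg, tr$planted_irae)
  expect_equal(anyDuplicated(all_planted), 0L)
  expect_true(all(all_planted %in% attr(sim$binding, "peptide_ids")))
  expect_error(sim_config(n_peptides = 10, n_informative_pos = 20), "exceed")
  expect_error(sim_config(prevalence_in_group = 0.1, prevalence_out_group = 0.2),
               "exceed")
})

test_that("truly bound pairs are called positive at the default rule almost surely", {
  # aggregate over seeds: the lognormal replicate jitter at cv 0.15 leaves
  # >= 99% of bound pairs over threshold in at least 2 of 4 replicates
  called <- total <- 0
  for (seed in 1:5) {
    sim <- simulate_cohort(small_config(), seed = seed)
    m <- positivity_matrix(call_positivity(sim$binding))
    bound <- sim$truth$bound
    called <- called + sum(m & bound)
    total <- total + sum(bound)
  }
  expect_gt(total, 500)
  expect_gte(called / total, 0.99)
})

test_that("null-peptide positive-call rate matches the configured baseline", {
  # closed form: a null (sample, peptide) pair is called positive iff truly
  # bound (rate r), since background essentially never crosses threshold and
  # bound pairs essentially always do
  rates <- c()
  n_cells <- 0
  for (seed in 1:10) {
    sim <- simulate_cohort(small_config(), seed = 100 + seed)
    nulls <- setdiff(attr(sim$binding, "peptide_ids"),
                     c(sim$truth$planted_pos, sim$truth$planted_neg,
                       sim$truth$planted_irae))
    m <- positivity_matrix(call_positivity(sim$binding))[, nulls]
    rates <- c(rates, mean(m))
    n_cells <- n_cells + length(m)
  }
  p0 <- small_config()$baseline_positive_rate
  se <- sqrt(p0 * (1 - p0) / n_cells)
  expect_lt(abs(mean(rates) - p0), 3 * se + 1e-6)
})

test_that("replicate dropout lowers the bound-pair call rate", {
  cfg_drop <- small_config(replicate_dropout_rate = 0.6)
  called <- total <- 0
  for (seed in 1:3) {
    sim <- simulate_cohort(cfg_drop, seed = seed)
    m <- positivity_matrix(call_positivity(sim$binding))
    called <- called + sum(m & sim$truth$bound)
    total <- total + sum(sim$truth$bound)
  }
  expect_lt(called / total, 0.95)
})

test_that("annotations honour the study's stratum sizes", {
  sim <- simulate_cohort(sim_config(n_peptides = 200), seed = 11)
  ann <- sim$annotations
  expect_equal(nrow(ann), 74)
  expect_equal(unname(table(ann$best_response)[c("CR", "PR", "SD", "PD")]),
               c(1L, 25L, 13L, 27L), ignore_attr = TRUE)
  expect_equal(sum(is.na(ann$best_response)), 8)
  expect_true(all(ann$treatment_weeks[is.na(ann$best_response)] < 6))
  expect_equal(sum(ann$irae_grade == "unknown"), 14)
  expect_equal(sum(ann$irae_grade %in% c("2", "3", "4")), 18)
  expect_equal(sum(ann$therapy == "combination"), 30)
  expect_equal(sum(ann$subtype == "SCLC"), 10)
  expect_equal(sum(ann$egfr_mutant), 2)
  expect_true(all(ann$best_response[ann$egfr_mutant] == "PD"))
})

test_that("label permutation destroys planted-marker recovery", {
  # with correct labels the planted peptides are recovered; with labels
  # shuffled before selection, recovery collapses to chance
  recalls <- shuffled_recalls <- c()
  for (seed in 1:3) {
    cfg <- sim_config_balanced(n_per_group = 20, n_peptides = 800,
                               n_informative_pos = 10, n_informative_neg = 10,
                               n_informative_irae = 0)
    sim <- simulate_cohort(cfg, seed = seed)
    cohort <- build_cohort(sim$annotations, "progression")
    pos <- call_positivity(sim$binding)
    planted <- c(sim$truth$planted_pos, sim$truth$planted_neg)

    model <- fit_contrast_model(pos, cohort, seed = seed,
                                scoring_mode = "bidirectional")
    recalls <- c(recalls, mean(planted %in% model$peptide_id))

    set.seed(seed + 1000)
    shuf <- cohort
    shuf$label <- sample(shuf$label)
    sh_model <- tryCatch(
      fit_contrast_model(pos, shuf, seed = seed, scoring_mode = "bidirectional"),
      error = function(e) NULL)
    sh_recall <- if (is.null(sh_model)) 0 else mean(planted %in% sh_model$peptide_id)
    shuffled_recalls <- c(shuffled_recalls, sh_recall)
  }
  expect_gte(mean(recalls), 0.9)
  expect_lte(mean(shuffled_recalls), 0.1)
})

test_that("recovery experiment summarises per-seed pipeline runs", {
  rec <- recovery_experiment(
    config = sim_config_balanced(n_per_group = 15, n_peptides = 500,
                                 n_informative_pos = 10, n_informative_neg = 10,
                                 n_informative_irae = 0),
    n_seeds = 3, seed = 7, holdout_per_group = 5)
  expect_equal(nrow(rec), 3)
  expect_true(all(is.na(rec$error)))
  gl <- glance(rec)
  expect_equal(gl$n_seeds, 3)
  expect_true(gl$mean_recall >= 0 && gl$mean_recall <= 1)
  expect_true(gl$mean_holdout_coverage > 0)
})
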