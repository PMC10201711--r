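#' Configuration for the synthetic serology cohort generator
#'
#' The generator emulates the statistical structure of high-density peptide
#' array serology: per-sample binding is sparse (a per-sample baseline rate
#' of truly bound peptides), the RFU distribution is bimodal and positively
#' skewed (a lognormal background with median ~400 RFU against a bound-signal
#' mode at 25,000--60,000 RFU, roughly 50-fold separation), replicates jitter
#' multiplicatively, and outcome-associated peptides are planted with a
#' prevalence differential between clinical groups. Defaults mirror a
#' 74-sample immunotherapy lung-cancer cohort (1 CR, 25 PR, 13 SD, 27 PD plus
#' 8 short-treatment samples; 18 symptomatic vs 42 asymptomatic irAE with 14
#' unknown; 26 of the 66 evaluable samples on combination therapy; 9 SCLC)
#' at a desk-scale array of 5,000 peptides.
#'
#' @param n_peptides Peptides on the simulated array.
#' @param response_counts Named counts for `CR`, `PR`, `SD`, `PD`.
#' @param n_short_treatment Samples treated under 6 weeks (no best response).
#' @param irae_counts Named counts for `symptomatic` (grade 2--4),
#'   `asymptomatic` (grade 0--1), `unknown`; must sum to the total sample
#'   count.
#' @param n_combination_evaluable,n_combination_short Combination-therapy
#'   samples among response-evaluable and short-treatment samples.
#' @param n_sclc_evaluable,n_sclc_short SCLC samples in each stratum.
#' @param n_egfr_mutant EGFR-mutant samples (assigned among PD samples).
#' @param n_replicates Replicate arrays per sample (default quadruplicate).
#' @param background_log_mean,background_log_sd Lognormal parameters of the
#'   unbound background RFU (defaults give median 400 RFU).
#' @param positive_rfu_low,positive_rfu_high Uniform range of the true
#'   bound-signal level in RFU.
#' @param saturation Scanner saturation; values are clipped here (16-bit).
#' @param replicate_cv Multiplicative coefficient of variation across
#'   replicate arrays.
#' @param baseline_positive_rate Per-sample fraction of peptides truly bound
#'   irrespective of group.
#' @param n_informative_pos,n_informative_neg Peptides planted as associated
#'   with the non-progressor / progressor pole of the response contrast.
#' @param n_informative_irae Peptides planted one-sidedly in the symptomatic
#'   irAE group (disjoint from the response-planted sets).
#' @param prevalence_in_group,prevalence_out_group True-binding prevalence of
#'   a planted peptide in its associated group vs elsewhere.
#' @param replicate_dropout_rate Per-replicate probability that a bound
#'   replicate fails to background.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_peptides = 5000,
                       response_counts = c(CR = 1, PR = 25, SD = 13, PD = 27),
                       n_short_treatment = 8,
                       irae_counts = c(symptomatic = 18, asymptomatic = 42,
                                       unknown = 14),
                       n_combination_evaluable = 26, n_combination_short = 4,
                       n_sclc_evaluable = 9, n_sclc_short = 1,
                       n_egfr_mutant = 2,
                       n_replicates = 4,
                       background_log_mean = log(400), background_log_sd = 0.5,
                       positive_rfu_low = 25000, positive_rfu_high = 60000,
                       saturation = 65535,
                       replicate_cv = 0.15,
                       baseline_positive_rate = 0.003,
                       n_informative_pos = 30, n_informative_neg = 30,
                       n_informative_irae = 11,
                       prevalence_in_group = 0.5, prevalence_out_group = 0.03,
                       replicate_dropout_rate = 0) {
  response_counts <- response_counts[c("CR", "PR", "SD", "PD")]
  stopifnot(!anyNA(response_counts), all(response_counts >= 0),
            n_short_treatment >= 0, n_replicates >= 1,
            positive_rfu_low < positive_rfu_high,
            replicate_cv >= 0, replicate_dropout_rate >= 0,
            replicate_dropout_rate <= 1,
            baseline_positive_rate >= 0, baseline_positive_rate <= 1)
  n_total <- sum(response_counts) + n_short_treatment
  irae_counts <- irae_counts[c("symptomatic", "asymptomatic", "unknown")]
  if (anyNA(irae_counts) || sum(irae_counts) != n_total) {
    stop("irae_counts must name symptomatic/asymptomatic/unknown and sum to ",
         n_total, " samples", call. = FALSE)
  }
  if (prevalence_in_group <= prevalence_out_group) {
    stop("prevalence_in_group must exceed prevalence_out_group", call. = FALSE)
  }
  n_planted <- n_informative_pos + n_informative_neg + n_informative_irae
  if (n_planted > n_peptides) {
    stop("planted peptide counts exceed n_peptides", call. = FALSE)
  }
  if (n_combination_evaluable > sum(response_counts) ||
      n_sclc_evaluable > sum(response_counts) ||
      n_combination_short > n_short_treatment ||
      n_sclc_short > n_short_treatment) {
    stop("therapy/subtype counts exceed stratum sizes", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a binding tensor, annotations, and ground truth
#'
#' Generation proceeds in four steps. (1) Per-sample true-binding indicators
#' are drawn: every peptide binds with `baseline_positive_rate`; planted
#' peptides bind with `prevalence_in_group` in samples of their associated
#' group and `prevalence_out_group` elsewhere. (2) Each truly bound
#' (sample, peptide) pair draws a signal level uniform in
#' `[positive_rfu_low, positive_rfu_high]`; unbound pairs draw a lognormal
#' background level. (3) Replicates jitter the level multiplicatively at the
#' configured coefficient of variation; bound replicates optionally drop out
#' to background; values are clipped at `saturation`. (4) Annotations assign
#' response category, treatment weeks, therapy arm, subtype, irAE grade and
#' EGFR status per the configured stratum sizes, at random with respect to
#' one another.
#'
#' Output is bit-reproducible for a fixed `(config, seed)`; the caller's RNG
#' state is left untouched.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List of class `sero_simulation` with elements `binding`
#'   (a `binding_tbl`), `annotations` (annotation tibble) and `truth` (list:
#'   `planted_pos`, `planted_neg`, `planted_irae` peptide ids, and `bound`,
#'   the logical sample x peptide true-binding matrix).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  n_eval <- sum(config$response_counts)
  n <- n_eval + config$n_short_treatment
  samples <- sprintf("S%03d", seq_len(n))
  peptides <- sprintf("FSP%05d", seq_len(config$n_peptides))

  ann <- simulate_annotations(config, samples)

  # planted peptide sets, pairwise disjoint
  n_planted <- config$n_informative_pos + config$n_informative_neg +
    config$n_informative_irae
  planted <- sample(peptides, n_planted)
  planted_pos <- planted[seq_len(config$n_informative_pos)]
  planted_neg <- planted[config$n_informative_pos + seq_len(config$n_informative_neg)]
  planted_irae <- planted[config$n_informative_pos + config$n_informative_neg +
                            seq_len(config$n_informative_irae)]

  evaluable <- !is.na(ann$treatment_weeks) & ann$treatment_weeks >= 6
  in_nonprog <- evaluable & !is.na(ann$best_response) &
    ann$best_response %in% c("CR", "PR", "SD")
  in_prog <- evaluable & !is.na(ann$best_response) & ann$best_response == "PD"
  in_sympt <- ann$irae_grade %in% as.character(2:4)

  prob <- matrix(config$baseline_positive_rate, nrow = n, ncol = config$n_peptides,
                 dimnames = list(samples, peptides))
  plant <- function(prob, pep, members) {
    prob[, pep] <- config$prevalence_out_group
    prob[members, pep] <- config$prevalence_in_group
    prob
  }
  prob <- plant(prob, planted_pos, in_nonprog)
  prob <- plant(prob, planted_neg, in_prog)
  prob <- plant(prob, planted_irae, in_sympt)

  bound <- matrix(stats::runif(length(prob)) < prob, nrow = n,
                  dimnames = dimnames(prob))
  level <- matrix(stats::rlnorm(length(bound), config$background_log_mean,
                                config$background_log_sd),
                  nrow = n, dimnames = dimnames(bound))
  level[bound] <- stats::runif(sum(bound), config$positive_rfu_low,
                               config$positive_rfu_high)

  sdlog <- sqrt(log(1 + config$replicate_cv^2))
  rfu <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    jitter <- stats::rlnorm(length(level), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    v <- level * jitter
    if (config$replicate_dropout_rate > 0) {
      drop <- bound & (stats::runif(length(v)) < config$replicate_dropout_rate)
      v[drop] <- stats::rlnorm(sum(drop), config$background_log_mean,
                               config$background_log_sd)
    }
    rfu[[r]] <- pmin(as.vector(v), config$saturation)
  }

  sv <- rep(samples, times = config$n_peptides)
  pv <- rep(peptides, each = n)
  long <- tibble::tibble(
    sample_id = rep(sv, config$n_replicates),
    peptide_id = rep(pv, config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), each = n * config$n_peptides),
    rfu = unlist(rfu, use.names = FALSE)
  )
  binding <- structure(long,
                       class = c("binding_tbl", class(tibble::tibble())),
                       n_replicates = as.integer(config$n_replicates),
                       sample_ids = samples,
                       peptide_ids = peptides,
                       missing = tibble::tibble(sample_id = character(),
                                                peptide_id = character(),
                                                n_obs = integer()))
  structure(list(binding = binding, annotations = ann,
                 truth = list(planted_pos = planted_pos,
                              planted_neg = planted_neg,
                              planted_irae = planted_irae,
                              bound = bound)),
            class = "sero_simulation", config = config, seed = seed)
}

simulate_annotations <- function(config, samples) {
  n_eval <- sum(config$response_counts)
  n <- length(samples)
  resp <- sample(c(rep(names(config$response_counts), config$response_counts),
                   rep(NA_character_, config$n_short_treatment)))
  weeks <- ifelse(is.na(resp),
                  round(stats::runif(n, 0.5, 5.9), 1),
                  round(stats::runif(n, 6, 52), 1))
  grade_pool <- c(sample(as.character(2:4), config$irae_counts[["symptomatic"]],
                         replace = TRUE),
                  sample(as.character(0:1), config$irae_counts[["asymptomatic"]],
                         replace = TRUE),
                  rep("unknown", config$irae_counts[["unknown"]]))
  irae <- sample(grade_pool)
  therapy <- rep("monotherapy", n)
  is_eval <- !is.na(resp)
  therapy[sample(which(is_eval), config$n_combination_evaluable)] <- "combination"
  if (config$n_combination_short > 0) {
    therapy[sample(which(!is_eval), config$n_combination_short)] <- "combination"
  }
  subtype <- rep("NSCLC", n)
  if (config$n_sclc_evaluable > 0) {
    subtype[sample(which(is_eval), config$n_sclc_evaluable)] <- "SCLC"
  }
  if (config$n_sclc_short > 0) {
    subtype[sample(which(!is_eval), config$n_sclc_short)] <- "SCLC"
  }
  egfr <- rep(FALSE, n)
  pd <- which(!is.na(resp) & resp == "PD")
  n_egfr <- min(config$n_egfr_mutant, length(pd))
  if (n_egfr > 0) egfr[sample(pd, n_egfr)] <- TRUE
  validate_annotations(tibble::tibble(
    sample_id = samples, best_response = resp, treatment_weeks = weeks,
    therapy = therapy, subtype = subtype, irae_grade = irae,
    egfr_mutant = egfr
  ))
}

#' Restrict a cohort to a subset of its samples
#'
#' Keeps the cohort's contrast, pole names and filter provenance while
#' retaining only the requested samples (e.g. a training split).
#'
#' @param cohort A `contrast_cohort`.
#' @param sample_ids Samples to keep; all must belong to the cohort.
#' @export
cohort_subset <- function(cohort, sample_ids) {
  stopifnot(inherits(cohort, "contrast_cohort"))
  missing <- setdiff(sample_ids, cohort$sample_id)
  if (length(missing) > 0) {
    stop("sample(s) not in cohort: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  keep <- cohort$sample_id %in% sample_ids
  new_contrast_cohort(tibble::tibble(sample_id = cohort$sample_id[keep],
                                     label = cohort$label[keep]),
                      attr(cohort, "contrast"),
                      attr(cohort, "group_pos"), attr(cohort, "group_neg"),
                      c(attr(cohort, "filters_applied"), "subset"))
}

#' Balanced two-group configuration for recovery experiments
#'
#' A convenience configuration for parameter-recovery runs: `n_per_group`
#' responders (PR) vs progressors (PD), no short-treatment or irAE-unknown
#' samples, all monotherapy NSCLC, with the default planted-marker structure.
#'
#' @param n_per_group Samples per response pole.
#' @param ... Overrides passed to [sim_config()].
#' @export
sim_config_balanced <- function(n_per_group = 25, ...) {
  n <- 2 * n_per_group
  n_sym <- round(0.3 * n)
  defaults <- list(
    response_counts = c(CR = 0, PR = n_per_group, SD = 0, PD = n_per_group),
    n_short_treatment = 0,
    irae_counts = c(symptomatic = n_sym, asymptomatic = n - n_sym, unknown = 0),
    n_combination_evaluable = 0, n_combination_short = 0,
    n_sclc_evaluable = 0, n_sclc_short = 0, n_egfr_mutant = 0
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' Planted-marker recovery experiment over many seeds
#'
#' Runs the full pipeline -- simulate, call positivity, prevalence-filter,
#' stability-select, code directions, score a holdout -- once per seed, and
#' reports per-seed planted-peptide recall, null-peptide admission, and
#' holdout classification accuracy/coverage. Holdout samples are generated
#' from the same process (extra samples appended to each response pole) but
#' excluded from selection.
#'
#' @param config A [sim_config()]; default is the balanced 25-vs-25 recovery
#'   configuration of [sim_config_balanced()].
#' @param n_seeds Number of independent simulated cohorts.
#' @param seed Master seed from which per-run seeds are drawn.
#' @param holdout_per_group Extra samples per pole, scored but never used in
#'   selection.
#' @param min_prevalence,subsample_fraction,n_iterations,p_threshold,recurrence_threshold,correct
#'   Selection parameters, as [fit_contrast_model()].
#' @return A tibble of class `recovery_experiment`: one row per seed with
#'   `recall`, `null_admission`, `holdout_accuracy`, `holdout_coverage`,
#'   `n_model_peptides`, and an `error` column for runs that failed (their
#'   metrics are NA). Use [glance()] for the across-seed means.
#' @export
recovery_experiment <- function(config = sim_config_balanced(),
                                n_seeds = 20, seed = 1,
                                holdout_per_group = 10,
                                min_prevalence = 3,
                                subsample_fraction = 0.8, n_iterations = 100,
                                p_threshold = 0.05, recurrence_threshold = 70,
                                correct = FALSE) {
  stopifnot(inherits(config, "sim_config"), n_seeds >= 1)
  old <- get_rng_state()
  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max %/% 2L, n_seeds)
  restore_rng_state(old)

  cfg2 <- inflate_poles(config, holdout_per_group)
  rows <- purrr::map(seq_len(n_seeds), function(i) {
    res <- tryCatch(
      recovery_run(cfg2, config, run_seeds[i], holdout_per_group,
                   min_prevalence, subsample_fraction, n_iterations,
                   p_threshold, recurrence_threshold, correct),
      error = function(e) list(recall = NA_real_, null_admission = NA_real_,
                               holdout_accuracy = NA_real_,
                               holdout_coverage = NA_real_,
                               n_model_peptides = NA_integer_,
                               error = conditionMessage(e)))
    tibble::tibble(seed = run_seeds[i], recall = res$recall,
                   null_admission = res$null_admission,
                   holdout_accuracy = res$holdout_accuracy,
                   holdout_coverage = res$holdout_coverage,
                   n_model_peptides = res$n_model_peptides,
                   error = res$error %||% NA_character_)
  })
  structure(dplyr::bind_rows(rows),
            class = c("recovery_experiment", class(tibble::tibble())),
            config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

inflate_poles <- function(config, extra) {
  if (extra == 0) return(config)
  rc <- config$response_counts
  pos_pole <- if (rc[["PR"]] > 0) "PR" else if (rc[["SD"]] > 0) "SD" else "CR"
  rc[[pos_pole]] <- rc[[pos_pole]] + extra
  rc[["PD"]] <- rc[["PD"]] + extra
  ic <- config$irae_counts
  ic[["asymptomatic"]] <- ic[["asymptomatic"]] + 2 * extra
  cfg <- config
  cfg$response_counts <- rc
  cfg$irae_counts <- ic
  cfg
}

recovery_run <- function(cfg2, config, run_seed, holdout_per_group,
                         min_prevalence, subsample_fraction, n_iterations,
                         p_threshold, recurrence_threshold, correct) {
  sim <- simulate_cohort(cfg2, seed = run_seed)
  cohort <- suppressWarnings(build_cohort(sim$annotations, "progression"))
  split_seed <- (run_seed + 104729L) %% .Machine$integer.max
  old <- get_rng_state()
  set.seed(split_seed)
  holdout_ids <- unlist(lapply(unique(cohort$label), function(lb) {
    ids <- cohort$sample_id[cohort$label == lb]
    sample(ids, min(holdout_per_group, length(ids) - 1L))
  }))
  restore_rng_state(old)
  train <- cohort_subset(cohort, setdiff(cohort$sample_id, holdout_ids))

  pos <- call_positivity(sim$binding)
  model <- fit_contrast_model(pos, train,
                              min_prevalence = min_prevalence,
                              subsample_fraction = subsample_fraction,
                              n_iterations = n_iterations,
                              p_threshold = p_threshold,
                              recurrence_threshold = recurrence_threshold,
                              seed = run_seed, correct = correct,
                              scoring_mode = "bidirectional")
  planted <- c(sim$truth$planted_pos, sim$truth$planted_neg)
  nulls <- setdiff(attr(sim$binding, "peptide_ids"), planted)
  preds <- score_samples(pos, model, holdout_ids)
  report <- evaluate_predictions(preds, cohort)
  list(recall = mean(planted %in% model$peptide_id),
       null_admission = sum(model$peptide_id %in% nulls) / length(nulls),
       holdout_accuracy = report$accuracy_classified,
       holdout_coverage = report$coverage,
       n_model_peptides = nrow(model),
       error = NULL)
}
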