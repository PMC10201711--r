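# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Binding table from a 3-d array (samples x peptides x replicates).
binding_from_array <- function(arr, samples = NULL, peptides = NULL) {
  dn <- dimnames(arr)
  samples <- samples %||% dn[[1]] %||% sprintf("S%02d", seq_len(dim(arr)[1]))
  peptides <- peptides %||% dn[[2]] %||% sprintf("P%02d", seq_len(dim(arr)[2]))
  n_rep <- dim(arr)[3]
  long <- expand.grid(sample_id = samples, peptide_id = peptides,
                      replicate = seq_len(n_rep),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$rfu <- as.vector(arr)
  binding_tbl(long, n_replicates = n_rep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Positivity table straight from a logical matrix (samples x peptides).
positivity_from_matrix <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("P%02d", seq_len(ncol(m)))
  serocontrast:::new_positivity_tbl(m)
}

# Deterministic annotations reproducing the study cohort's printed margins:
# 74 samples = 1 CR + 25 PR + 13 SD + 27 PD evaluable + 8 short-treatment;
# irAE grades 18 symptomatic / 42 asymptomatic / 14 unknown; 26 of the 66
# evaluable on combination therapy; 9 evaluable SCLC.
table1_annotations <- function() {
  resp <- c("CR", rep("PR", 25), rep("SD", 13), rep("PD", 27),
            rep(NA_character_, 8))
  n <- length(resp)
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    best_response = resp,
    treatment_weeks = c(rep(12, 66), rep(3, 8)),
    therapy = c(rep("monotherapy", 40), rep("combination", 26),
                rep("monotherapy", 8)),
    subtype = c(rep("NSCLC", 57), rep("SCLC", 9), rep("NSCLC", 8)),
    irae_grade = c(rep("unknown", 14), rep("3", 18), rep("0", 42)),
    egfr_mutant = c(rep(FALSE, 40), TRUE, TRUE, rep(FALSE, n - 42))
  )
}

# A tiny two-group cohort for selection/scoring tests.
toy_cohort <- function(n_pos = 10, n_neg = 10,
                       group_pos = "non_progressor", group_neg = "progressor") {
  serocontrast:::new_contrast_cohort(
    tibble::tibble(
      sample_id = sprintf("S%02d", seq_len(n_pos + n_neg)),
      label = c(rep(group_pos, n_pos), rep(group_neg, n_neg))
    ),
    "progression", group_pos, group_neg, "fixture")
}

# Minimal hand-built contrast model.
toy_model <- function(codes, scoring_mode = "bidirectional",
                      group_pos = "non_progressor", group_neg = "progressor",
                      unidirectional_threshold = 1) {
  structure(
    tibble::tibble(peptide_id = names(codes), code = as.integer(codes),
                   recurrence = NA_integer_,
                   n_pos_group_pos = NA_integer_,
                   n_pos_group_neg = NA_integer_),
    class = c("contrast_model", class(tibble::tibble())),
    contrast = "progression", group_pos = group_pos, group_neg = group_neg,
    scoring_mode = scoring_mode,
    unidirectional_threshold = as.integer(unidirectional_threshold))
}
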