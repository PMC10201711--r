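#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a contrast model
#'
#' @param x A `contrast_model`.
#' @param ... Unused.
#' @return A plain tibble of model peptides: `peptide_id`, `code`
#'   (±1 contrast code), `recurrence` (significant iterations), the pole
#'   name the peptide is associated with, and per-pole positive counts.
#' @method tidy contrast_model
#' @export
tidy.contrast_model <- function(x, ...) {
  tibble::tibble(
    peptide_id = x$peptide_id,
    code = x$code,
    associated_group = ifelse(x$code == 1L, attr(x, "group_pos"),
                              attr(x, "group_neg")),
    recurrence = x$recurrence,
    n_pos_group_pos = x$n_pos_group_pos,
    n_pos_group_neg = x$n_pos_group_neg
  )
}

#' @rdname tidy.contrast_model
#' @method glance contrast_model
#' @export
glance.contrast_model <- function(x, ...) {
  tibble::tibble(
    contrast = attr(x, "contrast"),
    scoring_mode = attr(x, "scoring_mode"),
    n_peptides = nrow(x),
    n_code_pos = sum(x$code == 1L),
    n_code_neg = sum(x$code == -1L),
    group_pos = attr(x, "group_pos"),
    group_neg = attr(x, "group_neg")
  )
}

#' Tidy a performance report
#'
#' @param x A `performance_report`.
#' @param ... Unused.
#' @return `tidy()`: the confusion counts in long form (`observed`,
#'   `predicted`, `n`). `glance()`: a one-row tibble of the summary metrics.
#' @method tidy performance_report
#' @export
tidy.performance_report <- function(x, ...) {
  df <- as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)
  names(df) <- c("observed", "predicted", "n")
  tibble::as_tibble(df)
}

#' @rdname tidy.performance_report
#' @method glance performance_report
#' @export
glance.performance_report <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total,
    coverage = x$coverage,
    accuracy_classified = x$accuracy_classified,
    accuracy_overall = x$accuracy_overall,
    sensitivity = x$sensitivity,
    specificity = x$specificity
  )
}

#' Summarise a recovery experiment across seeds
#'
#' @param x A `recovery_experiment`.
#' @param ... Unused.
#' @return One-row tibble of across-seed means (failed runs excluded) and
#'   the failure count.
#' @method glance recovery_experiment
#' @export
glance.recovery_experiment <- function(x, ...) {
  ok <- is.na(x$error)
  tibble::tibble(
    n_seeds = nrow(x),
    n_failed = sum(!ok),
    mean_recall = mean(x$recall[ok]),
    mean_null_admission = mean(x$null_admission[ok]),
    mean_holdout_accuracy = mean(x$holdout_accuracy[ok], na.rm = TRUE),
    mean_holdout_coverage = mean(x$holdout_coverage[ok]),
    mean_model_size = mean(x$n_model_peptides[ok])
  )
}
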