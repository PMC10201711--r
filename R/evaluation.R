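#' Indeterminate-aware performance report from a confusion table
#'
#' The report is built on a 2 x 3 table: rows are the observed groups
#' (positive pole first), columns are predicted positive pole, predicted
#' negative pole, and indeterminate. Metrics follow the abstaining-classifier
#' convention:
#'
#' * `coverage` -- fraction of samples receiving a determinate prediction;
#' * `accuracy_classified` -- accuracy among classified samples only (`NA`
#'   when everything is indeterminate);
#' * `accuracy_overall` -- intent-to-classify accuracy counting
#'   indeterminates as errors, reported for transparency;
#' * `sensitivity`, `specificity` -- computed among classified samples,
#'   treating the positive pole as the positive class (`NA` when a row has
#'   no classified samples).
#'
#' One-sided (unidirectional) models never abstain, so their reports have an
#' all-zero indeterminate column and coverage 1.
#'
#' @param counts 2x3 (or 2x2, implying zero indeterminates) numeric matrix of
#'   confusion counts, observed groups in rows.
#' @param group_pos,group_neg Pole names used for labelling.
#' @return Object of class `performance_report`.
#' @export
performance_report <- function(counts, group_pos = "group_pos",
                               group_neg = "group_neg") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2 || !ncol(counts) %in% c(2, 3)) {
    stop("counts must be a 2x2 or 2x3 matrix", call. = FALSE)
  }
  if (ncol(counts) == 2) counts <- cbind(counts, c(0, 0))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  dimnames(counts) <- list(
    observed = c(group_pos, group_neg),
    predicted = c(group_pos, group_neg, "indeterminate")
  )
  n_total <- sum(counts)
  n_ind <- sum(counts[, 3])
  n_classified <- n_total - n_ind
  correct <- counts[1, 1] + counts[2, 2]
  structure(list(
    counts = counts,
    n_total = n_total,
    coverage = n_classified / n_total,
    accuracy_classified = if (n_classified > 0) correct / n_classified else NA_real_,
    accuracy_overall = correct / n_total,
    sensitivity = ratio_or_na(counts[1, 1], counts[1, 1] + counts[1, 2]),
    specificity = ratio_or_na(counts[2, 2], counts[2, 1] + counts[2, 2]),
    group_pos = group_pos,
    group_neg = group_neg
  ), class = "performance_report")
}

ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_

#' Evaluate predictions against observed labels
#'
#' Joins predictions to observed pole labels, assembles the 2 x 3 confusion
#' table (observed positive pole first) and derives the indeterminate-aware
#' metrics of [performance_report()].
#'
#' @param predictions A `sample_predictions` tibble from [score_samples()].
#' @param observed A `contrast_cohort`, or a data frame with `sample_id` and
#'   `label` columns using the prediction's pole names.
#' @return A `performance_report`.
#' @export
evaluate_predictions <- function(predictions, observed) {
  stopifnot(inherits(predictions, "sample_predictions"))
  gp <- attr(predictions, "group_pos")
  gn <- attr(predictions, "group_neg")
  obs <- if (is.data.frame(observed)) observed else
    tibble::tibble(sample_id = names(observed), label = unname(observed))
  lab <- obs$label[match(predictions$sample_id, obs$sample_id)]
  bad <- predictions$sample_id[is.na(lab) | !(lab %in% c(gp, gn))]
  if (length(bad) > 0) {
    stop("no valid observed label for sample(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(lab, levels = c(gp, gn)),
                  factor(predictions$predicted,
                         levels = c(gp, gn, "indeterminate")))
  performance_report(unclass(as.matrix(counts)), group_pos = gp, group_neg = gn)
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report> n =", x$n_total, "\n")
  print(x$counts)
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat("coverage ", pct(x$coverage),
      "; accuracy (classified) ", pct(x$accuracy_classified),
      "; sensitivity ", pct(x$sensitivity),
      "; specificity ", pct(x$specificity), "\n", sep = "")
  invisible(x)
}

#' Peptide overlap across contrast models
#'
#' For every non-empty subset of the supplied models, counts the peptides
#' coded in exactly that subset of models (the exclusive regions of a Venn
#' diagram), plus per-model totals.
#'
#' @param models Named list of `contrast_model` objects (at least two);
#'   unnamed lists use each model's contrast attribute as its name.
#' @return A tibble with one logical membership column per model, `n_models`,
#'   and `n_peptides` (exclusive count for that membership pattern; patterns
#'   with zero peptides are kept). Per-model totals are in the `totals`
#'   attribute.
#' @export
model_overlap <- function(models) {
  if (length(models) < 2) stop("need at least two models", call. = FALSE)
  nms <- names(models)
  if (is.null(nms) || any(nms == "")) {
    nms <- vapply(models, function(m) attr(m, "contrast"), character(1))
  }
  if (anyDuplicated(nms)) stop("duplicate model names", call. = FALSE)
  sets <- lapply(models, function(m) unique(m$peptide_id))
  names(sets) <- nms
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, nms))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(nms)))
  names(patterns) <- nms
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  key <- apply(membership, 1, paste, collapse = "|")
  pattern_key <- apply(as.matrix(patterns), 1, paste, collapse = "|")
  n_pep <- as.integer(table(factor(key, levels = pattern_key)))
  out <- tibble::as_tibble(patterns)
  out$n_models <- as.integer(rowSums(patterns))
  out$n_peptides <- n_pep
  out <- dplyr::arrange(out, dplyr::desc(.data$n_models))
  structure(out, totals = vapply(sets, length, integer(1)))
}
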