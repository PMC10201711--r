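#' Score samples against a contrast model
#'
#' Each sample's score is the sum of the model's codes over the model
#' peptides it is patient-positive for (a peptide not bound contributes
#' zero), so the score always equals the count of positives on +1 peptides
#' minus the count on -1 peptides. Classification depends on the model's
#' scoring mode:
#'
#' * bidirectional: positive score predicts the positive pole, negative the
#'   negative pole, and a zero score -- no model peptide bound, or balanced
#'   binding -- is `"indeterminate"`.
#' * unidirectional: a sample binding at least the model's threshold number
#'   of model peptides (default 1) is predicted to the pole the peptides are
#'   associated with; all other samples default to the opposite pole. There
#'   is no indeterminate class.
#'
#' Samples need not belong to the model-building cohort, so held-out samples
#' score through the same function. Positivity calls are sample-local and are
#' used as-is.
#'
#' @param pos A `positivity_tbl` covering the model's peptides.
#' @param model A `contrast_model`.
#' @param samples Sample ids (character vector, data frame with `sample_id`,
#'   or `contrast_cohort`); `NULL` scores every sample in `pos`.
#' @return A tibble of class `sample_predictions` with columns `sample_id`,
#'   `score`, `n_model_peptides_positive`, `predicted`; prediction levels are
#'   the model's pole names plus `"indeterminate"`. Input sample order is
#'   preserved.
#' @export
score_samples <- function(pos, model, samples = NULL) {
  stopifnot(inherits(model, "contrast_model"))
  m <- positivity_matrix(pos)
  ids <- resolve_sample_ids(samples, rownames(m))
  missing_pep <- setdiff(model$peptide_id, colnames(m))
  if (length(missing_pep) > 0) {
    stop("model peptide(s) absent from positivity matrix: ",
         paste(utils::head(missing_pep, 5), collapse = ", "), call. = FALSE)
  }
  mm <- m[ids, model$peptide_id, drop = FALSE]
  score <- as.integer(mm %*% model$code)
  n_bound <- as.integer(rowSums(mm))
  predicted <- classify_scores(score, n_bound, model)
  structure(tibble::tibble(sample_id = ids, score = score,
                           n_model_peptides_positive = n_bound,
                           predicted = predicted),
            class = c("sample_predictions", class(tibble::tibble())),
            contrast = attr(model, "contrast"),
            group_pos = attr(model, "group_pos"),
            group_neg = attr(model, "group_neg"),
            scoring_mode = attr(model, "scoring_mode"))
}

classify_scores <- function(score, n_bound, model) {
  gp <- attr(model, "group_pos")
  gn <- attr(model, "group_neg")
  if (attr(model, "scoring_mode") == "unidirectional") {
    thr <- attr(model, "unidirectional_threshold")
    pole <- if (all(model$code == 1L)) gp else gn
    other <- if (pole == gp) gn else gp
    ifelse(n_bound >= thr, pole, other)
  } else {
    ifelse(score > 0, gp, ifelse(score < 0, gn, "indeterminate"))
  }
}

#' Score one sample's positivity profile
#'
#' @param pos_row Named logical vector of patient-positive calls; names must
#'   cover the model's peptide ids.
#' @param model A `contrast_model`.
#' @param sample_id Identifier for the returned row.
#' @return One-row prediction tibble, as [score_samples()].
#' @export
score_sample <- function(pos_row, model, sample_id = "sample") {
  stopifnot(is.logical(pos_row))
  if (is.null(names(pos_row)) || !all(model$peptide_id %in% names(pos_row))) {
    stop("pos_row must be named and cover every model peptide id", call. = FALSE)
  }
  calls <- matrix(pos_row, nrow = 1, dimnames = list(sample_id, names(pos_row)))
  score_samples(new_positivity_tbl(calls), model)
}

#' @export
print.sample_predictions <- function(x, ...) {
  tab <- table(factor(x$predicted,
                      levels = c(attr(x, "group_pos"), attr(x, "group_neg"),
                                 "indeterminate")))
  cat("<sample_predictions> ", nrow(x), " samples: ",
      paste(names(tab), tab, sep = " = ", collapse = ", "), "\n", sep = "")
  NextMethod()
}
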