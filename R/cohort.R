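contrast_defs <- list(
  progression = list(
    group_pos = "non_progressor", group_neg = "progressor",
    pos_levels = c("CR", "PR", "SD"), neg_levels = "PD",
    needs_weeks = TRUE, drop_levels = character()
  ),
  response_noSD = list(
    group_pos = "responder", group_neg = "non_responder",
    pos_levels = c("CR", "PR"), neg_levels = "PD",
    needs_weeks = TRUE, drop_levels = "SD"
  ),
  irae = list(
    group_pos = "symptomatic", group_neg = "asymptomatic",
    pos_levels = as.character(2:4), neg_levels = as.character(0:1),
    needs_weeks = FALSE, drop_levels = character()
  )
)

#' Build an analysis cohort for a two-group contrast
#'
#' Applies the study's inclusion filters in a fixed order and assigns each
#' remaining sample to one pole of the contrast:
#'
#' * `"progression"` — non-progressor (CR/PR/SD) vs progressor (PD); samples
#'   on therapy for under 6 weeks are dropped first (6.0 weeks exactly is
#'   kept: the requirement is "at least" 6 weeks; missing `treatment_weeks`
#'   cannot certify 6 weeks and is dropped).
#' * `"response_noSD"` — responder (CR/PR) vs non-responder (PD); the
#'   short-treatment filter applies and SD samples are additionally removed
#'   (they are the conventional holdout for this contrast).
#' * `"irae"` — symptomatic (grade 2--4) vs asymptomatic (grade 0--1)
#'   immune-related adverse events; samples with unknown grade are dropped.
#'
#' Optional subset filters (`monotherapy_only`, `nsclc_only`) are applied
#' after the contrast's own filters. Every filter applied is recorded in the
#' `filters_applied` attribute, so the cohort is reproducible from the
#' annotations alone.
#'
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @param contrast One of `"progression"`, `"response_noSD"`, `"irae"`.
#' @param monotherapy_only Drop combination-therapy samples.
#' @param nsclc_only Drop SCLC samples.
#' @param min_treatment_weeks Inclusion threshold for response contrasts
#'   (default 6, inclusive).
#' @return A tibble of class `contrast_cohort` with columns `sample_id`,
#'   `label`, and attributes `contrast`, `group_pos`, `group_neg`,
#'   `filters_applied`.
#' @export
build_cohort <- function(annotations,
                         contrast = c("progression", "response_noSD", "irae"),
                         monotherapy_only = FALSE, nsclc_only = FALSE,
                         min_treatment_weeks = 6) {
  contrast <- tryCatch(match.arg(contrast),
                       error = function(e) stop("unknown contrast name", call. = FALSE))
  ann <- validate_annotations(annotations)
  def <- contrast_defs[[contrast]]
  filters <- character()

  if (def$needs_weeks) {
    keep <- !is.na(ann$treatment_weeks) & ann$treatment_weeks >= min_treatment_weeks
    ann <- ann[keep, ]
    filters <- c(filters, sprintf("treatment_weeks >= %g", min_treatment_weeks))
  }
  if (contrast == "irae") {
    ann <- ann[ann$irae_grade != "unknown", ]
    filters <- c(filters, "irae_grade != unknown")
  }
  if (length(def$drop_levels) > 0) {
    ann <- ann[!(!is.na(ann$best_response) & ann$best_response %in% def$drop_levels), ]
    filters <- c(filters, paste0("drop best_response in {",
                                 paste(def$drop_levels, collapse = ","), "}"))
  }
  if (monotherapy_only) {
    ann <- ann[ann$therapy == "monotherapy", ]
    filters <- c(filters, "therapy == monotherapy")
  }
  if (nsclc_only) {
    ann <- ann[ann$subtype == "NSCLC", ]
    filters <- c(filters, "subtype == NSCLC")
  }

  lab_col <- if (contrast == "irae") ann$irae_grade else ann$best_response
  label <- rep(NA_character_, nrow(ann))
  label[lab_col %in% def$pos_levels] <- def$group_pos
  label[lab_col %in% def$neg_levels] <- def$group_neg
  keep <- !is.na(label)
  if (any(!keep)) {
    # response contrasts: samples past the week filter with NA best_response
    warning(sum(!keep), " sample(s) with no pole label dropped from contrast ",
            contrast, call. = FALSE)
  }
  out <- tibble::tibble(sample_id = ann$sample_id[keep], label = label[keep])
  for (pole in c(def$group_pos, def$group_neg)) {
    if (!any(out$label == pole)) {
      stop("contrast pole \"", pole, "\" has no samples", call. = FALSE)
    }
  }
  new_contrast_cohort(out, contrast, def$group_pos, def$group_neg, filters)
}

new_contrast_cohort <- function(df, contrast, group_pos, group_neg, filters) {
  structure(tibble::as_tibble(df),
            class = c("contrast_cohort", class(tibble::tibble())),
            contrast = contrast,
            group_pos = group_pos,
            group_neg = group_neg,
            filters_applied = filters)
}

#' Pole names of a contrast cohort or model
#'
#' @param x A `contrast_cohort` or `contrast_model`.
#' @return Named character vector with elements `group_pos` and `group_neg`.
#' @export
pole_names <- function(x) {
  c(group_pos = attr(x, "group_pos"), group_neg = attr(x, "group_neg"))
}

#' Swap the pole definitions of a cohort
#'
#' Returns the same membership with `group_pos` and `group_neg` exchanged.
#' Used to check label-swap antisymmetry of downstream selection and scoring.
#'
#' @param cohort A `contrast_cohort`.
#' @export
swap_poles <- function(cohort) {
  stopifnot(inherits(cohort, "contrast_cohort"))
  new_contrast_cohort(tibble::tibble(sample_id = cohort$sample_id,
                                     label = cohort$label),
                      attr(cohort, "contrast"),
                      attr(cohort, "group_neg"),
                      attr(cohort, "group_pos"),
                      c(attr(cohort, "filters_applied"), "poles swapped"))
}

#' @export
print.contrast_cohort <- function(x, ...) {
  cat("<contrast_cohort> ", attr(x, "contrast"), ": ",
      sum(x$label == attr(x, "group_pos")), " ", attr(x, "group_pos"), " vs ",
      sum(x$label == attr(x, "group_neg")), " ", attr(x, "group_neg"), "\n",
      sep = "")
  cat("filters:", paste(attr(x, "filters_applied"), collapse = "; "), "\n")
  NextMethod()
}
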