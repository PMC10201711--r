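#' Call patient-positive peptides from replicate RFU values
#'
#' A peptide is patient-positive for a sample when strictly more than
#' `rfu_threshold` RFU is observed in at least `min_positive_replicates` of
#' its replicate arrays (default: over 20,000 RFU in at least 2 of 4 --
#' roughly 50-fold above the background of these assays). Pairs flagged
#' missing in the binding table are called on the replicates present, with
#' the required count unchanged, so incomplete measurement can only make a
#' call more conservative.
#'
#' @param binding A `binding_tbl` (see [binding_tbl()], [read_binding()]).
#' @param rfu_threshold Positivity threshold in RFU; comparison is strict
#'   (`rfu > rfu_threshold`). Default 20000.
#' @param min_positive_replicates Replicates that must exceed the threshold.
#'   Default 2; must not exceed the tensor's replicate count.
#' @return A tibble of class `positivity_tbl`: column `sample_id` followed by
#'   one logical column per peptide, peptides in the binding table's order.
#' @export
call_positivity <- function(binding, rfu_threshold = 20000,
                            min_positive_replicates = 2) {
  stopifnot(inherits(binding, "binding_tbl"))
  n_rep <- attr(binding, "n_replicates")
  if (min_positive_replicates < 1 || min_positive_replicates > n_rep) {
    stop("min_positive_replicates must be in [1, n_replicates = ", n_rep, "]",
         call. = FALSE)
  }
  if (rfu_threshold <= 0) stop("rfu_threshold must be positive", call. = FALSE)
  samples <- attr(binding, "sample_ids")
  peptides <- attr(binding, "peptide_ids")
  si <- match(binding$sample_id, samples)
  pi <- match(binding$peptide_id, peptides)
  cell <- (pi - 1L) * length(samples) + si
  n_cells <- length(samples) * length(peptides)
  n_over <- tabulate(cell[binding$rfu > rfu_threshold], nbins = n_cells)
  calls <- matrix(n_over >= min_positive_replicates,
                  nrow = length(samples), ncol = length(peptides),
                  dimnames = list(samples, peptides))
  new_positivity_tbl(calls)
}

new_positivity_tbl <- function(calls) {
  out <- tibble::as_tibble(as.data.frame(calls, optional = TRUE),
                           .name_repair = "minimal")
  out <- tibble::add_column(out, sample_id = rownames(calls), .before = 1)
  structure(out, class = c("positivity_tbl", class(tibble::tibble())))
}

#' Convert a positivity table to a logical matrix
#'
#' @param pos A `positivity_tbl`.
#' @return Logical matrix, samples as rows, peptides as columns.
#' @export
positivity_matrix <- function(pos) {
  stopifnot(is.data.frame(pos), names(pos)[1] == "sample_id")
  m <- as.matrix(pos[, -1, drop = FALSE])
  storage.mode(m) <- "logical"
  rownames(m) <- pos$sample_id
  m
}

#' Retain peptides by cohort prevalence
#'
#' Keeps peptides that are patient-positive in at least `min_prevalence`
#' samples, counting only the samples listed (a cohort or a vector of ids).
#' This is the filter that defines the peptide universe entering the
#' chi-square selection: the study's convention is at least 3 positives
#' within the analysis cohort, while `min_prevalence = 1` over the full
#' sample set reproduces the global "seen in anyone" pre-filter.
#'
#' @param pos A `positivity_tbl`.
#' @param samples A `contrast_cohort`, a data frame with a `sample_id`
#'   column, or a character vector of sample ids; `NULL` uses all samples.
#' @param min_prevalence Minimum positive-sample count (default 3).
#' @return Character vector of retained peptide ids, in the positivity
#'   table's column order. A zero-length result raises a warning.
#' @export
prevalence_filter <- function(pos, samples = NULL, min_prevalence = 3) {
  stopifnot(min_prevalence >= 1)
  m <- positivity_matrix(pos)
  ids <- resolve_sample_ids(samples, rownames(m))
  counts <- colSums(m[ids, , drop = FALSE])
  keep <- colnames(m)[counts >= min_prevalence]
  if (length(keep) == 0) {
    warning("no peptide meets min_prevalence = ", min_prevalence, call. = FALSE)
  }
  keep
}

resolve_sample_ids <- function(samples, available) {
  if (is.null(samples)) return(available)
  ids <- if (is.data.frame(samples)) samples$sample_id else as.character(samples)
  missing <- setdiff(ids, available)
  if (length(missing) > 0) {
    stop("sample(s) absent from positivity matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ids
}

#' @export
print.positivity_tbl <- function(x, ...) {
  cat("<positivity_tbl> ", nrow(x), " samples x ", ncol(x) - 1L, " peptides; ",
      sum(positivity_matrix(x)), " positive calls\n", sep = "")
  invisible(x)
}
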