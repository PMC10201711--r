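#' Construct a validated binding table
#'
#' The canonical container for raw array data is a long tibble with one row
#' per measured replicate: columns `sample_id`, `peptide_id`, `replicate`
#' (1-based integer) and `rfu` (raw relative fluorescence units from the
#' scanner). Validation enforces non-negative finite RFU, unique
#' (sample, peptide, replicate) triples, and a homogeneous replicate count;
#' (sample, peptide) pairs observed with fewer than `n_replicates` values are
#' flagged as missing with a warning and kept (positivity calling uses the
#' replicates that are present).
#'
#' @param x A data frame with columns `sample_id`, `peptide_id`, `replicate`,
#'   `rfu`. The aliases `sample` and `peptide` are accepted and renamed.
#' @param n_replicates Expected replicates per (sample, peptide). Default
#'   `NULL` infers the maximum observed count (assays here run quadruplicate).
#' @return A tibble of class `binding_tbl` with attributes `n_replicates`,
#'   `sample_ids`, `peptide_ids` (first-appearance order) and `missing`
#'   (tibble of incomplete pairs, possibly empty).
#' @export
binding_tbl <- function(x, n_replicates = NULL) {
  x <- as_binding_frame(x)
  if (!is.numeric(x$rfu)) {
    bad <- which(!is.na(suppressWarnings(as.numeric(x$rfu))) == FALSE)
    stop("non-numeric RFU values at rows: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(x$rfu) | x$rfu < 0)
  if (length(bad) > 0) {
    stop("negative or non-finite RFU values at rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  sample_ids <- unique(x$sample_id)
  peptide_ids <- unique(x$peptide_id)
  key <- paste(x$sample_id, x$peptide_id, x$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (sample, peptide, replicate) entries; first at row ",
         which(duplicated(key))[1], call. = FALSE)
  }
  counts <- dplyr::count(x, .data$sample_id, .data$peptide_id, name = "n_obs")
  if (is.null(n_replicates)) n_replicates <- max(counts$n_obs)
  stopifnot(n_replicates >= 1)
  missing <- dplyr::filter(counts, .data$n_obs < n_replicates)
  if (nrow(missing) > 0) {
    warning(nrow(missing), " (sample, peptide) pair(s) have fewer than ",
            n_replicates, " replicates; flagged as missing", call. = FALSE)
  }
  if (any(counts$n_obs > n_replicates)) {
    stop("some (sample, peptide) pairs have more than n_replicates = ",
         n_replicates, " values", call. = FALSE)
  }
  out <- tibble::as_tibble(x)
  structure(out,
            class = c("binding_tbl", class(tibble::tibble())),
            n_replicates = as.integer(n_replicates),
            sample_ids = sample_ids,
            peptide_ids = peptide_ids,
            missing = tibble::as_tibble(missing))
}

as_binding_frame <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  nm <- names(x)
  nm[nm == "sample"] <- "sample_id"
  nm[nm == "peptide"] <- "peptide_id"
  names(x) <- nm
  need <- c("sample_id", "peptide_id", "replicate", "rfu")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("binding data must have columns sample, peptide, replicate, rfu; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x$sample_id <- as.character(x$sample_id)
  x$peptide_id <- as.character(x$peptide_id)
  x$replicate <- as.integer(x$replicate)
  x[need]
}

#' Read array binding data from TSV
#'
#' Two layouts are supported. `"long"` has columns `sample`, `peptide`,
#' `replicate`, `rfu` (or the `_id` variants). `"wide"` has peptides as rows
#' (first column holds the peptide id) and one column per replicate array
#' named `<sampleID>_<replicate index>`, 1-based; the sample id may itself
#' contain underscores, so the replicate index is taken from the final
#' underscore-separated token. `"auto"` sniffs the header.
#'
#' @param path Path to a TSV file.
#' @param layout One of `"auto"`, `"wide"`, `"long"`.
#' @param n_replicates Passed to [binding_tbl()].
#' @return A `binding_tbl`.
#' @export
read_binding <- function(path, layout = c("auto", "wide", "long"),
                         n_replicates = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                        progress = FALSE, show_col_types = FALSE)
  if (layout == "auto") {
    long_names <- c("sample", "peptide", "replicate", "rfu")
    has_long <- all(long_names %in% names(df)) ||
      all(c("sample_id", "peptide_id", "replicate", "rfu") %in% names(df))
    layout <- if (has_long) "long" else "wide"
  }
  if (layout == "long") {
    return(binding_tbl(df, n_replicates = n_replicates))
  }
  # wide: peptide rows x sample_replicate columns
  if (ncol(df) < 2) stop("wide layout needs a peptide column plus data columns",
                         call. = FALSE)
  pep_col <- names(df)[1]
  value_cols <- names(df)[-1]
  rep_tok <- sub(".*_", "", value_cols)
  bad <- value_cols[!grepl("_", value_cols) | is.na(suppressWarnings(as.integer(rep_tok)))]
  if (length(bad) > 0) {
    stop("malformed wide-layout column name(s) (expected <sample>_<replicate>): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  long <- tidyr::pivot_longer(df, -dplyr::all_of(pep_col),
                              names_to = "column", values_to = "rfu")
  long$sample_id <- sub("_[^_]*$", "", long$column)
  long$replicate <- as.integer(sub(".*_", "", long$column))
  long$peptide_id <- as.character(long[[pep_col]])
  long <- dplyr::filter(long, !is.na(.data$rfu))
  binding_tbl(long[, c("sample_id", "peptide_id", "replicate", "rfu")],
              n_replicates = n_replicates)
}

#' Write binding data to TSV
#'
#' The long layout round-trips any binding table, including tensors with
#' missing replicates. The wide layout (peptide rows, `<sample>_<replicate>`
#' columns) is only available for complete tensors, because an absent cell in
#' a wide table cannot be told apart from an unmeasured one.
#'
#' @param binding A `binding_tbl`.
#' @param path Output path.
#' @param layout `"long"` (default) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_binding <- function(binding, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  stopifnot(inherits(binding, "binding_tbl"))
  if (layout == "long") {
    out <- tibble::as_tibble(binding)
    names(out) <- c("sample", "peptide", "replicate", "rfu")
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(path))
  }
  if (nrow(attr(binding, "missing")) > 0) {
    stop("wide layout cannot represent missing replicates; use layout = \"long\"",
         call. = FALSE)
  }
  wide <- binding |>
    dplyr::mutate(column = paste0(.data$sample_id, "_", .data$replicate)) |>
    dplyr::select("peptide_id", "column", "rfu") |>
    tidyr::pivot_wider(names_from = "column", values_from = "rfu")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

annotation_columns <- c("sample_id", "best_response", "treatment_weeks",
                        "therapy", "subtype", "irae_grade", "egfr_mutant")

#' Read or validate clinical annotations
#'
#' Annotations are one row per serum sample with the exact columns
#' `sample_id`, `best_response` (CR/PR/SD/PD or NA), `treatment_weeks`
#' (non-negative, NA allowed), `therapy` (monotherapy/combination), `subtype`
#' (NSCLC/SCLC), `irae_grade` (0--4 or "unknown") and `egfr_mutant`
#' (logical or NA). `validate_annotations()` checks an in-memory data frame;
#' `read_annotations()` reads and validates a CSV.
#'
#' @param path CSV path.
#' @return A validated tibble of annotations.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    best_response = readr::col_character(),
    treatment_weeks = readr::col_double(),
    therapy = readr::col_character(),
    subtype = readr::col_character(),
    irae_grade = readr::col_character(),
    egfr_mutant = readr::col_logical()
  ), progress = FALSE, show_col_types = FALSE)
  validate_annotations(df)
}

#' @rdname read_annotations
#' @param x A data frame of annotations.
#' @export
validate_annotations <- function(x) {
  miss <- setdiff(annotation_columns, names(x))
  if (length(miss) > 0) {
    stop("annotation columns missing: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)[annotation_columns]
  x$irae_grade <- as.character(x$irae_grade)
  if (anyDuplicated(x$sample_id)) stop("duplicated sample_id in annotations", call. = FALSE)
  ok_resp <- is.na(x$best_response) | x$best_response %in% c("CR", "PR", "SD", "PD")
  if (!all(ok_resp)) {
    stop("invalid best_response for: ",
         paste(x$sample_id[!ok_resp], collapse = ", "), call. = FALSE)
  }
  ok_ther <- x$therapy %in% c("monotherapy", "combination")
  if (!all(ok_ther)) stop("therapy must be monotherapy or combination", call. = FALSE)
  ok_sub <- x$subtype %in% c("NSCLC", "SCLC")
  if (!all(ok_sub)) stop("subtype must be NSCLC or SCLC", call. = FALSE)
  ok_irae <- x$irae_grade %in% c(as.character(0:4), "unknown")
  if (!all(ok_irae)) stop("irae_grade must be 0-4 or \"unknown\"", call. = FALSE)
  if (any(!is.na(x$treatment_weeks) & x$treatment_weeks < 0)) {
    stop("treatment_weeks must be non-negative", call. = FALSE)
  }
  x
}

#' @rdname read_annotations
#' @param annotations A validated annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  annotations <- validate_annotations(annotations)
  readr::write_csv(annotations, path, progress = FALSE)
  invisible(path)
}
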