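# Vectorised Pearson statistic for 2x2 tables laid out as
#   a = positive & group_pos, b = negative & group_pos,
#   c = positive & group_neg, d = negative & group_neg.
# Any zero marginal gives statistic 0 (an uninformative peptide must simply
# fail the significance test, rather than propagate NaN).
pearson_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  stat <- numeric(length(n))
  ok <- denom > 0
  stat[ok] <- ((a * d - b * c)[ok])^2 * n[ok] / denom[ok]
  stat
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Computes the uncorrected Pearson statistic
#' \deqn{X^2 = \frac{(ad - bc)^2\, N}{(a+b)(c+d)(a+c)(b+d)},\quad N = a+b+c+d,}
#' with the p-value from the chi-square distribution on 1 degree of freedom.
#' No continuity correction is applied by default (set `correct = TRUE` for
#' the Yates-corrected statistic). Tables with a zero marginal return
#' statistic 0 and p-value 1. Inputs are vectorised over tables.
#'
#' The layout follows the peptide-screening use: `a` = positive calls in the
#' first group, `b` = negatives in the first group, `c` = positives in the
#' second group, `d` = negatives in the second group.
#'
#' @param a,b,c,d Non-negative integer cell counts (vectorised).
#' @param correct Apply the Yates continuity correction. Default `FALSE`.
#' @return A tibble with columns `statistic` and `p_value`.
#' @export
chisq_2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- vctrs_recycle(a, b, c, d)
  a <- counts[[1]]; b <- counts[[2]]; c <- counts[[3]]; d <- counts[[4]]
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  n <- a + b + c + d
  if (any(n == 0)) stop("degenerate table: all four counts are zero", call. = FALSE)
  if (correct) {
    denom <- (a + b) * (c + d) * (a + c) * (b + d)
    num <- pmax(abs(a * d - b * c) - n / 2, 0)^2 * n
    stat <- ifelse(denom > 0, num / denom, 0)
  } else {
    stat <- pearson_2x2(a, b, c, d)
  }
  tibble::tibble(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == n) x else rep_len(x, n)
  })
}

#' Stability-selection recurrence by iterated-subsample chi-square tests
#'
#' For each of `n_iterations` iterations a fraction `subsample_fraction` of
#' the cohort (size `floor(fraction * n)`) is drawn without replacement, and
#' each candidate peptide's positivity is tested against the cohort labels
#' with the uncorrected chi-square test on the subsample's 2x2 table. A
#' peptide's recurrence is the number of iterations in which its p-value
#' fell below `p_threshold`. Defaults reproduce the screening convention:
#' 80% subsamples, 100 iterations, p < 0.05.
#'
#' Each iteration draws from its own seed, spawned up front from the master
#' seed, so raising `n_iterations` extends the iteration list without
#' changing earlier draws. Subsampling is unstratified: one draw from the
#' pooled cohort. A subsample that empties one pole makes every table in
#' that iteration have a zero margin (p = 1 by convention) and logs a
#' warning.
#'
#' @param pos A `positivity_tbl`.
#' @param cohort A `contrast_cohort`.
#' @param peptides Candidate peptide ids (normally the output of
#'   [prevalence_filter()] on the same cohort).
#' @param subsample_fraction Fraction of samples per iteration, in (0, 1].
#' @param n_iterations Number of resampling iterations.
#' @param p_threshold Significance level counted toward recurrence.
#' @param seed Master seed for the subsample draws.
#' @param correct Continuity correction, passed to the test.
#' @return Tibble with columns `peptide_id` and `recurrence` covering every
#'   candidate peptide (zero counts included), in candidate order.
#' @export
resample_select <- function(pos, cohort, peptides,
                            subsample_fraction = 0.8, n_iterations = 100,
                            p_threshold = 0.05, seed = 1, correct = FALSE) {
  stopifnot(inherits(cohort, "contrast_cohort"),
            subsample_fraction > 0, subsample_fraction <= 1,
            n_iterations >= 1, p_threshold > 0, p_threshold < 1)
  m <- positivity_matrix(pos)
  ids <- resolve_sample_ids(cohort, rownames(m))
  missing_pep <- setdiff(peptides, colnames(m))
  if (length(missing_pep) > 0) {
    stop("peptide(s) absent from positivity matrix: ",
         paste(utils::head(missing_pep, 5), collapse = ", "), call. = FALSE)
  }
  m <- m[ids, peptides, drop = FALSE]
  is_pos <- cohort$label == attr(cohort, "group_pos")
  n <- length(ids)
  n_sub <- floor(subsample_fraction * n)
  if (n_sub < 1) stop("subsample size is zero", call. = FALSE)

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  iter_seeds <- sample.int(.Machine$integer.max, n_iterations)

  recurrence <- integer(length(peptides))
  empty_pole_iters <- 0L
  for (i in seq_len(n_iterations)) {
    set.seed(iter_seeds[i])
    idx <- sample.int(n, n_sub)
    sub <- m[idx, , drop = FALSE]
    gp <- is_pos[idx]
    n_gp <- sum(gp)
    n_gn <- n_sub - n_gp
    if (n_gp == 0L || n_gn == 0L) empty_pole_iters <- empty_pole_iters + 1L
    a <- colSums(sub[gp, , drop = FALSE])
    c_ <- colSums(sub[!gp, , drop = FALSE])
    res <- chisq_2x2(a, n_gp - a, c_, n_gn - c_, correct = correct)
    recurrence <- recurrence + (res$p_value < p_threshold)
  }
  if (empty_pole_iters > 0) {
    warning(empty_pole_iters, " iteration(s) drew a subsample with an empty pole",
            call. = FALSE)
  }
  tibble::tibble(peptide_id = peptides, recurrence = as.integer(recurrence))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Assign contrast codes to retained peptides
#'
#' Each retained peptide is coded +1 if more cohort samples of the positive
#' pole are patient-positive for it than of the negative pole, and -1 in the
#' opposite case, counting over the full cohort. A peptide with equal counts
#' has no majority group and is dropped with a warning.
#'
#' @param pos A `positivity_tbl`.
#' @param cohort A `contrast_cohort`.
#' @param retained Tibble with `peptide_id` and `recurrence` columns (as from
#'   [resample_select()], already filtered to the recurrence threshold) or a
#'   character vector of peptide ids.
#' @param scoring_mode `"auto"` (default) selects `"unidirectional"` when
#'   every surviving code shares one sign and `"bidirectional"` otherwise;
#'   either mode can be forced.
#' @param unidirectional_threshold Positive-peptide count at or above which a
#'   one-sided model predicts the positive pole (default 1).
#' @return A tibble of class `contrast_model` with columns `peptide_id`,
#'   `code`, `recurrence`, `n_pos_group_pos`, `n_pos_group_neg`, and
#'   attributes `contrast`, `group_pos`, `group_neg`, `scoring_mode`,
#'   `unidirectional_threshold`.
#' @export
assign_directions <- function(pos, cohort, retained,
                              scoring_mode = c("auto", "bidirectional", "unidirectional"),
                              unidirectional_threshold = 1) {
  scoring_mode <- match.arg(scoring_mode)
  stopifnot(inherits(cohort, "contrast_cohort"), unidirectional_threshold >= 1)
  if (is.character(retained)) {
    retained <- tibble::tibble(peptide_id = retained, recurrence = NA_integer_)
  }
  if (nrow(retained) == 0) stop("empty retained set: no peptides to code", call. = FALSE)
  m <- positivity_matrix(pos)
  ids <- resolve_sample_ids(cohort, rownames(m))
  m <- m[ids, retained$peptide_id, drop = FALSE]
  is_pos <- cohort$label == attr(cohort, "group_pos")
  n_pos_gp <- colSums(m[is_pos, , drop = FALSE])
  n_pos_gn <- colSums(m[!is_pos, , drop = FALSE])
  code <- unname(ifelse(n_pos_gp > n_pos_gn, 1L,
                        ifelse(n_pos_gn > n_pos_gp, -1L, NA_integer_)))
  tied <- is.na(code)
  if (any(tied)) {
    warning(sum(tied), " peptide(s) dropped: equal positive counts in both poles",
            call. = FALSE)
  }
  out <- tibble::tibble(
    peptide_id = retained$peptide_id,
    code = code,
    recurrence = retained$recurrence,
    n_pos_group_pos = as.integer(n_pos_gp),
    n_pos_group_neg = as.integer(n_pos_gn)
  )[!tied, ]
  if (nrow(out) == 0) stop("empty model: all retained peptides were tied", call. = FALSE)
  one_sided <- length(unique(out$code)) == 1L
  if (scoring_mode == "auto") {
    scoring_mode <- if (one_sided) "unidirectional" else "bidirectional"
  }
  if (scoring_mode == "unidirectional" && !one_sided) {
    stop("unidirectional scoring requires all codes to share one sign", call. = FALSE)
  }
  structure(out,
            class = c("contrast_model", class(tibble::tibble())),
            contrast = attr(cohort, "contrast"),
            group_pos = attr(cohort, "group_pos"),
            group_neg = attr(cohort, "group_neg"),
            scoring_mode = scoring_mode,
            unidirectional_threshold = as.integer(unidirectional_threshold))
}

#' Fit a contrast model end to end
#'
#' Convenience wrapper chaining [prevalence_filter()] (within the cohort),
#' [resample_select()], the recurrence cut, and [assign_directions()].
#'
#' @inheritParams resample_select
#' @inheritParams assign_directions
#' @param min_prevalence Cohort prevalence filter (default 3 samples).
#' @param recurrence_threshold Iterations a peptide must reach significance
#'   in to be retained (default 70 of 100).
#' @return A `contrast_model`.
#' @export
fit_contrast_model <- function(pos, cohort,
                               min_prevalence = 3,
                               subsample_fraction = 0.8, n_iterations = 100,
                               p_threshold = 0.05, recurrence_threshold = 70,
                               seed = 1, correct = FALSE,
                               scoring_mode = c("auto", "bidirectional", "unidirectional"),
                               unidirectional_threshold = 1) {
  stopifnot(recurrence_threshold <= n_iterations)
  candidates <- prevalence_filter(pos, cohort, min_prevalence = min_prevalence)
  rec <- resample_select(pos, cohort, candidates,
                         subsample_fraction = subsample_fraction,
                         n_iterations = n_iterations,
                         p_threshold = p_threshold, seed = seed,
                         correct = correct)
  retained <- rec[rec$recurrence >= recurrence_threshold, ]
  assign_directions(pos, cohort, retained,
                    scoring_mode = scoring_mode,
                    unidirectional_threshold = unidirectional_threshold)
}

#' @export
print.contrast_model <- function(x, ...) {
  cat("<contrast_model> ", attr(x, "contrast"), " (", attr(x, "scoring_mode"), "): ",
      sum(x$code == 1L), " peptides coded +1 (", attr(x, "group_pos"), "), ",
      sum(x$code == -1L), " coded -1 (", attr(x, "group_neg"), ")\n", sep = "")
  NextMethod()
}
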