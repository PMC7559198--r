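#' Screening-burden decomposition at a stopping point
#'
#' The counts from which every reported outcome is computed. At the
#' stopping point, the records screened decompose into the title/abstract
#' true positives found (`tp_found`) and the excluded records screened
#' (`tn_screened`); the includes not yet identified are the title/abstract
#' false negatives (`fn = n_ta_includes - tp_found`). Replicate *means* are
#' legal inputs, so all fields accept non-integer reals.
#'
#' @param n_total Total records in the corpus.
#' @param n_ta_includes Title/abstract includes at 100% recall.
#' @param tp_found Includes identified at the stop.
#' @param tn_screened Excluded records screened at the stop.
#' @return An object of class `screening_counts` with the derived `fn` and
#'   `screened` fields.
#' @export
screening_counts <- function(n_total, n_ta_includes, tp_found, tn_screened) {
  fn <- n_ta_includes - tp_found
  screened <- tp_found + tn_screened
  stopifnot(n_total >= 0, n_ta_includes >= 0, tp_found >= 0,
            tn_screened >= 0, fn >= -1e-9)
  if (screened > n_total + 1e-9) {
    rlang::abort("screened exceeds n_total")
  }
  if (tn_screened > n_total - n_ta_includes + 1e-9) {
    rlang::abort("tn_screened exceeds the number of excluded records")
  }
  structure(list(n_total = n_total, n_ta_includes = n_ta_includes,
                 tp_found = tp_found, fn = fn, tn_screened = tn_screened,
                 screened = screened),
            class = "screening_counts")
}

#' @rdname screening_counts
#' @param result A [run_simulation()] result to take the counts from.
#' @export
counts_from_result <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  screening_counts(result$n_total, result$n_ta_includes,
                   result$tp_at_stop, result$tn_screened_at_stop)
}

#' True recall
#'
#' `TP / (TP + FN)`: the fraction of all records ultimately passed to full
#' text that have been identified. Computable only retrospectively, once all
#' labels are known — as opposed to a tool's prospective "estimated recall".
#'
#' @param tp_found Title/abstract true positives identified.
#' @param fn Title/abstract false negatives (includes not yet identified).
#' @return A proportion in \[0, 1\].
#' @export
true_recall <- function(tp_found, fn) {
  if (tp_found + fn <= 0) {
    rlang::abort("recall undefined: no title/abstract includes")
  }
  tp_found / (tp_found + fn)
}

#' Screening-burden percentages
#'
#' @param counts A [screening_counts()].
#' @return List of percentages: `screened_pct` (records screened / total),
#'   `reduction_pct` (its complement — the burden reduction),
#'   `excluded_screened_pct` (excluded records screened / all excluded
#'   records), and `fn_pct_of_includes` (false negatives / all includes;
#'   just under 5% at a 95% target).
#' @export
burden_percentages <- function(counts) {
  stopifnot(inherits(counts, "screening_counts"))
  if (counts$n_total <= 0) rlang::abort("n_total must be positive")
  n_excl <- counts$n_total - counts$n_ta_includes
  if (n_excl <= 0) {
    rlang::abort("no excluded records: excluded_screened_pct undefined")
  }
  if (counts$n_ta_includes <= 0) {
    rlang::abort("no includes: fn_pct_of_includes undefined")
  }
  scr <- 100 * counts$screened / counts$n_total
  list(
    screened_pct = scr,
    reduction_pct = 100 - scr,
    excluded_screened_pct = 100 * counts$tn_screened / n_excl,
    fn_pct_of_includes = 100 * counts$fn / counts$n_ta_includes
  )
}

#' Per-record time constants for the savings model
#'
#' Title/abstract screening is costed at one record per minute. Avoided
#' full-text work on the false negatives is costed at 4 minutes per record
#' to retrieve the full text and 5 minutes per record per reviewer to screen
#' it, with full-text screening done in duplicate by default. Conflict
#' resolution at full text (about 5 minutes per conflict) is deliberately
#' excluded from totals and defaults to 0; set `conflict_minutes_per_record`
#' to include it.
#'
#' @param ta_minutes_per_record Minutes to screen one record at
#'   title/abstract (default 1).
#' @param retrieval_minutes_per_record Minutes to retrieve one full text
#'   (default 4).
#' @param ft_minutes_per_record_per_reviewer Minutes for one reviewer to
#'   screen one full text (default 5).
#' @param ft_reviewers Number of full-text reviewers (default 2, duplicate
#'   screening).
#' @param conflict_minutes_per_record Optional extra minutes per false
#'   negative for conflict resolution (default 0 = excluded).
#' @return An object of class `time_model`.
#' @export
time_model <- function(ta_minutes_per_record = 1,
                       retrieval_minutes_per_record = 4,
                       ft_minutes_per_record_per_reviewer = 5,
                       ft_reviewers = 2,
                       conflict_minutes_per_record = 0) {
  vals <- c(ta_minutes_per_record, retrieval_minutes_per_record,
            ft_minutes_per_record_per_reviewer, ft_reviewers,
            conflict_minutes_per_record)
  stopifnot(all(vals >= 0))
  structure(list(
    ta_minutes_per_record = ta_minutes_per_record,
    retrieval_minutes_per_record = retrieval_minutes_per_record,
    ft_minutes_per_record_per_reviewer = ft_minutes_per_record_per_reviewer,
    ft_reviewers = ft_reviewers,
    conflict_minutes_per_record = conflict_minutes_per_record
  ), class = "time_model")
}

#' Hours saved by the modified screening approach
#'
#' Under the modified approach, once the recall target is reached the
#' machine excludes all remaining records, so one human reviewer no longer
#' screens them: `ta_hours = (n_total - screened) * ta_minutes / 60`. The
#' false negatives additionally never reach full text, saving
#' `fn * retrieval_minutes / 60` retrieval hours and
#' `fn * ft_minutes * ft_reviewers / 60` full-text screening hours.
#'
#' @param counts A [screening_counts()].
#' @param model A [time_model()].
#' @return List with `ta_hours`, `retrieval_hours`, `ft_hours`,
#'   `total_hours` (their exact sum; rounding is a display concern only).
#' @export
hours_saved <- function(counts, model = time_model()) {
  stopifnot(inherits(counts, "screening_counts"), inherits(model, "time_model"))
  ta <- (counts$n_total - counts$screened) * model$ta_minutes_per_record / 60
  retr <- counts$fn * model$retrieval_minutes_per_record / 60
  ft <- counts$fn * model$ft_minutes_per_record_per_reviewer *
    model$ft_reviewers / 60
  confl <- counts$fn * model$conflict_minutes_per_record / 60
  list(ta_hours = ta, retrieval_hours = retr, ft_hours = ft,
       conflict_hours = confl,
       total_hours = ta + retr + ft + confl)
}

#' Replicate / cross-review summary statistics
#'
#' Mean with sample (n-1) standard deviation, median with range, and
#' quartiles by linear interpolation between order statistics (the position
#' `p*(n-1)+1` convention, R's default quantile type 7) — the convention
#' under which the published cross-review medians and interquartile ranges
#' are reproduced exactly.
#'
#' @param values Numeric vector, at least one value (`sd` is `NA` for a
#'   single value).
#' @return List with `mean`, `sd`, `median`, `min`, `max`, `q1`, `q3`.
#' @export
aggregate_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values)) {
    rlang::abort("aggregate_values needs at least one non-missing value")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(
    mean = mean(values),
    sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
    median = q[2], min = min(values), max = max(values),
    q1 = q[1], q3 = q[3]
  )
}

#' Display rounding (half away from zero)
#'
#' Reported tables round half-up (27.94 -> 27.9, 11.25 -> 11.3), unlike base
#' `round()`'s round-half-to-even. All internal computation stays unrounded;
#' this is applied only when printing.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return `x` rounded half away from zero to `digits` places.
#' @export
display_round <- function(x, digits = 1) {
  m <- 10^digits
  # the epsilon keeps binary representation error (40.45 stored as
  # 40.44999...) from flipping a half-case downward
  sign(x) * floor(abs(x) * m + 0.5 + 1e-8) / m
}

#' Union analysis of false negatives across replicates
#'
#' Quantifies how consistently the same records are missed: the difference
#' between the number of *unique* records missed in at least one replicate
#' and the largest single-replicate miss count. Zero means every replicate
#' misses the same records.
#'
#' @param replicates List of [run_simulation()] results over the same corpus.
#' @return List with `union_fn_count`, `max_fn_count`, `difference`
#'   (union - max), and `missed_final_union` (unique final includes missed
#'   in any replicate — the safety outcome).
#' @export
fn_union_analysis <- function(replicates) {
  stopifnot(length(replicates) >= 1,
            all(vapply(replicates, inherits, logical(1), "simulation_result")))
  names_seen <- unique(vapply(replicates, `[[`, character(1), "corpus_name"))
  sizes_seen <- unique(vapply(replicates, `[[`, numeric(1), "n_total"))
  if (length(names_seen) > 1 || length(sizes_seen) > 1) {
    rlang::abort("replicates come from different corpora")
  }
  fn_sets <- lapply(replicates, `[[`, "fn_ids")
  union_fn <- unique(unlist(fn_sets))
  max_fn <- max(lengths(fn_sets))
  list(
    union_fn_count = length(union_fn),
    max_fn_count = max_fn,
    difference = length(union_fn) - max_fn,
    missed_final_union = unique(unlist(lapply(replicates, `[[`,
                                              "missed_final_ids")))
  )
}
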