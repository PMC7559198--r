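#' Configuration of the rank-and-screen simulation
#'
#' The loop screens records in fixed-size iterations: each iteration is 2%
#' of the dataset, clamped to a minimum of 25 and a maximum of 200 records,
#' with truncation (floor) to an integer. After each iteration the relevance
#' scorer is refit on all screened records and the remaining records are
#' re-ranked by descending score. The stopping state is recorded at the
#' first iteration whose cumulative true recall reaches `recall_target`
#' (default 95%), the common workload-reduction operating point, which also
#' approximates the human screening error rate.
#'
#' @param batch_fraction Fraction of the dataset per iteration (default 0.02).
#' @param batch_min,batch_max Clamp bounds on the iteration size (25, 200).
#' @param recall_target True-recall target in (0, 1] (default 0.95).
#' @param scorer A [scorer_spec()].
#' @param seed Base seed; replicate `r` shuffles with `seed + r`.
#' @param n_replicates Number of shuffled replicate runs (default 10).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(batch_fraction = 0.02, batch_min = 25,
                              batch_max = 200, recall_target = 0.95,
                              scorer = scorer_spec(), seed = 1,
                              n_replicates = 10) {
  stopifnot(batch_fraction > 0, batch_fraction <= 1,
            batch_min >= 1, batch_min <= batch_max,
            recall_target > 0, recall_target <= 1,
            inherits(scorer, "scorer_spec"), n_replicates >= 1)
  structure(list(
    batch_fraction = batch_fraction, batch_min = as.integer(batch_min),
    batch_max = as.integer(batch_max), recall_target = recall_target,
    scorer = scorer, seed = as.integer(seed),
    n_replicates = as.integer(n_replicates)
  ), class = "simulation_config")
}

#' Records per iteration for a corpus of a given size
#'
#' `floor(batch_fraction * n_total)` clamped to
#' `[batch_min, batch_max]` (and never above `n_total`). Truncation, not
#' rounding: 2% of 2,889 is 57.78 and the iteration size is 57 records.
#'
#' @param n_total Number of records in the corpus.
#' @param config A [simulation_config()].
#' @return Integer batch size.
#' @examples
#' batch_size(2569)  # 51
#' batch_size(22309) # clamped to 200
#' batch_size(1000)  # raised to the minimum, 25
#' @export
batch_size <- function(n_total, config = simulation_config()) {
  stopifnot(n_total >= 1)
  b <- floor(config$batch_fraction * n_total + 1e-9)
  b <- max(config$batch_min, min(config$batch_max, b))
  as.integer(min(b, n_total))
}

#' Run one replicate of the retrospective prioritized-screening simulation
#'
#' Replays recorded labels through the active-learning loop: (i) shuffle the
#' corpus with `replicate_seed`; (ii) screen iteration 1 = the first batch of
#' the shuffled order (the initial training set); (iii) before each
#' subsequent iteration refit the scorer on all screened records, score the
#' remaining records, and reorder them by descending score with ties broken
#' by shuffled position; (iv) labels are revealed only as records are
#' screened; continue until all records are screened. Once every
#' title/abstract include has been found (cumulative recall 1) the remaining
#' records — all excludes — are emitted in their current ranked order
#' without further refits, since no ordering of pure excludes can change any
#' recorded quantity.
#'
#' If the training set is still single-class after an iteration (cold
#' start), ordering falls back to the shuffled order and the fit is
#' reattempted after every subsequent iteration.
#'
#' @param x A [corpus()]; must contain at least one title/abstract include,
#'   otherwise recall is undefined.
#' @param config A [simulation_config()].
#' @param replicate_seed Seed for this replicate's shuffle (defaults to
#'   `config$seed`). The run is fully deterministic given
#'   (corpus, config, replicate_seed).
#' @return An object of class `simulation_result`:
#'   \describe{
#'     \item{trajectory}{tibble with one row per iteration: `iteration`,
#'       `screened_ids` (list), `n_screened`, `cumulative_screened`,
#'       `cumulative_tp`, `cumulative_recall`.}
#'     \item{stop_iteration}{first iteration whose cumulative recall reaches
#'       the target.}
#'     \item{screened_at_stop, tp_at_stop, tn_screened_at_stop}{the
#'       screening-burden decomposition at the stop.}
#'     \item{fn_ids}{title/abstract includes not yet identified at the stop
#'       (the title/abstract false negatives).}
#'     \item{missed_final_ids}{final includes among `fn_ids` — the safety
#'       outcome.}
#'   }
#' @export
run_simulation <- function(x, config = simulation_config(),
                           replicate_seed = config$seed) {
  stopifnot(inherits(x, "corpus"), inherits(config, "simulation_config"))
  if (x$n_ta_includes < 1) {
    rlang::abort("recall undefined: corpus has no title/abstract includes")
  }
  n <- x$n_total
  b <- batch_size(n, config)
  rec <- x$records
  spec <- config$scorer
  if (spec$kind == "default_linear") {
    rec$.tokens <- tokenize_record(rec$title, rec$abstract, spec$ngram_max)
  }
  oracle_labels <- NULL
  if (spec$kind == "oracle") {
    oracle_labels <- stats::setNames(rec$ta_include, rec$record_id)
  }
  shuffled <- local_seed(replicate_seed, sample.int(n))
  shuffle_rank <- integer(n)
  shuffle_rank[shuffled] <- seq_len(n)

  ta <- rec$ta_include
  T_total <- x$n_ta_includes
  remaining <- shuffled
  screened <- integer(0)
  n_iter_max <- ceiling(n / b)
  it_ids <- vector("list", n_iter_max)
  it_n <- integer(n_iter_max)
  it_cum_scr <- integer(n_iter_max)
  it_cum_tp <- integer(n_iter_max)
  k <- 0
  cum_tp <- 0
  all_found <- FALSE
  while (length(remaining) > 0) {
    k <- k + 1
    take <- min(b, length(remaining))
    batch <- remaining[seq_len(take)]
    remaining <- remaining[-seq_len(take)]
    screened <- c(screened, batch)
    cum_tp <- cum_tp + sum(ta[batch])
    it_ids[[k]] <- rec$record_id[batch]
    it_n[k] <- take
    it_cum_scr[k] <- length(screened)
    it_cum_tp[k] <- cum_tp
    if (!all_found && cum_tp >= T_total) all_found <- TRUE
    if (length(remaining) > 0 && !all_found) {
      state <- fit_scorer(spec, rec[screened, , drop = FALSE],
                          oracle_labels = oracle_labels)
      sc <- score_records(state, rec[remaining, , drop = FALSE])
      remaining <- remaining[order(-sc, shuffle_rank[remaining])]
    }
  }
  traj <- tibble::tibble(
    iteration = seq_len(k),
    screened_ids = it_ids[seq_len(k)],
    n_screened = it_n[seq_len(k)],
    cumulative_screened = it_cum_scr[seq_len(k)],
    cumulative_tp = it_cum_tp[seq_len(k)],
    cumulative_recall = it_cum_tp[seq_len(k)] / T_total
  )
  stop_it <- which(traj$cumulative_tp >= config$recall_target * T_total - 1e-9)[1]
  stop_ids <- unlist(traj$screened_ids[seq_len(stop_it)], use.names = FALSE)
  found <- rec$record_id %in% stop_ids
  fn_ids <- rec$record_id[ta & !found]
  missed_final <- rec$record_id[rec$final_include & !found]
  structure(list(
    corpus_name = x$name,
    n_total = n,
    n_ta_includes = T_total,
    batch_size = b,
    recall_target = config$recall_target,
    scorer_kind = spec$kind,
    oracle_used = spec$kind == "oracle",
    replicate_seed = as.integer(replicate_seed),
    trajectory = traj,
    stop_iteration = stop_it,
    screened_at_stop = traj$cumulative_screened[stop_it],
    tp_at_stop = traj$cumulative_tp[stop_it],
    tn_screened_at_stop = traj$cumulative_screened[stop_it] -
      traj$cumulative_tp[stop_it],
    fn_ids = fn_ids,
    missed_final_ids = missed_final
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result '%s'%s> batch %d; stop at iteration %d/%d: %d/%d screened, recall %.3f, %d FN (%d final includes missed)\n",
    x$corpus_name, if (x$oracle_used) " [ORACLE SCORER - test only]" else "",
    x$batch_size, x$stop_iteration, nrow(x$trajectory),
    x$screened_at_stop, x$n_total,
    x$tp_at_stop / x$n_ta_includes, length(x$fn_ids),
    length(x$missed_final_ids)
  ))
  invisible(x)
}

#' Run the configured number of shuffled replicates
#'
#' Replicate `r` uses shuffle seed `config$seed + r`, so the replicates are
#' independent shuffles while the whole set is reproducible from one seed.
#'
#' @param x A [corpus()].
#' @param config A [simulation_config()].
#' @return List of `config$n_replicates` [run_simulation()] results.
#' @export
run_replicates <- function(x, config = simulation_config()) {
  lapply(seq_len(config$n_replicates), function(r) {
    run_simulation(x, config, replicate_seed = config$seed + r)
  })
}

#' Records screened when a recall target is first reached
#'
#' Post-hoc query of a completed trajectory at any target (e.g. comparing
#' the screening burden at 100% versus 95% recall).
#'
#' @param trajectory The `trajectory` tibble of a [run_simulation()] result
#'   (or the result itself).
#' @param recall_target Target in \[0, 1\].
#' @return `cumulative_screened` at the first iteration whose cumulative
#'   recall reaches the target.
#' @export
screened_to_reach <- function(trajectory, recall_target) {
  if (inherits(trajectory, "simulation_result")) {
    trajectory <- trajectory$trajectory
  }
  stopifnot(recall_target <= 1)
  hit <- which(trajectory$cumulative_recall >= recall_target - 1e-12)
  if (length(hit) == 0) {
    rlang::abort(sprintf("recall target %.3f not reached in trajectory",
                         recall_target))
  }
  trajectory$cumulative_screened[hit[1]]
}
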