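#' Configure a full multi-corpus screening experiment
#'
#' An experiment runs `n_replicates` shuffled simulations on each corpus,
#' computes all per-replicate outcomes, aggregates them per corpus
#' (mean/SD, median/range) and across corpora (median/IQR), and optionally
#' writes the result tables, a structured JSON summary and a run log to an
#' output directory.
#'
#' @param corpora Named list of corpus sources: [corpus()] objects,
#'   [generator_spec()]s (generated on the fly), or file paths (read with
#'   [read_corpus()]; `.ris` files as RIS, anything else as delimited).
#' @param simulation A [simulation_config()].
#' @param time A [time_model()].
#' @param out_dir Optional output directory (created if needed).
#' @param verbose Emit progress messages.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(corpora, simulation = simulation_config(),
                              time = time_model(), out_dir = NULL,
                              verbose = FALSE) {
  if (length(corpora) == 0) {
    rlang::abort("experiment needs at least one corpus source",
                 class = "screensim_config_error")
  }
  if (is.null(names(corpora)) || any(!nzchar(names(corpora)))) {
    names(corpora) <- paste0("corpus", seq_along(corpora))
  }
  stopifnot(inherits(simulation, "simulation_config"),
            inherits(time, "time_model"))
  structure(list(corpora = corpora, simulation = simulation, time = time,
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "experiment_config")
}

resolve_corpus_source <- function(src, name) {
  if (inherits(src, "corpus")) {
    src
  } else if (inherits(src, "generator_spec")) {
    generate_corpus(src, name = name)
  } else if (is.character(src) && length(src) == 1) {
    fmt <- if (grepl("\\.ris$", src, ignore.case = TRUE)) "ris" else "delimited"
    read_corpus(src, format = fmt, name = name)
  } else {
    rlang::abort(sprintf(
      "corpus source '%s' must be a corpus, generator_spec or file path", name))
  }
}

# One row of raw outcomes per simulation replicate.
replicate_row <- function(res, tm) {
  cnt <- counts_from_result(res)
  pct <- burden_percentages(cnt)
  hrs <- hours_saved(cnt, tm)
  tibble::tibble(
    project = res$corpus_name,
    scorer = res$scorer_kind,
    replicate_seed = res$replicate_seed,
    n_total = res$n_total,
    n_ta_includes = res$n_ta_includes,
    batch_size = res$batch_size,
    stop_iteration = res$stop_iteration,
    screened = cnt$screened,
    screened_pct = pct$screened_pct,
    tp_found = cnt$tp_found,
    fn = cnt$fn,
    fn_pct = pct$fn_pct_of_includes,
    tn_screened = cnt$tn_screened,
    excluded_screened_pct = pct$excluded_screened_pct,
    ta_hours = hrs$ta_hours,
    retrieval_hours = hrs$retrieval_hours,
    ft_hours = hrs$ft_hours,
    total_hours = hrs$total_hours,
    missed_finals = length(res$missed_final_ids)
  )
}

#' Aggregate per-replicate outcomes into one summary row per corpus
#'
#' @param replicate_rows Tibble of per-replicate outcomes as produced by
#'   [run_experiment()] (`$replicates`), possibly re-read from its CSV log.
#' @return A tibble with one row per project: replicate means, SDs, medians
#'   and ranges of the screening burden, false negatives and hours saved,
#'   plus the iteration range and the total of missed final includes.
#' @export
summarize_replicates <- function(replicate_rows) {
  stopifnot(nrow(replicate_rows) >= 1)
  dplyr::group_by(replicate_rows, .data$project) |>
    dplyr::summarise(
      n_total = .data$n_total[1],
      n_ta_includes = .data$n_ta_includes[1],
      n_final = NA_integer_,
      batch_size = .data$batch_size[1],
      n_replicates = dplyr::n(),
      scorer = .data$scorer[1],
      iter_min = min(.data$stop_iteration),
      iter_max = max(.data$stop_iteration),
      screened_mean = mean(.data$screened),
      screened_pct_mean = mean(.data$screened_pct),
      screened_sd = stats::sd(.data$screened),
      screened_median = stats::median(.data$screened),
      screened_min = min(.data$screened),
      screened_max = max(.data$screened),
      fn_mean = mean(.data$fn),
      fn_pct_mean = mean(.data$fn_pct),
      fn_sd = stats::sd(.data$fn),
      fn_median = stats::median(.data$fn),
      fn_min = min(.data$fn),
      fn_max = max(.data$fn),
      excluded_screened_pct_mean = mean(.data$excluded_screened_pct),
      ta_hours_mean = mean(.data$ta_hours),
      ta_hours_sd = stats::sd(.data$ta_hours),
      ta_hours_median = stats::median(.data$ta_hours),
      ta_hours_min = min(.data$ta_hours),
      ta_hours_max = max(.data$ta_hours),
      total_hours_mean = mean(.data$total_hours),
      missed_finals_total = sum(.data$missed_finals),
      .groups = "drop"
    )
}

# Cross-corpus medians/IQRs over the per-corpus replicate means.
cross_corpus_aggregates <- function(summary_rows) {
  agg <- function(v) aggregate_values(v)
  list(
    screened_pct = agg(summary_rows$screened_pct_mean),
    excluded_screened_pct = agg(summary_rows$excluded_screened_pct_mean),
    fn_pct = agg(summary_rows$fn_pct_mean),
    ta_hours = agg(summary_rows$ta_hours_mean),
    total_hours = agg(summary_rows$total_hours_mean)
  )
}

#' Run the full experiment
#'
#' For each corpus source: resolve it, validate it, run the replicates, and
#' collect per-replicate outcome rows. A corpus that fails its integrity
#' checks is skipped with a logged error; it does not abort the experiment.
#' Identical configuration (including seed) yields identical output,
#' including every stochastic component.
#'
#' @param config An [experiment_config()].
#' @return List with `replicates` (tibble, one row per corpus x replicate),
#'   `summary` (one row per corpus, via [summarize_replicates()]), `report`
#'   (formatted table, via [report_table()]), `cross` (cross-corpus
#'   aggregates of the per-corpus means), `fn_union` (per-corpus
#'   [fn_union_analysis()]), `results` (raw simulation results), and `log`
#'   (character vector: seeds, scorer spec, any per-corpus errors).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  sim <- config$simulation
  log <- c(
    sprintf("screensim experiment; base seed %d; %d replicates per corpus",
            sim$seed, sim$n_replicates),
    sprintf("scorer: %s (min_df=%d, ngram_max=%d, lambda=%g, seed=%d)",
            sim$scorer$kind, sim$scorer$min_df, sim$scorer$ngram_max,
            sim$scorer$lambda, sim$scorer$seed),
    sprintf("batch rule: floor(%g * n) clamped to [%d, %d]; recall target %g",
            sim$batch_fraction, sim$batch_min, sim$batch_max,
            sim$recall_target)
  )
  if (sim$scorer$kind == "oracle") {
    log <- c(log, "WARNING: oracle scorer uses true labels; results are a test-only upper bound")
  }
  rows <- list()
  all_results <- list()
  fn_union <- list()
  n_final_by_project <- c()
  for (nm in names(config$corpora)) {
    res <- tryCatch({
      cps <- resolve_corpus_source(config$corpora[[nm]], nm)
      if (config$verbose) message("simulating '", nm, "' (", cps$n_total, " records)")
      reps <- run_replicates(cps, sim)
      log <- c(log, sprintf(
        "corpus '%s': n=%d, includes=%d, finals=%d, batch=%d, replicate seeds %d..%d",
        nm, cps$n_total, cps$n_ta_includes, cps$n_final,
        batch_size(cps$n_total, sim), sim$seed + 1, sim$seed + sim$n_replicates))
      n_final_by_project[cps$name] <- cps$n_final
      list(reps = reps)
    }, error = function(e) {
      log <<- c(log, sprintf("ERROR corpus '%s' skipped: %s", nm,
                             conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    all_results[[nm]] <- res$reps
    fn_union[[nm]] <- fn_union_analysis(res$reps)
    rows[[nm]] <- dplyr::bind_rows(lapply(res$reps, replicate_row,
                                          tm = config$time))
  }
  if (length(rows) == 0) {
    rlang::abort(paste0("no corpus could be simulated:\n",
                        paste(log, collapse = "\n")))
  }
  replicates <- dplyr::bind_rows(rows)
  summary <- summarize_replicates(replicates)
  summary$n_final <- as.integer(n_final_by_project[summary$project])
  out <- list(
    replicates = replicates,
    summary = summary,
    report = report_table(summary),
    cross = cross_corpus_aggregates(summary),
    fn_union = fn_union,
    results = all_results,
    log = log
  )
  if (!is.null(config$out_dir)) {
    write_experiment_outputs(out, config$out_dir)
  }
  out
}

fmt1 <- function(x) formatC(display_round(x, 1), format = "fg", big.mark = "")
fmt_sd <- function(x) {
  # footnote convention: zero variance printed as a bare 0
  if (is.na(x) || x < 5e-4) "0" else formatC(signif(x, 3), format = "fg")
}
fmt_range <- function(lo, hi) {
  if (abs(hi - lo) < 5e-4) "(0)" else sprintf("(%s-%s)", fmt1(lo), fmt1(hi))
}

#' Format experiment summaries as a study-results table
#'
#' One row per corpus with the columns of the published study-results
#' layout: project details (total; includes (%); finals (%)), iteration
#' details, records needed to screen "mean (%) [SD]; median (range)", the
#' includes not yet identified in the same layout, hours saved, and final
#' included studies missed. Zero-variance SDs and ranges are printed as a
#' bare 0. Display rounding is one decimal; the underlying summary keeps
#' full precision.
#'
#' @param summary A summary tibble from [summarize_replicates()] /
#'   [run_experiment()].
#' @return A tibble of formatted character columns.
#' @export
report_table <- function(summary) {
  stopifnot(nrow(summary) >= 1)
  iter_details <- function(b, lo, hi) {
    it <- if (lo == hi) sprintf("%d iterations", lo)
    else if (hi - lo == 1) sprintf("%d or %d iterations", lo, hi)
    else sprintf("%d-%d iterations", lo, hi)
    sprintf("%d records; %s", b, it)
  }
  tibble::tibble(
    project = summary$project,
    project_details = sprintf(
      "%d; %d (%s%%); %s (%s%%)",
      summary$n_total, summary$n_ta_includes,
      fmt1(100 * summary$n_ta_includes / summary$n_total),
      ifelse(is.na(summary$n_final), "?", as.character(summary$n_final)),
      ifelse(is.na(summary$n_final), "?",
             formatC(round(100 * summary$n_final / summary$n_total, 2),
                     format = "fg"))
    ),
    iteration_details = mapply(iter_details, summary$batch_size,
                               summary$iter_min, summary$iter_max),
    screened = sprintf(
      "%s (%s%%) [%s]; %s %s",
      fmt1(summary$screened_mean), fmt1(summary$screened_pct_mean),
      vapply(summary$screened_sd, fmt_sd, character(1)),
      fmt1(summary$screened_median),
      mapply(fmt_range, summary$screened_min, summary$screened_max)
    ),
    fn = sprintf(
      "%s (%s%%) [%s]; %s %s",
      fmt1(summary$fn_mean), fmt1(summary$fn_pct_mean),
      vapply(summary$fn_sd, fmt_sd, character(1)),
      fmt1(summary$fn_median),
      mapply(fmt_range, summary$fn_min, summary$fn_max)
    ),
    hours_saved = sprintf(
      "%s [%s]; %s %s",
      fmt1(summary$ta_hours_mean),
      vapply(summary$ta_hours_sd, fmt_sd, character(1)),
      fmt1(summary$ta_hours_median),
      mapply(fmt_range, summary$ta_hours_min, summary$ta_hours_max)
    ),
    final_included_missed = as.character(summary$missed_finals_total)
  )
}

write_experiment_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(out$replicates, file.path(out_dir, "replicates.csv"),
                   progress = FALSE)
  readr::write_csv(out$summary, file.path(out_dir, "summary.csv"),
                   progress = FALSE)
  readr::write_csv(out$report, file.path(out_dir, "report.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(cross = out$cross,
         fn_union = out$fn_union),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(out$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Build an experiment configuration from a JSON file
#'
#' The structured-text configuration used by the command-line driver in
#' `inst/cli/screensim.R`. Top-level keys: `corpora` (array of objects with
#' `name` and either `path`/`format` or a `generator` object of
#' [generator_spec()] fields), `simulation` ([simulation_config()] fields,
#' with `scorer` as a nested [scorer_spec()] object), `time`
#' ([time_model()] fields) and `out_dir`.
#'
#' @param path JSON configuration file.
#' @return An [experiment_config()].
#' @export
experiment_config_from_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$corpora) || length(cfg$corpora) == 0) {
    rlang::abort("configuration lists no corpora",
                 class = "screensim_config_error")
  }
  corpora <- list()
  for (src in cfg$corpora) {
    nm <- if (!is.null(src$name)) src$name else paste0("corpus", length(corpora) + 1)
    corpora[[nm]] <- if (!is.null(src$generator)) {
      do.call(generator_spec, src$generator)
    } else if (!is.null(src$profile)) {
      extra <- src$generator_args %||% list()
      do.call(profile_spec, c(list(profile = src$profile), extra))
    } else if (!is.null(src$path)) {
      src$path
    } else {
      rlang::abort(sprintf("corpus source '%s' has neither generator, profile nor path", nm))
    }
  }
  scorer <- do.call(scorer_spec, cfg$simulation$scorer %||% list())
  sim_args <- cfg$simulation %||% list()
  sim_args$scorer <- scorer
  simulation <- do.call(simulation_config, sim_args)
  time <- do.call(time_model, cfg$time %||% list())
  experiment_config(corpora, simulation = simulation, time = time,
                    out_dir = cfg$out_dir, verbose = isTRUE(cfg$verbose))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
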