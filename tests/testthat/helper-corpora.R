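# Fixture builders: all corpora are generated in code at test time.

# Small synthetic corpus with a strong text-label signal.
make_corpus <- function(n = 120, n_inc = 20, n_fin = 3, seed = 1,
                        signal = 4, name = "fix") {
  generate_corpus(
    generator_spec(n, include_rate = n_inc / n, final_rate = n_fin / n,
                   signal_strength = signal, seed = seed),
    name = name
  )
}

# Hand-built corpus with fully deterministic distinct texts.
make_plain_corpus <- function(n = 30, inc_idx = 1:5,
                              fin_idx = utils::head(inc_idx, 2),
                              name = "plain") {
  corpus(tibble::tibble(
    record_id = sprintf("r%03d", seq_len(n)),
    title = sprintf("trial number %d of an intervention", seq_len(n)),
    abstract = sprintf("background and methods for study %d with outcomes", seq_len(n)),
    ta_include = seq_len(n) %in% inc_idx,
    final_include = seq_len(n) %in% fin_idx
  ), name = name)
}

# Held-out ranking AUC of the default linear scorer: fit on the first half
# of a shuffled corpus, score the second half against its true labels.
heldout_auc <- function(cps, seed = 1) {
  n <- cps$n_total
  # decorrelate the split from any generator seed: equal seeds replay the
  # same RNG stream, which would put every include in one half
  idx <- withr::with_seed(1000003L + 7919L * seed, sample.int(n))
  half <- floor(n / 2)
  train <- cps$records[idx[1:half], ]
  test <- cps$records[idx[(half + 1):n], ]
  if (length(unique(train$ta_include)) < 2 ||
      length(unique(test$ta_include)) < 2) {
    return(NA_real_)
  }
  st <- fit_scorer(scorer_spec("default_linear"), train)
  sc <- score_records(st, test)
  ranking_auc(sc, test$ta_include)
}

# The ten published review profiles' printed study-results values, used by
# metrics and aggregation tests: total records, mean records screened at the
# 95%-recall stop, mean title/abstract false negatives, printed hours saved.
published_results <- function() {
  tibble::tibble(
    n_total = c(2569, 16282, 2889, 3145, 8278, 2250, 3265, 4174, 4502, 22309),
    n_ta_includes = c(451, 984, 332, 795, 395, 881, 482, 126, 1184, 4993),
    screened_mean = c(892.5, 4480, 1168.5, 1829, 3019.5, 1575, 1488.5, 2025,
                      2700, 12800),
    screened_pct = c(34.7, 27.5, 40.5, 58.2, 36.5, 70.0, 45.6, 48.5, 60.0,
                     57.4),
    fn_mean = c(19.2, 46.1, 15.0, 33.7, 18.8, 39.9, 22.5, 5.8, 53.7, 242.7),
    hours_mean = c(27.9, 196.7, 28.7, 21.9, 87.6, 11.3, 29.6, 35.8, 30.0,
                   158.5)
  )
}
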