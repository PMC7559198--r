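test_that("batch sizing is floor(2% n) clamped to [25, 200]", {
  n_all <- c(2569, 16282, 2889, 3145, 8278, 2250, 3265, 4174, 4502, 22309)
  expected <- c(51, 200, 57, 62, 165, 45, 65, 83, 90, 200)
  expect_equal(vapply(n_all, batch_size, integer(1)), as.integer(expected))
  expect_equal(batch_size(1000), 25L)  # 2% = 20, raised to the minimum
  expect_equal(batch_size(30), 25L)    # never above n_total either
  expect_equal(batch_size(10), 10L)
})

test_that("simulation is deterministic given corpus, config and seed", {
  cps <- make_corpus(n = 200, n_inc = 30, n_fin = 4, seed = 2)
  cfg <- simulation_config(scorer = scorer_spec("default_linear"), seed = 5)
  r1 <- run_simulation(cps, cfg, replicate_seed = 17)
  r2 <- run_simulation(cps, cfg, replicate_seed = 17)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$fn_ids, r2$fn_ids)
  r3 <- run_simulation(cps, cfg, replicate_seed = 18)
  expect_false(identical(r1$trajectory$screened_ids,
                         r3$trajectory$screened_ids))
})

test_that("trajectory invariants hold across scorers", {
  cps <- make_corpus(n = 300, n_inc = 45, n_fin = 5, seed = 8)
  for (kind in c("default_linear", "oracle", "random")) {
    cfg <- simulation_config(scorer = scorer_spec(kind), seed = 1)
    res <- run_simulation(cps, cfg, replicate_seed = 3)
    traj <- res$trajectory
    b <- res$batch_size
    n_it <- nrow(traj)
    # conservation and monotonicity
    expect_equal(res$tp_at_stop + length(res$fn_ids), cps$n_ta_includes,
                 info = kind)
    expect_true(all(diff(traj$cumulative_tp) >= 0), info = kind)
    expect_true(all(traj$cumulative_recall >= 0 &
                      traj$cumulative_recall <= 1), info = kind)
    expect_equal(traj$cumulative_recall[n_it], 1, info = kind)
    # full coverage, no record screened twice
    ids <- unlist(traj$screened_ids)
    expect_setequal(ids, cps$records$record_id)
    expect_equal(anyDuplicated(ids), 0, info = kind)
    # screened counts are multiples of batch size except the final batch
    expect_equal(traj$n_screened[-n_it], rep(b, n_it - 1), info = kind)
    expect_equal(traj$cumulative_screened, cumsum(traj$n_screened))
    # threshold semantics: first crossing, strictly below before
    expect_gte(res$tp_at_stop / cps$n_ta_includes, cfg$recall_target)
    if (res$stop_iteration > 1) {
      expect_lt(traj$cumulative_tp[res$stop_iteration - 1] /
                  cps$n_ta_includes, cfg$recall_target)
    }
    # stop-state bookkeeping
    expect_equal(res$screened_at_stop,
                 res$tp_at_stop + res$tn_screened_at_stop)
    expect_true(all(res$missed_final_ids %in% res$fn_ids))
  }
})

test_that("oracle stop iteration matches its closed form on small corpora", {
  cases <- expand.grid(n = c(80, 140, 200), inc = c(0.1, 0.25), seed = 1:3)
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]
    cps <- make_corpus(n = n, n_inc = round(n * cases$inc[i]), n_fin = 1,
                       seed = 30 + i)
    cfg <- simulation_config(scorer = scorer_spec("oracle"), seed = 1)
    res <- run_simulation(cps, cfg, replicate_seed = cases$seed[i])
    T_inc <- cps$n_ta_includes
    b <- res$batch_size
    needed <- ceiling(cfg$recall_target * T_inc - 1e-9)
    tp1 <- res$trajectory$cumulative_tp[1]
    expected <- if (tp1 >= needed) 1 else 1 + ceiling((needed - tp1) / b)
    expect_equal(res$stop_iteration, expected,
                 info = sprintf("case %d (n=%d)", i, n))
  }
})

test_that("a recall target of exactly 1 stops when the last include is found", {
  cps <- make_corpus(n = 150, n_inc = 12, n_fin = 2, seed = 6)
  cfg <- simulation_config(recall_target = 1,
                           scorer = scorer_spec("random"), seed = 2)
  res <- run_simulation(cps, cfg, replicate_seed = 4)
  traj <- res$trajectory
  expect_equal(res$tp_at_stop, cps$n_ta_includes)
  expect_equal(length(res$fn_ids), 0)
  first_full <- which(traj$cumulative_tp == cps$n_ta_includes)[1]
  expect_equal(res$stop_iteration, first_full)
})

test_that("a corpus with no includes is refused", {
  cps <- make_plain_corpus(n = 40, inc_idx = integer(0))
  expect_error(run_simulation(cps, simulation_config()), "recall undefined")
})

test_that("cold start (single-class first batch) completes and recovers", {
  # 2 includes in 200 records: the first batch of 25 usually has none
  cps <- make_corpus(n = 200, n_inc = 2, n_fin = 1, seed = 13)
  cfg <- simulation_config(scorer = scorer_spec("default_linear"), seed = 1)
  res <- run_simulation(cps, cfg, replicate_seed = 1)
  expect_equal(res$trajectory$cumulative_recall[nrow(res$trajectory)], 1)
  expect_equal(sum(res$trajectory$n_screened), 200)
})

test_that("screened_to_reach equals a brute-force scan of the trajectory", {
  # direct-lookup example: recalls (.4, .9, .96, 1) with batch 50
  traj <- tibble::tibble(
    iteration = 1:4, screened_ids = list("a", "b", "c", "d"),
    n_screened = 50, cumulative_screened = c(50, 100, 150, 200),
    cumulative_tp = c(20, 45, 48, 50), cumulative_recall = c(.4, .9, .96, 1)
  )
  expect_equal(screened_to_reach(traj, 0.95), 150)
  expect_equal(screened_to_reach(traj, 1.0), 200)
  expect_equal(screened_to_reach(traj, 0), 50)

  # randomized trajectories against an independent scan
  for (s in 1:20) {
    recalls <- withr::with_seed(s, sort(c(runif(7), 1)))
    traj <- tibble::tibble(
      iteration = 1:8, screened_ids = as.list(letters[1:8]),
      n_screened = 10, cumulative_screened = seq(10, 80, by = 10),
      cumulative_tp = round(recalls * 40), cumulative_recall = recalls
    )
    target <- withr::with_seed(100 + s, runif(1))
    brute <- NA
    for (k in 1:8) {
      if (traj$cumulative_recall[k] >= target) { brute <- traj$cumulative_screened[k]; break }
    }
    expect_equal(screened_to_reach(traj, target), brute)
  }
  expect_error(screened_to_reach(traj[1:3, ], 1), "not reached")
})
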