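test_that("true recall is TP / (TP + FN)", {
  expect_equal(true_recall(19, 0), 1)
  expect_equal(true_recall(0, 19), 0)
  # the hot-flashes replicate mean: 19.2 of 451 includes not yet identified
  expect_equal(round(true_recall(451 - 19.2, 19.2), 3), 0.957)
  expect_gte(true_recall(451 - 19.2, 19.2), 0.95)
  expect_error(true_recall(0, 0), "undefined")
})

test_that("burden percentages reproduce the published screened fractions", {
  smoking <- screening_counts(2250, 881, 881 - 39.9, 1575 - (881 - 39.9))
  expect_equal(display_round(burden_percentages(smoking)$screened_pct), 70.0)
  opioid <- screening_counts(16282, 984, 984 - 46.1, 4480 - (984 - 46.1))
  expect_equal(display_round(burden_percentages(opioid)$screened_pct), 27.5)

  full <- screening_counts(1000, 100, 100, 900)
  p <- burden_percentages(full)
  expect_equal(p$reduction_pct, 0)
  expect_equal(p$excluded_screened_pct, 100)
  expect_equal(p$fn_pct_of_includes, 0)
  # complement property on arbitrary valid counts
  for (s in 1:10) {
    cnt <- withr::with_seed(s, {
      n <- sample(500:5000, 1); ninc <- round(n * runif(1, .05, .4))
      tp <- runif(1, 0.5, 1) * ninc
      screening_counts(n, ninc, tp, runif(1) * (n - ninc))
    })
    p <- burden_percentages(cnt)
    expect_equal(p$screened_pct + p$reduction_pct, 100)
  }
  expect_error(burden_percentages(screening_counts(50, 50, 50, 0)),
               "no excluded")
})

test_that("the hours-saved formula reproduces all ten published means", {
  pub <- published_results()
  ta_hours <- (pub$n_total - pub$screened_mean) / 60
  expect_equal(display_round(ta_hours, 1), pub$hours_mean)
})

test_that("full-text savings match the published worked examples", {
  tm <- time_model() # 1 min/record TA; 4 min retrieval; 5 min x 2 reviewers
  # smoking cessation: an average of 40 title/abstract false negatives
  smoking <- screening_counts(2250, 881, 881 - 40, 1575 - (881 - 40))
  h <- hours_saved(smoking, tm)
  expect_equal(display_round(h$retrieval_hours), 2.7)
  expect_equal(display_round(h$ft_hours), 6.7)
  # SSBs: grand total 215.1 h (158.5 TA + 16.2 retrieval + 40.5 full text)
  ssb <- screening_counts(22309, 4993, 4993 - 242.7, 12800 - (4993 - 242.7))
  h <- hours_saved(ssb, tm)
  expect_equal(display_round(h$ta_hours), 158.5)
  expect_equal(display_round(h$retrieval_hours), 16.2)
  expect_equal(display_round(h$ft_hours), 40.5)
  expect_equal(display_round(h$total_hours), 215.1)
  # degenerate: everything screened, nothing missed -> no savings
  z <- hours_saved(screening_counts(100, 10, 10, 90), tm)
  expect_equal(z$total_hours, 0)
})

test_that("hours saved are linear in the false-negative count", {
  tm <- time_model()
  a <- hours_saved(screening_counts(4000, 400, 400 - 80, 1000), tm)
  b <- hours_saved(screening_counts(4000, 400, 400 - 40, 1000), tm)
  expect_equal(b$retrieval_hours * 2, a$retrieval_hours)
  expect_equal(b$ft_hours * 2, a$ft_hours)
  # optional conflict-resolution time is off by default but additive
  tmc <- time_model(conflict_minutes_per_record = 5)
  expect_equal(hours_saved(a_cnt <- screening_counts(4000, 400, 320, 1000),
                           tmc)$conflict_hours, 80 * 5 / 60)
  expect_equal(hours_saved(a_cnt, tm)$conflict_hours, 0)
})

test_that("aggregation uses n-1 SD and interpolated quartiles", {
  pub <- published_results()
  scr <- aggregate_values(pub$screened_pct)
  expect_equal(scr$median, 47.05)
  expect_equal(scr$q1, 37.5)
  expect_equal(scr$q3, 58.0)
  hrs <- aggregate_values(pub$hours_mean)
  expect_equal(display_round(hrs$mean), 62.8)
  expect_equal(display_round(hrs$median), 29.8)
  expect_equal(display_round(hrs$q1), 28.1)
  expect_equal(display_round(hrs$q3), 74.7)

  one <- aggregate_values(5)
  expect_equal(one$mean, 5)
  expect_equal(one$median, 5)
  expect_equal(one$q1, 5)
  expect_equal(one$q3, 5)
  expect_true(is.na(one$sd))
  expect_equal(aggregate_values(c(2, 4))$sd, sd(c(2, 4)))
  expect_error(aggregate_values(numeric(0)))
})

test_that("FN union analysis is plain set arithmetic over replicates", {
  fake_result <- function(fn, finals = character(0)) {
    structure(list(corpus_name = "c", n_total = 100, fn_ids = fn,
                   missed_final_ids = finals),
              class = "simulation_result")
  }
  reps <- list(fake_result(c("a", "b")), fake_result(c("b", "c")),
               fake_result(c("c", "d"), finals = "c"))
  u <- fn_union_analysis(reps)
  expect_equal(u$union_fn_count, 4)
  expect_equal(u$max_fn_count, 2)
  expect_equal(u$difference, 2)
  expect_equal(u$missed_final_union, "c")

  same <- list(fake_result(c("x", "y")), fake_result(c("x", "y")))
  expect_equal(fn_union_analysis(same)$difference, 0)

  other <- structure(list(corpus_name = "other", n_total = 100,
                          fn_ids = "z", missed_final_ids = character(0)),
                     class = "simulation_result")
  expect_error(fn_union_analysis(c(reps, list(other))), "different corpora")
})

test_that("FN union analysis on real replicates equals brute force", {
  cps <- make_corpus(n = 250, n_inc = 40, n_fin = 5, seed = 44)
  cfg <- simulation_config(scorer = scorer_spec("random"), seed = 7,
                           n_replicates = 6)
  reps <- run_replicates(cps, cfg)
  u <- fn_union_analysis(reps)
  sets <- lapply(reps, `[[`, "fn_ids")
  expect_equal(u$union_fn_count, length(Reduce(union, sets)))
  expect_equal(u$max_fn_count, max(vapply(sets, length, integer(1))))
  expect_equal(u$difference, u$union_fn_count - u$max_fn_count)
})
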