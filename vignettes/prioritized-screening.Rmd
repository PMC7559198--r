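---
title: "Simulating prioritized title/abstract screening: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating prioritized title/abstract screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the simulation answers

In a completed systematic review every record carries two known labels: the
title/abstract decision (include for full-text review, or exclude) and the
final inclusion status after full-text assessment. Replaying those labels
through an active-learning screening loop answers a counterfactual: *had the
team used prioritized screening and stopped (or handed the remainder to the
machine) once 95% of the eventual title/abstract includes were identified,
how much screening would have been avoided, what would have been missed,
and how much time would have been saved?* Because the labels are complete,
the recall at any point is the *true* recall — unlike the prospective
"estimated recall" a live tool must guess, which is out of scope here.

## The screening loop

One replicate of `run_simulation()`:

1. **Shuffle** the corpus with the replicate seed. Replicate `r` of a
   configuration uses seed `seed + r`, so the ten default replicates are
   independent shuffles of one reproducible experiment.
2. **Iteration 1** screens the first batch of the shuffled order; this is
   the initial training set. The batch size is `floor(0.02 N)` clamped to
   `[25, 200]`. Truncation rather than rounding is deliberate: the studied
   reviews' printed iteration sizes (e.g. 57 records for `N = 2889`, where
   2% is 57.78) are only consistent with the floor.
3. **Refit, re-rank, screen.** Before each subsequent iteration the scorer
   is refit on *all* screened records (labels are revealed only as records
   are screened), every remaining record is rescored, and the remainder is
   reordered by descending score, ties broken by shuffled position so runs
   are fully deterministic. The loop continues until every record is
   screened.
4. **Stopping state.** The recall test is evaluated at iteration boundaries
   only — mid-batch stopping would contradict the published screened counts,
   which are exact batch multiples. The stop is the first iteration with
   `cumulative TP ≥ target × total includes`; the crossing batch may
   contain several includes, so recall at the stop can exceed the target
   slightly.

Two pragmatic choices deserve a note:

* **Cold start.** If the screened set is still single-class (or a class has
  fewer than two members, the minimum the ridge fit accepts), no model is
  fit; scores are uniform, ordering falls back to the shuffled order, and
  the fit is retried after every iteration. The behaviour of the commercial
  tool this emulates is undocumented; this fallback is our declared choice.
* **Post-completion ordering.** Once cumulative recall reaches 1 every
  remaining record is an exclude, and no ordering of pure excludes can
  change any recorded quantity (stop state, trajectory counts, false
  negatives). The remaining batches are therefore emitted in their current
  ranked order without further refits. This is purely an efficiency device;
  it deviates from "refit before every iteration" only where the refit is
  provably inconsequential.

## The relevance scorer

The tool that motivated this package keeps its ranker proprietary, so the
default scorer is a documented stand-in chosen to be the reproducible
baseline of the screening-automation literature: TF-IDF (smoothed idf,
L2-normalized rows) over lowercased unigrams and bigrams of title and
abstract (bigrams never straddle the title/abstract boundary; minimum
document frequency 2), feeding an L2-regularized logistic model
(`glmnet`, ridge, prediction at `lambda = 0.01`) with balanced class
weights — weighting, not resampling, so the fitted state is deterministic.
Two baseline scorers exist for testing: an `oracle` that looks up true
labels (an upper bound; results are flagged and must never be reported as
performance) and a seeded `random` scorer (the no-learning lower bound,
equivalent to screening in random order). Any numeric agreement between
this stand-in's stochastic outcomes and the commercial tool's published
per-review numbers would be coincidental and is not claimed; only the
deterministic arithmetic around the loop is expected to reproduce.

## Outcomes and the time model

All outcomes derive from the stop-state counts: screening burden
`TP + TN`, burden-reduction percentage, the fraction of excluded records
screened, false negatives as a percentage of all includes, and the final
includes among the false negatives (the safety outcome). Time savings use
per-record constants: 1 minute per title/abstract record (the single
reviewer who no longer screens the machine-excluded remainder), 4 minutes
to retrieve and `5 × 2` minutes to dual-screen each full text avoided.
Conflict-resolution time (about 5 min per conflict) is exposed as an
optional `time_model()` field but defaults to off, matching the published
totals, which exclude it. Replicate aggregation uses the sample (n−1) SD
and type-7 (linear-interpolation) quartiles; that quartile convention was
back-derived from the published cross-review IQRs and is the only common
convention that reproduces them. Displayed numbers round half away from
zero (675/60 = 11.25 prints as 11.3) — base R's round-half-to-even would
disagree with the published tables; internal computation is never rounded.

## What the synthetic generator emulates — and what it does not

No screening dataset is distributed with the evaluation this package
reopens, so `generate_corpus()` produces corpora with the structure the
analysis needs: exact label counts by `round(N × rate)` (final includes
capped at and sampled uniformly from the title/abstract includes, since
nothing in the data distinguishes them textually), document lengths Poisson
around 60 tokens, about 5% of records abstract-free, and text from a
two-component multinomial mixture: a Zipf background shared by all records
and an include topic concentrated on the 10% of words rarest in the
background. Include-labeled records draw each token from the topic with
probability `0.1 · tanh(signal_strength / 2)`.

Two constants there are calibrated choices:

* **The 0.1 cap on the mixture weight.** With ~60 informative tokens per
  record, even a few percent of topic tokens separates the classes
  strongly; an uncapped weight made every corpus perfectly separable and
  the signal dial useless. The cap makes the dial span chance
  (`signal_strength = 0`, where the text distribution is identical for both
  classes) through realistic held-out AUCs (~0.85–0.95) to near-perfect
  ranking at saturation.
* **The default `signal_strength = 2`.** The only available anchor is
  qualitative: across the ten studied reviews, prioritized screening
  reduced burden by 30.0–72.5%. At the default, simulated burden reduction
  on profile-sized corpora lands inside that band (the worked example in
  the README shows 51.7% on the 2,569-record profile).

The ten `preset_profiles()` reproduce the studied reviews'
(records, includes, finals) triples exactly, summing to 69,663 records.

The generator does **not** emulate: real English (tokens are synthetic
words, so absolute vocabulary statistics are meaningless), human screening
error or label noise, duplicate records (planted explicitly in tests for
`check_duplicates()`), or any textual difference between final includes
and other title/abstract includes. A green test on synthetic corpora
therefore establishes that the machinery is correct and that the loop
behaves as theory predicts across the signal dial — not that any particular
burden reduction will be achieved on a real review.

One subtlety worth recording: the generator derives its RNG stream from an
LCG-remapped seed. Sampling the include set and shuffling the corpus both
consume `sample.int(N)` from the seed they are given; with numerically
equal seeds they would replay the same permutation, silently handing the
first screening batch exactly the include set. The remapping makes equal
user-facing seeds safe.

## Numerical and degenerate-input choices

* Batch size: floor, clamped to `[25, 200]`, never above `N`; a tiny
  epsilon guards the floor against binary representation error
  (`0.02 × 4502` is 90.04 in decimal but may sit just below in binary).
* Recall threshold: `TP ≥ target × T − 10⁻⁹`; the epsilon makes
  `target = 1` and integer crossings exact.
* A corpus with no title/abstract includes is refused (recall undefined),
  as is an empty training set, an oracle scorer without labels, and scoring
  any record that is already in the training set.
* `final_include` implies `ta_include`; duplicate ids and empty
  title+abstract are integrity errors naming the offending record.
* RIS carries no screening-decision field, so labels travel in a
  configurable notes tag (`N1` by default) in a fixed machine-readable
  form; no installed package parses RIS, so a minimal line-oriented
  reader/writer for exactly the emitted tags is included.

## Known limitations

* The scorer is a stand-in; per-review stochastic outcomes are not
  comparable numerically to the commercial tool's published table, and the
  headline safety finding there (no final include missed at the 95% stop)
  need not replicate with the default scorer — the worked example misses
  some.
* Only retrospective simulation is supported: no prospective
  (estimated-recall) stopping, no human-in-the-loop mode, no mid-batch
  stopping.
* The excluded-records-screened percentage uses its literal definition
  (`TN screened / all excludes`); one published summary figure for that
  quantity is not derivable from the published per-review values under any
  definition we tested and is not targeted.
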