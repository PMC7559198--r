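#' Specification of a relevance scorer
#'
#' The simulator is agnostic about how unscreened records are scored; the
#' scorer is pluggable. Three kinds are provided:
#'
#' * `default_linear` — the reporting scorer: TF-IDF unigrams+bigrams over
#'   the lowercased title+abstract (minimum document frequency 2), feeding an
#'   L2-regularized (ridge) logistic model with balanced class weights. This
#'   is the standard reproducible baseline in screening-automation work; any
#'   commercial tool's proprietary ranker is a black box this stands in for.
#' * `oracle` — looks up the true labels; a test-only upper bound. Results
#'   produced with it are flagged and must never be reported as performance.
#' * `random` — seeded uniform scores; the no-learning lower bound
#'   (equivalent to screening in random order).
#'
#' @param kind One of `"default_linear"`, `"oracle"`, `"random"`.
#' @param min_df Minimum document frequency for a term to enter the
#'   vocabulary (default 2).
#' @param ngram_max Largest n-gram order (default 2: unigrams + bigrams).
#' @param lambda Ridge penalty used at prediction (default 0.01).
#' @param seed Seed for the `random` kind.
#' @return An object of class `scorer_spec`.
#' @export
scorer_spec <- function(kind = c("default_linear", "oracle", "random"),
                        min_df = 2, ngram_max = 2, lambda = 0.01, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(min_df >= 1, ngram_max %in% c(1, 2), lambda > 0)
  structure(list(kind = kind, min_df = as.integer(min_df),
                 ngram_max = as.integer(ngram_max), lambda = lambda,
                 seed = as.integer(seed)),
            class = "scorer_spec")
}

# Tokenization: lowercase, alphanumeric runs. Title and abstract are
# tokenized separately (a field boundary acts as the separator), so bigrams
# never straddle the title/abstract boundary; empty abstracts fall out
# naturally.
adjacent_bigrams <- function(tk) {
  if (length(tk) < 2) return(character(0))
  paste(tk[-length(tk)], tk[-1], sep = "_")
}

tokenize_record <- function(title, abstract, ngram_max) {
  tt <- stringr::str_extract_all(tolower(title), "[a-z0-9]+")
  at <- stringr::str_extract_all(tolower(abstract), "[a-z0-9]+")
  mapply(function(a, b) {
    uni <- c(a, b)
    if (ngram_max < 2) return(uni)
    c(uni, adjacent_bigrams(a), adjacent_bigrams(b))
  }, tt, at, SIMPLIFY = FALSE)
}

# Terms for a set of records, using a cached ".tokens" list column if present
# (the simulator tokenizes the whole corpus once up front).
record_terms <- function(records, ngram_max) {
  if (".tokens" %in% names(records)) return(records$.tokens)
  tokenize_record(records$title, records$abstract, ngram_max)
}

# Sparse document-term count matrix restricted to `vocab`. One flat match
# so the vocabulary hash is built once, not once per document; repeated
# (i, j) pairs are summed into counts by sparseMatrix.
terms_to_dtm <- function(terms, vocab) {
  flat <- unlist(terms, use.names = FALSE)
  m <- match(flat, vocab)
  keep <- !is.na(m)
  i <- rep.int(seq_along(terms), lengths(terms))
  Matrix::sparseMatrix(i = i[keep], j = m[keep], x = 1,
                       dims = c(length(terms), length(vocab)))
}

tfidf_transform <- function(dtm, idf) {
  x <- dtm %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(x^2))
  norms[norms == 0] <- 1
  Matrix::Diagonal(x = 1 / norms) %*% x
}

#' Fit a relevance scorer on the screened (labeled) records
#'
#' For the default linear kind, a TF-IDF representation is fitted on the
#' training texts (vocabulary = terms with document frequency >= `min_df`;
#' smoothed idf) and a ridge logistic model with balanced class weights is
#' estimated with glmnet. If the training set contains only one class — the
#' cold-start situation when the first screened batch holds no includes —
#' no model can be fit and the returned state is flagged `single_class`,
#' which makes [score_records()] return uniform scores so the simulator falls
#' back to its shuffled ordering and retries the fit next iteration.
#'
#' @param spec A [scorer_spec()].
#' @param training Data frame of screened records: `record_id`, `title`,
#'   `abstract`, and the revealed `ta_include` labels. Must be non-empty.
#' @param oracle_labels For the oracle kind only: named logical vector of
#'   true labels keyed by `record_id`, covering every record that may be
#'   scored.
#' @return A `scorer_state` list usable by [score_records()]; plain R
#'   objects throughout, so it serializes for audit.
#' @export
fit_scorer <- function(spec, training, oracle_labels = NULL) {
  stopifnot(inherits(spec, "scorer_spec"))
  if (is.null(training) || nrow(training) == 0) {
    rlang::abort("empty training set")
  }
  base <- list(spec = spec, trained_ids = as.character(training$record_id),
               single_class = FALSE)
  if (spec$kind == "oracle") {
    if (is.null(oracle_labels)) {
      rlang::abort("oracle scorer requires oracle_labels (true labels); test use only")
    }
    return(structure(c(base, list(labels = oracle_labels)),
                     class = "scorer_state"))
  }
  if (spec$kind == "random") {
    return(structure(base, class = "scorer_state"))
  }
  y <- as.logical(training$ta_include)
  # glmnet refuses classes with < 2 observations; treat that cold-start
  # situation like a single-class training set and retry next iteration
  if (sum(y) < 2 || sum(!y) < 2) {
    base$single_class <- TRUE
    return(structure(base, class = "scorer_state"))
  }
  terms <- record_terms(training, spec$ngram_max)
  df <- table(unlist(lapply(terms, unique)))
  vocab <- names(df)[df >= spec$min_df]
  if (length(vocab) < 2) {
    # not enough shared vocabulary to fit anything useful
    base$single_class <- TRUE
    return(structure(base, class = "scorer_state"))
  }
  n <- length(terms)
  idf <- log((1 + n) / (1 + as.numeric(df[vocab]))) + 1
  x <- tfidf_transform(terms_to_dtm(terms, vocab), idf)
  n1 <- sum(y)
  w <- ifelse(y, n / (2 * n1), n / (2 * (n - n1)))
  lam_path <- spec$lambda * c(100, 10, 1)
  # small early training sets trigger glmnet's "fewer than 8 observations"
  # class-size warning every iteration; the imbalance is inherent here
  fit <- suppressWarnings(
    glmnet::glmnet(x, factor(y, levels = c(FALSE, TRUE)),
                   family = "binomial", alpha = 0, lambda = lam_path,
                   weights = w, standardize = FALSE))
  structure(c(base, list(fit = fit, vocab = vocab, idf = idf)),
            class = "scorer_state")
}

#' Score unscreened candidate records
#'
#' Returns one relevance score in \[0, 1\] per candidate, keyed by
#' `record_id`. A record already in the scorer's training set is refused —
#' in the simulation a record is never scored after it has been screened.
#' Scores depend only on candidate text (and fitted state), never on
#' candidate labels, except under the oracle kind.
#'
#' @param state A fitted `scorer_state` from [fit_scorer()].
#' @param candidates Data frame of unscreened records (`record_id`, `title`,
#'   `abstract`).
#' @return Named numeric vector of scores, one per candidate, all finite.
#' @export
score_records <- function(state, candidates) {
  stopifnot(inherits(state, "scorer_state"))
  ids <- as.character(candidates$record_id)
  overlap <- intersect(ids, state$trained_ids)
  if (length(overlap) > 0) {
    rlang::abort(sprintf(
      "candidate(s) overlap the training set (already screened): %s",
      paste(utils::head(overlap, 3), collapse = ", ")))
  }
  spec <- state$spec
  scores <- if (spec$kind == "oracle") {
    lab <- state$labels[ids]
    if (anyNA(lab)) rlang::abort("oracle labels missing for some candidates")
    as.numeric(lab)
  } else if (spec$kind == "random") {
    local_seed(spec$seed, stats::runif(length(ids)))
  } else if (state$single_class) {
    rep(0.5, length(ids))
  } else {
    terms <- record_terms(candidates, spec$ngram_max)
    x <- tfidf_transform(terms_to_dtm(terms, state$vocab), state$idf)
    as.numeric(stats::predict(state$fit, newx = x, s = spec$lambda,
                              type = "response"))
  }
  names(scores) <- ids
  scores
}
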