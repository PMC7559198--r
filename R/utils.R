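# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's
# .Random.seed afterwards so package functions never perturb the global
# stream.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

abort_format <- function(msg) {
  rlang::abort(msg, class = "screensim_format_error")
}

abort_integrity <- function(msg) {
  rlang::abort(msg, class = "screensim_integrity_error")
}

# Coerce 1/0, TRUE/FALSE, "true"/"false" to logical; anything else errors.
as_bool01 <- function(x, field) {
  if (is.logical(x)) return(x)
  x_chr <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x_chr))
  out[x_chr %in% c("1", "true", "t", "yes")] <- TRUE
  out[x_chr %in% c("0", "false", "f", "no", "")] <- FALSE
  if (anyNA(out) && !anyNA(x_chr)) {
    bad <- unique(x_chr[is.na(out)])
    abort_format(sprintf(
      "field '%s' contains values not interpretable as booleans: %s",
      field, paste(utils::head(bad, 3), collapse = ", ")
    ))
  }
  out[is.na(x_chr)] <- FALSE
  out
}

#' Area under the ROC curve of a score-based ranking
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' positive record is scored above a randomly chosen negative one, with ties
#' counted as half. Used throughout the test-suite to quantify how well a
#' relevance scorer separates title/abstract includes from excludes.
#'
#' @param scores Numeric vector of relevance scores.
#' @param labels Logical vector, `TRUE` for positives, same length as `scores`.
#' @return A single number in \[0, 1\]; 0.5 is chance-level ranking.
#' @export
ranking_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    rlang::abort("AUC undefined: need at least one positive and one negative")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
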