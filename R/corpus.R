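#' Construct a labeled screening corpus
#'
#' A corpus is the simulation's universe: one bibliographic record per row,
#' each carrying the two recorded screening decisions of a completed
#' systematic review. `ta_include` is the title/abstract decision (`TRUE` =
#' the record was passed through to full-text review, i.e. a title/abstract
#' true positive once found by the simulation); `final_include` flags the
#' studies included in the completed review after full-text assessment.
#'
#' Integrity conditions enforced here, because the simulator assumes them:
#' `record_id` unique; every final include must also be a title/abstract
#' include; every record has at least one of title or abstract non-empty.
#' Records with an empty abstract are legal (title-only records occur in real
#' screening data).
#'
#' @param records A data frame with columns `record_id` (character), `title`,
#'   `abstract` (character, may be empty strings), `ta_include`,
#'   `final_include` (logical or 0/1). Input order is preserved.
#' @param name A label for the corpus.
#' @return An object of class `corpus`: a list with `name`, `records` (a
#'   tibble), and the counts `n_total`, `n_ta_includes`, `n_final`.
#' @examples
#' corpus(data.frame(
#'   record_id = c("r1", "r2"), title = c("a trial", "a cohort"),
#'   abstract = c("", "text"), ta_include = c(1, 0), final_include = c(0, 0)
#' ))
#' @export
corpus <- function(records, name = "corpus") {
  required <- c("record_id", "title", "abstract", "ta_include", "final_include")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort_format(paste0("missing required field(s): ",
                        paste(missing, collapse = ", ")))
  }
  rec <- tibble::tibble(
    record_id = as.character(records$record_id),
    title = ifelse(is.na(records$title), "", as.character(records$title)),
    abstract = ifelse(is.na(records$abstract), "",
                      as.character(records$abstract)),
    ta_include = as_bool01(records$ta_include, "ta_include"),
    final_include = as_bool01(records$final_include, "final_include")
  )
  dup <- unique(rec$record_id[duplicated(rec$record_id)])
  if (length(dup) > 0) {
    abort_integrity(sprintf("duplicate record_id: %s",
                            paste(utils::head(dup, 5), collapse = ", ")))
  }
  bad <- rec$record_id[rec$final_include & !rec$ta_include]
  if (length(bad) > 0) {
    abort_integrity(sprintf(
      "final_include without ta_include (a final include must have passed title/abstract screening): %s",
      paste(utils::head(bad, 5), collapse = ", ")))
  }
  empty <- rec$record_id[!nzchar(trimws(rec$title)) &
                           !nzchar(trimws(rec$abstract))]
  if (length(empty) > 0) {
    abort_integrity(sprintf("record with neither title nor abstract: %s",
                            paste(utils::head(empty, 5), collapse = ", ")))
  }
  structure(
    list(
      name = name,
      records = rec,
      n_total = nrow(rec),
      n_ta_includes = sum(rec$ta_include),
      n_final = sum(rec$final_include)
    ),
    class = "corpus"
  )
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf(
    "<corpus '%s'> %d records; %d title/abstract includes (%.1f%%); %d final includes (%.2f%%)\n",
    x$name, x$n_total, x$n_ta_includes,
    100 * x$n_ta_includes / max(x$n_total, 1),
    x$n_final, 100 * x$n_final / max(x$n_total, 1)
  ))
  invisible(x)
}

default_column_map <- c(
  record_id = "record_id", title = "title", abstract = "abstract",
  ta_include = "ta_include", final_include = "final_include"
)

#' Read a labeled screening corpus from disk
#'
#' Supports two formats. `"delimited"` is comma-separated UTF-8 text with a
#' header row; booleans are read as 1/0 (or TRUE/FALSE); extra columns are
#' ignored. `"ris"` is the RIS reference-manager format (TI/AB/ID tags); since
#' RIS carries no screening-decision field, the two labels travel in a
#' configurable tag (default `N1`, a notes tag) as
#' `screening: ta_include=1; final_include=0`.
#'
#' @param path File to read.
#' @param format `"delimited"` (CSV) or `"ris"`.
#' @param column_map Named character vector mapping the canonical field names
#'   (`record_id`, `title`, `abstract`, `ta_include`, `final_include`) to the
#'   column names actually present in a delimited file.
#' @param name Corpus label; defaults to the file name.
#' @param ris_label_tag Two-letter RIS tag carrying the screening labels.
#' @return A validated [corpus()].
#' @export
read_corpus <- function(path, format = c("delimited", "ris"),
                        column_map = NULL, name = NULL,
                        ris_label_tag = "N1") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path))
  }
  if (is.null(name)) name <- basename(path)
  if (format == "delimited") {
    map <- default_column_map
    if (!is.null(column_map)) map[names(column_map)] <- column_map
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    missing <- setdiff(unname(map), names(df))
    if (length(missing) > 0) {
      abort_format(paste0("delimited file lacks required column(s): ",
                          paste(missing, collapse = ", ")))
    }
    rec <- tibble::tibble(
      record_id = df[[map[["record_id"]]]],
      title = df[[map[["title"]]]],
      abstract = df[[map[["abstract"]]]],
      ta_include = df[[map[["ta_include"]]]],
      final_include = df[[map[["final_include"]]]]
    )
    corpus(rec, name = name)
  } else {
    corpus(read_ris_records(path, ris_label_tag), name = name)
  }
}

#' Write a labeled screening corpus to disk
#'
#' The file is re-readable by [read_corpus()] into an equal corpus (round
#' trip on every field). The delimited dialect serializes booleans as 1/0 and
#' is byte-stable: writing, re-reading and re-writing yields an identical
#' file. Empty abstracts are emitted as empty fields, never dropped.
#'
#' @param x A [corpus()].
#' @param path Output file.
#' @param format `"delimited"` or `"ris"`.
#' @param ris_label_tag RIS tag used to carry the screening labels.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("delimited", "ris"),
                         ris_label_tag = "N1") {
  stopifnot(inherits(x, "corpus"))
  format <- match.arg(format)
  if (format == "delimited") {
    out <- tibble::tibble(
      record_id = x$records$record_id,
      title = x$records$title,
      abstract = x$records$abstract,
      ta_include = as.integer(x$records$ta_include),
      final_include = as.integer(x$records$final_include)
    )
    readr::write_csv(out, path, na = "", progress = FALSE)
  } else {
    write_ris_records(x$records, path, ris_label_tag)
  }
  invisible(path)
}

# --- RIS support -----------------------------------------------------------
# No installed R package parses RIS, so a minimal reader/writer for the tags
# we emit (TY/ID/TI/AB plus the label tag) lives here. Continuation lines
# (not starting with "XX  - ") are appended to the previous tag's value.

ris_tag_re <- "^([A-Z][A-Z0-9])  - ?(.*)$"

read_ris_records <- function(path, label_tag) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- list()
  cur <- list()
  last_tag <- NULL
  flush <- function(cur) {
    if (length(cur) == 0) return(NULL)
    lab <- cur[[label_tag]]
    if (is.null(lab)) {
      abort_format(sprintf(
        "RIS record '%s' lacks the screening-label tag %s",
        if (is.null(cur$ID)) "<no ID>" else cur$ID, label_tag))
    }
    ta <- stringr::str_match(lab, "ta_include=([01])")[, 2]
    fi <- stringr::str_match(lab, "final_include=([01])")[, 2]
    if (is.na(ta) || is.na(fi)) {
      abort_format(sprintf(
        "RIS label tag %s of record '%s' is not of the form 'screening: ta_include=<0|1>; final_include=<0|1>'",
        label_tag, if (is.null(cur$ID)) "<no ID>" else cur$ID))
    }
    if (is.null(cur$ID)) abort_format("RIS record lacks an ID tag")
    list(record_id = cur$ID,
         title = if (is.null(cur$TI)) "" else cur$TI,
         abstract = if (is.null(cur$AB)) "" else cur$AB,
         ta_include = ta == "1", final_include = fi == "1")
  }
  for (line in lines) {
    m <- stringr::str_match(line, ris_tag_re)
    if (!is.na(m[1, 1])) {
      tag <- m[1, 2]
      val <- m[1, 3]
      if (tag == "ER") {
        r <- flush(cur)
        if (!is.null(r)) recs[[length(recs) + 1]] <- r
        cur <- list()
        last_tag <- NULL
      } else {
        cur[[tag]] <- if (is.null(cur[[tag]])) val else paste(cur[[tag]], val)
        last_tag <- tag
      }
    } else if (nzchar(trimws(line)) && !is.null(last_tag)) {
      cur[[last_tag]] <- paste(cur[[last_tag]], trimws(line))
    }
  }
  if (length(cur) > 0) {
    r <- flush(cur)
    if (!is.null(r)) recs[[length(recs) + 1]] <- r
  }
  if (length(recs) == 0) abort_format("RIS file contains no records")
  dplyr::bind_rows(lapply(recs, tibble::as_tibble))
}

write_ris_records <- function(rec, path, label_tag) {
  # newlines inside fields would break the line-oriented format
  clean <- function(x) stringr::str_replace_all(x, "[\r\n]+", " ")
  blocks <- vapply(seq_len(nrow(rec)), function(i) {
    paste(
      "TY  - JOUR",
      paste0("ID  - ", clean(rec$record_id[i])),
      paste0("TI  - ", clean(rec$title[i])),
      paste0("AB  - ", clean(rec$abstract[i])),
      paste0(label_tag, "  - screening: ta_include=",
             as.integer(rec$ta_include[i]), "; final_include=",
             as.integer(rec$final_include[i])),
      "ER  - ",
      sep = "\n"
    )
  }, character(1))
  writeLines(blocks, path, useBytes = TRUE)
  invisible(path)
}

# --- duplicate detection ---------------------------------------------------

normalize_screening_text <- function(title, abstract) {
  x <- tolower(paste(title, abstract))
  x <- stringr::str_replace_all(x, "[^a-z0-9]+", " ")
  stringr::str_squish(x)
}

#' Detect suspected duplicate records
#'
#' Prioritized-screening results are only meaningful on a deduplicated
#' dataset: a duplicate pair with conflicting decisions both corrupts model
#' training and makes the recall denominator ambiguous. This check groups
#' records whose normalized title+abstract (lowercased, punctuation stripped,
#' whitespace collapsed) are identical, and flags groups whose members
#' disagree on the title/abstract decision. Detection only — no merging.
#'
#' @param x A [corpus()].
#' @return A tibble with one row per suspected duplicate group: `group`,
#'   `record_ids` (list column), `n`, and `conflicting` (`TRUE` when members
#'   disagree on `ta_include`). Zero rows when the corpus looks clean.
#' @export
check_duplicates <- function(x) {
  stopifnot(inherits(x, "corpus"))
  rec <- x$records
  key <- normalize_screening_text(rec$title, rec$abstract)
  grp <- split(seq_len(nrow(rec)), key)
  grp <- grp[lengths(grp) > 1]
  if (length(grp) == 0) {
    return(tibble::tibble(group = integer(), record_ids = list(),
                          n = integer(), conflicting = logical()))
  }
  # stable order: by first occurrence in the corpus
  grp <- grp[order(vapply(grp, min, integer(1)))]
  tibble::tibble(
    group = seq_along(grp),
    record_ids = lapply(grp, function(i) rec$record_id[i]),
    n = lengths(grp),
    conflicting = vapply(grp, function(i) {
      length(unique(rec$ta_include[i])) > 1
    }, logical(1))
  )
}
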