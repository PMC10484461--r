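# Corpus ingestion and housekeeping. A corpus is a plain data frame with
# columns article_id, database, year, title, keywords (one row per article),
# carrying a "load_report" attribute from ingestion. Keeping the container a
# data frame keeps every downstream step composable with ordinary R tooling.

CORPUS_COLUMNS <- c("article_id", "database", "year", "title", "keywords")

#' Validate a corpus data frame
#'
#' Checks the required columns, the uniqueness of `article_id`, and that
#' `year` is a positive integer. Returns the corpus with columns coerced to
#' canonical types.
#'
#' @param corpus a data frame with columns `article_id`, `database`,
#'   `year`, `title`, `keywords`.
#' @return the validated corpus (invisibly the same data).
#' @export
validate_corpus <- function(corpus) {
  if (!is.data.frame(corpus)) stop("corpus must be a data frame", call. = FALSE)
  missing_cols <- setdiff(CORPUS_COLUMNS, names(corpus))
  if (length(missing_cols))
    stop("corpus is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  corpus$article_id <- as.character(corpus$article_id)
  corpus$database <- as.character(corpus$database)
  corpus$title <- as.character(corpus$title)
  corpus$keywords <- as.character(corpus$keywords)
  corpus$keywords[is.na(corpus$keywords)] <- ""
  dup <- duplicated(corpus$article_id)
  if (any(dup))
    stop("duplicated article_id: ", corpus$article_id[dup][1L], call. = FALSE)
  yr <- suppressWarnings(as.integer(corpus$year))
  if (any(is.na(yr)) || any(yr <= 0L))
    stop("year must be a positive integer for every record", call. = FALSE)
  corpus$year <- yr
  corpus
}

#' Read article records from a file
#'
#' Two plain-text layouts are supported: `"table"`, a UTF-8 delimited table
#' (comma or tab, sniffed from the header line) with a header row naming the
#' five corpus columns; and `"jsonl"`, one JSON object per line with the
#' same fields. Rows whose year does not parse as a positive integer are
#' skipped and collected in the load report; rows with an empty keyword
#' field are retained and counted.
#'
#' @param path input file.
#' @param format `"table"` (default) or `"jsonl"`.
#' @return a corpus data frame with attribute `load_report`, a list with
#'   `n_rows`, `n_loaded`, `n_skipped`, `skipped` (data frame of offending
#'   rows with a reason), `n_missing_keywords`, and `source`.
#' @export
read_corpus <- function(path, format = c("table", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "table") {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    raw <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                             colClasses = "character", comment.char = "",
                             fileEncoding = "UTF-8", check.names = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    raw <- do.call(rbind, lapply(recs, function(r) {
      as.data.frame(lapply(r[CORPUS_COLUMNS[CORPUS_COLUMNS %in% names(r)]],
                           as.character),
                    stringsAsFactors = FALSE)
    }))
    if (is.null(raw)) raw <- data.frame()
  }
  missing_cols <- setdiff(CORPUS_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("input is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- raw[, CORPUS_COLUMNS, drop = FALSE]
  raw$keywords[is.na(raw$keywords)] <- ""

  yr <- suppressWarnings(as.integer(raw$year))
  bad <- is.na(yr) | yr <= 0L
  skipped <- raw[bad, , drop = FALSE]
  if (nrow(skipped)) skipped$reason <- "unparseable year"
  corpus <- raw[!bad, , drop = FALSE]
  corpus$year <- yr[!bad]
  rownames(corpus) <- NULL
  corpus <- validate_corpus(corpus)
  attr(corpus, "load_report") <- list(
    source = path,
    n_rows = nrow(raw),
    n_loaded = nrow(corpus),
    n_skipped = nrow(skipped),
    skipped = skipped,
    n_missing_keywords = sum(!nzchar(trimws(corpus$keywords)))
  )
  corpus
}

#' Write a corpus as a delimited table
#'
#' @param corpus a corpus data frame.
#' @param path output file.
#' @param sep field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, sep = "\t") {
  corpus <- validate_corpus(corpus)
  utils::write.table(corpus[, CORPUS_COLUMNS], path, sep = sep,
                     quote = sep == ",", row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# title key used for duplicate detection: casefold, strip punctuation,
# collapse whitespace
normalize_title <- function(title) {
  x <- tolower(title)
  x <- gsub("[^[:alnum:][:space:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Remove duplicate articles by normalized title
#'
#' Articles indexed by more than one source database typically share a
#' title; records whose titles are equal after casefolding, punctuation
#' stripping and whitespace collapsing are collapsed to the first occurrence
#' in input order.
#'
#' @param corpus a corpus data frame.
#' @return a list with `corpus` (the deduplicated corpus), `removed_count`,
#'   and `removed_ids` (article ids of the dropped records).
#' @examples
#' corp <- data.frame(article_id = c("a", "b"), database = c("db1", "db2"),
#'                    year = 2020, title = c("Low Back Pain.", "low back pain"),
#'                    keywords = "pain")
#' deduplicate(corp)$removed_count
#' @export
deduplicate <- function(corpus) {
  corpus <- validate_corpus(corpus)
  key <- normalize_title(corpus$title)
  dup <- duplicated(key)
  out <- corpus[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "load_report") <- attr(corpus, "load_report")
  list(corpus = out,
       removed_count = sum(dup),
       removed_ids = corpus$article_id[dup])
}

#' Time window
#'
#' @param start_year,end_year inclusive calendar-year bounds.
#' @return an object of class `time_window`.
#' @export
time_window <- function(start_year, end_year) {
  start_year <- as.integer(start_year)
  end_year <- as.integer(end_year)
  if (is.na(start_year) || is.na(end_year) || start_year > end_year)
    stop("need start_year <= end_year", call. = FALSE)
  structure(list(start_year = start_year, end_year = end_year),
            class = "time_window")
}

#' @export
format.time_window <- function(x, ...) {
  paste0(x$start_year, "-", x$end_year)
}

#' @export
print.time_window <- function(x, ...) {
  cat("<time_window ", format(x), ">\n", sep = "")
  invisible(x)
}

#' The four canonical five-year windows, 2002--2021
#'
#' @return list of four `time_window` objects: 2002--2006, 2007--2011,
#'   2012--2016, 2017--2021.
#' @export
canonical_windows <- function() {
  list(time_window(2002, 2006), time_window(2007, 2011),
       time_window(2012, 2016), time_window(2017, 2021))
}

#' Restrict a corpus to one time window
#'
#' @param corpus a corpus data frame.
#' @param window a `time_window`.
#' @return the records with `start_year <= year <= end_year`, input order
#'   preserved.
#' @export
slice_window <- function(corpus, window) {
  corpus <- validate_corpus(corpus)
  stopifnot(inherits(window, "time_window"))
  out <- corpus[corpus$year >= window$start_year &
                corpus$year <= window$end_year, , drop = FALSE]
  rownames(out) <- NULL
  out
}
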