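# Research-trend classification: keywords are assigned (by the user) to
# category tracks, ranked by document frequency within a track for each
# time window, and a keyword is called emerging when its rank improved from
# the first to the last window (or it newly entered the top-N), declining
# when its rank worsened (or it dropped out), stable when unchanged.

TREND_TRACKS <- c("sensors/methods", "biomedical", "treatment", "unassigned")

#' Category map: canonical keyword -> track label
#'
#' Track labels are `"sensors/methods"`, `"biomedical"`, `"treatment"` or
#' `"unassigned"`. Category assignment is domain knowledge supplied as
#' configuration, not computed.
#'
#' @param assignments named character vector: names are canonical keywords,
#'   values are track labels.
#' @return an object of class `category_map` (a named character vector).
#' @export
category_map <- function(assignments) {
  assignments <- vapply(assignments, as.character, character(1))
  if (length(assignments) &&
      (is.null(names(assignments)) || any(!nzchar(names(assignments)))))
    stop("assignments must be named by keyword", call. = FALSE)
  bad <- !assignments %in% TREND_TRACKS
  if (any(bad))
    stop("unknown track label(s): ",
         paste(unique(assignments[bad]), collapse = ", "), call. = FALSE)
  structure(assignments, class = "category_map")
}

#' Read a category map from a two-column delimited file
#'
#' @param path file with tab- or comma-separated columns keyword, track
#'   (no header; `#` comments allowed).
#' @return a `category_map`.
#' @export
read_category_map <- function(path) {
  m <- read_exception_map(path)  # same two-column layout
  category_map(m)
}

#' Illustrative default category map
#'
#' A small map over canonical (stemmed) forms of keywords commonly discussed
#' under the sensors/methods, biomedical and treatment headings of pain
#' research. Shipped purely as an illustration of the format -- real analyses
#' should supply their own domain categorization.
#'
#' @return a `category_map`.
#' @export
default_category_map <- function() {
  category_map(c(
    "machin learn" = "sensors/methods",
    "biomark" = "sensors/methods",
    "electromyographi" = "sensors/methods",
    "visual analog scale" = "sensors/methods",
    "pain assess" = "sensors/methods",
    "pain measur" = "sensors/methods",
    "microdialysi" = "sensors/methods",
    "magnetoencephalographi" = "sensors/methods",
    "chronic pain" = "biomedical",
    "low back pain" = "biomedical",
    "neuropath pain" = "biomedical",
    "acut pain" = "biomedical",
    "cancer pain" = "biomedical",
    "neck pain" = "biomedical",
    "visceral pain" = "biomedical",
    "dorsal root ganglion" = "biomedical",
    "opioid" = "treatment",
    "rehabilit" = "treatment",
    "analges" = "treatment",
    "surgeri" = "treatment",
    "exercis" = "treatment",
    "acupunctur" = "treatment",
    "morphin" = "treatment",
    "laser" = "treatment"
  ))
}

#' Rank the keywords of one track by document frequency
#'
#' @param freq a `keyword_frequency` table (see [document_frequency()]).
#' @param categories a `category_map`.
#' @param track one track label.
#' @param top_n number of ranks to keep (default 20).
#' @return data frame `rank`, `keyword`, `count` for the track's keywords,
#'   sorted by decreasing frequency (ties lexicographic), truncated to
#'   `top_n`.
#' @export
rank_keywords <- function(freq, categories, track, top_n = 20L) {
  stopifnot(inherits(freq, "keyword_frequency"), top_n >= 1L)
  if (!track %in% TREND_TRACKS)
    stop("unknown track label: ", track, call. = FALSE)
  if (!inherits(categories, "category_map"))
    categories <- category_map(categories)
  kws <- names(categories)[categories == track]
  sub <- freq[freq$keyword %in% kws, , drop = FALSE]
  sub <- sub[order(-sub$count, sub$keyword), , drop = FALSE]
  sub <- utils::head(sub, top_n)
  out <- data.frame(rank = seq_len(nrow(sub)), keyword = sub$keyword,
                    count = sub$count, stringsAsFactors = FALSE)
  attr(out, "track") <- track
  attr(out, "top_n") <- as.integer(top_n)
  out
}

#' Classify keywords as emerging, declining or stable
#'
#' Compares a track's top-N ranking in the first time window with the last:
#' a keyword is emerging when its rank improved (numerically smaller) or it
#' newly entered the top-N; declining when its rank worsened or it dropped
#' out; stable when the rank is identical. Keywords absent from both
#' rankings are not reported.
#'
#' @param first_window_ranks,last_window_ranks rankings from
#'   [rank_keywords()] for the same track and `top_n`.
#' @param top_n the ranking depth both lists were built with.
#' @return data frame `keyword`, `rank_first`, `count_first`, `rank_last`,
#'   `count_last`, `status`; rank columns are `NA` where the keyword is
#'   outside that window's top-N.
#' @export
classify_trends <- function(first_window_ranks, last_window_ranks,
                            top_n = 20L) {
  kws <- sort(union(first_window_ranks$keyword, last_window_ranks$keyword))
  i1 <- match(kws, first_window_ranks$keyword)
  i2 <- match(kws, last_window_ranks$keyword)
  r1 <- first_window_ranks$rank[i1]
  r2 <- last_window_ranks$rank[i2]
  status <- ifelse(
    is.na(r1), "emerging",
    ifelse(is.na(r2), "declining",
           ifelse(r2 < r1, "emerging",
                  ifelse(r2 > r1, "declining", "stable")))
  )
  data.frame(
    keyword = kws,
    rank_first = r1,
    count_first = first_window_ranks$count[i1],
    rank_last = r2,
    count_last = last_window_ranks$count[i2],
    status = status,
    stringsAsFactors = FALSE
  )
}
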