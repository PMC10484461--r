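# Keyword normalization: raw author-keyword fields -> canonical stemmed
# keywords. The pipeline is: split the field on delimiters, lowercase,
# delete in-token punctuation (digits survive), tokenize on spaces and
# hyphens, map irregular plurals, Porter-stem each token, apply any
# user-supplied stem overrides, drop tokens shorter than three characters,
# and rejoin with single spaces.

#' Exception table for keyword normalization
#'
#' Holds two token-level maps consulted during normalization:
#' `irregular_plurals` is applied before stemming (e.g. children -> child),
#' `stem_overrides` after stemming, for domain-specific canonical forms the
#' Porter algorithm does not produce. Both maps are lowercase single tokens.
#'
#' @param irregular_plurals named character vector (name = surface token,
#'   value = replacement) applied before stemming.
#' @param stem_overrides named character vector applied to stems.
#' @return an object of class `kcn_exceptions`.
#' @examples
#' ex <- exception_table(irregular_plurals = c(children = "child"))
#' normalize_keyword("Children", ex)
#' @export
exception_table <- function(irregular_plurals = character(0),
                            stem_overrides = character(0)) {
  chk <- function(x, what) {
    x <- vapply(x, as.character, character(1))
    if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
      stop(what, " must be a named character vector", call. = FALSE)
    bad <- grepl("[^a-z0-9]", c(names(x), unname(x)))
    if (any(bad))
      stop(what, " keys and values must be lowercase single tokens",
           call. = FALSE)
    x
  }
  structure(
    list(irregular_plurals = chk(irregular_plurals, "irregular_plurals"),
         stem_overrides = chk(stem_overrides, "stem_overrides")),
    class = "kcn_exceptions"
  )
}

#' Default exception table
#'
#' Ships a small irregular-plural list (children, feet, teeth, mice, men,
#' women) and no stem overrides; extend via [exception_table()] or
#' [read_exception_table()].
#'
#' @return a `kcn_exceptions` object.
#' @export
default_exceptions <- function() {
  exception_table(
    irregular_plurals = c(children = "child", feet = "foot", teeth = "tooth",
                          mice = "mouse", men = "man", women = "woman")
  )
}

#' Read one exception map from a two-column delimited file
#'
#' @param path file with two tab- or comma-separated columns (from, to),
#'   no header.
#' @return named character vector suitable for [exception_table()].
#' @export
read_exception_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(character(0))
  parts <- strsplit(lines, "[\t,]")
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("malformed exception line(s): ", lines[bad][1L], call. = FALSE)
  from <- trimws(vapply(parts, `[[`, character(1), 1L))
  to <- trimws(vapply(parts, `[[`, character(1), 2L))
  stats::setNames(to, from)
}

#' Read a full exception table from files
#'
#' @param irregular_plurals_path,stem_overrides_path optional paths to
#'   two-column files as read by [read_exception_map()].
#' @return a `kcn_exceptions` object.
#' @export
read_exception_table <- function(irregular_plurals_path = NULL,
                                 stem_overrides_path = NULL) {
  ip <- if (is.null(irregular_plurals_path)) default_exceptions()$irregular_plurals
        else read_exception_map(irregular_plurals_path)
  so <- if (is.null(stem_overrides_path)) character(0)
        else read_exception_map(stem_overrides_path)
  exception_table(irregular_plurals = ip, stem_overrides = so)
}

#' Split a raw keyword field into individual raw keywords
#'
#' Author keyword fields arrive as one delimited string; `;`, `:` and `/`
#' separate keywords. Hyphens are not field delimiters -- they separate
#' tokens within a keyword and are handled by [normalize_keyword()].
#'
#' @param raw character vector of raw keyword fields.
#' @return a list (one element per input field) of character vectors of
#'   trimmed raw keywords; empty fragments are dropped.
#' @examples
#' parse_keyword_field("machine learning; SVM")
#' @export
parse_keyword_field <- function(raw) {
  if (length(raw) == 0L) return(list())
  raw[is.na(raw)] <- ""
  out <- strsplit(raw, "[;:/]")
  lapply(out, function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
}

#' Stem a single lowercase token
#'
#' Applies, in order: irregular-plural lookup, the Porter stem
#' ([porter_stem()]), and any stem override from the exception table.
#'
#' @param token character vector of nonempty lowercase tokens.
#' @param exceptions a `kcn_exceptions` object; default [default_exceptions()].
#' @return character vector of canonical stems.
#' @examples
#' stem_token(c("painfulness", "children", "assessment"))
#' @export
stem_token <- function(token, exceptions = default_exceptions()) {
  stopifnot(inherits(exceptions, "kcn_exceptions"))
  ip <- exceptions$irregular_plurals
  hit <- match(token, names(ip))
  token[!is.na(hit)] <- ip[hit[!is.na(hit)]]
  stems <- porter_stem(token)
  so <- exceptions$stem_overrides
  hit <- match(stems, names(so))
  stems[!is.na(hit)] <- so[hit[!is.na(hit)]]
  stems
}

#' Normalize one raw keyword to its canonical stemmed form
#'
#' Applies the full text-indexing chain to each element: lowercase; delete
#' punctuation inside tokens (commas, periods, apostrophes and the like
#' disappear, digits are kept, so "1,3,4 -Oxadiazole" becomes tokens "134"
#' and "oxadiazole"); tokenize on spaces and hyphens; stem each token via
#' [stem_token()]; drop tokens of one or two characters; rejoin with single
#' spaces. Returns an empty string when no token survives.
#'
#' @param raw character vector of single raw keywords (already field-split).
#' @param exceptions a `kcn_exceptions` object.
#' @return character vector of canonical keywords ("" where nothing
#'   survives).
#' @examples
#' normalize_keyword(c("Neuropathic Pain", "pain management", "of"))
#' @export
normalize_keyword <- function(raw, exceptions = default_exceptions()) {
  if (length(raw) == 0L) return(character(0))
  stopifnot(is.character(raw))
  x <- tolower(raw)
  # hyphen-family characters (ASCII hyphen, unicode hyphens, en/em dash)
  # become token separators ...
  x <- gsub("[-\u2010\u2011\u2012\u2013\u2014]", " ", x)
  # ... all other punctuation is deleted in place (letters/digits/spaces kept)
  x <- gsub("[^a-z0-9 ]", "", x)
  toks <- strsplit(x, " +")
  vapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    if (!length(tk)) return("")
    st <- stem_token(tk, exceptions)
    st <- st[nchar(st) >= 3L]
    paste(st, collapse = " ")
  }, character(1))
}

#' Build the before/after stemming dictionary for a corpus
#'
#' Maps every distinct raw keyword appearing in the corpus to its canonical
#' stemmed form, and groups originals per canonical form (the classic
#' before/after stemming table).
#'
#' @param corpus a corpus data frame (see [read_corpus()]).
#' @param exceptions a `kcn_exceptions` object.
#' @return an object of class `stem_dictionary`: a data frame with columns
#'   `original` and `canonical` (one row per distinct original keyword,
#'   originals mapping to an empty canonical form are retained with
#'   canonical `""`), plus attribute `inverse`, a named list canonical ->
#'   character vector of originals.
#' @export
build_stem_dictionary <- function(corpus, exceptions = default_exceptions()) {
  corpus <- validate_corpus(corpus)
  raws <- unique(unlist(parse_keyword_field(corpus$keywords), use.names = FALSE))
  if (is.null(raws) || !length(raws)) {
    d <- data.frame(original = character(0), canonical = character(0),
                    stringsAsFactors = FALSE)
  } else {
    raws <- sort(raws)
    d <- data.frame(original = raws,
                    canonical = normalize_keyword(raws, exceptions),
                    stringsAsFactors = FALSE)
  }
  nonempty <- d[nzchar(d$canonical), , drop = FALSE]
  attr(d, "inverse") <- split(nonempty$original, nonempty$canonical)
  class(d) <- c("stem_dictionary", "data.frame")
  d
}

#' Write a stem dictionary as a two-column delimited table
#'
#' @param dictionary a `stem_dictionary`.
#' @param path output file; tab-separated with header original, canonical.
#' @return `path`, invisibly.
#' @export
write_stem_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "stem_dictionary"))
  utils::write.table(as.data.frame(dictionary)[, c("original", "canonical")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# canonical keyword set of each article: parse the raw field, normalize,
# drop empties, unique within article
article_keyword_sets <- function(corpus, exceptions = default_exceptions(),
                                 dictionary = NULL) {
  corpus <- validate_corpus(corpus)
  fields <- parse_keyword_field(corpus$keywords)
  if (is.null(dictionary)) {
    raws <- unique(unlist(fields, use.names = FALSE))
    canon <- if (length(raws)) normalize_keyword(raws, exceptions) else character(0)
    map <- stats::setNames(canon, raws)
  } else {
    stopifnot(inherits(dictionary, "stem_dictionary"))
    map <- stats::setNames(dictionary$canonical, dictionary$original)
  }
  lapply(fields, function(f) {
    if (!length(f)) return(character(0))
    k <- map[f]
    # raw keywords absent from the dictionary are normalized on the fly
    miss <- is.na(k)
    if (any(miss)) k[miss] <- normalize_keyword(f[miss], exceptions)
    sort(unique(k[nzchar(k) & !is.na(k)]))
  })
}
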