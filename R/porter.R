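# Porter (1980) suffix-stripping stemmer.
#
# Rule-based stemming is the backbone of keyword normalization here: surface
# variants ("opioids", "opioide") must collapse onto a single canonical form
# before any co-occurrence counting. The implementation below follows the
# classic algorithm: words are viewed as [C](VC){m}[V] where m is the
# "measure"; five sequential steps strip plural and derivational suffixes,
# each step applying at most its longest matching rule.

# consonant/vowel classification; 'y' is a consonant at word start or after
# a vowel ("toy", "yellow") and a vowel after a consonant ("happy")
.pt_cons <- function(ch) {
  n <- length(ch)
  cons <- logical(n)
  for (i in seq_len(n)) {
    c_i <- ch[i]
    if (c_i %in% c("a", "e", "i", "o", "u")) {
      cons[i] <- FALSE
    } else if (c_i == "y") {
      cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    } else {
      cons[i] <- TRUE
    }
  }
  cons
}

# the measure m: number of VC block pairs in the collapsed C/V sequence
.pt_m <- function(w) {
  if (!nzchar(w)) return(0L)
  blocks <- rle(.pt_cons(strsplit(w, "", fixed = TRUE)[[1L]]))$values
  if (length(blocks) < 2L) return(0L)
  sum(!blocks[-length(blocks)] & blocks[-1L])
}

.pt_has_vowel <- function(w) {
  nzchar(w) && any(!.pt_cons(strsplit(w, "", fixed = TRUE)[[1L]]))
}

# *d: ends with a double consonant
.pt_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  a <- substr(w, n - 1L, n - 1L)
  b <- substr(w, n, n)
  if (a != b) return(FALSE)
  cons <- .pt_cons(strsplit(w, "", fixed = TRUE)[[1L]])
  cons[n]
}

# *o: ends consonant-vowel-consonant where the final consonant is not w, x, y
.pt_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  cons <- .pt_cons(strsplit(w, "", fixed = TRUE)[[1L]])
  last <- substr(w, n, n)
  cons[n - 2L] && !cons[n - 1L] && cons[n] && !(last %in% c("w", "x", "y"))
}

.pt_drop <- function(w, k) substr(w, 1L, nchar(w) - k)

# apply the longest matching suffix rule of a step; if its condition fails,
# the step does nothing (no fallback to shorter suffixes)
.pt_rule_step <- function(w, suffixes, replacements, min_m) {
  ord <- order(nchar(suffixes), decreasing = TRUE)
  for (i in ord) {
    suf <- suffixes[i]
    if (endsWith(w, suf)) {
      stem <- .pt_drop(w, nchar(suf))
      if (.pt_m(stem) > min_m) {
        return(paste0(stem, replacements[i]))
      }
      return(w)
    }
  }
  w
}

.porter_one <- function(w) {
  if (nchar(w) <= 2L) return(w)

  # step 1a: plurals
  if (endsWith(w, "sses")) {
    w <- .pt_drop(w, 2L)
  } else if (endsWith(w, "ies")) {
    w <- paste0(.pt_drop(w, 3L), "i")
  } else if (!endsWith(w, "ss") && endsWith(w, "s")) {
    w <- .pt_drop(w, 1L)
  }

  # step 1b: -eed/-ed/-ing
  if (endsWith(w, "eed")) {
    if (.pt_m(.pt_drop(w, 3L)) > 0L) w <- .pt_drop(w, 1L)
  } else {
    stripped <- FALSE
    if (endsWith(w, "ed") && .pt_has_vowel(.pt_drop(w, 2L))) {
      w <- .pt_drop(w, 2L)
      stripped <- TRUE
    } else if (endsWith(w, "ing") && .pt_has_vowel(.pt_drop(w, 3L))) {
      w <- .pt_drop(w, 3L)
      stripped <- TRUE
    }
    if (stripped) {
      if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
        w <- paste0(w, "e")
      } else if (.pt_double_cons(w) &&
                 !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
        w <- .pt_drop(w, 1L)
      } else if (.pt_m(w) == 1L && .pt_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c: terminal y -> i when the stem has a vowel
  if (endsWith(w, "y") && .pt_has_vowel(.pt_drop(w, 1L))) {
    w <- paste0(.pt_drop(w, 1L), "i")
  }

  # step 2 (m > 0): double suffixes to single
  w <- .pt_rule_step(
    w,
    c("ational", "tional", "enci", "anci", "izer", "abli", "alli",
      "entli", "eli", "ousli", "ization", "ation", "ator", "alism",
      "iveness", "fulness", "ousness", "aliti", "iviti", "biliti"),
    c("ate", "tion", "ence", "ance", "ize", "able", "al",
      "ent", "e", "ous", "ize", "ate", "ate", "al",
      "ive", "ful", "ous", "al", "ive", "ble"),
    0L
  )

  # step 3 (m > 0): -icate, -ative, -alize, -iciti, -ical, -ful, -ness
  w <- .pt_rule_step(
    w,
    c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
    c("ic", "", "al", "ic", "ic", "", ""),
    0L
  )

  # step 4 (m > 1): strip remaining derivational suffixes; -ion only after s/t
  suf4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
            "ement", "ment", "ent", "ou", "ism", "ate", "iti", "ous",
            "ive", "ize", "ion")
  ord <- order(nchar(suf4), decreasing = TRUE)
  for (i in ord) {
    suf <- suf4[i]
    if (endsWith(w, suf)) {
      stem <- .pt_drop(w, nchar(suf))
      ok <- .pt_m(stem) > 1L
      if (suf == "ion") {
        last <- if (nzchar(stem)) substr(stem, nchar(stem), nchar(stem)) else ""
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # step 5a: drop terminal e
  if (endsWith(w, "e")) {
    stem <- .pt_drop(w, 1L)
    m <- .pt_m(stem)
    if (m > 1L || (m == 1L && !.pt_cvc(stem))) w <- stem
  }

  # step 5b: -ll -> -l for m > 1
  if (.pt_m(w) > 1L && .pt_double_cons(w) && endsWith(w, "l")) {
    w <- .pt_drop(w, 1L)
  }

  w
}

#' Porter stem of lowercase word tokens
#'
#' Applies the Porter suffix-stripping algorithm to each element of a
#' character vector. Tokens of length one or two, and tokens containing
#' characters outside `a`-`z` (for example purely numeric tokens such as
#' `"134"`), are returned unchanged.
#'
#' @param tokens character vector of lowercase word tokens.
#' @return character vector of stems, same length as `tokens`.
#' @examples
#' porter_stem(c("painfulness", "opioids", "quality", "assessment"))
#' @export
porter_stem <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  stopifnot(is.character(tokens))
  out <- tokens
  alpha <- grepl("^[a-z]+$", tokens)
  out[alpha] <- vapply(tokens[alpha], .porter_one, character(1),
                       USE.NAMES = FALSE)
  out
}
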