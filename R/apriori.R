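# Affinity analysis over article keyword sets: level-wise Apriori frequent-
# itemset mining with candidate join + downward-closure pruning, followed by
# association-rule generation scored by support count, confidence and lift.
# Transactions are the canonical keyword sets of articles pooled over the
# whole study period.

#' Build the transaction set for affinity analysis
#'
#' One transaction per article: its canonical keyword set (items are unique
#' within a transaction by construction). All time windows are pooled.
#'
#' @param corpus a corpus data frame (deduplicated).
#' @param exceptions a `kcn_exceptions` object.
#' @param dictionary optional `stem_dictionary`.
#' @return an object of class `transaction_set`: a list with `transactions`
#'   (list of sorted character vectors) and `n` (number of transactions).
#' @export
build_transactions <- function(corpus, exceptions = default_exceptions(),
                               dictionary = NULL) {
  sets <- article_keyword_sets(corpus, exceptions, dictionary)
  structure(list(transactions = sets, n = length(sets)),
            class = "transaction_set")
}

#' @export
print.transaction_set <- function(x, ...) {
  cat("<transaction_set: ", x$n, " transactions, ",
      length(unique(unlist(x$transactions))), " distinct items>\n", sep = "")
  invisible(x)
}

# inverted index: item -> sorted integer vector of transaction indices
.tx_index <- function(transactions) {
  items <- unlist(transactions, use.names = FALSE)
  if (is.null(items) || !length(items)) return(list())
  tid <- rep(seq_along(transactions), lengths(transactions))
  split(tid, items)
}

.itemset_key <- function(items) paste(items, collapse = "\x1f")

#' Apriori frequent-itemset mining
#'
#' Level-wise search: frequent single items first, then candidates of size
#' k joined from frequent (k-1)-itemsets sharing their first k-2 items, with
#' any candidate discarded whose (k-1)-subsets are not all frequent
#' (downward closure). Counts are exact transaction-containment counts,
#' computed by intersecting per-item transaction-id lists.
#'
#' @param transactions a `transaction_set`.
#' @param min_support_count minimum number of transactions an itemset must
#'   occur in (>= 1).
#' @return data frame with columns `items` (list column of sorted character
#'   vectors), `size`, `count`; every itemset of size >= 1 meeting the
#'   threshold, ordered by size then lexicographically.
#' @export
apriori_frequent_itemsets <- function(transactions, min_support_count) {
  stopifnot(inherits(transactions, "transaction_set"))
  min_support_count <- as.integer(min_support_count)
  if (transactions$n < 1L) stop("no transactions to mine", call. = FALSE)
  if (min_support_count < 1L)
    stop("min_support_count must be >= 1", call. = FALSE)

  idx <- .tx_index(transactions$transactions)
  counts <- lengths(idx)
  frequent_items <- sort(names(counts)[counts >= min_support_count])

  res_items <- list()
  res_count <- integer(0)
  res_size <- integer(0)
  add <- function(sets, tids) {
    res_items[[length(res_items) + 1L]] <<- sets
    res_count <<- c(res_count, lengths(tids))
    res_size <<- c(res_size, lengths(sets))
  }

  if (!length(frequent_items)) {
    out <- data.frame(size = integer(0), count = integer(0))
    out$items <- list()
    return(out[, c("items", "size", "count")])
  }

  level_sets <- as.list(frequent_items)
  level_tids <- idx[frequent_items]
  add(level_sets, level_tids)

  repeat {
    n_prev <- length(level_sets)
    if (n_prev < 2L) break
    prev_keys <- vapply(level_sets, .itemset_key, character(1))
    k <- length(level_sets[[1L]]) + 1L
    # join step: combine itemsets sharing the first k-2 items
    prefixes <- vapply(level_sets, function(s) .itemset_key(s[-length(s)]),
                       character(1))
    groups <- split(seq_len(n_prev), prefixes)
    cand_sets <- list()
    cand_tids <- list()
    for (g in groups) {
      if (length(g) < 2L) next
      for (a in seq_along(g)) {
        for (b in seq_along(g)) {
          if (a >= b) next
          s1 <- level_sets[[g[a]]]
          s2 <- level_sets[[g[b]]]
          cand <- sort(unique(c(s1, s2)))
          if (length(cand) != k) next
          # prune: every (k-1)-subset must be frequent
          ok <- all(vapply(seq_len(k), function(d) {
            .itemset_key(cand[-d]) %in% prev_keys
          }, logical(1)))
          if (!ok) next
          tids <- intersect(level_tids[[g[a]]], level_tids[[g[b]]])
          if (length(tids) >= min_support_count) {
            cand_sets[[length(cand_sets) + 1L]] <- cand
            cand_tids[[length(cand_tids) + 1L]] <- tids
          }
        }
      }
    }
    if (!length(cand_sets)) break
    # de-duplicate candidates generated from different joins
    keys <- vapply(cand_sets, .itemset_key, character(1))
    keep <- !duplicated(keys)
    cand_sets <- cand_sets[keep]
    cand_tids <- cand_tids[keep]
    ord <- order(vapply(cand_sets, .itemset_key, character(1)))
    cand_sets <- cand_sets[ord]
    cand_tids <- cand_tids[ord]
    add(cand_sets, cand_tids)
    level_sets <- cand_sets
    level_tids <- cand_tids
  }

  items <- do.call(c, res_items)
  out <- data.frame(size = res_size, count = res_count)
  out$items <- items
  out <- out[, c("items", "size", "count")]
  rownames(out) <- NULL
  out
}

#' Derive association rules from frequent itemsets
#'
#' For every frequent itemset of size >= 2 and every nonempty proper subset
#' A (the antecedent, consequent C = itemset \ A), the rule A -> C is
#' emitted when its confidence reaches `min_confidence`. Support count is
#' the count of the full itemset; confidence = count(itemset) / count(A);
#' lift = confidence / (count(C) / N). Output is sorted by decreasing lift,
#' then decreasing confidence, then lexicographic antecedent.
#'
#' @param itemsets output of [apriori_frequent_itemsets()] on the same
#'   transactions.
#' @param transactions the `transaction_set` the itemsets were mined from.
#' @param min_confidence confidence threshold in (0, 1].
#' @param single_consequent if `TRUE`, restrict to rules with a one-item
#'   consequent (the layout of printed rule tables).
#' @return data frame with list columns `antecedent`, `consequent` and
#'   numeric columns `support_count`, `confidence`, `lift`.
#' @export
derive_rules <- function(itemsets, transactions, min_confidence,
                         single_consequent = FALSE) {
  stopifnot(inherits(transactions, "transaction_set"))
  if (!(min_confidence > 0 && min_confidence <= 1))
    stop("min_confidence must be in (0, 1]", call. = FALSE)
  n_tx <- transactions$n
  count_of <- stats::setNames(
    itemsets$count,
    vapply(itemsets$items, .itemset_key, character(1))
  )

  ante <- list(); cons <- list()
  supp <- integer(0); conf <- numeric(0); lift <- numeric(0)
  big <- itemsets[itemsets$size >= 2L, , drop = FALSE]
  for (r in seq_len(nrow(big))) {
    items <- big$items[[r]]
    cnt <- big$count[r]
    m <- length(items)
    # enumerate nonempty proper subsets as antecedents
    for (mask in seq_len(2L^m - 2L)) {
      sel <- as.logical(bitwAnd(mask, 2L^(seq_len(m) - 1L)))
      a <- items[sel]
      c_ <- items[!sel]
      if (single_consequent && length(c_) != 1L) next
      cnt_a <- count_of[[.itemset_key(a)]]
      confidence <- cnt / cnt_a
      if (confidence < min_confidence) next
      cnt_c <- count_of[[.itemset_key(c_)]]
      ante[[length(ante) + 1L]] <- a
      cons[[length(cons) + 1L]] <- c_
      supp <- c(supp, cnt)
      conf <- c(conf, confidence)
      lift <- c(lift, confidence / (cnt_c / n_tx))
    }
  }
  out <- data.frame(support_count = supp, confidence = conf, lift = lift)
  out$antecedent <- ante
  out$consequent <- cons
  out <- out[, c("antecedent", "consequent", "support_count",
                 "confidence", "lift")]
  if (nrow(out)) {
    akey <- vapply(out$antecedent, function(a) paste(a, collapse = "; "),
                   character(1))
    out <- out[order(-out$lift, -out$confidence, akey), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Format association rules as a printable table
#'
#' @param rules output of [derive_rules()].
#' @param digits decimal places for confidence and lift (default 2, the
#'   usual report precision); full precision is retained in `rules` itself.
#' @return data frame with character columns `antecedent`, `consequent`
#'   (items joined by `"; "`) and rounded `confidence`, `lift`.
#' @export
rule_table <- function(rules, digits = 2L) {
  data.frame(
    antecedent = vapply(rules$antecedent, paste, character(1),
                        collapse = "; "),
    consequent = vapply(rules$consequent, paste, character(1),
                        collapse = "; "),
    support_count = rules$support_count,
    confidence = round(rules$confidence, digits),
    lift = round(rules$lift, digits),
    stringsAsFactors = FALSE
  )
}
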