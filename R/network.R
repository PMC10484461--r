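# Keyword co-occurrence network (KCN) construction. For one time window,
# nodes are the canonical keywords observed in that window and the weight
# w_ij counts the articles in which keywords i and j co-occur (each article
# contributes at most once per unordered pair -- keyword lists are sets after
# normalization). The network is undirected with a zero diagonal.

#' Per-window keyword document frequencies
#'
#' The document frequency of a keyword is the number of articles in the
#' window whose canonical keyword set contains it (an article counts once
#' even if several raw variants collapse onto the keyword).
#'
#' @param corpus a corpus data frame (deduplicated).
#' @param window a `time_window`; `NULL` uses the whole corpus.
#' @param exceptions a `kcn_exceptions` object.
#' @param dictionary optional `stem_dictionary` mapping raw keywords to
#'   canonical forms; built on the fly when omitted.
#' @return an object of class `keyword_frequency`: a data frame with
#'   columns `keyword` and `count`, sorted by decreasing count (ties
#'   lexicographic), with attribute `window`.
#' @export
document_frequency <- function(corpus, window = NULL,
                               exceptions = default_exceptions(),
                               dictionary = NULL) {
  corpus <- validate_corpus(corpus)
  if (!is.null(window)) corpus <- slice_window(corpus, window)
  sets <- article_keyword_sets(corpus, exceptions, dictionary)
  all_kw <- unlist(sets, use.names = FALSE)
  if (is.null(all_kw) || !length(all_kw)) {
    out <- data.frame(keyword = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    tab <- table(all_kw)
    out <- data.frame(keyword = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$keyword), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "window") <- window
  class(out) <- c("keyword_frequency", "data.frame")
  out
}

#' Build the keyword co-occurrence network for one time window
#'
#' For each article, every unordered pair of distinct canonical keywords in
#' its set increments the pair's weight by one. Articles listing a single
#' keyword contribute an isolated node.
#'
#' @inheritParams document_frequency
#' @return an object of class `kcn_network`: a list with `nodes` (sorted
#'   character vector), `edges` (data frame `from`, `to`, `weight` with
#'   `from < to` lexicographically), `window`, and `n_articles` (articles in
#'   the window).
#' @export
build_network <- function(corpus, window = NULL,
                          exceptions = default_exceptions(),
                          dictionary = NULL) {
  corpus <- validate_corpus(corpus)
  if (!is.null(window)) corpus <- slice_window(corpus, window)
  sets <- article_keyword_sets(corpus, exceptions, dictionary)
  nodes <- sort(unique(unlist(sets, use.names = FALSE)))

  pair_from <- vector("list", length(sets))
  pair_to <- vector("list", length(sets))
  for (a in seq_along(sets)) {
    s <- sets[[a]]  # already sorted and unique
    if (length(s) >= 2L) {
      cmb <- utils::combn(s, 2L)
      pair_from[[a]] <- cmb[1L, ]
      pair_to[[a]] <- cmb[2L, ]
    }
  }
  from <- unlist(pair_from, use.names = FALSE)
  to <- unlist(pair_to, use.names = FALSE)
  if (is.null(from) || !length(from)) {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
  } else {
    key <- paste(from, to, sep = "\x1f")
    tab <- table(key)
    parts <- strsplit(names(tab), "\x1f", fixed = TRUE)
    edges <- data.frame(
      from = vapply(parts, `[[`, character(1), 1L),
      to = vapply(parts, `[[`, character(1), 2L),
      weight = as.integer(tab),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(
    list(nodes = nodes, edges = edges, window = window,
         n_articles = nrow(corpus)),
    class = "kcn_network"
  )
}

#' @export
print.kcn_network <- function(x, ...) {
  win <- if (is.null(x$window)) "all years" else format(x$window)
  cat("<kcn_network ", win, ": ", length(x$nodes), " nodes, ",
      nrow(x$edges), " links, ", x$n_articles, " articles>\n", sep = "")
  invisible(x)
}

#' Weighted adjacency matrix of a KCN
#'
#' @param network a `kcn_network`.
#' @param weighted logical; `FALSE` gives the binary adjacency a_ij.
#' @return a dense symmetric matrix with zero diagonal, dimnames = nodes.
#' @export
adjacency_matrix <- function(network, weighted = TRUE) {
  stopifnot(inherits(network, "kcn_network"))
  n <- length(network$nodes)
  m <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  if (nrow(network$edges)) {
    i <- match(network$edges$from, network$nodes)
    j <- match(network$edges$to, network$nodes)
    w <- if (weighted) network$edges$weight else 1
    m[cbind(i, j)] <- w
    m[cbind(j, i)] <- w
  }
  m
}

#' Summary statistics of a KCN
#'
#' Reports article, node and link counts, mean and maximum degree, strength
#' and link weight for one window network. The average network weight is the
#' sum of all link weights divided by the number of links; it is `NA` when
#' the network has no links.
#'
#' @param network a `kcn_network`.
#' @return a one-row data frame with columns `window`, `n_articles`,
#'   `n_nodes`, `n_links`, `avg_degree`, `max_degree`, `avg_strength`,
#'   `max_strength`, `avg_weight`, `max_weight`.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "kcn_network"))
  k <- kcn_degree(network)
  s <- kcn_strength(network)
  n_links <- nrow(network$edges)
  data.frame(
    window = if (is.null(network$window)) NA_character_
             else format(network$window),
    n_articles = network$n_articles,
    n_nodes = length(network$nodes),
    n_links = n_links,
    avg_degree = if (length(k)) mean(k) else NA_real_,
    max_degree = if (length(k)) max(k) else NA_integer_,
    avg_strength = if (length(s)) mean(s) else NA_real_,
    max_strength = if (length(s)) max(s) else NA_integer_,
    avg_weight = if (n_links) sum(network$edges$weight) / n_links else NA_real_,
    max_weight = if (n_links) max(network$edges$weight) else NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Write a KCN as a weighted edge list
#'
#' Tab-separated `source`, `target`, `weight`, one line per link.
#'
#' @param network a `kcn_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "kcn_network"))
  edges <- network$edges
  names(edges) <- c("source", "target", "weight")
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a KCN to an igraph graph
#'
#' @param network a `kcn_network`.
#' @return an undirected weighted `igraph` graph with isolated nodes kept.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "kcn_network"))
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for graph conversion", call. = FALSE)
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = data.frame(name = network$nodes))
  igraph::E(g)$weight <- network$edges$weight
  g
}

#' Write a KCN in GraphML format
#'
#' @param network a `kcn_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
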