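# The five weighted-network statistics used to characterize a KCN:
#   degree           k_i = sum_j a_ij
#   strength         s_i = sum_j w_ij
#   average weight vs endpoint degree: edges grouped by the product k_i*k_j,
#                    each class reporting the mean member weight
#   weighted nearest-neighbor degree  k^w_nn,i = (1/s_i) sum_j w_ij k_j
#   weighted clustering (geometric-mean form)
#                    c_i = [1/(k_i(k_i-1))] sum_{j,k} (w-hat_ij w-hat_ik w-hat_jk)^{1/3}
# with w-hat = w / max(w) over the window network, the clustering sum running
# over ordered neighbor pairs so the complete unit-weight graph attains 1.

#' Node degrees of a KCN
#'
#' @param network a `kcn_network`.
#' @return named integer vector, one entry per node; isolated nodes get 0.
#' @export
kcn_degree <- function(network) {
  stopifnot(inherits(network, "kcn_network"))
  k <- stats::setNames(integer(length(network$nodes)), network$nodes)
  if (nrow(network$edges)) {
    tab <- table(c(network$edges$from, network$edges$to))
    k[names(tab)] <- as.integer(tab)
  }
  k
}

#' Node strengths of a KCN
#'
#' The strength of a node is the sum of the weights of its incident links.
#'
#' @param network a `kcn_network`.
#' @return named numeric vector; isolated nodes get 0.
#' @export
kcn_strength <- function(network) {
  stopifnot(inherits(network, "kcn_network"))
  s <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  if (nrow(network$edges)) {
    inc <- c(network$edges$from, network$edges$to)
    w <- rep(network$edges$weight, 2L)
    agg <- tapply(w, inc, sum)
    s[names(agg)] <- as.numeric(agg)
  }
  s
}

#' Average link weight as a function of endpoint degree
#'
#' Every link is assigned to the class given by the exact integer product of
#' its endpoint degrees; each class reports the arithmetic mean of its
#' member weights. The default method takes externally supplied degrees so
#' a network fragment with known degrees can be profiled directly; the
#' `kcn_network` method uses the network's own degrees.
#'
#' @param x a `kcn_network`, or a named numeric vector of node degrees.
#' @param edges for the default method, a data frame with columns `from`,
#'   `to`, `weight`; every endpoint must have a degree entry.
#' @param ... unused.
#' @return a data frame with columns `endpoint_degree`, `mean_weight`,
#'   `n_edges`, sorted by `endpoint_degree`; attribute `edge_classes` holds
#'   the per-edge class assignment.
#' @examples
#' deg <- c(n1 = 1, n2 = 60, n3 = 20, n4 = 3)
#' ed <- data.frame(from = c("n1","n1","n1","n2","n2","n3"),
#'                  to   = c("n2","n3","n4","n3","n4","n4"),
#'                  weight = c(30, 35, 40, 50, 25, 100))
#' endpoint_degree_profile(deg, ed)
#' @export
endpoint_degree_profile <- function(x, ...) UseMethod("endpoint_degree_profile")

#' @rdname endpoint_degree_profile
#' @export
endpoint_degree_profile.default <- function(x, edges, ...) {
  stopifnot(is.numeric(x), !is.null(names(x)), is.data.frame(edges))
  need <- setdiff(unique(c(edges$from, edges$to)), names(x))
  if (length(need))
    stop("edge endpoint(s) lacking a degree entry: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!nrow(edges)) {
    out <- data.frame(endpoint_degree = numeric(0), mean_weight = numeric(0),
                      n_edges = integer(0))
    attr(out, "edge_classes") <- edges
    return(out)
  }
  prod_k <- unname(x[edges$from] * x[edges$to])
  mw <- tapply(edges$weight, prod_k, mean)
  cnt <- tapply(edges$weight, prod_k, length)
  out <- data.frame(endpoint_degree = as.numeric(names(mw)),
                    mean_weight = as.numeric(mw),
                    n_edges = as.integer(cnt))
  out <- out[order(out$endpoint_degree), , drop = FALSE]
  rownames(out) <- NULL
  classes <- edges
  classes$endpoint_degree <- prod_k
  attr(out, "edge_classes") <- classes
  out
}

#' @rdname endpoint_degree_profile
#' @export
endpoint_degree_profile.kcn_network <- function(x, ...) {
  endpoint_degree_profile(kcn_degree(x), x$edges)
}

#' Weighted nearest-neighbor degree
#'
#' `k^w_nn,i = (1/s_i) * sum_j w_ij k_j` over the neighbors j of i: the
#' weight-averaged degree of a node's neighbors. An increasing trend with
#' degree indicates assortative mixing. Isolated nodes get `NA`.
#'
#' @param network a `kcn_network`.
#' @return named numeric vector.
#' @export
weighted_nn_degree <- function(network) {
  stopifnot(inherits(network, "kcn_network"))
  k <- kcn_degree(network)
  s <- kcn_strength(network)
  out <- stats::setNames(rep(NA_real_, length(network$nodes)), network$nodes)
  if (nrow(network$edges)) {
    ends <- c(network$edges$from, network$edges$to)
    other <- c(network$edges$to, network$edges$from)
    wk <- rep(network$edges$weight, 2L) * k[other]
    agg <- tapply(wk, ends, sum)
    out[names(agg)] <- as.numeric(agg) / s[names(agg)]
  }
  out
}

#' Weighted clustering coefficient (geometric-mean form)
#'
#' `c_i = [1/(k_i(k_i-1))] * sum_{j,k in V_i} (w-hat_ij w-hat_ik w-hat_jk)^(1/3)` with
#' weights normalized by the single global maximum weight of the network.
#' Nodes of degree 0 or 1 get exactly 0. The per-degree profile averages
#' `c_i` over all nodes sharing a degree.
#'
#' @param network a `kcn_network`.
#' @return a list with `per_node` (named numeric vector in \[0,1\]) and
#'   `by_degree` (data frame `degree`, `mean_clustering`, `n_nodes`);
#'   attribute `max_weight` records the normalization constant.
#' @export
weighted_clustering <- function(network) {
  stopifnot(inherits(network, "kcn_network"))
  n <- length(network$nodes)
  k <- kcn_degree(network)
  ci <- stats::setNames(numeric(n), network$nodes)
  max_w <- if (nrow(network$edges)) max(network$edges$weight) else NA_real_
  if (nrow(network$edges)) {
    # cube-root-normalized weight matrix; diag(W3 %*% W3 %*% W3) yields
    # twice the triangle sum per node (ordered neighbor pairs)
    w3 <- adjacency_matrix(network, weighted = TRUE)
    w3 <- (w3 / max_w)^(1 / 3)
    tri <- diag(w3 %*% w3 %*% w3)
    denom <- k * (k - 1)
    pos <- denom > 0
    ci[pos] <- tri[pos] / denom[pos]
  }
  by_deg <- if (nrow(network$edges) && n > 0) {
    mc <- tapply(ci, k, mean)
    cnt <- tapply(ci, k, length)
    data.frame(degree = as.integer(names(mc)),
               mean_clustering = as.numeric(mc),
               n_nodes = as.integer(cnt))
  } else {
    data.frame(degree = integer(0), mean_clustering = numeric(0),
               n_nodes = integer(0))
  }
  rownames(by_deg) <- NULL
  out <- list(per_node = ci, by_degree = by_deg)
  attr(out, "max_weight") <- max_w
  out
}

#' All per-node KCN metrics in one table
#'
#' @param network a `kcn_network`.
#' @return data frame with columns `keyword`, `degree`, `strength`,
#'   `weighted_nn_degree`, `clustering`, one row per node.
#' @export
node_metrics <- function(network) {
  cl <- weighted_clustering(network)
  data.frame(
    keyword = network$nodes,
    degree = unname(kcn_degree(network)),
    strength = unname(kcn_strength(network)),
    weighted_nn_degree = unname(weighted_nn_degree(network)),
    clustering = unname(cl$per_node),
    stringsAsFactors = FALSE
  )
}

#' Top keywords ranked by strength
#'
#' @param network a `kcn_network`.
#' @param k number of keywords to report.
#' @return data frame `keyword`, `strength`, sorted by decreasing strength,
#'   ties broken lexicographically, truncated to `k` rows.
#' @export
top_keywords_by_strength <- function(network, k = 20L) {
  stopifnot(k >= 1L)
  s <- kcn_strength(network)
  out <- data.frame(keyword = names(s), strength = unname(s),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$strength, out$keyword), , drop = FALSE]
  out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

#' Top keyword pairs ranked by co-occurrence weight
#'
#' @param network a `kcn_network`.
#' @param k number of pairs to report.
#' @return data frame `from`, `to`, `weight`, sorted by decreasing weight,
#'   ties lexicographic on (from, to), truncated to `k` rows.
#' @export
top_pairs_by_weight <- function(network, k = 20L) {
  stopifnot(k >= 1L)
  ed <- network$edges
  ed <- ed[order(-ed$weight, ed$from, ed$to), , drop = FALSE]
  ed <- utils::head(ed, k)
  rownames(ed) <- NULL
  ed
}
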