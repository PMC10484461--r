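# Independent brute-force oracles: naive loops over matrices and exhaustive
# enumeration, deliberately written without reusing any package internals
# beyond the kcn_network edge-list layout.

# random weighted undirected graph in kcn_network layout
random_kcn <- function(n_nodes, p = 0.35, max_w = 9) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  cmb <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(cmb)) < p
  edges <- data.frame(from = cmb[1L, keep], to = cmb[2L, keep],
                      weight = sample.int(max_w, sum(keep), replace = TRUE),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, window = NULL,
                 n_articles = NA_integer_),
            class = "kcn_network")
}

oracle_matrix <- function(net) {
  n <- length(net$nodes)
  W <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  for (r in seq_len(nrow(net$edges))) {
    i <- net$edges$from[r]; j <- net$edges$to[r]
    W[i, j] <- net$edges$weight[r]
    W[j, i] <- net$edges$weight[r]
  }
  W
}

oracle_degree <- function(net) {
  W <- oracle_matrix(net)
  apply(W, 1L, function(row) sum(row > 0))
}

oracle_strength <- function(net) {
  rowSums(oracle_matrix(net))
}

oracle_knn <- function(net) {
  W <- oracle_matrix(net)
  k <- oracle_degree(net)
  out <- rep(NA_real_, length(net$nodes))
  names(out) <- net$nodes
  for (i in seq_along(net$nodes)) {
    nb <- which(W[i, ] > 0)
    if (!length(nb)) next
    out[i] <- sum(W[i, nb] * k[nb]) / sum(W[i, nb])
  }
  out
}

# geometric-mean weighted clustering, triple loop over ordered neighbor pairs
oracle_clustering <- function(net) {
  W <- oracle_matrix(net)
  n <- length(net$nodes)
  out <- stats::setNames(numeric(n), net$nodes)
  if (!nrow(net$edges)) return(out)
  What <- W / max(W)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2L) next
    acc <- 0
    for (j in nb) for (h in nb) {
      if (j != h) acc <- acc + (What[i, j] * What[i, h] * What[j, h])^(1 / 3)
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

# binary clustering: 2 * triangles / (k (k-1)), counted by brute force
oracle_binary_clustering <- function(net) {
  A <- oracle_matrix(net) > 0
  n <- length(net$nodes)
  out <- stats::setNames(numeric(n), net$nodes)
  for (i in seq_len(n)) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k < 2L) next
    tri <- 0L
    for (j in nb) for (h in nb) if (j < h && A[j, h]) tri <- tri + 1L
    out[i] <- 2 * tri / (k * (k - 1))
  }
  out
}

oracle_endpoint_profile <- function(degrees, edges) {
  prod_k <- degrees[edges$from] * degrees[edges$to]
  cls <- sort(unique(prod_k))
  data.frame(
    endpoint_degree = as.numeric(cls),
    mean_weight = vapply(cls, function(p) mean(edges$weight[prod_k == p]),
                         numeric(1)),
    n_edges = vapply(cls, function(p) sum(prod_k == p), integer(1))
  )
}

# --- Apriori oracles -------------------------------------------------------

random_transactions <- function(n_items = 8L, n_tx = 40L, lambda = 3) {
  items <- letters[seq_len(n_items)]
  tx <- lapply(seq_len(n_tx), function(i) {
    k <- min(n_items, 1L + stats::rpois(1L, lambda))
    sort(sample(items, k))
  })
  structure(list(transactions = tx, n = n_tx), class = "transaction_set")
}

oracle_count <- function(transactions, itemset) {
  sum(vapply(transactions, function(t) all(itemset %in% t), logical(1)))
}

# exhaustive enumeration of every itemset over the item universe, counted
# against a transaction/item membership matrix
oracle_itemsets <- function(tx, min_support_count) {
  items <- sort(unique(unlist(tx$transactions)))
  M <- vapply(items, function(it) {
    vapply(tx$transactions, function(t) it %in% t, logical(1))
  }, logical(tx$n))
  if (is.null(dim(M))) M <- matrix(M, nrow = tx$n)
  sets <- list(); counts <- integer(0)
  for (k in seq_along(items)) {
    cmb <- utils::combn(seq_along(items), k)
    for (cc in seq_len(ncol(cmb))) {
      idx <- cmb[, cc]
      cnt <- sum(rowSums(M[, idx, drop = FALSE]) == k)
      if (cnt >= min_support_count) {
        sets[[length(sets) + 1L]] <- items[idx]
        counts <- c(counts, cnt)
      }
    }
  }
  list(sets = sets, counts = counts)
}

# exhaustive rule enumeration from direct counting
oracle_rules <- function(tx, min_support_count, min_confidence) {
  or <- oracle_itemsets(tx, min_support_count)
  keys <- character(0); conf <- numeric(0); lift <- numeric(0)
  supp <- integer(0)
  for (r in seq_along(or$sets)) {
    s <- or$sets[[r]]
    m <- length(s)
    if (m < 2L) next
    for (mask in seq_len(2L^m - 2L)) {
      sel <- as.logical(bitwAnd(mask, 2L^(seq_len(m) - 1L)))
      a <- s[sel]; c_ <- s[!sel]
      cf <- or$counts[r] / oracle_count(tx$transactions, a)
      if (cf < min_confidence) next
      keys <- c(keys, paste(paste(a, collapse = ","), "=>",
                            paste(c_, collapse = ",")))
      conf <- c(conf, cf)
      supp <- c(supp, or$counts[r])
      lift <- c(lift, cf / (oracle_count(tx$transactions, c_) / tx$n))
    }
  }
  ord <- order(keys)
  data.frame(key = keys[ord], support_count = supp[ord],
             confidence = conf[ord], lift = lift[ord],
             stringsAsFactors = FALSE)
}

rule_keys <- function(rules) {
  vapply(seq_len(nrow(rules)), function(i) {
    paste(paste(rules$antecedent[[i]], collapse = ","), "=>",
          paste(rules$consequent[[i]], collapse = ","))
  }, character(1))
}

itemset_keys <- function(itemsets) {
  vapply(itemsets$items, function(s) paste(s, collapse = ","), character(1))
}

# tiny hand-rolled corpus builder for I/O and network tests
make_corpus <- function(keyword_fields, years = NULL, titles = NULL,
                        databases = "PubMed") {
  n <- length(keyword_fields)
  data.frame(
    article_id = sprintf("art%03d", seq_len(n)),
    database = rep_len(databases, n),
    year = if (is.null(years)) rep(2020L, n) else years,
    title = if (is.null(titles)) sprintf("Title number %03d", seq_len(n))
            else titles,
    keywords = keyword_fields,
    stringsAsFactors = FALSE
  )
}
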