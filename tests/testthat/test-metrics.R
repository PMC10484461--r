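triangle_net <- function(weights = c(1, 1, 1)) {
  structure(list(
    nodes = c("a", "b", "c"),
    edges = data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                       weight = weights, stringsAsFactors = FALSE),
    window = NULL, n_articles = NA_integer_), class = "kcn_network")
}

star_net <- function(leaves = 4L) {
  lv <- paste0("leaf", seq_len(leaves))
  structure(list(
    nodes = c("hub", lv),
    edges = data.frame(from = "hub", to = lv, weight = 1,
                       stringsAsFactors = FALSE),
    window = NULL, n_articles = NA_integer_), class = "kcn_network")
}

test_that("degree and strength on canonical small graphs", {
  tri <- triangle_net()
  expect_equal(unname(kcn_degree(tri)), c(2L, 2L, 2L))
  st <- star_net(4L)
  expect_equal(unname(kcn_degree(st)["hub"]), 4L)
  expect_equal(unname(kcn_degree(st)["leaf1"]), 1L)

  net <- triangle_net(c(3, 5, 2))
  expect_equal(unname(kcn_strength(net)["a"]), 8)
  # unit weights: strength equals degree
  expect_equal(kcn_strength(tri), setNames(as.numeric(kcn_degree(tri)),
                                           names(kcn_degree(tri))))
})

test_that("endpoint-degree profile groups by exact product with external degrees", {
  deg <- c(n1 = 1, n2 = 60, n3 = 20, n4 = 3)
  ed <- data.frame(from = c("n1", "n1", "n1", "n2", "n2", "n3"),
                   to = c("n2", "n3", "n4", "n3", "n4", "n4"),
                   weight = c(30, 35, 40, 50, 25, 100))
  prof <- endpoint_degree_profile(deg, ed)
  cls <- attr(prof, "edge_classes")
  expect_equal(sort(cls$endpoint_degree), sort(c(60, 20, 3, 1200, 180, 60)))
  expect_equal(prof$mean_weight[prof$endpoint_degree == 60], 65)
  expect_equal(prof$n_edges[prof$endpoint_degree == 60], 2L)
  # all weights equal -> every class mean is that weight
  ed2 <- ed; ed2$weight <- 7
  prof2 <- endpoint_degree_profile(deg, ed2)
  expect_true(all(prof2$mean_weight == 7))
  # unknown endpoint is an input error
  expect_error(endpoint_degree_profile(deg[1:3], ed), "n4")
})

test_that("endpoint-degree profile sums reconstruct the totals", {
  set.seed(21)
  for (rep in 1:10) {
    net <- random_kcn(sample(5:25, 1))
    prof <- endpoint_degree_profile(net)
    expect_equal(sum(prof$n_edges), nrow(net$edges))
    expect_equal(sum(prof$mean_weight * prof$n_edges), sum(net$edges$weight))
    ora <- oracle_endpoint_profile(oracle_degree(net), net$edges)
    expect_equal(prof$endpoint_degree, ora$endpoint_degree)
    expect_equal(prof$mean_weight, ora$mean_weight, tolerance = 1e-12)
  }
})

test_that("weighted nearest-neighbor degree matches hand and oracle values", {
  st <- star_net(5L)
  knn <- weighted_nn_degree(st)
  expect_equal(unname(knn["hub"]), 1)
  expect_equal(unname(knn["leaf1"]), 5)

  # node a: neighbors b (k=2, w=1) and c (k=4, w=3) -> (2 + 12) / 4 = 3.5
  net <- structure(list(
    nodes = c("a", "b", "c", "d", "e"),
    edges = data.frame(
      from = c("a", "a", "b", "c", "c"),
      to = c("b", "c", "c", "d", "e"),
      weight = c(1, 3, 1, 1, 1), stringsAsFactors = FALSE),
    window = NULL, n_articles = NA_integer_), class = "kcn_network")
  expect_equal(unname(weighted_nn_degree(net)["a"]), 3.5)

  set.seed(33)
  for (rep in 1:10) {
    rnet <- random_kcn(sample(5:25, 1))
    expect_equal(weighted_nn_degree(rnet), oracle_knn(rnet),
                 tolerance = 1e-12)
  }
})

test_that("knn values lie between min and max neighbor degree", {
  set.seed(44)
  for (rep in 1:5) {
    net <- random_kcn(sample(8:25, 1))
    k <- kcn_degree(net)
    knn <- weighted_nn_degree(net)
    W <- oracle_matrix(net)
    for (i in names(knn)) {
      if (is.na(knn[i])) next
      nb <- names(which(W[i, ] > 0))
      expect_gte(knn[[i]], min(k[nb]) - 1e-12)
      expect_lte(knn[[i]], max(k[nb]) + 1e-12)
    }
  }
})

test_that("weighted clustering: complete graphs, paths, and the 1-2-4 triangle", {
  tri <- triangle_net()
  expect_equal(unname(weighted_clustering(tri)$per_node), rep(1, 3))

  path3 <- structure(list(
    nodes = c("a", "b", "c"),
    edges = data.frame(from = c("a", "b"), to = c("b", "c"), weight = c(1, 1),
                       stringsAsFactors = FALSE),
    window = NULL, n_articles = NA_integer_), class = "kcn_network")
  expect_equal(unname(weighted_clustering(path3)$per_node), rep(0, 3))

  wtri <- triangle_net(c(1, 2, 4))
  expect_equal(unname(weighted_clustering(wtri)$per_node),
               rep((0.25 * 0.5 * 1)^(1 / 3), 3), tolerance = 1e-12)

  # edgeless network: all zero, empty profile, no division attempted
  iso <- structure(list(nodes = c("a", "b"),
                        edges = data.frame(from = character(0),
                                           to = character(0),
                                           weight = numeric(0)),
                        window = NULL, n_articles = NA_integer_),
                   class = "kcn_network")
  wc <- weighted_clustering(iso)
  expect_equal(unname(wc$per_node), c(0, 0))
  expect_equal(nrow(wc$by_degree), 0L)
})

test_that("unit-weight clustering equals the binary coefficient (brute force)", {
  set.seed(55)
  for (rep in 1:10) {
    net <- random_kcn(sample(5:30, 1))
    net$edges$weight <- rep(1, nrow(net$edges))
    got <- weighted_clustering(net)$per_node
    expect_equal(got, oracle_binary_clustering(net), tolerance = 1e-12)
  }
})

test_that("per-degree clustering profile averages nodes sharing a degree", {
  set.seed(66)
  net <- random_kcn(15)
  wc <- weighted_clustering(net)
  k <- kcn_degree(net)
  for (r in seq_len(nrow(wc$by_degree))) {
    d <- wc$by_degree$degree[r]
    expect_equal(wc$by_degree$mean_clustering[r],
                 mean(wc$per_node[k == d]), tolerance = 1e-12)
  }
  expect_true(all(wc$per_node >= 0 & wc$per_node <= 1))
})

test_that("strength and weight rankings use descending order with lexicographic ties", {
  net <- structure(list(
    nodes = c("a", "b", "c"),
    edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                       weight = c(5, 4), stringsAsFactors = FALSE),
    window = NULL, n_articles = NA_integer_), class = "kcn_network")
  expect_equal(top_keywords_by_strength(net, 1)$keyword, "b")

  tie <- triangle_net(c(2, 2, 2))
  tk <- top_keywords_by_strength(tie, 3)
  expect_equal(tk$keyword, c("a", "b", "c"))
  tp <- top_pairs_by_weight(tie, 2)
  expect_equal(tp$from, c("a", "a"))
  expect_equal(tp$to, c("b", "c"))

  pq <- structure(list(
    nodes = c("p", "q", "r"),
    edges = data.frame(from = c("p", "p"), to = c("q", "r"),
                       weight = c(3, 1), stringsAsFactors = FALSE),
    window = NULL, n_articles = NA_integer_), class = "kcn_network")
  expect_equal(top_pairs_by_weight(pq, 1)$to, "q")
})

test_that("node_metrics table is internally consistent", {
  set.seed(77)
  net <- random_kcn(12)
  nm <- node_metrics(net)
  expect_equal(nm$degree, unname(kcn_degree(net)))
  expect_equal(nm$strength, unname(kcn_strength(net)))
  expect_true(all(nm$strength >= nm$degree))
  zero <- nm$degree == 0
  expect_true(all(nm$strength[zero] == 0))
  expect_true(all(is.na(nm$weighted_nn_degree[zero])))
  expect_true(all(nm$clustering[zero] == 0))
})
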