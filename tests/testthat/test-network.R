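test_that("document frequency uses set semantics per article", {
  corp <- make_corpus(c("chronic pain", "chronic pains", "opioid; opioids"))
  f <- document_frequency(corp)
  expect_equal(f$count[f$keyword == "chronic pain"], 2L)
  expect_equal(f$count[f$keyword == "opioid"], 1L)
  expect_equal(nrow(document_frequency(make_corpus(character(0)))), 0L)
})

test_that("build_network counts each unordered pair once per article", {
  corp <- make_corpus(c("p; q", "p; r"))
  net <- build_network(corp)
  expect_equal(nrow(net$edges), 0L)  # one- and two-letter tokens drop

  corp <- make_corpus(c("pain; quality", "pain; rehab"))
  net <- build_network(corp)
  w <- setNames(net$edges$weight, paste(net$edges$from, net$edges$to))
  expect_equal(unname(w["pain qualiti"]), 1L)
  expect_equal(unname(w["pain rehab"]), 1L)
  expect_false("qualiti rehab" %in% names(w))

  corp3 <- make_corpus(rep("pain; opioid", 3L))
  expect_equal(build_network(corp3)$edges$weight, 3L)

  # article with k keywords yields all pairs; single-keyword article is isolated
  corp4 <- make_corpus(c("alpha; beta; gamma", "delta"))
  net4 <- build_network(corp4)
  expect_equal(nrow(net4$edges), 3L)
  expect_true("delta" %in% net4$nodes)
  expect_equal(unname(kcn_degree(net4)["delta"]), 0L)
})

test_that("pair enumeration matches brute force on random articles", {
  set.seed(101)
  # all normalization fixed points, so raw keys match canonical node names
  vocab <- c("pain", "opioid", "analgesia", "rehab", "morphin", "cancer",
             "anxieti", "sleep")
  fields <- vapply(seq_len(30), function(i) {
    paste(sample(vocab, sample(2:8, 1)), collapse = "; ")
  }, character(1))
  corp <- make_corpus(fields)
  net <- build_network(corp)
  # oracle: count pairs by direct enumeration
  counts <- new.env()
  for (f in fields) {
    s <- sort(unique(trimws(strsplit(f, ";")[[1]])))
    if (length(s) < 2) next
    cmb <- utils::combn(s, 2)
    for (cc in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, cc], cmb[2, cc], sep = "|")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  got <- setNames(net$edges$weight, paste(net$edges$from, net$edges$to,
                                          sep = "|"))
  expect_equal(length(got), length(ls(counts)))
  for (key in ls(counts)) expect_equal(unname(got[key]), counts[[key]])
})

test_that("network construction is order-invariant and additive over corpora", {
  set.seed(7)
  corp <- make_corpus(c("pain; opioid", "pain; opioid; cancer",
                        "cancer; sleep", "pain"))
  net1 <- build_network(corp)
  net2 <- build_network(corp[sample(nrow(corp)), ])
  expect_equal(net1$edges, net2$edges)
  expect_equal(net1$nodes, net2$nodes)

  corpA <- corp[1:2, ]
  corpB <- corp[3:4, ]
  corpB$article_id <- paste0("b", corpB$article_id)
  netA <- build_network(corpA)
  netB <- build_network(corpB)
  merged <- build_network(rbind(corpA, corpB))
  wm <- setNames(merged$edges$weight, paste(merged$edges$from, merged$edges$to))
  wa <- setNames(netA$edges$weight, paste(netA$edges$from, netA$edges$to))
  wb <- setNames(netB$edges$weight, paste(netB$edges$from, netB$edges$to))
  for (key in names(wm)) {
    expect_equal(unname(wm[key]),
                 sum(wa[key], wb[key], na.rm = TRUE))
  }
})

test_that("degree and strength sums balance the link and weight totals", {
  set.seed(5)
  for (rep in 1:5) {
    net <- random_kcn(sample(5:20, 1))
    expect_equal(sum(kcn_degree(net)), 2L * nrow(net$edges))
    expect_equal(sum(kcn_strength(net)), 2 * sum(net$edges$weight))
  }
})

test_that("network summary covers the triangle and degenerate cases", {
  corp <- make_corpus("alpha; beta; gamma")
  s <- network_summary(build_network(corp))
  expect_equal(s$n_nodes, 3L)
  expect_equal(s$n_links, 3L)
  expect_equal(s$avg_degree, 2)
  expect_equal(s$avg_weight, 1)

  iso <- build_network(make_corpus(c("alpha", "beta")))
  s2 <- network_summary(iso)
  expect_equal(s2$n_nodes, 2L)
  expect_equal(s2$n_links, 0L)
  expect_true(is.na(s2$avg_weight))
})

test_that("edge lists and adjacency matrices are consistent exports", {
  net <- build_network(make_corpus(c("pain; opioid", "pain; cancer")))
  M <- adjacency_matrix(net)
  expect_true(isSymmetric(M))
  expect_equal(unname(diag(M)), rep(0, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(names(back), c("source", "target", "weight"))
})
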