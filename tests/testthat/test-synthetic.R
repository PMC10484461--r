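small_profile <- function(seed = 5L, duplicate_rate = 0.1) {
  synthetic_config(
    windows = data.frame(start_year = c(2002L, 2017L),
                         end_year = c(2006L, 2021L),
                         n_articles = c(60L, 100L),
                         vocab_size = c(30L, 60L)),
    planted_pairs = data.frame(keyword1 = "opioid", keyword2 = "analgesia",
                               count = 9L, window = 2L),
    planted_frequencies = data.frame(
      keyword = c("biomark", "electromyographi"),
      window = c(2L, 1L), count = c(12L, 8L)),
    planted_rules = list(list(antecedent = "bladder pain syndrom",
                              consequent = "cystiti",
                              support_count = 6L, confidence = 0.75)),
    duplicate_rate = duplicate_rate,
    seed = seed
  )
}

test_that("generation is deterministic given the seed", {
  g1 <- generate_corpus(small_profile(seed = 17L))
  g2 <- generate_corpus(small_profile(seed = 17L))
  expect_identical(g1$corpus, g2$corpus)
  expect_identical(g1$ground_truth$doc_freq, g2$ground_truth$doc_freq)
  g3 <- generate_corpus(small_profile(seed = 18L))
  expect_false(identical(g1$corpus$keywords, g3$corpus$keywords))
})

test_that("config validation rejects unsatisfiable or non-canonical plantings", {
  expect_error(synthetic_config(
    windows = data.frame(start_year = 2002L, end_year = 2006L,
                         n_articles = 10L, vocab_size = 10L),
    planted_rules = list(list(antecedent = "alpha", consequent = "beta",
                              support_count = 10L, confidence = 0.3))),
    "whole number")
  expect_error(synthetic_config(
    windows = data.frame(start_year = 2002L, end_year = 2006L,
                         n_articles = 10L, vocab_size = 10L),
    planted_pairs = data.frame(keyword1 = "Opioids", keyword2 = "pain",
                               count = 2L, window = 1L)),
    "fixed point")
  expect_error(synthetic_config(
    windows = data.frame(start_year = 2002L, end_year = 2006L,
                         n_articles = 10L, vocab_size = 10L),
    zipf_exponent = -1), "zipf")
})

test_that("injected duplicates are exactly what deduplication removes", {
  gen <- generate_corpus(small_profile(seed = 23L))
  dd <- deduplicate(gen$corpus)
  expect_equal(dd$removed_count, nrow(gen$ground_truth$duplicates))
  expect_setequal(dd$removed_ids, gen$ground_truth$duplicates$duplicate_id)
  # survivors are the originals (first occurrence wins)
  expect_true(all(gen$ground_truth$duplicates$original_id %in%
                  dd$corpus$article_id))
})

test_that("pipeline recovers planted document frequencies exactly", {
  gen <- generate_corpus(small_profile(seed = 31L))
  corpus <- deduplicate(gen$corpus)$corpus
  gt <- gen$ground_truth$doc_freq
  for (w in 1:2) {
    win <- time_window(c(2002, 2017)[w], c(2006, 2021)[w])
    f <- document_frequency(corpus, win)
    truth <- gt[gt$window == w, ]
    got <- setNames(f$count, f$keyword)
    expect_equal(length(got), nrow(truth))
    expect_equal(unname(got[truth$keyword]), truth$count)
  }
})

test_that("pipeline recovers the planted pair weight and rule measures", {
  gen <- generate_corpus(small_profile(seed = 41L))
  corpus <- deduplicate(gen$corpus)$corpus
  net <- build_network(corpus, time_window(2017, 2021))
  ed <- net$edges
  w <- ed$weight[(ed$from == "analgesia" & ed$to == "opioid") |
                 (ed$from == "opioid" & ed$to == "analgesia")]
  expect_equal(w, 9L)

  tx <- build_transactions(corpus)
  rules <- derive_rules(apriori_frequent_itemsets(tx, 5L), tx, 0.5)
  keys <- rule_keys(rules)
  i <- which(keys == "bladder pain syndrom => cystiti")
  expect_length(i, 1L)
  truth <- gen$ground_truth$rules[[1]]
  expect_equal(rules$support_count[i], truth$support_count)
  expect_equal(rules$confidence[i], truth$confidence, tolerance = 1e-12)
  expect_equal(rules$lift[i], truth$lift, tolerance = 1e-12)
})

test_that("surface variants all normalize back to their canonical keyword", {
  cfg <- small_profile()
  for (kw in names(cfg$surface_forms)) {
    expect_equal(unique(normalize_keyword(cfg$surface_forms[[kw]])), kw)
  }
  # raw fields in a generated corpus normalize onto ground-truth keywords
  gen <- generate_corpus(small_profile(seed = 3L, duplicate_rate = 0))
  f <- document_frequency(gen$corpus, time_window(2002, 2021))
  truth <- stats::aggregate(count ~ keyword, gen$ground_truth$doc_freq, sum)
  expect_setequal(f$keyword, truth$keyword)
})

test_that("a dominating planted pair ranks first; the root hub leads by strength", {
  # pair heavier than any possible background co-occurrence (count > articles)
  cfg <- synthetic_config(
    windows = data.frame(start_year = 2002L, end_year = 2006L,
                         n_articles = 50L, vocab_size = 30L),
    planted_pairs = data.frame(keyword1 = "opioid", keyword2 = "analgesia",
                               count = 60L, window = 1L),
    root_fraction = 0, duplicate_rate = 0, seed = 77L)
  net <- build_network(generate_corpus(cfg)$corpus)
  tp <- top_pairs_by_weight(net, 1L)
  expect_equal(sort(c(tp$from, tp$to)), c("analgesia", "opioid"))
  expect_equal(tp$weight, 60L)

  # the ever-present root keyword is the strength hub
  cfg2 <- small_profile(seed = 19L)
  net2 <- build_network(deduplicate(generate_corpus(cfg2)$corpus)$corpus)
  expect_equal(top_keywords_by_strength(net2, 1L)$keyword, "pain")
})

test_that("background document frequencies recover the Zipf exponent", {
  cfg <- synthetic_config(
    windows = data.frame(start_year = 2002L, end_year = 2006L,
                         n_articles = 2500L, vocab_size = 1000L),
    zipf_exponent = 1.0,
    keywords_per_article = c(4L, 8L),
    duplicate_rate = 0, variant_rate = 0,
    seed = 61L
  )
  gen <- generate_corpus(cfg)
  f <- document_frequency(gen$corpus, time_window(2002, 2006))
  bg <- f[grepl("^kw[0-9]+$", f$keyword), ]
  expect_gt(sum(bg$count), 1e4)
  est <- estimate_zipf_exponent(bg$count)
  expect_lt(abs(est - 1.0), 0.2)
})
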