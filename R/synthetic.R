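# Seeded synthetic-corpus generator. Emulates the statistical structure the
# KCN analysis assumes: four growing time windows, heavy-tailed (Zipf-like)
# background keyword frequencies, an ever-present root keyword, surface
# variants that the normalizer must collapse, cross-database duplicate
# titles, and constructively planted co-occurrence pairs, document-frequency
# ladders and association rules whose exact counts are recorded as
# machine-readable ground truth. Planted structure is injected
# deterministically so recovery tests are exact; only the background is
# stochastic under the seed.

# natural surface forms (first entry = primary) for the real-word keywords
# the default profile plants; every form must normalize to its list name
.default_surface_forms <- function() {
  list(
    "pain" = c("pain", "Pain", "pains", "painful", "PAIN"),
    "chronic pain" = c("chronic pain", "Chronic Pain", "chronic pains"),
    "postop pain" = c("postoperative pain", "Postoperative Pain",
                      "postop pain"),
    "opioid" = c("opioid", "opioids", "Opioid", "opioides"),
    "analgesia" = c("analgesia", "Analgesia"),
    "machin learn" = c("machine learning", "Machine Learning",
                       "machine-learning"),
    "biomark" = c("biomarker", "biomarkers", "Biomarker"),
    "electromyographi" = c("electromyography", "Electromyography"),
    "microdialysi" = c("microdialysis", "Microdialysis"),
    "magnetoencephalographi" = c("magnetoencephalography",
                                 "Magnetoencephalography"),
    "pain assess" = c("pain assessment", "Pain Assessment",
                      "pain assessments"),
    "bladder pain syndrom" = c("bladder pain syndrome",
                               "Bladder Pain Syndrome"),
    "cystiti" = c("cystitis", "Cystitis"),
    "acut coronari syndrom" = c("acute coronary syndrome",
                                "Acute Coronary Syndrome"),
    "chest pain" = c("chest pain", "Chest Pain", "chest pains")
  )
}

#' Configuration of the synthetic-corpus generator
#'
#' @param windows data frame with columns `start_year`, `end_year`,
#'   `n_articles` (background articles per window) and `vocab_size`
#'   (background vocabulary available in the window; vocabularies are
#'   nested, so earlier keywords persist).
#' @param zipf_exponent positive exponent of the rank-frequency law the
#'   background keywords are drawn from.
#' @param keywords_per_article integer range `c(min, max)` of background
#'   keyword draws per article (draws are with replacement, the article
#'   keeps the distinct ones).
#' @param root_keyword canonical keyword present in (a fraction of) every
#'   article -- the "pain" analogue of a topical corpus.
#' @param root_fraction fraction of articles (background and planted)
#'   carrying the root keyword (default 1: every article matched the root
#'   query).
#' @param planted_pairs data frame `keyword1`, `keyword2`, `count`,
#'   `window` (window index): `count` dedicated articles containing exactly
#'   the pair (plus the root) are injected into that window.
#' @param planted_frequencies data frame `keyword`, `window`, `count`:
#'   `count` dedicated articles containing the keyword (plus the root) are
#'   injected, fixing the keyword's document frequency.
#' @param planted_rules list of lists with elements `antecedent` (character
#'   vector), `consequent` (single keyword), `support_count`, `confidence`;
#'   `support_count / confidence` must be a whole number (the antecedent
#'   count). Rule articles are spread over all windows.
#' @param variant_rate probability that a keyword is emitted as a surface
#'   variant (case change, plural, hyphenation) instead of its primary form.
#' @param duplicate_rate fraction of articles re-emitted under a second
#'   database label with an identical title.
#' @param databases source labels to draw from.
#' @param surface_forms named list canonical keyword -> character vector of
#'   surface forms (first = primary); all must normalize back to the name.
#' @param seed integer RNG seed; generation is deterministic given the
#'   configuration.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(windows,
                             zipf_exponent = 1.0,
                             keywords_per_article = c(2L, 7L),
                             root_keyword = "pain",
                             root_fraction = 1.0,
                             planted_pairs = NULL,
                             planted_frequencies = NULL,
                             planted_rules = list(),
                             variant_rate = 0.3,
                             duplicate_rate = 0.1,
                             databases = c("PubMed", "WebOfScience",
                                           "IEEE", "EngineeringVillage"),
                             surface_forms = .default_surface_forms(),
                             seed = 42L) {
  stopifnot(is.data.frame(windows),
            all(c("start_year", "end_year", "n_articles", "vocab_size")
                %in% names(windows)))
  if (any(windows$start_year > windows$end_year))
    stop("window start_year must be <= end_year", call. = FALSE)
  if (zipf_exponent <= 0) stop("zipf_exponent must be positive", call. = FALSE)
  stopifnot(length(keywords_per_article) == 2L,
            keywords_per_article[1] >= 1L,
            keywords_per_article[1] <= keywords_per_article[2])
  if (root_fraction < 0 || root_fraction > 1)
    stop("root_fraction must be in [0, 1]", call. = FALSE)
  if (variant_rate < 0 || variant_rate > 1)
    stop("variant_rate must be in [0, 1]", call. = FALSE)
  if (duplicate_rate < 0 || duplicate_rate > 1)
    stop("duplicate_rate must be in [0, 1]", call. = FALSE)
  if (length(databases) < 2L)
    stop("need at least two database labels for duplicate injection",
         call. = FALSE)

  if (is.null(planted_pairs))
    planted_pairs <- data.frame(keyword1 = character(0),
                                keyword2 = character(0),
                                count = integer(0), window = integer(0))
  if (is.null(planted_frequencies))
    planted_frequencies <- data.frame(keyword = character(0),
                                      window = integer(0), count = integer(0))

  planted_kw <- unique(c(
    planted_pairs$keyword1, planted_pairs$keyword2,
    planted_frequencies$keyword,
    unlist(lapply(planted_rules, function(r) c(r$antecedent, r$consequent)))
  ))

  # every planted keyword and the root must be a fixed point of
  # normalization, and must not collide with the background vocabulary
  for (kw in c(root_keyword, planted_kw)) {
    if (normalize_keyword(kw) != kw)
      stop("planted keyword is not a fixed point of normalization: ",
           kw, call. = FALSE)
    if (grepl("^kw[0-9]+$", kw))
      stop("planted keyword collides with background vocabulary: ",
           kw, call. = FALSE)
  }
  # surface variants must round-trip through the normalizer
  for (kw in names(surface_forms)) {
    got <- normalize_keyword(surface_forms[[kw]])
    if (any(got != kw))
      stop("surface form '", surface_forms[[kw]][got != kw][1L],
           "' does not normalize to '", kw, "'", call. = FALSE)
  }
  if (any(planted_pairs$window < 1L |
          planted_pairs$window > nrow(windows)) ||
      any(planted_frequencies$window < 1L |
          planted_frequencies$window > nrow(windows)))
    stop("planted window index out of range", call. = FALSE)
  if (any(planted_pairs$count < 1L) || any(planted_frequencies$count < 1L))
    stop("planted counts must be >= 1", call. = FALSE)
  for (r in planted_rules) {
    stopifnot(length(r$consequent) == 1L, length(r$antecedent) >= 1L,
              r$support_count >= 1L, r$confidence > 0, r$confidence <= 1)
    n_ante <- r$support_count / r$confidence
    if (abs(n_ante - round(n_ante)) > 1e-9)
      stop("support_count / confidence must be a whole number for rule -> ",
           r$consequent, call. = FALSE)
  }

  structure(
    list(windows = windows, zipf_exponent = zipf_exponent,
         keywords_per_article = as.integer(keywords_per_article),
         root_keyword = root_keyword, root_fraction = root_fraction,
         planted_pairs = planted_pairs,
         planted_frequencies = planted_frequencies,
         planted_rules = planted_rules,
         variant_rate = variant_rate, duplicate_rate = duplicate_rate,
         databases = databases, surface_forms = surface_forms,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Default desk-scale corpus profile
#'
#' Four windows 2002--2006 ... 2017--2021 with background article counts
#' 500/720/1025/1445 (growth ratio about 1:1.44:2.05:2.89, i.e. near
#' threefold over the study period) and background vocabularies
#' 120/216/504/900 (about 1:1.8:4.2:7.5, a sevenfold vocabulary growth).
#' The root keyword "pain" appears in every article. Plants two heavy
#' co-occurrence pairs in the last window, a six-keyword sensors/methods
#' frequency ladder across the first and last windows (three emerging,
#' three declining), and two association rules with known support and
#' confidence.
#'
#' @param seed RNG seed passed through to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
default_corpus_profile <- function(seed = 42L) {
  windows <- data.frame(
    start_year = c(2002L, 2007L, 2012L, 2017L),
    end_year = c(2006L, 2011L, 2016L, 2021L),
    n_articles = c(500L, 720L, 1025L, 1445L),
    vocab_size = c(120L, 216L, 504L, 900L)
  )
  planted_pairs <- data.frame(
    keyword1 = c("opioid", "chronic pain"),
    keyword2 = c("analgesia", "postop pain"),
    count = c(37L, 25L),
    window = c(4L, 4L)
  )
  planted_frequencies <- data.frame(
    keyword = c("machin learn", "biomark", "pain assess",
                "electromyographi", "microdialysi", "magnetoencephalographi",
                "machin learn", "biomark", "pain assess",
                "electromyographi", "microdialysi", "magnetoencephalographi"),
    window = c(rep(4L, 6L), rep(1L, 6L)),
    count = c(60L, 55L, 40L, 18L, 4L, 3L,
              1L, 1L, 12L, 45L, 30L, 25L)
  )
  planted_rules <- list(
    list(antecedent = "bladder pain syndrom", consequent = "cystiti",
         support_count = 40L, confidence = 0.8),
    list(antecedent = "acut coronari syndrom", consequent = "chest pain",
         support_count = 30L, confidence = 0.6)
  )
  synthetic_config(windows = windows,
                   planted_pairs = planted_pairs,
                   planted_frequencies = planted_frequencies,
                   planted_rules = planted_rules,
                   seed = seed)
}

# render one canonical keyword as a raw surface string
.render_keyword <- function(kw, config, use_variant) {
  forms <- config$surface_forms[[kw]]
  if (is.null(forms)) {
    # background/opaque keyword: only a case variant is invertible
    if (use_variant) toupper(kw) else kw
  } else if (use_variant && length(forms) > 1L) {
    sample(forms[-1L], 1L)
  } else {
    forms[1L]
  }
}

#' Generate a synthetic article corpus with ground truth
#'
#' Deterministic given `config` (including its seed). Background articles
#' draw keywords from a Zipf-like rank-frequency law over the window
#' vocabulary; planted pairs, frequency ladders and rules are injected as
#' dedicated articles at exactly their target counts; a fraction of
#' articles is re-emitted under another database label with the same title;
#' keywords are rendered as surface variants at the configured rate.
#'
#' @param config a `synthetic_config`.
#' @return a list with `corpus` (a corpus data frame ready for
#'   [read_corpus()]-style processing) and `ground_truth`, a list holding
#'   `doc_freq` (per-window tallied document frequencies of every canonical
#'   keyword), `pair_counts` (planted pairs with their exact co-occurrence
#'   counts), `rules` (planted rules with support, antecedent count,
#'   confidence and the implied lift over the full pooled corpus),
#'   `duplicates` (data frame `original_id`, `duplicate_id`),
#'   `n_articles_per_window` (pre-duplication), and `variant_map`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nw <- nrow(config$windows)
  vmax <- max(config$windows$vocab_size)
  background_vocab <- sprintf("kw%04d", seq_len(vmax))

  sets <- list()     # canonical keyword sets
  win_of <- integer(0)

  # background articles
  for (w in seq_len(nw)) {
    vs <- config$windows$vocab_size[w]
    n_art <- config$windows$n_articles[w]
    probs <- seq_len(vs)^(-config$zipf_exponent)
    probs <- probs / sum(probs)
    kmin <- config$keywords_per_article[1]
    kmax <- config$keywords_per_article[2]
    for (a in seq_len(n_art)) {
      k <- sample(kmin:kmax, 1L)
      draw <- sample.int(vs, k, replace = TRUE, prob = probs)
      s <- background_vocab[sort(unique(draw))]
      if (stats::runif(1) <= config$root_fraction)
        s <- c(config$root_keyword, s)
      sets[[length(sets) + 1L]] <- sort(s)
      win_of <- c(win_of, w)
    }
  }

  with_root <- function(s) {
    if (stats::runif(1) <= config$root_fraction)
      c(config$root_keyword, s) else s
  }

  # planted co-occurrence pairs: dedicated articles {[root], k1, k2}
  pp <- config$planted_pairs
  for (r in seq_len(nrow(pp))) {
    for (i in seq_len(pp$count[r])) {
      sets[[length(sets) + 1L]] <-
        sort(with_root(c(pp$keyword1[r], pp$keyword2[r])))
      win_of <- c(win_of, pp$window[r])
    }
  }

  # planted document frequencies: dedicated articles {root, kw}
  pf <- config$planted_frequencies
  for (r in seq_len(nrow(pf))) {
    for (i in seq_len(pf$count[r])) {
      sets[[length(sets) + 1L]] <- sort(with_root(pf$keyword[r]))
      win_of <- c(win_of, pf$window[r])
    }
  }

  # planted rules: support articles carry antecedent + consequent, the rest
  # of the antecedent count carries the antecedent alone; spread round-robin
  # over all windows (rules are mined on the pooled corpus)
  for (r in config$planted_rules) {
    n_ante <- as.integer(round(r$support_count / r$confidence))
    wins <- rep(seq_len(nw), length.out = n_ante)
    for (i in seq_len(n_ante)) {
      s <- r$antecedent
      if (i <= r$support_count) s <- c(s, r$consequent)
      sets[[length(sets) + 1L]] <- sort(with_root(s))
      win_of <- c(win_of, wins[i])
    }
  }

  n_base <- length(sets)
  ord <- sample.int(n_base)
  sets <- sets[ord]
  win_of <- win_of[ord]

  years <- integer(n_base)
  for (w in seq_len(nw)) {
    idx <- which(win_of == w)
    years[idx] <- sample(config$windows$start_year[w]:config$windows$end_year[w],
                         length(idx), replace = TRUE)
  }

  delims <- c("; ", " / ", ": ")
  render_field <- function(s) {
    raw <- vapply(s, function(kw) {
      .render_keyword(kw, config, stats::runif(1) < config$variant_rate)
    }, character(1))
    paste(raw, collapse = sample(delims, 1L, prob = c(0.8, 0.1, 0.1)))
  }

  corpus <- data.frame(
    article_id = sprintf("A%05d", seq_len(n_base)),
    database = sample(config$databases, n_base, replace = TRUE),
    year = years,
    title = sprintf("Synthetic article %05d: %s", seq_len(n_base),
                    vapply(sets, `[[`, character(1), 1L)),
    keywords = vapply(sets, render_field, character(1)),
    stringsAsFactors = FALSE
  )

  # cross-database duplicates: same title, other database label, fresh id
  n_dup <- floor(config$duplicate_rate * n_base)
  dup_df <- data.frame(original_id = character(0), duplicate_id = character(0))
  if (n_dup >= 1L) {
    pick <- sort(sample.int(n_base, n_dup))
    dups <- corpus[pick, , drop = FALSE]
    dups$article_id <- sprintf("D%05d", seq_len(n_dup))
    dups$database <- vapply(dups$database, function(db) {
      sample(setdiff(config$databases, db), 1L)
    }, character(1))
    dup_df <- data.frame(original_id = corpus$article_id[pick],
                         duplicate_id = dups$article_id,
                         stringsAsFactors = FALSE)
    corpus <- rbind(corpus, dups)
    rownames(corpus) <- NULL
  }

  # ground truth tallied directly from the constructed canonical sets
  doc_freq <- do.call(rbind, lapply(seq_len(nw), function(w) {
    kws <- unlist(sets[win_of == w], use.names = FALSE)
    if (is.null(kws) || !length(kws))
      return(data.frame(window = integer(0), keyword = character(0),
                        count = integer(0)))
    tab <- table(kws)
    data.frame(window = w, keyword = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  }))
  rownames(doc_freq) <- NULL

  pair_counts <- config$planted_pairs
  rules_truth <- lapply(config$planted_rules, function(r) {
    n_ante <- as.integer(round(r$support_count / r$confidence))
    list(antecedent = r$antecedent, consequent = r$consequent,
         support_count = as.integer(r$support_count),
         antecedent_count = n_ante,
         confidence = r$support_count / n_ante,
         lift = (r$support_count / n_ante) / (r$support_count / n_base))
  })

  ground_truth <- list(
    doc_freq = doc_freq,
    pair_counts = pair_counts,
    rules = rules_truth,
    duplicates = dup_df,
    n_articles_per_window = as.integer(table(factor(win_of,
                                                    levels = seq_len(nw)))),
    n_articles_total = n_base,
    variant_map = config$surface_forms
  )
  list(corpus = validate_corpus(corpus), ground_truth = ground_truth)
}

#' Write generator ground truth as JSON
#'
#' @param ground_truth the `ground_truth` element of [generate_corpus()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Estimate the Zipf exponent from a document-frequency table
#'
#' Ordinary least squares of log(count) on log(rank) over the middle of the
#' rank-frequency curve: the head (low ranks) is flattened by per-article
#' set semantics and the tail by count discreteness, so ranks below
#' `min_rank` and counts below `min_count` are excluded.
#'
#' @param counts numeric vector of keyword document frequencies (any
#'   order).
#' @param min_rank first rank included in the fit (default 5).
#' @param max_rank last rank included (default 300).
#' @param min_count smallest count included (default 5).
#' @return the estimated exponent (positive) as a single number.
#' @export
estimate_zipf_exponent <- function(counts, min_rank = 5L, max_rank = 300L,
                                   min_count = 5L) {
  counts <- sort(as.numeric(counts), decreasing = TRUE)
  rank <- seq_along(counts)
  keep <- rank >= min_rank & rank <= max_rank & counts >= min_count
  if (sum(keep) < 3L)
    stop("too few ranks for a Zipf fit", call. = FALSE)
  fit <- stats::lm(log(counts[keep]) ~ log(rank[keep]))
  -unname(stats::coef(fit)[2L])
}
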