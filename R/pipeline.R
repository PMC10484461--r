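# End-to-end orchestration: ingest -> deduplicate -> normalize -> per-window
# network build -> metrics -> trends -> affinity mining, with every artifact
# written as a delimited table or edge list and a machine-readable run
# report recording the counts at each stage.

#' Pipeline configuration
#'
#' @param input path to a corpus file (see [read_corpus()]), or `NULL` to
#'   generate a synthetic corpus from `synthetic` instead.
#' @param input_format `"table"` or `"jsonl"`.
#' @param synthetic a `synthetic_config` used when `input` is `NULL`
#'   (default: [default_corpus_profile()] under `seed`).
#' @param windows list of `time_window`s (default [canonical_windows()]);
#'   must be non-overlapping and ordered.
#' @param exceptions a `kcn_exceptions` object.
#' @param categories a `category_map` for trend tracks.
#' @param top_n ranking depth for top-keyword, top-pair and trend tables.
#' @param min_support_count,min_confidence Apriori thresholds (defaults 200
#'   and 0.55, the usual corpus-scale settings; scale them down for small
#'   corpora).
#' @param single_consequent restrict reported rules to one-item consequents.
#' @param out_dir output directory (created if missing); `NULL` computes
#'   everything but writes nothing.
#' @param seed RNG seed for synthetic generation.
#' @param verbose print stage progress to stderr.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            input_format = "table",
                            synthetic = NULL,
                            windows = canonical_windows(),
                            exceptions = default_exceptions(),
                            categories = default_category_map(),
                            top_n = 20L,
                            min_support_count = 200L,
                            min_confidence = 0.55,
                            single_consequent = TRUE,
                            out_dir = NULL,
                            seed = 42L,
                            verbose = FALSE) {
  if (top_n < 1L) stop("top_n must be >= 1", call. = FALSE)
  if (min_support_count < 1L)
    stop("min_support_count must be >= 1", call. = FALSE)
  if (!(min_confidence > 0 && min_confidence <= 1))
    stop("min_confidence must be in (0, 1]", call. = FALSE)
  stopifnot(all(vapply(windows, inherits, logical(1), "time_window")))
  if (length(windows) > 1L) {
    for (i in seq_len(length(windows) - 1L)) {
      if (windows[[i + 1L]]$start_year <= windows[[i]]$end_year)
        stop("windows must be ordered and non-overlapping", call. = FALSE)
    }
  }
  if (is.null(input) && is.null(synthetic))
    synthetic <- default_corpus_profile(seed = seed)
  structure(
    list(input = input, input_format = input_format, synthetic = synthetic,
         windows = windows, exceptions = exceptions, categories = categories,
         top_n = as.integer(top_n),
         min_support_count = as.integer(min_support_count),
         min_confidence = min_confidence,
         single_consequent = single_consequent,
         out_dir = out_dir, seed = as.integer(seed), verbose = verbose),
    class = "pipeline_config"
  )
}

#' Run the full KCN pipeline
#'
#' Executes every stage and (when `out_dir` is set) writes: the cleaned
#' corpus, the stem dictionary, per-window network summary rows, top-keyword
#' and top-pair tables, per-node metric tables, weighted edge lists, trend
#' tables per track, the association-rule table, and `run_report.json` with
#' stage counts.
#'
#' @param config a `pipeline_config`.
#' @return (invisibly) a list with elements `corpus`, `dictionary`,
#'   `networks` (per window), `summary` (one row per window), `top_keywords`,
#'   `top_pairs`, `metrics`, `trends` (per track), `rules`, and `report`.
#' @export
run_kcn_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message("[kcnlit] ", ...)

  # ingest
  if (is.null(config$input)) {
    say("generating synthetic corpus (seed ", config$synthetic$seed, ")")
    gen <- generate_corpus(config$synthetic)
    corpus_raw <- gen$corpus
    load_report <- list(source = "synthetic",
                        n_rows = nrow(corpus_raw),
                        n_loaded = nrow(corpus_raw), n_skipped = 0L)
  } else {
    say("reading ", config$input)
    corpus_raw <- read_corpus(config$input, config$input_format)
    load_report <- attr(corpus_raw, "load_report")
  }

  # deduplicate
  dd <- deduplicate(corpus_raw)
  corpus <- dd$corpus
  say("deduplicated: ", dd$removed_count, " removed, ",
      nrow(corpus), " kept")

  # normalize
  dictionary <- build_stem_dictionary(corpus, config$exceptions)
  n_raw_kw <- nrow(dictionary)
  n_canon_kw <- length(unique(dictionary$canonical[nzchar(dictionary$canonical)]))
  say("keywords: ", n_raw_kw, " raw -> ", n_canon_kw, " canonical")

  # per-window networks, metrics, rankings
  networks <- list()
  summaries <- list()
  top_kws <- list()
  top_prs <- list()
  metrics <- list()
  freqs <- list()
  for (w in seq_along(config$windows)) {
    win <- config$windows[[w]]
    wname <- format(win)
    say("window ", wname)
    net <- build_network(corpus, win, config$exceptions, dictionary)
    networks[[wname]] <- net
    summaries[[wname]] <- network_summary(net)
    top_kws[[wname]] <- top_keywords_by_strength(net, config$top_n)
    top_prs[[wname]] <- top_pairs_by_weight(net, config$top_n)
    metrics[[wname]] <- node_metrics(net)
    freqs[[wname]] <- document_frequency(corpus, win, config$exceptions,
                                         dictionary)
  }
  summary_tab <- do.call(rbind, summaries)
  rownames(summary_tab) <- NULL

  # trends: first vs last window, per track
  trends <- list()
  if (length(config$windows) >= 2L) {
    f_first <- freqs[[1L]]
    f_last <- freqs[[length(freqs)]]
    for (track in setdiff(TREND_TRACKS, "unassigned")) {
      r1 <- rank_keywords(f_first, config$categories, track, config$top_n)
      r2 <- rank_keywords(f_last, config$categories, track, config$top_n)
      trends[[track]] <- classify_trends(r1, r2, config$top_n)
    }
  }

  # affinity mining on the pooled corpus
  tx <- build_transactions(corpus, config$exceptions, dictionary)
  itemsets <- apriori_frequent_itemsets(tx, config$min_support_count)
  rules <- derive_rules(itemsets, tx, config$min_confidence,
                        single_consequent = config$single_consequent)
  say(nrow(rules), " association rules")

  report <- list(
    load = load_report,
    articles_in = nrow(corpus_raw),
    duplicates_removed = dd$removed_count,
    articles_analyzed = nrow(corpus),
    raw_keywords = n_raw_kw,
    canonical_keywords = n_canon_kw,
    windows = vapply(config$windows, format, character(1)),
    articles_per_window = vapply(networks, function(n) n$n_articles,
                                 numeric(1)),
    min_support_count = config$min_support_count,
    min_confidence = config$min_confidence,
    n_frequent_itemsets = nrow(itemsets),
    n_rules = nrow(rules)
  )

  result <- list(corpus = corpus, dictionary = dictionary,
                 networks = networks, summary = summary_tab,
                 top_keywords = top_kws, top_pairs = top_prs,
                 metrics = metrics, frequencies = freqs, trends = trends,
                 rules = rules, report = report)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    wt <- function(x, f) utils::write.table(
      x, file.path(od, f), sep = "\t", quote = FALSE, row.names = FALSE)
    write_corpus(corpus, file.path(od, "corpus_clean.tsv"))
    write_stem_dictionary(dictionary, file.path(od, "stem_dictionary.tsv"))
    wt(summary_tab, "network_summary.tsv")
    for (wname in names(networks)) {
      tag <- gsub("-", "_", wname)
      wt(top_kws[[wname]], paste0("top_keywords_", tag, ".tsv"))
      wt(top_prs[[wname]], paste0("top_pairs_", tag, ".tsv"))
      wt(metrics[[wname]], paste0("node_metrics_", tag, ".tsv"))
      write_edge_list(networks[[wname]], file.path(od, paste0(
        "edges_", tag, ".tsv")))
      if (requireNamespace("igraph", quietly = TRUE))
        write_graphml(networks[[wname]], file.path(od, paste0(
          "network_", tag, ".graphml")))
    }
    for (track in names(trends)) {
      tag <- gsub("[^a-z]+", "_", track)
      wt(trends[[track]], paste0("trends_", tag, ".tsv"))
    }
    wt(rule_table(rules), "rules.tsv")
    jsonlite::write_json(report, file.path(od, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("artifacts written to ", od)
  }

  invisible(result)
}
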