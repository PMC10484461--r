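# kcnlit

Keyword co-occurrence network (KCN) analysis of literature corpora in R.

## What it does

When a research field produces hundreds of thousands of articles, reading
them is no longer a way to survey it. `kcnlit` maps a field's knowledge
structure from the author keywords of its articles: each keyword is a node,
and two keywords are linked when they appear together in an article, the
link weight `w_ij` counting the number of articles in which they co-occur.
Built per time window, these networks show which concepts dominate, which
pairs of concepts researchers combine, and how both change over time. The
package is aimed at bibliometric and science-mapping analyses of any corpus
of article records with author keywords.

The pipeline is:

1. **Ingestion and screening** — read article tables (id, database, year,
   title, keyword field), drop records with unparseable years into a load
   report, and remove duplicate articles (same title after casefolding,
   punctuation stripping and whitespace collapsing) within and across
   source databases.
2. **Keyword normalization** — split keyword fields on `;` `:` `/`,
   lowercase, delete in-token punctuation (digits survive), tokenize on
   spaces and hyphens, Porter-stem every token (with an irregular-plural
   table and optional user stem overrides), drop tokens of one or two
   characters, and rejoin. This collapses "opioids", "Opioid" and
   "opioides" onto `opioid`, and "Pain Management" onto `pain manag`, with
   the full before/after mapping exported as a stem dictionary.
3. **Network construction** — per time window, a document-frequency table
   and the symmetric weighted adjacency (`a_ij`, `w_ij`, zero diagonal),
   with each unordered keyword pair counted once per article.
4. **Network statistics** — for each node *i* with neighbor set *V_i*:
   - degree `k_i = Σ_{j∈V_i} a_ij`
   - strength `s_i = Σ_{j∈V_i} w_ij`
   - average weight versus endpoint degree: links grouped by the exact
     product `k_i·k_j`, each class reporting its mean weight `⟨w_ij⟩`
   - weighted nearest-neighbor degree
     `k^w_nn,i = (1/s_i) Σ_{j∈V_i} w_ij k_j` (assortativity)
   - weighted clustering coefficient (geometric-mean form)
     `c_i = [1/(k_i(k_i−1))] Σ_{j,h∈V_i} (ŵ_ij ŵ_ih ŵ_jh)^{1/3}` with
     `ŵ = w / max(w)` (cohesiveness), averaged per degree for profiles.
5. **Trend classification** — keywords assigned to category tracks
   (user-supplied configuration), ranked by document frequency per window;
   a keyword is *emerging* when its rank improved from the first to the
   last window or it newly entered the top-N, *declining* when it worsened
   or dropped out.
6. **Affinity analysis** — from-scratch Apriori frequent-itemset mining
   over article keyword sets with association rules scored by support
   count, confidence `P(consequent | antecedent)` and lift
   `confidence / P(consequent)`.

A seeded synthetic-corpus generator (`generate_corpus()`,
`default_corpus_profile()`) emulates the statistical structure such corpora
have — growing windows, Zipf-like keyword frequencies, an ever-present root
keyword, surface variants, cross-database duplicates — and plants pairs,
frequency ladders and rules at exact counts with machine-readable ground
truth, so the whole pipeline is testable without any external data.

## Worked example

The endpoint-degree profile on a four-node network with degrees
`k = (1, 60, 20, 3)` and weights `w_12=30, w_13=35, w_14=40, w_23=50,
w_24=25, w_34=100`:

```r
library(kcnlit)
deg <- c(n1 = 1, n2 = 60, n3 = 20, n4 = 3)
ed <- data.frame(from = c("n1","n1","n1","n2","n2","n3"),
                 to   = c("n2","n3","n4","n3","n4","n4"),
                 weight = c(30, 35, 40, 50, 25, 100))
endpoint_degree_profile(deg, ed)
#>   endpoint_degree mean_weight n_edges
#> 1               3          40       1
#> 2              20          35       1
#> 3              60          65       2
#> 4             180          25       1
#> 5            1200          50       1
```

Edges 1–2 and 3–4 share the endpoint-degree product 60, so that class
averages their weights: `(30 + 100) / 2 = 65`.

Normalization collapses surface variants onto canonical stemmed keywords:

```r
normalize_keyword(c("Neuropathic Pains", "1,3,4 –Oxadiazole"))
#> [1] "neuropath pain" "134 oxadiazol"
```

A full synthetic run (desk-scale profile, thresholds scaled to corpus
size):

```r
cfg <- pipeline_config(synthetic = default_corpus_profile(seed = 42),
                       min_support_count = 25, min_confidence = 0.55)
res <- run_kcn_pipeline(cfg)
res$summary[, c("window","n_articles","n_nodes","n_links","avg_weight")]
#>      window n_articles n_nodes n_links avg_weight
#> 1 2002-2006        640     130    1617      3.594
#> 2 2007-2011        746     219    2760      2.996
#> 3 2012-2016       1049     453    5256      2.392
#> 4 2017-2021       1711     777    8203      2.320
head(rule_table(res$rules), 2)
#>     antecedent  consequent support_count confidence   lift
#> 1 chronic pain postop pain            25          1 165.84
#> 2 ...
```

The summary shows the corpus growth the profile encodes (articles roughly
tripling, vocabulary roughly sevenfold across windows); the rule table
recovers the planted associations — `chronic pain` and `postop pain` were
planted to co-occur in 25 dedicated articles, so the rule between them has
support 25, confidence 1 and a lift of `1 / (25/4146) ≈ 165.8`.

A thin command-line wrapper is at `inst/cli/kcn-pipeline.R`:

```sh
Rscript inst/cli/kcn-pipeline.R --out-dir kcn_out --min-support 25 --seed 42
```

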