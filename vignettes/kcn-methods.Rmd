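---
title: "Keyword co-occurrence networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keyword co-occurrence networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcnlit)
```

## The model

A keyword co-occurrence network (KCN) treats the author keywords of a
literature corpus as nodes and connects two keywords when at least one
article lists both. The network is undirected and weighted: `w_ij` counts
the articles in which keywords *i* and *j* co-occur, `a_ij = 1` wherever
`w_ij >= 1`, and the diagonal is zero. Networks are built per time window
(by default the four five-year spans 2002--2006 through 2017--2021), so
their evolution tracks the field's. The underlying assumptions are that
author keywords are a faithful, compact summary of an article's topics,
and that co-listing two keywords signals a substantive association between
the topics. Both assumptions degrade when keyword vocabularies are
uncontrolled — which is why normalization (below) does the heavy lifting.

Keyword lists become *sets* after normalization: within one article a
canonical keyword counts once, and each unordered pair of distinct
keywords in an article increments its edge weight by exactly one. The node
universe of a window is the set of keywords observed in that window; no
padding with a global vocabulary, so node counts are comparable across
windows.

## Keyword normalization

Raw keyword fields arrive as delimited strings in inconsistent case,
number and derivational form. The normalization chain is, in order:

1. split the field on `;`, `:` and `/` (hyphens are *not* field
   delimiters);
2. lowercase;
3. delete punctuation inside tokens — commas, periods, apostrophes vanish
   so that `"1,3,4 -Oxadiazole"` yields the token `134`; digits are kept;
4. tokenize on spaces and hyphen-family characters;
5. map irregular plurals (children → child, ...), apply the Porter
   suffix-stripping stemmer to each purely alphabetic token, then apply
   any user-supplied stem overrides;
6. drop tokens of fewer than three characters;
7. rejoin with single spaces.

The Porter algorithm is implemented in full (steps 1a--5b of the classic
formulation) in `R/porter.R`; it reproduces the standard before/after
pairs (`painfulness → pain`, `quality → qualiti`, `management → manag`,
`postoperative → postop`, `neuropathic → neuropath`). The exception table
ships with a six-entry irregular-plural list and an *empty* override map:
the plain stemmer already yields every canonical form the shipped
vocabulary needs. Overrides exist for corpora whose domain usage disagrees
with Porter output (e.g. forcing an abbreviation); they apply
token-by-token after stemming.

Two design notes. First, single-pass stemming is the standard convention
and is what we implement; iterated stemming is not idempotent-safe (a stem
ending in a bare `s`, such as `analges` from "analgesics", would lose it
on a second pass). Normalization is idempotent on the canonical vocabulary
the package's corpora produce — every shipped canonical form is a fixed
point — and the test suite checks exactly that property on those
vocabularies rather than asserting it for all of English, where rare
derivational chains violate it. Second, hyphens are treated as token
separators (so "machine-learning" and "machine learning" agree), never as
field delimiters; a field-level hyphen delimiter would shred hyphenated
single keywords.

Duplicate articles are detected by *normalized title only* (casefold,
strip punctuation, collapse whitespace; first occurrence in input order
survives). Matching on authors or keywords as well would catch retitled
reprints but also merge genuinely distinct articles with generic titles;
title-exact matching is deterministic and conservative.

## The five statistics

With `V_i` the neighbor set of node *i*:

* **Degree** `k_i = Σ_{j∈V_i} a_ij` — breadth of a keyword's associations.
* **Strength** `s_i = Σ_{j∈V_i} w_ij` — total co-occurrence volume;
  strength rankings define the "top keywords" tables.
* **Average weight vs endpoint degree.** Each link is assigned to the
  class given by the exact integer product `k_i k_j` of its endpoint
  degrees; a class reports the arithmetic mean of its member weights. An
  increasing profile means heavily co-used keyword pairs tend to join two
  high-degree keywords. Classes are keyed by the exact product — binning
  (for log-scale plots) is a presentation choice deliberately left out of
  the computational contract.
* **Weighted nearest-neighbor degree**
  `k^w_nn,i = (1/s_i) Σ_{j∈V_i} w_ij k_j` — the weight-averaged degree of
  a node's neighbors; rising with `k_i` indicates assortative mixing. The
  value is the degree of the *neighbor* `j` weighted by `w_ij`; for
  isolated nodes it is reported as absent (`NA`), never zero.
* **Weighted clustering (geometric-mean form)**
  `c_i = [1/(k_i(k_i−1))] Σ_{j,h∈V_i} (ŵ_ij ŵ_ih ŵ_jh)^{1/3}`, with
  weights normalized by the single global maximum `max(w)` of the window
  network. The sum runs over *ordered* neighbor pairs `j ≠ h`, matching
  the `1/(k(k−1))` prefactor so that a complete unit-weight graph attains
  `c_i = 1`; an unordered-pair reading would halve every value. Per-node
  normalization by a local maximum was rejected: a single global `max(w)`
  keeps coefficients comparable across nodes of one window (not across
  windows). `c_i` is defined as exactly 0 for `k_i ≤ 1`, which keeps the
  per-degree profile total; the profile averages `c_i` over nodes sharing
  a degree and is empty for an edgeless network (no division attempted).

All rankings break ties lexicographically — an arbitrary but reproducible
convention.

## Trend classification

Keywords are assigned to category tracks (sensors/methods, biomedical,
treatment, unassigned) by a user-supplied two-column map; categorization
is domain knowledge, not computation, and the shipped
`default_category_map()` is explicitly illustrative. Within a track,
keywords are ranked by document frequency per window (ties lexicographic,
ranks ordinal 1..top_n, default top_n = 20). Comparing the first and last
windows: rank improved or newly entered the top-N ⇒ *emerging*; worsened
or dropped out ⇒ *declining*; identical ⇒ *stable*. Ranking is within
track, not global-then-filtered: track figures conventionally start at
rank 1.

## Affinity analysis

Transactions are the canonical keyword sets of articles pooled over all
windows. Frequent itemsets are mined level-wise (Apriori): candidates of
size *k* are joined from frequent (k−1)-itemsets sharing their first k−2
items and pruned by downward closure; counts are exact, computed by
intersecting per-item transaction-id lists. For every frequent itemset of
size ≥ 2 and every nonempty proper subset A, the rule A → C (C the
complement) is emitted when `confidence = count(itemset)/count(A)` meets
the threshold, with `lift = confidence / (count(C)/N)`. Reports sort by
lift, then confidence, then antecedent. Multi-item consequents are
generated by default; `single_consequent = TRUE` restricts to the layout
of conventional rule tables. The corpus-scale defaults are a minimum
support count of 200 and minimum confidence 0.55; on the desk-scale
synthetic profile (about 4,000 articles rather than hundreds of
thousands) the tests and acceptance script scale the support threshold to
25, keeping the support-to-corpus ratio in the same regime.

## The synthetic generator

`generate_corpus()` emulates the features of a real multi-database keyword
corpus that this pipeline is sensitive to:

* four windows with growing article counts (500/720/1025/1445, ratio
  ≈ 1:1.44:2.05:2.89) and nested background vocabularies (120/216/504/900,
  ratio ≈ 1:1.8:4.2:7.5) — the roughly threefold article growth and
  sevenfold vocabulary growth typical of a fast-expanding field at desk
  scale;
* background keywords drawn per article (2--7 draws with replacement,
  distinct kept) from a rank-frequency law `p_r ∝ r^(−s)` with `s = 1` —
  the Zipf-like skew of real keyword frequencies;
* a root keyword ("pain") present in every article, emulating a corpus
  retrieved by a topical query;
* surface variants (case, plural, derivational, hyphenation) emitted at
  rate 0.3 from a curated table validated to normalize back to the
  canonical form, and three field-delimiter styles;
* cross-database duplicates at rate 0.1 (same title, different database
  label);
* *constructively* planted structure: dedicated articles realize
  co-occurrence pairs, document-frequency ladders and association rules at
  exactly their target counts, recorded in the ground truth. Planted
  keywords must be fixed points of normalization and disjoint from the
  background vocabulary (validated before generation), so their recovery
  by the pipeline is exact, not approximate.

Ground truth (per-window document frequencies tallied at construction,
pair counts, rule support/confidence/lift, the duplicate list) is what
end-to-end tests compare against. What the generator does **not** emulate:
natural-language titles and abstracts, semantically correlated keyword
choices, synonymy beyond surface variation, database-specific field
quirks, or citation structure. Passing the synthetic recovery suite
therefore demonstrates that counting, normalization inversion,
deduplication and mining are exact under the stated corpus model — not
that the normalizer resolves real-world synonymy, nor that category
assignments are meaningful.

The Zipf exponent check fits OLS of log frequency on log rank, excluding
ranks below 5 (the head is flattened because an article keeps only
distinct draws) and counts below 5 (tail discreteness); the generator's
exponent is recovered within ±0.2 at the default profile's roughly 6,000
background keyword emissions per window, and more tightly at larger
sizes.

## Numerical conventions and degenerate inputs

* Average network weight (Σ link weights / number of links) is reported
  absent (`NA`), not zero, for an edgeless network.
* `k^w_nn` is absent for isolated nodes; `c_i = 0` for degree ≤ 1.
* Co-occurrence weights are integers; clustering uses double precision,
  and oracle-equivalence tests require agreement to 1e-12 relative.
* Record order never matters: networks are order-invariant, duplicate
  survivors are chosen by input order, and all randomness in the
  generator flows from one integer seed (runs are byte-identical given
  the configuration).
* Problem sizes in the test suite — random graphs up to 30 nodes, 100
  random transaction sets up to 12 items, the ~4,000-article synthetic
  profile — were chosen as the smallest sizes at which every contract is
  exercised, including multi-level Apriori recursion and four-window
  growth.

## Known limitations

* Title-only duplicate matching misses retitled duplicates and cannot
  distinguish distinct articles sharing a title verbatim.
* The Porter stemmer over- and under-stems in the usual documented ways
  ("analgesia" and "analgesic" stay distinct; "interstitial" stems to a
  form that would stem further); no lemmatization, spelling correction or
  multilingual support.
* Category maps are single-membership and manual by design.
* Networks are per-window and undirected; no per-year temporal resolution
  and no directionality of keyword association.
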