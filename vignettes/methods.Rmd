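---
title: "Methods: fielded retrieval and query expansion for dataset metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fielded retrieval and query expansion for dataset metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biodatasearch)
```

## The retrieval model

`biodatasearch` treats dataset discovery as fielded keyword retrieval.
Every dataset record is a bag of named fields drawn from a closed 11-name
vocabulary; nine fields hold analyzed text, and two (`repository`,
`category`) are stored labels used for filtering, never analyzed. All text
— record fields and queries alike — passes through one analysis chain:
lowercasing, tokenization on maximal runs of letters and digits,
a 33-word English stopword list, and Porter stemming. Keeping digit-bearing
tokens intact matters here: gene symbols such as `BeF3` or `TP53` must
survive analysis unchanged apart from case.

Scoring follows the classic practical TF-IDF/vector-space formulation used
by the Lucene engine family:

$$\mathrm{score}(q,d) \;=\; \mathrm{coord}(q,d)\,
\sum_{(c,t)\,\in\,q}\; \sqrt{tf(t,d,c_f)}\;\cdot\; idf(t,c_f)^2 \cdot
b_{c,t} \cdot \frac{1}{\sqrt{|d_{c_f}|}}$$

with $idf = 1 + \ln\!\big(N/(df+1)\big)$ and coord the fraction of the
query's (clause, term) pairs that match the document. Two deliberate
simplifications are documented rather than hidden: the per-query
normalization constant is omitted because it is identical for every
document and therefore cannot change ranks, and the field-length norm is
the exact $1/\sqrt{\text{length}}$ rather than a byte-quantized
approximation — reproducibility beats bug-compatibility with any
particular engine release. Matching is disjunctive across all clause
terms; there are no mandatory terms. Ties in score are broken by ascending
document identifier so that rankings, run files and feedback sets are
fully deterministic.

## Query formulation

A raw query is processed three ways before retrieval:

1. **Category identification.** An ordered rule list maps key phrases
   ("gene expression", "clinical trial", "protein structure", …) to data
   categories; matching is a case-insensitive substring test on the
   whitespace-normalized query and the first rule wins. The identified
   category becomes a hard candidate filter — with the important exception
   that documents labelled `"Unspecified"` are always admitted, because
   repositories of unspecified type hold relevant datasets for queries of
   every category.
2. **Entity tagging.** Gene, organism and disease mentions are found by
   longest-match, case-insensitive dictionary matching over the canonical
   names and synonyms of a lexicon, on word boundaries, with overlapping
   shorter matches suppressed. A dictionary tagger (rather than an external
   statistical NER system) keeps the artifact self-contained and exactly
   testable; the lexicon is an input, so richer dictionaries drop in
   without code changes.
3. **Multi-field building.** The `title`, `description` and
   `article_title` clauses always carry the full analyzed term set; an
   `organisms` (`genes`) clause is added if and only if organism (gene)
   mentions exist, carrying only the mention terms; every entity-mention
   term is boosted by a factor of 2 wherever it appears. Disease mentions
   receive the concept boost but do *not* add a `diseases` clause by
   default: disease fields in aggregated collections are sparsely populated
   and dominated by generic terms ("cancer", "tumor"), and targeting them
   drags relevant documents down. The clause remains available via
   `disease_clause = TRUE` for ablation.

## Query expansion

Two term sources are implemented behind one interface.

**Rocchio.** The combined vector
$\vec{Q'} = \alpha\vec{Q} + \frac{\beta}{|DR|}\sum \vec{d_r} -
\frac{\gamma}{|DNR|}\sum \vec{d_{nr}}$ is computed coordinate-wise over the
union vocabulary with the conventional weights $\alpha = 1$,
$\beta = 0.5$, $\gamma = 0.1$. Document vectors are raw
$tf \times idf$ over a single source field (default `description`, the
best-performing source; `title` is configurable). Pseudo-relevance
feedback uses the top $k = 10$ documents of an initial run as $DR$ and
leaves $DNR$ empty — pseudo-relevance has no evidence of irrelevance —
while the judgment-based ("oracle") mode uses graded judgments directly:
grade ≥ 1 forms $DR$, grade 0 forms $DNR$, grade −1 is excluded. Negative
coordinates after combination are clamped to zero, the standard practice
when the subtraction term overwhelms a coordinate. An empty feedback set
contributes nothing (its term is dropped; there is no division by zero).

**Lexicon.** The synonyms and canonical names of every entity mentioned in
the query are analyzed and ranked by $idf$ in the source field — terms
frequent in the collection are of low utility, rare terms of high utility.
This requires no initial retrieval pass, which is its practical appeal.

In both methods the top $m = 5$ candidate terms not already in the query
are selected (ties broken lexicographically so expansion is deterministic)
and appended *unboosted* to the three always-on clauses. The selection
weights are used only for ranking, not for reformulation weighting: the
expanded query stays engine-agnostic, and applying the same expansion
twice is a no-op. Five terms is small enough to preserve the query's
original sense.

## Evaluation

Judgments use the four-value scale {2, 1, 0, −1}. Binary metrics (P@k,
Recall, AP) count grade ≥ 1 as relevant — partial relevance is relevance —
and treat unjudged as non-relevant. NDCG uses gain $2^g - 1$ with a
$1/\log_2(r+1)$ discount and normalizes by the ideal ordering of the
query's judged grades; both conventions are stated because the metrics are
tested to machine precision against an independent naive evaluator.
Rankings shorter than a precision cutoff are treated as padded with
non-relevant documents.

The inferred estimators address uniformly sampled judgments with a known
per-query sampling rate $p$ (recorded in a sidecar file). For infAP, each
*sampled* relevant document retrieved at rank $k$ contributes an estimated
precision $\min\{1, (1 + s_k/p)/k\}$, where $s_k$ counts sampled relevant
documents above rank $k$; the mean over all sampled relevant documents
(retrieved or not) estimates AP. For infNDCG, the DCG of sampled judged
documents is inflated by $1/p$ and normalized by an ideal DCG built from
the inflated grade counts, with fractional counts handled by positional
interpolation. Both estimators reduce *exactly* to AP/NDCG at $p = 1$ —
that reduction and a Monte-Carlo unbiasedness check (mean over 10,000
half-rate resamples of a fixed 200-document query) pin the implementation
in place of any particular published variant. Degenerate inputs are
explicit: no sampled judgments is an error; a sample with no relevant
documents yields `NA` with a warning, mirroring the exclusion of
zero-relevant queries from MAP.

The overlap diagnostic
$\mathrm{Overlap}(X_1,X_2) = |X_1 \cap X_2| / \min(|X_1|,|X_2|)$ between
query and field term sets quantifies why expansion is needed at all:
relevant datasets share little vocabulary with the queries that seek them,
and `overlap_by_field()` / `overlap_stats()` reproduce that analysis on
any collection.

## What the synthetic generator emulates

`generate_collection()` builds, from a single integer seed, a collection
with the structural features the pipeline is sensitive to:

* **Field heterogeneity.** Five repositories populate different subsets of
  the canonical fields (one has no `description` at all; one carries PMIDs
  whose articles are linked into the literature fields), each with a fixed
  category, including an `"Unspecified"` repository.
* **Background text** is drawn from a Zipf-like vocabulary (exponent 1.1)
  whose rank distribution is shifted by 20 before normalization. The shift
  mimics text that has already lost its stopword head: analyzed metadata
  has no tokens with double-digit-percentage frequency, and without it the
  head tokens would act as synthetic stopwords that no English stopword
  list removes and that raw-tf feedback vectors would latch onto.
* **Entities** (150 genes, 150 organisms, 30 diseases, each with synonyms)
  come from an alphabet disjoint from the background so planted signal is
  controllable, and entity name density per document matches the sparsity
  of real taxonomies rather than saturating the collection. Each query
  targets its own gene and organism (sampled without replacement across
  queries) so one query's planted documents cannot masquerade as strong
  unjudged matches for another.
* **Planted relevance.** Per query: 12 grade-2 documents receive one topic
  term plus the gene name in the title, a sample of topic terms, six
  per-query "theme" terms and the gene's synonym in the description, and
  the organism/gene in the matching entity fields; 8 grade-1 documents
  receive a strict subset (one topic term, three theme terms, the organism
  in its field) — partially relevant means "right organism, thin text
  overlap"; 40 judged grade-0 documents receive nothing. Thirty further
  *unjudged* documents per query receive topic terms only, emulating the
  generality of short keyword queries over a large corpus. Relevant
  documents are drawn from repositories compatible with the query's
  category so the category filter can never exclude them.

This construction makes the qualitative orderings the pipeline is designed
to produce — plain baseline < multi-field builder < builder with Rocchio
expansion, and judgment-based Rocchio at least as good as PRF — properties
of the data-generating process rather than accidents of a seed, which is
what the directional acceptance tests check across ten seeds. What the
generator does **not** emulate: natural biomedical language (morphology,
ambiguity, abbreviations), realistic collection scale, correlated topics
between queries, pooled judgment bias, or entity synonymy errors. Passing
tests on these collections therefore demonstrate the machinery — not
retrieval quality on any real collection.

## Parameters that matter

| Parameter | Default | Notes |
|---|---|---|
| Stopword list | 33 words | compact on purpose; configurable |
| Stemmer | Porter | `"none"` disables stemming |
| Concept boost | 2 | multiplies entity-mention terms and entity clauses |
| Disease clause | off | ablation toggle |
| Rocchio α, β, γ | 1, 0.5, 0.1 | conventional weighting |
| PRF depth k | 10 | top ranked documents of the initial run |
| Expansion terms m | 5 | preserves the query's original sense |
| Expansion source field | `description` | `title` or lexicon mode configurable |
| Ranking depth | 1000 | TREC-style run depth |

## Problem sizes

The defaults are chosen so everything runs on one CPU in minutes: the
default synthetic collection holds 2,000 documents in 5 repositories with
20 queries and 60 judged documents per query; the test suite exercises the
metric implementations on 1,000 randomized micro-instances (≤ 50
documents), the Rocchio arithmetic on 500 random instances against dense
brute force, the scorer on random micro-corpora (≤ 20 documents) against a
literal re-implementation of the formula, the inferred metrics on 10,000
Monte-Carlo resamples of one fixed 200-document query, and the directional
ordering on ten seeded default collections.

## Known limitations

* No positional or phrase indexing: dictionary tagging operates on raw
  query text, but the index itself is bag-of-words per field.
* No BM25 or probabilistic scoring, no learning-to-rank; the scorer is
  fixed to the stated vector-space variant.
* The inferred estimators implement the uniform-sampling expected-value
  forms; stratified pools are supported only as per-query rates in the
  sidecar, and ratio-estimator bias, though measured to be small, is not
  corrected analytically.
* The Porter stemmer is the original algorithm; no language other than
  English is supported.
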