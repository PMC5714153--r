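---
title: "Ranking biomedical dataset records with term-relevance bins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking biomedical dataset records with term-relevance bins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(datamedrank)
```

## The problem

Dataset discovery indexes hold hundreds of thousands of metadata-only
records: a title, a repository name, and a JSON payload whose string values
describe a dataset (organism, assay, study group, ...). Users search them
with short natural-language queries. Two features make this retrieval
setting awkward. First, short queries leave frequency-normalization
parameters of probabilistic rankers (BM25, divergence from randomness)
badly constrained, so tuning on one query set transfers poorly to another.
Second, relevance judgments over such corpora are necessarily *pooled and
incomplete*: most retrieved documents were never assessed, and the grading
is graded (relevant / partially relevant / not relevant / pooled but
unjudged), which standard AP and NDCG do not handle gracefully.

This package implements a complete pipeline for that setting — corpus and
query normalization, embedding-based query expansion, a deliberately simple
bin-ranking similarity measure, category-constrained boosting, rank fusion
— plus the matching evaluation stack (inferred AP, inferred NDCG, P@10
with/without partial relevance, NDCG@10, UIR).

## Normalization

`normalize_text()` applies, in order: Greek letters to literal names,
lower-casing and tokenization on non-alphanumeric boundaries, stopword
removal, original Porter stemming, a residual non-alphanumeric strip,
truncation to 20 characters, and replacement of purely numeric tokens with
the literal `_number_`. The numeric substitution is deliberately last so
its underscores survive the non-alphanumeric strip. Query mode additionally
removes a *query-stopword* list of search-intent words (*find*, *search*,
*data*, *databases*, *related*, *across*, *all*, ...). That list is a
package choice reconstructed from how scaffold words behave in canonical
example queries — words like *data* are content-bearing in a corpus but
pure scaffolding in a query — and is user-overridable, as is the general
list (we ship the standard Snowball English list; any published system's
exact list is unknowable from the outside). The Porter stemmer is the
original 1980 algorithm, implemented in the package and verified against
the classic reference pairs.

```{r}
normalize_text(
  "Find protein sequencing data related to bacterial chemotaxis across all databases",
  mode = "query")
```

## Key-relevant terms and the RTRL measure

For a query of `L` terms, a term is **key-relevant** when its collection
document frequency is at or below the median of the query terms'
frequencies; otherwise it is merely relevant (an even count takes the mean
of the middle pair; out-of-index terms have frequency 0 and are always
key-relevant). We read "collection frequency" as *document* frequency
rather than total occurrence count, because the 50%-of-terms cut-off that
defines the class is phrased over document frequencies; a config switch on
the index would allow the other reading if wanted.

A document's score is the sum, over query terms it contains, of
`w_d + w_q`, where `w_d` is 1 for a single occurrence and 2 otherwise, and
`w_q` is 1 for relevant terms and `w_q'' = c(2L - 2)` for key-relevant
ones. The key weight comes from the worst-case dominance requirement: a
document holding all `k` key-relevant terms at minimal evidence
(`w_d = 1`) must score at least as high as one holding `k - 1` key terms
plus all remaining relevant terms at maximal evidence (`w_d = 2`):

`k (w_d' + w_q'') >= (k - 1)(w_d'' + w_q'') + (L - k)(w_d'' + w_q')`.

With `w_d' = w_q' = 1`, `w_d'' = 2` and `k = L/2`, the smallest solution is
`w_q'' = 2L - 2`, scaled by a gain `c >= 1`; at `c = 1` the inequality is
tight (zero margin), which the test suite checks symbolically for
`L = 2..20` and exhaustively over occurrence patterns for `L = 2..10`.
Because the median rule guarantees at least half the terms are
key-relevant, the dominance property holds for every `k >= L/2`.

Scores built from integer weights land in integer **relevance bins**; two
documents each holding one distinct key-relevant term and nothing else are
deliberately indistinguishable at this level. Inside a bin, documents are
ordered by a tf·idf tie-break: `tf = 0.5 + 0.5 f_td / max_t' f_t'd`,
`idf = log(N/n_t)` (natural log by default; the base is config-exposed
since within-bin max-scaling makes it only approximately immaterial),
summed over query terms present and divided by the bin maximum plus a
small epsilon, so every tie-break lies strictly in (0, 1) and can never
reorder documents across bins. A bin whose members all have zero raw
tf·idf (every term everywhere) falls back to a uniform epsilon and doc-id
order. The final score is bin + tie-break, so ordering, persistence to
TREC run files and re-reading all agree.

Expanded terms (below) enter the sum with their expansion weight
multiplying `(w_d + w_q)`; original terms have weight 1, so the formula
degenerates to the plain sum for unexpanded queries. An expanded term
inherits the relevance class of its parent. When the same expansion is
produced by two parents it is kept once at the maximum weight. These three
conventions are implementation choices the scoring equations leave open.

## Query expansion

`expand_query()` adds, per original term, its `k` nearest vocabulary terms
by cosine in a word-embedding space (default `k = 10`), weighted by the
similarity, excluding the original query terms; ties at the k-th position
break lexicographically. Retrieved neighbours are re-normalized (stemmed)
so they match index terms. An optional minimum-similarity cut-off (default
off) supports threshold-style expansion. Model 2 multiplies the weight of
every *non*-key-relevant original term and its expansions by `1 - l`
(default `l = 0.01`); reading "reduced by the factor" as multiplication
*by* `l` is one flag away (`loss_mode = "multiply"`) — we default to the
milder reading since a 1% reduction, not a 99% one, is what a loss factor
of 1% most plausibly means, and `l = 0` then coincides exactly with
model 1. Expansion operates on whatever surface forms the embedding
vocabulary holds; with stemmed vocabularies (as our synthetic spaces) the
lookup is exact.

`train_embeddings()` is a compact CBOW trainer with negative sampling
(window 5, dimension configurable; the conventional production setting is
dimension 200 on a domain corpus). It exists so the pipeline is
self-contained and seed-reproducible on synthetic text; for real corpora
one would train externally and load the standard word2vec text format with
`read_embeddings()`.

## Categorization and boosting

Queries are string-matched (1-grams, 2-skip-2-grams, 3-skip-2-grams,
stemmed) against descriptor phrases of the 11 UniProt curator categories
plus *Clinical trial*; the clinical class additionally fires on the
keywords *inclusion, exclusion, criteria, patients, subjects, stage,
duration, study*. Query classification runs on tokens *before*
query-stopword removal, because constraint words like *data* may
participate in qualifier grams. The shipped descriptor table is a starter
seed (the full curator qualifier inventory is not redistributable) and is
meant to be extended via a plain two-column file.

Datasets are classified either by the same string matching plus the
*clinical/trial/clinicaltrial* keyword rule, or by a trained multi-label
classifier: documents are embedded by tf-idf + truncated SVD (a latent
semantic projector standing in for a paragraph-vector model) and scored by
one single-hidden-layer perceptron per class (`nnet`), thresholded at 0.5.
Training is seed-deterministic and the model round-trips through
save/load. It is exercised only on synthetic separable fixtures here; no
claim is made about its accuracy on real abstracts.

Boosting multiplies the score of every document in the top
`ceiling(top_fraction * n)` positions (default half) whose classes
intersect the query's classes by `1 + g` (default `g = 0.10`), then
re-sorts with ties keeping their previous order. We read "the top half,
with the highest rank as reference" as an eligibility window over
positions; the alternative reading (capping boosted scores at the rank-1
score) is not implemented. Multiple matching classes do not compound the
gain. The multiplier applies to the full final score (bin + tie-break) —
the boost is defined on the ranking score as a whole.

## Fusion

`combine_runs()` mixes two runs per query as
`alpha * A + (1 - alpha) * B` over the union of their documents (missing
documents score 0). Because the two fused scorers live on different scales,
scores are min-max normalized per query by default — the minimal scale
reconciliation; `normalize = "none"` reproduces raw summation for
same-scale runs.

## Evaluation and unjudged documents

Grades are 2 / 1 / 0 / -1 (pooled but unjudged); documents absent from the
qrels are *unpooled* and always count as not relevant. NDCG uses the linear
grade as gain (the grades are already the challenge's weights; exponential
gain is an option). Queries with no positively graded document are excluded
from means with a warning, and their count is reported.

`inf_ap()` implements the extended inferred-AP estimator: for a retrieved
sampled relevant document at rank `k`, the expected precision is
`1/k + (k-1)/k · d/(k-1) · (r + e)/(r + n + 2e)` with `d` the pooled
documents above, `r`/`n` the judged relevant/non-relevant above, and
`e = 1e-5` a smoothing constant (config-exposed); the estimate averages
over the sampled relevant documents. `inf_ndcg()` scales judged grade
counts by the inverse sampling rate for the ideal list (rounded to integer
counts) and substitutes the mean judged gain for retrieved
pooled-but-unjudged documents. Under complete judgments both reduce to
their exact forms within 1e-3, which the suite checks on 500 random
rankings; at 50% subsampling the mean inferred AP stays within 0.05 of the
full-judgment value over 100 seeded replicates. Official scoring tools'
exact treatment of grade -1 inside the estimators is not publicly pinned
down, so our `sampled` mode documents its own semantics (above) rather
than claiming bit-compatibility; the two diagnostic modes
(`as-nonrelevant`, `removed`) reproduce the standard sensitivity
experiment, and removing unjudged documents never scores below re-grading
them as not relevant.

`uir()` compares systems across several measures at once: per query, a
system scores an unanimous win over another when it is no worse on every
measure and strictly better on at least one; `UIR(A,B)` is the normalized
win difference, and a system's score is its mean against all others.
Whether the aggregation unit is the query or the full measure vector is
ambiguous in common usage, so the function takes per-query tables and the
caller may pass single-row tables for the vector reading.

## The synthetic collection

`make_collection()` generates a DOC-format corpus with Zipf-distributed
background vocabulary (exponent 1.1, so the median-based key-relevance
rule sees realistic document-frequency skew), heavy-tailed repository
sizes (a few repositories hold most records, as in real dataset dumps),
and planted topic clusters. Each topic yields one query of four terms;
planted relevant documents contain all four (grade 2), partially relevant
ones three (grade 1), and grades are derived from the generated documents
themselves, so accidental matches are graded honestly. All vocabulary
terms are fixed points of the normalizer, making manifest terms and index
terms identical. `make_embeddings()` places each topic on an orthogonal
centroid with members at cosine ≥ 0.9, so nearest-neighbour expectations
are exact by construction. `make_qrels()` can mark a fraction of judgments
as -1 to exercise the inferred estimators. Everything is byte-identical
under a fixed seed.

What passing on this fixture shows — and does not. The fixture is
separable by design: relevant documents contain every query term. Tests
therefore verify the *mechanics* (correct formulas, orderings,
estimators, identities), not retrieval quality on real data, where
vocabulary mismatch, noisy metadata and judgment depth dominate. Default
test problem sizes (tens to a few hundred documents, 2–3 topics) were
chosen as the smallest collections on which every property is
non-degenerate.

## Numerical and degenerate-input choices

* Single-term queries are degenerate for the key weight (`2L - 2 = 0`); we
  return the minimum useful weight `c · 1` with a warning.
* Tie-breaks use `eps = 1e-6` for the within-bin scaling and zero-raw
  fallback; any strictly positive value below 1 works since bins are at
  least 1 apart under integer weights.
* Cosines against zero-norm vectors are defined as 0.
* Duplicate judgments keep the last with a warning; duplicate embedding
  rows likewise; duplicate documents within a query are an error.
* Run files re-derive ranks from scores on read; stored ranks that
  disagree lose, with a warning. Scores are written at 10 significant
  digits so write/read round-trips preserve orderings.
* All randomness (generation, subsampling, embedding and classifier
  training) flows from explicit integer seeds.

## Known limitations

* The RTRL bin structure makes scores interpretable but coarse; with
  non-integer expansion weights, bins are no longer integers and the final
  ordering is by bin + tie-break rather than strict lexicographic bins.
* The CBOW trainer is a reference implementation in plain R — fine for
  fixture-scale vocabularies, not for production corpora.
* The inferred-NDCG ideal list rounds scaled grade counts to integers,
  adding small noise at low sampling rates.
* The shipped category descriptors are a seed list; recall of the
  string-matching classifier depends entirely on extending it.
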