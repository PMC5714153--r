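# datamedrank

A retrieval engine for biomedical **dataset records** — the kind of
metadata-only documents served by dataset discovery indexes such as
DataMed/bioCADDIE, where each record is a `<DOC>` block holding an
identifier, a title, a repository name and a JSON metadata payload. Casual
users search such indexes with short free-text queries ("Find protein
sequencing data related to bacterial chemotaxis across all databases"),
which is exactly the regime where heavily tuned probabilistic rankers are
at their most fragile. This package is aimed at people building or studying
dataset search: it provides the full pipeline plus the evaluation stack used
to score such systems against graded, incompletely judged relevance pools.

## What it implements

**Query normalization.** Greek letters to literal names, tokenization,
stopword removal (general list plus search-intent words like *find*,
*data*, *across*), original Porter stemming, 20-character truncation,
numeric tokens replaced by `_number_`.

**Embedding-based query expansion.** Each query term is expanded with its
*k* nearest neighbours by cosine in a word-embedding space, weighted by the
similarity. Model 1 treats all terms alike; model 2 multiplies the weight
of every non-key-relevant original term and its expansions by `1 - l`
(loss factor, default `l = 0.01`).

**The RTRL similarity measure** (robust term relevance logic). Query terms
split into *relevant* and *key-relevant* by collection document frequency:
a term is key-relevant when its document frequency is at or below the
median of the query's terms. Each query term present in a document
contributes `w_d + w_q`:

- `w_d = 1` if the term occurs once in the document, `2` if it occurs more;
- `w_q = 1` for relevant terms and `w_q'' = c (2L - 2)` for key-relevant
  terms, where `L` is the query length and `c >= 1` a gain.

`c (2L - 2)` is the smallest key weight for which a document containing all
`k ~ L/2` key-relevant terms (even at single occurrence) can never be
outranked by a document missing one of them, however strong its other
matches — documents are effectively ranked into integer *relevance bins*.
Inside a bin, a tf·idf tie-break (`tf = 0.5 + 0.5 f_td / max_t f_td`,
`idf = log(N / n_t)`, scaled into (0, 1] within the bin) orders documents
without ever crossing bin boundaries.

**A DFR baseline** (InL2): per-term contribution
`tfn/(tfn+1) · log2((N+1)/(n_t+0.5))` with
`tfn = f_td · log2(1 + c_norm · avg_len/len_d)`.

**Category boosting.** Queries and datasets are classified into the 11
UniProt curator categories plus *Clinical trial* (string matching on
1-grams and 2/3-skip-2-grams against descriptor phrases, clinical-trial
keyword rules, and an optional trained multi-label MLP classifier over an
LSA document embedding). Datasets in the top half of a ranking whose
classes intersect the query's classes get their score multiplied by
`1 + g` (default `g = 0.10`).

**Rank fusion.** `alpha · runA + (1 - alpha) · runB` after per-query
min-max normalization.

**Evaluation.** Graded qrels (2 relevant / 1 partial / 0 not relevant /
-1 pooled-but-unjudged), precision at 10 with and without partial
relevance, NDCG@10, inferred AP and inferred NDCG with three
unjudged-document policies (`sampled`, `as-nonrelevant`, `removed`), and
the unanimous improvement ratio (UIR) for multi-measure system comparison.

The five preset pipelines mirror the classic run configurations:
`sibtex-1` (DFR), `sibtex-2` (+ expansion model 1 + boost), `sibtex-3`
(+ expansion model 2 + boost), `sibtex-4` (RTRL + boost), `sibtex-5`
(fusion of 3 and 4).

## Worked example

Everything below runs self-contained on a seeded synthetic collection (200
records, 3 planted topics, one query per topic, graded qrels derived from
the planted terms):

```r
library(datamedrank)

col   <- make_collection(synthetic_spec(seed = 42))
idx   <- build_index(col$records)
emb   <- make_embeddings(col)
qrels <- make_qrels(col)

res <- run_pipeline(idx, col$queries, pipeline_config("sibtex-5"),
                    embeddings = emb, records = col$records, qrels = qrels)
head(res$run, 5)
#>   query_id doc_id rank     score
#> 1       T1 557423    1 0.9740379
#> 2       T1 482042    2 0.9479643
#> 3       T1 524155    3 0.9295136
#> 4       T1 908868    4 0.9274813
#> 5       T1 459398    5 0.9029318
res$report
#> <metric_report 'sibtex-5' | unjudged: sampled | 3 queries>
#>     infAP   infNDCG  P10_plus P10_minus    NDCG10
#>         1         1         1         1         1
```

The run is a TREC-style ranking (fused scores lie in [0, 1] after min-max
normalization); the report shows every official measure at its ceiling
because the synthetic fixture is constructed to be separable — planted
relevant documents contain all four query terms, so a correct pipeline
should retrieve them perfectly. On real corpora, scores are whatever the
data gives.

A command-line front end with `synth`, `index`, `search`, `fuse`, `eval`
and `run` subcommands lives at `inst/cli/datamed-rank.R`
(`system.file("cli", "datamed-rank.R", package = "datamedrank")`) and can
drive the same pipeline end to end on user-supplied corpus, qrels and
embedding files.

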