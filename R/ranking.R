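# The RTRL ("robust term relevance logic") similarity measure and an InL2
# divergence-from-randomness baseline.
#
# RTRL ranks documents into integer relevance bins. Each query term present
# in a document contributes wd + wq, where wd reflects document relevance
# (wd' for a single occurrence, wd'' = 2 wd' for repeated occurrences) and wq
# reflects query relevance (wq' for relevant terms, wq'' = c(2L - 2) for
# key-relevant terms). The key weight wq'' is the smallest weight for which a
# document holding all k key-relevant terms at low document relevance can
# never be outranked by one missing a key term, assuming k is about L/2.
# Documents sharing a bin are ordered by a tf-idf tie-break scaled into
# (0, 1] so it can never cross bin boundaries.

#' RTRL weight parameters
#'
#' @param c key-term gain (>= 1); scales the key-relevant query weight.
#' @param wd_low weight of a term occurring once in a document (wd').
#' @param wd_high weight of a term occurring more than once (wd'', default
#'   twice `wd_low`).
#' @param wq_low weight of a merely relevant query term (wq').
#' @param idf_base logarithm base for the tie-break idf (default natural).
#' @param eps within-bin scaling offset keeping tie-breaks strictly below 1.
#' @return an object of class `rtrl_params`.
#' @export
rtrl_params <- function(c = 1, wd_low = 1, wd_high = 2 * wd_low,
                        wq_low = 1, idf_base = exp(1), eps = 1e-6) {
  stopifnot(c >= 1, wd_low > 0, wd_high >= wd_low, wq_low > 0)
  structure(list(c = c, wd_low = wd_low, wd_high = wd_high, wq_low = wq_low,
                 idf_base = idf_base, eps = eps),
            class = "rtrl_params")
}

#' Key-relevant query weight wq''
#'
#' Returns `c * (2L - 2)`: the minimal key weight (scaled by the gain `c`)
#' under unit low weights, a doubled high document weight, and k = L/2
#' key-relevant terms. At these defaults the worst-case dominance inequality
#' k(wd' + wq'') >= (k-1)(wd'' + wq'') + (L-k)(wd'' + wq') holds with margin
#' exactly zero for c = 1.
#'
#' @param L number of (original, non-stopword) query terms.
#' @param params an [rtrl_params()].
#' @return the key-relevant query weight.
#' @export
key_weight <- function(L, params = rtrl_params()) {
  if (L < 2) {
    warning("degenerate query of length ", L,
            "; using the minimum key weight")
    return(params$c * max(2 * L - 2, 1))
  }
  params$c * (2 * L - 2)
}

#' Document-relevance weight wd
#'
#' Two-level step function of the within-document count: `wd_low` for a
#' single occurrence, `wd_high` for more than one.
#'
#' @param ftd within-document occurrence count (>= 1).
#' @param params an [rtrl_params()].
#' @return numeric vector of document weights.
#' @export
doc_weight <- function(ftd, params = rtrl_params()) {
  if (any(ftd <= 0)) stop("doc_weight is defined only for present terms (ftd >= 1)")
  ifelse(ftd > 1, params$wd_high, params$wd_low)
}

#' Query-relevance weight wq
#'
#' @param relevance_class `"relevant"` or `"key-relevant"` (vectorized).
#' @param L number of original query terms.
#' @param params an [rtrl_params()].
#' @return numeric vector of query weights.
#' @export
query_weight <- function(relevance_class, L, params = rtrl_params()) {
  ifelse(relevance_class == "key-relevant",
         key_weight(L, params), params$wq_low)
}

# per-candidate-document bin scores for a weighted query
.rtrl_bin_scores <- function(query, index, params) {
  L <- attr(query, "L")
  scores <- numeric(0)
  for (i in seq_len(nrow(query))) {
    p <- index$postings[[query$term[i]]]
    if (is.null(p) || !length(p)) next
    wq <- query_weight(query$relevance_class[i], L, params)
    contrib <- query$weight[i] * (doc_weight(p, params) + wq)
    seen <- names(p) %in% names(scores)
    scores[names(p)[seen]] <- scores[names(p)[seen]] + contrib[seen]
    scores <- c(scores, contrib[!seen])
  }
  scores
}

#' RTRL bin score of one document
#'
#' Sum over the query terms present in the document of
#' `weight * (wd + wq)`, where `weight` is the expansion weight (1 for
#' original terms), so the formula reduces to the plain sum for unexpanded
#' queries. Absent terms contribute nothing.
#'
#' @param doc_id document identifier.
#' @param query a `weighted_query`.
#' @param index an `inverted_index`.
#' @param params an [rtrl_params()].
#' @return the bin score (0 when no query term occurs in the document).
#' @export
rtrl_bin_score <- function(doc_id, query, index, params = rtrl_params()) {
  L <- attr(query, "L")
  total <- 0
  for (i in seq_len(nrow(query))) {
    ftd <- unname(index$postings[[query$term[i]]][doc_id])
    if (is.null(ftd) || is.na(ftd)) next
    wq <- query_weight(query$relevance_class[i], L, params)
    total <- total + query$weight[i] * (doc_weight(ftd, params) + wq)
  }
  total
}

#' Within-bin tf-idf tie-break
#'
#' For documents sharing a bin score, computes per document the raw sum over
#' query terms present of `tf(t, d) * idf(t)` with
#' `tf = 0.5 + 0.5 f(t,d) / max_t' f(t',d)` and `idf = log(N / n_t)`, then
#' scales the raw values by the bin maximum (plus `eps`) so every tie-break
#' lies strictly in (0, 1) and can never cross a bin boundary. A bin whose
#' members all have raw value 0 receives the uniform tie-break `eps`.
#'
#' @param doc_ids documents sharing one bin score.
#' @param query a `weighted_query`.
#' @param index an `inverted_index`.
#' @param params an [rtrl_params()].
#' @return named numeric vector of tie-break values in (0, 1).
#' @export
bin_tiebreak <- function(doc_ids, query, index, params = rtrl_params()) {
  raw <- stats::setNames(numeric(length(doc_ids)), doc_ids)
  terms <- unique(query$term)
  for (t in terms) {
    p <- index$postings[[t]]
    if (is.null(p)) next
    nt <- length(p)
    idf <- log(index$N / nt, base = params$idf_base)
    present <- intersect(doc_ids, names(p))
    if (!length(present)) next
    tf <- 0.5 + 0.5 * p[present] / pmax(index$doc_maxtf[present], 1L)
    raw[present] <- raw[present] + tf * idf
  }
  mx <- max(raw)
  if (mx <= 0) {
    return(stats::setNames(rep(params$eps, length(doc_ids)), doc_ids))
  }
  raw / (mx + params$eps) + params$eps * (raw <= 0)
}

#' Rank documents with the RTRL measure
#'
#' Candidates are the union of the postings of the query terms. Documents are
#' ordered by decreasing bin score, then decreasing within-bin tf-idf
#' tie-break, then doc_id; the final score is bin score + tie-break.
#'
#' @param query a `weighted_query` (see [expand_query()]).
#' @param index an `inverted_index`.
#' @param params an [rtrl_params()].
#' @param cutoff maximum documents returned per query (default 1000).
#' @param query_id label used in the returned run (default "Q1").
#' @return a [ranked_run()] data.frame (empty if no query term is indexed).
#' @export
rtrl_rank <- function(query, index, params = rtrl_params(), cutoff = 1000L,
                      query_id = "Q1") {
  bins <- .rtrl_bin_scores(query, index, params)
  if (!length(bins)) return(ranked_run(tag = "rtrl"))
  tie <- numeric(length(bins))
  names(tie) <- names(bins)
  for (b in unique(bins)) {
    members <- names(bins)[bins == b]
    tie[members] <- bin_tiebreak(members, query, index, params)
  }
  final <- bins + tie
  ord <- order(-final, names(final), method = "radix")
  keep <- ord[seq_len(min(cutoff, length(ord)))]
  ranked_run(rep(query_id, length(keep)), names(final)[keep], final[keep],
             tag = "rtrl")
}

#' Rank documents with an InL2 divergence-from-randomness baseline
#'
#' Per query term, the normalized frequency is
#' `tfn = f(t,d) * log2(1 + c_norm * avg_len / len(d))` and the contribution
#' is `weight * tfn / (tfn + 1) * log2((N + 1) / (n_t + 0.5))`, where
#' `weight` is the query-term weight (expansion weight; 1 for original
#' terms). Documented operating points for the frequency normalization
#' parameter are `c_norm = 1` and `c_norm = 33`.
#'
#' @param query a `weighted_query`.
#' @param index an `inverted_index`.
#' @param c_norm term-frequency normalization parameter (> 0).
#' @param cutoff maximum documents returned.
#' @param query_id label used in the returned run.
#' @return a [ranked_run()] data.frame.
#' @export
dfr_rank <- function(query, index, c_norm = 1, cutoff = 1000L,
                     query_id = "Q1") {
  stopifnot(c_norm > 0)
  scores <- numeric(0)
  for (i in seq_len(nrow(query))) {
    p <- index$postings[[query$term[i]]]
    if (is.null(p) || !length(p)) next
    nt <- length(p)
    tfn <- p * log2(1 + c_norm * index$avg_len / index$doc_len[names(p)])
    contrib <- query$weight[i] * (tfn / (tfn + 1)) *
      log2((index$N + 1) / (nt + 0.5))
    seen <- names(p) %in% names(scores)
    scores[names(p)[seen]] <- scores[names(p)[seen]] + contrib[seen]
    scores <- c(scores, contrib[!seen])
  }
  if (!length(scores)) return(ranked_run(tag = "dfr"))
  ord <- order(-scores, names(scores), method = "radix")
  keep <- ord[seq_len(min(cutoff, length(ord)))]
  ranked_run(rep(query_id, length(keep)), names(scores)[keep], scores[keep],
             tag = "dfr")
}
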