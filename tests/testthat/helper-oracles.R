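# Independent oracles used across the test files. These deliberately avoid
# the package's index/ranking code paths: they work from raw token lists and
# the scoring equations directly, with naive loops.

# terms that pass through normalize_text() unchanged, so token lists made of
# them line up with index terms
oracle_vocab <- function(n) sprintf("t%02d", seq_len(n))

oracle_records <- function(doc_tokens) {
  lapply(names(doc_tokens), function(id) {
    dataset_record(id, title = paste(doc_tokens[[id]], collapse = " "))
  })
}

# Brute-force RTRL scorer from the weighting equations, computed straight
# off the token lists. Returns a data.frame ordered like rtrl_rank orders.
oracle_rtrl <- function(doc_tokens, query_df, c_gain = 1, eps = 1e-6) {
  N <- length(doc_tokens)
  L <- attr(query_df, "L")
  wq2 <- c_gain * (2 * L - 2)
  nt <- function(t) sum(vapply(doc_tokens, function(d) t %in% d, logical(1)))
  bins <- sapply(names(doc_tokens), function(id) {
    d <- doc_tokens[[id]]
    s <- 0
    for (i in seq_len(nrow(query_df))) {
      t <- query_df$term[i]
      ftd <- sum(d == t)
      if (ftd == 0) next
      wd <- if (ftd > 1) 2 else 1
      wq <- if (query_df$relevance_class[i] == "key-relevant") wq2 else 1
      s <- s + query_df$weight[i] * (wd + wq)
    }
    s
  })
  cand <- names(bins)[bins > 0]
  tie <- stats::setNames(numeric(length(cand)), cand)
  for (b in unique(bins[cand])) {
    members <- cand[bins[cand] == b]
    raw <- stats::setNames(numeric(length(members)), members)
    for (id in members) {
      d <- doc_tokens[[id]]
      maxtf <- max(table(d))
      for (t in unique(query_df$term)) {
        ftd <- sum(d == t)
        if (ftd == 0) next
        raw[id] <- raw[id] +
          (0.5 + 0.5 * ftd / maxtf) * log(N / nt(t))
      }
    }
    mx <- max(raw)
    if (mx <= 0) {
      tie[members] <- eps
    } else {
      tie[members] <- raw / (mx + eps) + eps * (raw <= 0)
    }
  }
  final <- bins[cand] + tie
  ord <- order(-final, cand, method = "radix")
  data.frame(doc_id = cand[ord], bin = unname(bins[cand][ord]),
             final = unname(final[ord]), stringsAsFactors = FALSE)
}

# median document-frequency rule, recomputed by hand
oracle_key_classes <- function(terms, doc_tokens) {
  dfs <- vapply(terms, function(t) {
    sum(vapply(doc_tokens, function(d) t %in% d, logical(1)))
  }, numeric(1))
  ifelse(dfs <= stats::median(dfs), "key-relevant", "relevant")
}

# hand-built weighted query (originals only unless expansion rows given)
oracle_query <- function(terms, classes, weights = rep(1, length(terms)),
                         origin = rep("original", length(terms)),
                         L = sum(origin == "original")) {
  df <- data.frame(term = terms, weight = weights, origin = origin,
                   parent = terms, relevance_class = classes,
                   stringsAsFactors = FALSE)
  attr(df, "L") <- L
  class(df) <- c("weighted_query", "data.frame")
  df
}

# exact average precision: unjudged/unpooled nonrelevant, denominator =
# total relevant in the qrels
oracle_ap <- function(grades_in_rank_order, n_rel_total, min_rel = 1L) {
  rel <- !is.na(grades_in_rank_order) & grades_in_rank_order >= min_rel
  if (n_rel_total == 0) return(NA_real_)
  if (!any(rel)) return(0)
  sum(cumsum(rel)[rel] / which(rel)) / n_rel_total
}

# exact NDCG with linear grade gain over the full ranking
oracle_ndcg <- function(grades_in_rank_order, qrels_grades, k = NULL) {
  g <- ifelse(is.na(grades_in_rank_order) | grades_in_rank_order < 0, 0,
              grades_in_rank_order)
  ideal <- sort(qrels_grades[qrels_grades > 0], decreasing = TRUE)
  if (!length(ideal)) return(NA_real_)
  if (!is.null(k)) {
    g <- g[seq_len(min(k, length(g)))]
    ideal <- ideal[seq_len(min(k, length(ideal)))]
  }
  dcg <- function(v) sum(v / log2(seq_along(v) + 1))
  dcg(g) / dcg(ideal)
}

# random small corpus + query for oracle comparisons
random_oracle_case <- function(seed, max_docs = 50, max_terms = 30,
                               with_expansion = FALSE) {
  set.seed(seed)
  vocab <- oracle_vocab(sample(5:max_terms, 1))
  n <- sample(3:max_docs, 1)
  doc_tokens <- stats::setNames(lapply(seq_len(n), function(i) {
    sample(vocab, max(1, stats::rpois(1, 12)), replace = TRUE)
  }), sprintf("d%03d", seq_len(n)))
  qterms <- sample(vocab, sample(2:min(6, length(vocab)), 1))
  classes <- oracle_key_classes(qterms, doc_tokens)
  q <- oracle_query(qterms, classes)
  if (with_expansion) {
    extra <- setdiff(vocab, qterms)
    if (length(extra)) {
      ne <- min(length(extra), 3)
      eterms <- sample(extra, ne)
      parent_idx <- sample(seq_along(qterms), ne, replace = TRUE)
      ex <- data.frame(term = eterms,
                       weight = round(stats::runif(ne, 0.1, 0.95), 3),
                       origin = "expanded", parent = qterms[parent_idx],
                       relevance_class = classes[parent_idx],
                       stringsAsFactors = FALSE)
      L <- attr(q, "L")
      q <- rbind(q, ex)
      attr(q, "L") <- L
      class(q) <- c("weighted_query", "data.frame")
    }
  }
  list(doc_tokens = doc_tokens, query = q)
}

# collection with document frequencies tcell 6, multipl 5, homeostasi 2,
# sclerosi 1 among 10 documents; yields bin scores 15 / 12 / 2 for d01-d03
rtrl_fixture_acc <- function() {
  toks <- c(
    list(d01 = c("homeostasi", "sclerosi", "sclerosi", "f01"),
         d02 = c("tcell", "tcell", "multipl", "homeostasi"),
         d03 = "tcell"),
    stats::setNames(lapply(1:4, function(i) c("tcell", "multipl")),
                    sprintf("d%02d", 4:7)),
    list(d08 = "f01", d09 = "f02", d10 = c("f01", "f03"))
  )
  idx <- build_index(oracle_records(toks))
  wq <- expand_query(c("tcell", "multipl", "homeostasi", "sclerosi"),
                     index = idx)
  list(toks = toks, idx = idx, wq = wq)
}
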