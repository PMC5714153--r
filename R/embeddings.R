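# Embedding-space utilities: cosine similarity, exact nearest-neighbour
# lookup, and a small CBOW trainer with negative sampling for building
# embeddings from tokenized text. The trainer exists so the whole pipeline
# can run self-contained on synthetic corpora; production embeddings are
# expected to be trained externally and loaded with read_embeddings().

#' Cosine similarity between one term and all rows of an embedding matrix
#' @param emb numeric matrix, rows are term vectors.
#' @param vec a single vector of the same dimensionality.
#' @return named numeric vector of cosines (0 for zero-norm rows).
#' @export
cosine_similarities <- function(emb, vec) {
  vnorm <- sqrt(sum(vec^2))
  rnorms <- sqrt(rowSums(emb^2))
  sims <- as.numeric(emb %*% vec)
  denom <- rnorms * vnorm
  sims <- ifelse(denom > 0, sims / denom, 0)
  stats::setNames(sims, rownames(emb))
}

#' Exact k-nearest neighbours of a term in an embedding space
#'
#' Exhaustive cosine scan over the vocabulary. Ties at the k-th position are
#' broken lexicographically so the result is deterministic.
#'
#' @param emb embedding matrix with term rownames.
#' @param term a term present in the vocabulary.
#' @param k number of neighbours.
#' @param exclude additional terms to exclude (the term itself is always
#'   excluded).
#' @param min_sim optional minimum cosine; neighbours below it are dropped.
#' @return data.frame with columns `term` and `sim`, ordered by decreasing
#'   similarity.
#' @export
nearest_terms <- function(emb, term, k, exclude = character(0), min_sim = 0) {
  if (!term %in% rownames(emb)) {
    return(data.frame(term = character(0), sim = numeric(0)))
  }
  sims <- cosine_similarities(emb, emb[term, ])
  sims <- sims[setdiff(names(sims), c(term, exclude))]
  if (k > length(sims)) {
    warning("k = ", k, " exceeds available vocabulary (", length(sims),
            "); returning all neighbours")
    k <- length(sims)
  }
  ord <- order(-sims, names(sims), method = "radix")
  out <- data.frame(term = names(sims)[ord], sim = as.numeric(sims[ord]),
                    stringsAsFactors = FALSE)
  out <- out[seq_len(min(k, nrow(out))), , drop = FALSE]
  if (min_sim > 0) out <- out[out$sim >= min_sim, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Train CBOW word embeddings with negative sampling
#'
#' A compact continuous bag-of-words trainer: each position's centre word is
#' predicted from the mean of its context vectors within `window`, with
#' `negative` noise words sampled from the unigram distribution raised to
#' 3/4. Intended for small synthetic corpora; all randomness flows from
#' `seed`.
#'
#' @param docs list of character vectors (tokenized documents).
#' @param dim embedding dimensionality (production default in the field is
#'   200; tests use far less).
#' @param window one-sided context window size (default 5).
#' @param seed integer seed; fixed seed gives identical vectors.
#' @param epochs training passes over the corpus.
#' @param negative negative samples per position.
#' @param learning_rate initial SGD step size, linearly decayed.
#' @param min_count drop words rarer than this.
#' @return embedding matrix with term rownames.
#' @export
train_embeddings <- function(docs, dim = 50, window = 5, seed = 1L,
                             epochs = 20, negative = 5,
                             learning_rate = 0.05, min_count = 1L) {
  stopifnot(dim >= 2)
  docs <- lapply(docs, as.character)
  total <- sum(lengths(docs))
  if (total < window + 1) {
    stop("corpus (", total, " tokens) is smaller than the context window")
  }
  counts <- table(unlist(docs))
  vocab <- names(counts)[counts >= min_count]
  vocab <- sort(vocab)
  V <- length(vocab)
  if (V < 2L) stop("vocabulary too small to train embeddings")
  wid <- stats::setNames(seq_len(V), vocab)
  noise <- as.numeric(counts[vocab])^0.75
  noise <- noise / sum(noise)

  set.seed(as.integer(seed))
  W_in <- matrix(stats::runif(V * dim, -0.5 / dim, 0.5 / dim), nrow = V)
  W_out <- matrix(0, nrow = V, ncol = dim)

  ids <- lapply(docs, function(d) unname(wid[d[d %in% vocab]]))
  ids <- ids[lengths(ids) >= 2L]
  step <- 0L
  total_steps <- max(1L, epochs * sum(lengths(ids)))
  for (ep in seq_len(epochs)) {
    for (doc in ids) {
      n <- length(doc)
      for (pos in seq_len(n)) {
        lo <- max(1L, pos - window)
        hi <- min(n, pos + window)
        ctx <- doc[setdiff(lo:hi, pos)]
        if (!length(ctx)) next
        step <- step + 1L
        lr <- learning_rate * max(1e-4, 1 - step / total_steps)
        h <- colMeans(W_in[ctx, , drop = FALSE])
        targets <- c(doc[pos],
                     sample.int(V, negative, replace = TRUE, prob = noise))
        labels <- c(1, numeric(negative))
        eh <- numeric(dim)
        for (j in seq_along(targets)) {
          tgt <- targets[j]
          f <- 1 / (1 + exp(-sum(h * W_out[tgt, ])))
          g <- lr * (labels[j] - f)
          eh <- eh + g * W_out[tgt, ]
          W_out[tgt, ] <- W_out[tgt, ] + g * h
        }
        W_in[ctx, ] <- W_in[ctx, , drop = FALSE] +
          matrix(eh / length(ctx), nrow = length(ctx), ncol = dim, byrow = TRUE)
      }
    }
  }
  rownames(W_in) <- vocab
  W_in
}
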