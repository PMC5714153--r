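# Query expansion by k-nearest neighbours in a word-embedding space, and the
# key-relevance classification that both expansion model 2 and the RTRL
# ranking weights depend on.

#' Classify query terms as relevant or key-relevant
#'
#' A term is *key-relevant* when its collection document frequency is at or
#' below the median document frequency of the query's terms (even-count
#' median = mean of the middle pair); the remaining terms are *relevant*.
#' Terms absent from the index (document frequency 0) are always
#' key-relevant. Rare terms carry the query's discriminative content, which
#' is why they receive the large bin weight in the RTRL measure.
#'
#' @param terms character vector of normalized original query terms.
#' @param index an `inverted_index`.
#' @return named character vector mapping each term to `"relevant"` or
#'   `"key-relevant"`.
#' @export
classify_key_relevance <- function(terms, index) {
  terms <- unique(as.character(terms))
  if (!length(terms)) stop("cannot classify an empty term list")
  dfs <- vapply(terms, function(t) term_stats(index, t)$doc_freq, integer(1))
  med <- stats::median(dfs)
  stats::setNames(ifelse(dfs <= med, "key-relevant", "relevant"), terms)
}

#' Build a weighted query, optionally expanded in an embedding space
#'
#' Each original term receives unit weight and contributes its `k` nearest
#' vocabulary terms by cosine similarity (excluding itself and the other
#' original terms), each weighted by that similarity. Retrieved neighbours
#' are passed through [normalize_text()] so they match index terms;
#' duplicates keep the maximum weight. Under model 2, every original term
#' that is not key-relevant — and all its expansions — has its weight reduced
#' by the loss factor `l` (multiplied by `1 - l`; set
#' `loss_mode = "multiply"` to multiply by `l` instead). Expansions inherit
#' the relevance class of their parent. Out-of-vocabulary terms stay in the
#' query unexpanded.
#'
#' @param query character vector of normalized query tokens.
#' @param space embedding matrix with term rownames (may be `NULL` when
#'   `k = 0`).
#' @param k neighbours per term (0 disables expansion; the official
#'   configuration used 10).
#' @param model expansion model, 1 or 2.
#' @param l loss factor in \[0, 1\] (model 2 only; the official value is
#'   0.01).
#' @param index an `inverted_index`, used to classify key relevance.
#' @param min_sim optional cosine cut-off below which neighbours are dropped.
#' @param loss_mode `"reduce"` (weight * (1 - l)) or `"multiply"`
#'   (weight * l).
#' @param config a [stopword_config()] for normalizing retrieved neighbours.
#' @return a `weighted_query` data.frame with columns term, weight, origin
#'   (original/expanded), parent, relevance_class, and attribute `L` (number
#'   of original terms).
#' @export
expand_query <- function(query, space = NULL, k = 0L, model = 1L, l = 0.01,
                         index, min_sim = 0, loss_mode = c("reduce", "multiply"),
                         config = stopword_config()) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(k >= 0L, l >= 0, l <= 1, model %in% c(1L, 2L))
  query <- unique(as.character(query))
  if (!length(query)) {
    out <- data.frame(term = character(0), weight = numeric(0),
                      origin = character(0), parent = character(0),
                      relevance_class = character(0), stringsAsFactors = FALSE)
    attr(out, "L") <- 0L
    class(out) <- c("weighted_query", "data.frame")
    return(out)
  }
  classes <- classify_key_relevance(query, index)

  rows <- data.frame(term = query, weight = 1, origin = "original",
                     parent = query, relevance_class = unname(classes[query]),
                     stringsAsFactors = FALSE)
  if (k > 0L && !is.null(space)) {
    for (q in query) {
      nb <- nearest_terms(space, q, k, exclude = query, min_sim = min_sim)
      if (!nrow(nb)) next
      for (i in seq_len(nrow(nb))) {
        norm <- normalize_text(nb$term[i], config = config, mode = "corpus")
        for (t in setdiff(norm, query)) {
          rows <- rbind(rows, data.frame(
            term = t, weight = nb$sim[i], origin = "expanded", parent = q,
            relevance_class = unname(classes[[q]]), stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (model == 2L && l > 0) {
    penalized <- rows$relevance_class != "key-relevant"
    factor <- if (loss_mode == "reduce") 1 - l else l
    rows$weight[penalized] <- rows$weight[penalized] * factor
  }
  # merge duplicate expansion terms, keeping the maximum weight
  rows <- rows[order(rows$origin != "original", -rows$weight, rows$term,
                     method = "radix"), , drop = FALSE]
  rows <- rows[!duplicated(rows$term), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "L") <- length(query)
  class(rows) <- c("weighted_query", "data.frame")
  rows
}

#' @export
print.weighted_query <- function(x, ...) {
  cat("<weighted_query> L =", attr(x, "L"), "original terms,",
      sum(x$origin == "expanded"), "expansions\n")
  print.data.frame(x, ...)
  invisible(x)
}
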