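# Inverted index over normalized dataset records. Holds exactly the
# statistics the ranking formulas need: within-document term counts f(t,d),
# collection document frequency n_t, document lengths, N and the average
# length. Titles and flattened metadata are pooled into a single field.

#' Build an inverted index
#'
#' Normalizes each record (title and flattened metadata concatenated, corpus
#' mode) and accumulates postings. Deterministic for a fixed record order.
#'
#' @param records list of [dataset_record()] objects.
#' @param config a [stopword_config()].
#' @return an object of class `inverted_index` with elements `postings`
#'   (term -> named integer vector of per-document counts), `doc_freq`,
#'   `doc_len`, `doc_maxtf` (largest single-term count per document), `N` and
#'   `avg_len`.
#' @export
build_index <- function(records, config = stopword_config()) {
  idx <- empty_index()
  index_add(idx, records, config)
}

#' Create an empty index
#' @return an `inverted_index` with no documents.
#' @export
empty_index <- function() {
  structure(list(postings = list(), doc_freq = integer(0),
                 doc_len = integer(0), doc_maxtf = integer(0),
                 N = 0L, avg_len = 0),
            class = "inverted_index")
}

#' Add records to an existing index
#'
#' Incremental indexing: adding records in batches yields the same index as a
#' one-shot build over the concatenated record list.
#'
#' @param index an `inverted_index`.
#' @param records list of [dataset_record()] objects to add.
#' @param config a [stopword_config()].
#' @return the grown `inverted_index`.
#' @export
index_add <- function(index, records, config = stopword_config()) {
  stopifnot(inherits(index, "inverted_index"))
  postings <- index$postings
  doc_len <- index$doc_len
  doc_maxtf <- index$doc_maxtf
  for (rec in records) {
    id <- rec$doc_id
    if (id %in% names(doc_len)) stop("duplicate doc_id: ", id)
    tokens <- normalize_text(c(rec$title, rec$metadata_text),
                             config = config, mode = "corpus")
    doc_len[[id]] <- length(tokens)
    if (length(tokens)) {
      counts <- table(tokens)
      doc_maxtf[[id]] <- max(counts)
      for (t in names(counts)) {
        if (is.null(postings[[t]])) {
          postings[[t]] <- stats::setNames(as.integer(counts[[t]]), id)
        } else {
          postings[[t]][[id]] <- as.integer(counts[[t]])
        }
      }
    } else {
      doc_maxtf[[id]] <- 0L
    }
  }
  N <- length(doc_len)
  structure(list(postings = postings,
                 doc_freq = vapply(postings, length, integer(1)),
                 doc_len = doc_len, doc_maxtf = doc_maxtf, N = N,
                 avg_len = if (N) mean(doc_len) else 0),
            class = "inverted_index")
}

#' @export
print.inverted_index <- function(x, ...) {
  cat("<inverted_index> N =", x$N, "docs,", length(x$postings),
      "terms, avg_len =", round(x$avg_len, 2), "\n")
  invisible(x)
}

#' Per-term collection statistics
#'
#' @param index an `inverted_index`.
#' @param term a normalized term.
#' @return list with `term`, `postings` (named integer vector doc -> f(t,d);
#'   empty for unseen terms), `doc_freq` (n_t) and `N`.
#' @export
term_stats <- function(index, term) {
  stopifnot(inherits(index, "inverted_index"))
  p <- index$postings[[term]]
  if (is.null(p)) p <- stats::setNames(integer(0), character(0))
  list(term = term, postings = p, doc_freq = length(p), N = index$N)
}
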