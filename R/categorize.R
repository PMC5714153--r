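# Query and dataset categorization against the UniProt topic scheme (11
# curator categories plus Clinical trial), and the rank boosting that
# promotes category-matching datasets in the top half of a result list.

.category_classes <- c(
  "Expression", "Family & Domains", "Function", "Interaction", "Names",
  "Pathology & Biotech", "PTM/processing", "Sequences", "Structure",
  "Subcellular location", "Unclassified", "Clinical trial"
)

.clinical_query_keywords <- c("inclusion", "exclusion", "criteria",
                              "patients", "subjects", "stage", "duration",
                              "study")
.clinical_doc_keywords <- c("clinical", "trial", "clinicaltrial")

#' Load a category scheme
#'
#' Reads a two-column `class<TAB>descriptor` file mapping each category to
#' its descriptor phrases (category names plus annotation qualifiers).
#' Descriptors are normalized (corpus mode, stemmed) so matching happens on
#' stems. The packaged default scheme seeds the 11 UniProt curator
#' categories plus Clinical trial with a starter qualifier list; it is meant
#' to be extended by the user.
#'
#' @param path scheme file; default is the scheme shipped with the package.
#' @param config a [stopword_config()].
#' @return an object of class `category_scheme`: named list class -> character
#'   vector of normalized descriptor grams.
#' @export
read_category_scheme <- function(path = system.file("extdata",
                                                    "uniprot_categories.tsv",
                                                    package = "datamedrank"),
                                 config = stopword_config()) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("scheme line ", bad[1], " is not class<TAB>descriptor")
  cls <- vapply(parts, `[`, character(1), 1L)
  desc <- vapply(parts, `[`, character(1), 2L)
  norm <- vapply(desc, function(d) {
    paste(normalize_text(d, config = config, mode = "corpus"), collapse = " ")
  }, character(1))
  keep <- nzchar(norm)
  scheme <- split(unname(norm[keep]), cls[keep])
  scheme <- lapply(scheme, unique)
  structure(scheme, class = "category_scheme")
}

#' Classify a query into dataset categories
#'
#' Extracts 1-grams, 2-skip-2-grams and 3-skip-2-grams from the normalized
#' query (general stopwords removed, stemmed, but search-intent words kept so
#' constraint words like "data" can participate in qualifier grams) and
#' assigns a class whenever a gram matches one of its descriptors. The
#' Clinical trial class is additionally assigned when any clinical-trial
#' keyword (inclusion, exclusion, criteria, patients, subjects, stage,
#' duration, study) occurs.
#'
#' @param query_text raw query text (or pre-normalized tokens).
#' @param scheme a `category_scheme`.
#' @param config a [stopword_config()].
#' @return character vector of class names (possibly empty).
#' @export
classify_query <- function(query_text, scheme = read_category_scheme(),
                           config = stopword_config()) {
  tokens <- normalize_text(query_text, config = config, mode = "corpus")
  if (!length(tokens)) return(character(0))
  grams <- unique(c(skipgrams(tokens, 1L),
                    skipgrams(tokens, 2L, 2L),
                    skipgrams(tokens, 2L, 3L)))
  classes <- names(scheme)[vapply(scheme, function(desc) {
    any(grams %in% desc)
  }, logical(1))]
  kw <- porter_stem(.clinical_query_keywords)
  if (any(tokens %in% kw)) classes <- union(classes, "Clinical trial")
  classes
}

# ---- dataset classifier -----------------------------------------------------

# tf-idf document-term matrix restricted to a vocabulary
.dtm <- function(token_docs, vocab, idf = NULL) {
  m <- matrix(0, nrow = length(token_docs), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(token_docs)) {
    tk <- token_docs[[i]]
    tk <- tk[tk %in% vocab]
    if (length(tk)) {
      tab <- table(tk)
      m[i, names(tab)] <- as.numeric(tab)
    }
  }
  if (is.null(idf)) {
    dfreq <- colSums(m > 0)
    idf <- log((nrow(m) + 1) / (dfreq + 1))
  }
  list(tfidf = sweep(log1p(m), 2, idf, `*`), idf = idf)
}

.embed_docs <- function(model, token_docs) {
  tf <- .dtm(token_docs, model$vocab, model$idf)$tfidf
  emb <- tf %*% model$projector
  norms <- sqrt(rowSums(emb^2))
  emb / pmax(norms, 1e-12)
}

#' Train the multi-label dataset classifier
#'
#' Documents are projected into a latent semantic space (tf-idf followed by a
#' truncated SVD of `embed_dim` components) and one single-hidden-layer
#' perceptron per class (one-vs-rest, via \pkg{nnet}) is fitted on the
#' embedded documents. Training is deterministic under a fixed seed.
#'
#' @param texts character vector of document texts.
#' @param labels list (parallel to `texts`) of character vectors of class
#'   names; multi-label.
#' @param embed_dim dimensionality of the document embedding.
#' @param seed integer seed.
#' @param hidden hidden units per class network.
#' @param config a [stopword_config()].
#' @return an object of class `dataset_classifier`.
#' @export
train_dataset_classifier <- function(texts, labels, embed_dim = 30,
                                     seed = 1L, hidden = 6,
                                     config = stopword_config()) {
  stopifnot(length(texts) == length(labels))
  classes <- sort(unique(unlist(labels)))
  if (length(classes) < 2L) {
    stop("need at least two classes to train the classifier")
  }
  n_per <- vapply(classes, function(cl) {
    sum(vapply(labels, function(l) cl %in% l, logical(1)))
  }, integer(1))
  if (any(n_per < 10L)) {
    stop("every class needs at least 10 training documents; got minimum ",
         min(n_per))
  }
  token_docs <- lapply(texts, normalize_text, config = config, mode = "corpus")
  vocab <- sort(unique(unlist(token_docs)))
  d <- .dtm(token_docs, vocab)
  embed_dim <- min(embed_dim, ncol(d$tfidf), nrow(d$tfidf))
  sv <- svd(d$tfidf, nu = 0, nv = embed_dim)
  model <- list(vocab = vocab, idf = d$idf, projector = sv$v,
                classes = classes, nets = list(), config = config)
  class(model) <- "dataset_classifier"
  emb <- .embed_docs(model, token_docs)
  for (cl in classes) {
    y <- vapply(labels, function(l) as.numeric(cl %in% l), numeric(1))
    set.seed(as.integer(seed))
    model$nets[[cl]] <- nnet::nnet(emb, y, size = hidden, decay = 1e-3,
                                   maxit = 200, entropy = TRUE, trace = FALSE)
  }
  model
}

#' Per-class classifier scores for a text
#'
#' @param model a `dataset_classifier`.
#' @param text document text.
#' @return named numeric vector of class scores in \[0, 1\].
#' @export
predict_dataset_scores <- function(model, text) {
  tokens <- normalize_text(text, config = model$config, mode = "corpus")
  emb <- .embed_docs(model, list(tokens))
  vapply(model$classes, function(cl) {
    as.numeric(stats::predict(model$nets[[cl]], emb))
  }, numeric(1))
}

#' Save / load a trained dataset classifier
#'
#' @param model a `dataset_classifier`.
#' @param path file path.
#' @return `classifier_load` returns the model.
#' @export
classifier_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname classifier_save
#' @export
classifier_load <- function(path) {
  readRDS(path)
}

#' Classify a dataset record
#'
#' Returns the classes whose classifier score reaches `threshold`, plus the
#' Clinical trial class whenever the record text contains one of the
#' keywords *clinical*, *trial* or *clinicaltrial*. With
#' `keyword_only = TRUE` (or `model = NULL`) no trained model is required
#' and classes are assigned by string matching the record text against the
#' scheme descriptors (same gram matching as [classify_query()]) plus the
#' clinical keyword rule.
#'
#' @param record a [dataset_record()].
#' @param model a `dataset_classifier`, or `NULL`.
#' @param threshold minimum classifier score.
#' @param keyword_only skip the trained model.
#' @param scheme a `category_scheme` (keyword mode only).
#' @param config a [stopword_config()].
#' @return character vector of class names.
#' @export
classify_dataset <- function(record, model = NULL, threshold = 0.5,
                             keyword_only = is.null(model),
                             scheme = NULL, config = stopword_config()) {
  text <- paste(record$title, record$metadata_text)
  tokens <- normalize_text(text, config = config, mode = "corpus")
  classes <- character(0)
  if (keyword_only) {
    if (!is.null(scheme)) {
      grams <- unique(c(skipgrams(tokens, 1L),
                        skipgrams(tokens, 2L, 2L),
                        skipgrams(tokens, 2L, 3L)))
      classes <- names(scheme)[vapply(scheme, function(desc) {
        any(grams %in% desc)
      }, logical(1))]
    }
  } else {
    if (is.null(model)) {
      stop("no trained model supplied; use keyword_only = TRUE for ",
           "string-matching classification")
    }
    scores <- predict_dataset_scores(model, text)
    classes <- names(scores)[scores >= threshold]
  }
  kw <- porter_stem(.clinical_doc_keywords)
  if (any(tokens %in% kw)) classes <- union(classes, "Clinical trial")
  classes
}

# ---- boosting ---------------------------------------------------------------

#' Boost category-matching documents in the top of a ranking
#'
#' For each query whose class set is non-empty, every document ranked within
#' the top `ceiling(top_fraction * n)` positions whose classes intersect the
#' query classes has its score multiplied by `1 + g`; the list is then
#' re-sorted by the new scores, ties keeping the previous order. Documents
#' outside the top fraction keep their exact scores. Queries with no classes
#' are returned unchanged.
#'
#' @param run a [ranked_run()].
#' @param query_classes named list query_id -> character vector of classes.
#' @param doc_classes named list doc_id -> character vector of classes.
#' @param g gain factor (>= 0; the official configuration used 0.10).
#' @param top_fraction eligible fraction of positions (default 0.5).
#' @return a re-ranked `ranked_run`.
#' @export
boost_run <- function(run, query_classes, doc_classes, g = 0.10,
                      top_fraction = 0.5) {
  stopifnot(g >= 0, top_fraction > 0, top_fraction <= 1)
  tag <- attr(run, "tag", exact = TRUE)
  pieces <- lapply(split(seq_len(nrow(run)), run$query_id), function(ii) {
    q <- run[ii, , drop = FALSE]
    q <- q[order(q$rank), , drop = FALSE]
    qcls <- query_classes[[q$query_id[1]]]
    if (is.null(qcls) || !length(qcls) || g == 0) return(q)
    n <- nrow(q)
    top_m <- ceiling(top_fraction * n)
    match_doc <- vapply(q$doc_id, function(d) {
      length(intersect(doc_classes[[d]], qcls)) > 0
    }, logical(1))
    eligible <- seq_len(n) <= top_m & match_doc
    q$score[eligible] <- q$score[eligible] * (1 + g)
    q <- q[order(-q$score, method = "radix"), , drop = FALSE] # stable: ties keep order
    q$rank <- seq_len(n)
    q
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "tag") <- if (is.null(tag)) "boosted" else tag
  class(out) <- c("ranked_run", "data.frame")
  out
}
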