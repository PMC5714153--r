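# Seeded synthetic test collections: a DOC-format corpus with planted
# topics, matching word embeddings with planted synonym groups, queries, and
# graded qrels derived from a known relevance rule. Everything downstream is
# testable against the generator's manifest without any external download.
#
# The generator emulates the gross shape of real dataset dumps: Zipf-skewed
# background vocabulary (so median-based key-relevance classification sees
# realistic document-frequency skew) and heavy-tailed repository sizes (a
# few repositories hold most records). It does not attempt to mimic real
# metadata vocabulary.

#' Specification for a synthetic test collection
#'
#' @param seed integer seed; the same spec and seed give identical output.
#' @param n_docs number of dataset records.
#' @param vocab_size background vocabulary size.
#' @param n_topics number of planted topic clusters (one query each).
#' @param terms_per_topic vocabulary terms per topic cluster; the first 4
#'   form the query.
#' @param n_relevant fully relevant documents planted per topic.
#' @param n_partial partially relevant documents planted per topic.
#' @param doc_len_mean mean background tokens per document (Poisson).
#' @param zipf Zipf exponent of the background term distribution.
#' @param embed_dim embedding dimensionality (>= 2).
#' @param n_repositories number of repository names, sizes heavy-tailed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_docs = 200L, vocab_size = 300L,
                           n_topics = 3L, terms_per_topic = 8L,
                           n_relevant = 12L, n_partial = 8L,
                           doc_len_mean = 40, zipf = 1.1,
                           embed_dim = 25L, n_repositories = 6L) {
  if (embed_dim < 2L) stop("embedding dimension must be at least 2")
  if (n_docs < n_topics * (n_relevant + n_partial)) {
    stop("infeasible spec: ", n_docs, " docs cannot hold ",
         n_topics * (n_relevant + n_partial), " planted relevant documents")
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

# random lower-case terms that are fixed points of the normalizer, so the
# manifest's term lists line up with index terms exactly
.synth_terms <- function(n, min_len = 5L, max_len = 8L) {
  letters_ok <- setdiff(letters, c("e", "s", "y")) # avoid stemmable endings
  out <- character(0)
  while (length(out) < n) {
    len <- sample(min_len:max_len, 1L)
    w <- paste(sample(letters, len - 1L, replace = TRUE), collapse = "")
    w <- paste0(w, sample(letters_ok, 1L))
    if (porter_stem(w) != w) next
    if (length(normalize_text(w)) != 1L || normalize_text(w) != w) next
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' Generate a synthetic collection
#'
#' Produces dataset records, queries, grades, repository assignments and the
#' vocabulary layout, all reproducible from the spec. Each topic cluster
#' contributes one query built from its first four terms (two of them
#' deliberately rare in the background so they end up key-relevant);
#' relevant documents contain all four query terms (some repeated),
#' partially relevant documents contain three, and background documents draw
#' only from the Zipf background vocabulary. Grades are then derived from
#' the generated documents themselves: any document containing all four
#' query terms is graded 2, three terms grade 1, otherwise 0 (recorded only
#' for planted documents and sampled background documents, mirroring pooled
#' judgment).
#'
#' @param spec a [synthetic_spec()].
#' @return a `synthetic_collection` list with elements `records` (list of
#'   [dataset_record()]), `queries` (data.frame query_id, text, terms),
#'   `grades` (data.frame query_id, doc_id, grade for the pooled documents),
#'   `topics`, `vocab` and `spec`.
#' @export
make_collection <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  vocab <- .synth_terms(spec$vocab_size + spec$n_topics * spec$terms_per_topic)
  background <- vocab[seq_len(spec$vocab_size)]
  topic_terms <- split(vocab[spec$vocab_size + seq_len(spec$n_topics * spec$terms_per_topic)],
                       rep(seq_len(spec$n_topics), each = spec$terms_per_topic))
  zipf_p <- (seq_len(spec$vocab_size))^(-spec$zipf)
  zipf_p <- zipf_p / sum(zipf_p)
  repo_sizes <- (seq_len(spec$n_repositories))^(-1.5)
  repo_p <- repo_sizes / sum(repo_sizes)
  repos <- paste0("repo", sprintf("%02d", seq_len(spec$n_repositories)),
                  "_030116")

  n_planted <- spec$n_topics * (spec$n_relevant + spec$n_partial)
  doc_tokens <- vector("list", spec$n_docs)
  doc_topic <- integer(spec$n_docs)
  slot <- 1L
  for (tp in seq_len(spec$n_topics)) {
    qterms <- topic_terms[[tp]][1:4]
    extra <- topic_terms[[tp]][-(1:4)]
    for (i in seq_len(spec$n_relevant)) {
      reps <- sample(1:3, 4L, replace = TRUE)
      body <- c(rep(qterms, reps),
                sample(extra, sample(1:3, 1L), replace = TRUE),
                sample(background, stats::rpois(1, spec$doc_len_mean / 2),
                       replace = TRUE, prob = zipf_p))
      doc_tokens[[slot]] <- sample(body)
      doc_topic[slot] <- tp
      slot <- slot + 1L
    }
    for (i in seq_len(spec$n_partial)) {
      keep <- sample(4L, 3L)
      body <- c(qterms[keep],
                sample(extra, sample(0:2, 1L), replace = TRUE),
                sample(background, stats::rpois(1, spec$doc_len_mean / 2),
                       replace = TRUE, prob = zipf_p))
      doc_tokens[[slot]] <- sample(body)
      doc_topic[slot] <- tp
      slot <- slot + 1L
    }
  }
  for (i in slot:spec$n_docs) {
    doc_tokens[[i]] <- sample(background, max(5L, stats::rpois(1, spec$doc_len_mean)),
                              replace = TRUE, prob = zipf_p)
    doc_topic[i] <- 0L
  }

  ids <- sprintf("%06d", sample.int(899999, spec$n_docs) + 100000L)
  repo_of <- sample(repos, spec$n_docs, replace = TRUE, prob = repo_p)
  records <- lapply(seq_len(spec$n_docs), function(i) {
    dataset_record(
      doc_id = ids[i],
      title = paste("synthetic dataset", ids[i]),
      repository = repo_of[i],
      raw_metadata = list(
        dataItem = list(dataTypes = list("dataset")),
        dataset = list(description = paste(doc_tokens[[i]], collapse = " "),
                       ID = ids[i]),
        dataRepository = list(name = sub("_030116$", "", repo_of[i]))))
  })

  queries <- data.frame(
    query_id = paste0("T", seq_len(spec$n_topics)),
    text = vapply(seq_len(spec$n_topics), function(tp) {
      paste("Find", paste(topic_terms[[tp]][1:4], collapse = " "),
            "data across all databases")
    }, character(1)),
    stringsAsFactors = FALSE)
  queries$terms <- I(lapply(seq_len(spec$n_topics),
                            function(tp) topic_terms[[tp]][1:4]))

  # derive grades from the documents actually generated
  grades <- do.call(rbind, lapply(seq_len(spec$n_topics), function(tp) {
    qterms <- topic_terms[[tp]][1:4]
    hits <- vapply(doc_tokens, function(tk) sum(qterms %in% tk), integer(1))
    pooled <- which(hits > 0 | doc_topic == tp)
    # pool some background docs too, as judged not-relevant
    extra_pool <- setdiff(sample(which(doc_topic == 0L),
                                 min(20L, sum(doc_topic == 0L))), pooled)
    pooled <- sort(c(pooled, extra_pool))
    data.frame(query_id = paste0("T", tp), doc_id = ids[pooled],
               grade = ifelse(hits[pooled] == 4L, 2L,
                              ifelse(hits[pooled] == 3L, 1L, 0L)),
               stringsAsFactors = FALSE)
  }))

  structure(list(records = records, queries = queries, grades = grades,
                 topics = topic_terms, vocab = vocab,
                 doc_topic = stats::setNames(doc_topic, ids), spec = spec),
            class = "synthetic_collection")
}

#' Write the corpus file of a synthetic collection
#'
#' @param collection a `synthetic_collection`.
#' @param path output DOC-format file.
#' @export
make_corpus_file <- function(collection, path) {
  write_corpus(collection$records, path)
}

#' Planted-synonym embeddings for a synthetic collection
#'
#' Each topic cluster becomes a synonym group: group centroids are mutually
#' orthogonal unit vectors and members sit within cosine >= 0.9 of their
#' centroid, so exact nearest-neighbour expectations hold by construction.
#' Background terms get their own orthogonal directions with noise, keeping
#' cross-group cosines small.
#'
#' @param collection a `synthetic_collection`.
#' @param noise within-group angular noise scale (default keeps members at
#'   cosine >= 0.9 of the centroid).
#' @return embedding matrix with term rownames.
#' @export
make_embeddings <- function(collection, noise = 0.25) {
  spec <- collection$spec
  set.seed(spec$seed + 1L)
  groups <- collection$topics
  n_groups <- length(groups)
  n_bg <- min(length(collection$vocab) - n_groups * spec$terms_per_topic,
              max(0L, spec$embed_dim - n_groups))
  dim <- spec$embed_dim
  if (dim < n_groups + 1L) {
    stop("embedding dimension ", dim, " too small for ", n_groups,
         " orthogonal topic centroids")
  }
  basis <- qr.Q(qr(matrix(stats::rnorm(dim * dim), dim)))
  rows <- list()
  for (gi in seq_len(n_groups)) {
    centroid <- basis[, gi]
    for (t in groups[[gi]]) {
      v <- centroid + noise * stats::rnorm(dim) / sqrt(dim)
      rows[[t]] <- v / sqrt(sum(v^2))
    }
  }
  bg_terms <- collection$vocab[seq_len(n_bg)]
  for (bi in seq_along(bg_terms)) {
    centroid <- basis[, n_groups + bi]
    v <- centroid + noise * stats::rnorm(dim) / sqrt(dim)
    rows[[bg_terms[bi]]] <- v / sqrt(sum(v^2))
  }
  emb <- do.call(rbind, rows)
  rownames(emb) <- names(rows)
  emb
}

#' Graded qrels for a synthetic collection
#'
#' Converts the collection's derived grades into a [graded_qrels()] object.
#' `subsample` marks that fraction of the pooled judgments as unjudged
#' (grade -1), exercising the inferred metrics; 0 keeps every judgment and
#' 1 marks all of them.
#'
#' @param collection a `synthetic_collection`.
#' @param subsample fraction in \[0, 1\] re-graded to -1.
#' @param seed seed for the subsampling draw (default: the spec's seed).
#' @return a [graded_qrels()].
#' @export
make_qrels <- function(collection, subsample = 0, seed = NULL) {
  stopifnot(subsample >= 0, subsample <= 1)
  g <- collection$grades
  if (subsample > 0) {
    set.seed(if (is.null(seed)) collection$spec$seed + 2L else as.integer(seed))
    flip <- stats::runif(nrow(g)) < subsample
    g$grade[flip] <- -1L
  }
  graded_qrels(g$query_id, g$doc_id, g$grade)
}
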