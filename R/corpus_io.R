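# Readers and writers for the artifacts the pipeline touches: the DOC-format
# dataset dump, TREC qrels and run files, and word2vec-style text embeddings.
#
# The DOC container is treated as a line-tolerant tag format rather than
# strict XML: real dumps embed raw HTML inside metadata notes, so records are
# delimited by <DOC>/</DOC> lines and fields by their own tags.

#' Construct a dataset record
#'
#' @param doc_id unique identifier (non-empty string).
#' @param title dataset title.
#' @param repository hosting repository name (usually with a snapshot-date
#'   suffix).
#' @param raw_metadata the structured metadata payload (a parsed list), or a
#'   raw string when the payload could not be parsed.
#' @param metadata_text flattened text of the metadata payload; computed from
#'   `raw_metadata` when missing.
#' @return an object of class `dataset_record`.
#' @export
dataset_record <- function(doc_id, title = "", repository = "",
                           raw_metadata = list(), metadata_text = NULL) {
  doc_id <- as.character(doc_id)
  if (!length(doc_id) || !nzchar(doc_id)) stop("doc_id must be non-empty")
  if (is.null(metadata_text)) {
    metadata_text <- flatten_metadata(raw_metadata)
  }
  structure(list(doc_id = doc_id, title = as.character(title),
                 repository = as.character(repository),
                 metadata_text = metadata_text, raw_metadata = raw_metadata),
            class = "dataset_record")
}

#' @export
print.dataset_record <- function(x, ...) {
  cat("<dataset_record ", x$doc_id, "> ", x$title, " [", x$repository, "]\n",
      sep = "")
  invisible(x)
}

#' Flatten a metadata payload to searchable text
#'
#' Collects every string-valued leaf of the (parsed JSON) payload by
#' depth-first traversal in field order and joins them with single spaces.
#' Keys are excluded by default: in the dump format the values, not the
#' attribute names, carry the searchable content.
#'
#' @param x a parsed JSON payload (nested lists), or a character scalar.
#' @param include_keys also emit attribute names ahead of their values.
#' @return a single string.
#' @export
flatten_metadata <- function(x, include_keys = FALSE) {
  out <- character(0)
  walk <- function(node) {
    if (is.list(node)) {
      nm <- names(node)
      for (i in seq_along(node)) {
        if (include_keys && !is.null(nm) && nzchar(nm[i])) {
          out[[length(out) + 1L]] <<- nm[i]
        }
        walk(node[[i]])
      }
    } else if (is.character(node)) {
      for (v in node) if (nzchar(v)) out[[length(out) + 1L]] <<- v
    }
    # numbers/logicals are dataset payload, not text; skipped
  }
  walk(x)
  paste(out, collapse = " ")
}

.extract_tag <- function(block, tag) {
  m <- regmatches(block, regexpr(paste0("(?s)<", tag, ">.*?</", tag, ">"),
                                 block, perl = TRUE))
  if (!length(m)) return(NULL)
  sub(paste0("</", tag, ">$"), "", sub(paste0("^<", tag, ">"), "", m))
}

#' Read a DOC-format dataset corpus
#'
#' Parses a dump of `<DOC>...</DOC>` records carrying `<DOCNO>`, `<TITLE>`,
#' `<REPOSITORY>` and a `<METADATA>` JSON payload. Records are processed one
#' block at a time in file order. A record whose metadata fails to parse as
#' JSON is kept, with `metadata_text` set to the raw text between the
#' METADATA tags; a record without a DOCNO is dropped with a warning.
#'
#' @param path path to the corpus dump (UTF-8; invalid bytes are replaced).
#' @param include_keys passed to [flatten_metadata()].
#' @return list of [dataset_record()] objects, in file order.
#' @export
read_corpus <- function(path, include_keys = FALSE) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- iconv(lines, from = "UTF-8", to = "UTF-8", sub = "�")
  records <- list()
  buf <- character(0)
  in_doc <- FALSE
  start_line <- NA_integer_
  offset <- 0L # bytes consumed before the current line
  doc_start_offset <- 0L
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!in_doc && grepl("<DOC>", line, fixed = TRUE)) {
      in_doc <- TRUE
      buf <- line
      start_line <- i
      doc_start_offset <- offset
    } else if (in_doc) {
      buf <- c(buf, line)
      if (grepl("</DOC>", line, fixed = TRUE)) {
        rec <- .parse_doc_block(paste(buf, collapse = "\n"), start_line,
                                include_keys)
        if (!is.null(rec)) records[[length(records) + 1L]] <- rec
        in_doc <- FALSE
        buf <- character(0)
      }
    }
    offset <- offset + nchar(line, type = "bytes") + 1L
  }
  if (in_doc) {
    stop("truncated final <DOC> block starting at byte offset ",
         doc_start_offset, " (line ", start_line, ") of ", path)
  }
  records
}

.parse_doc_block <- function(block, line_no, include_keys) {
  doc_id <- .extract_tag(block, "DOCNO")
  if (is.null(doc_id) || !nzchar(trimws(doc_id))) {
    warning("record at line ", line_no, " has no DOCNO; skipped")
    return(NULL)
  }
  title <- .extract_tag(block, "TITLE")
  repository <- .extract_tag(block, "REPOSITORY")
  meta_raw <- .extract_tag(block, "METADATA")
  raw_metadata <- list()
  metadata_text <- ""
  if (!is.null(meta_raw)) {
    parsed <- tryCatch(
      jsonlite::fromJSON(meta_raw, simplifyVector = FALSE),
      error = function(e) NULL)
    if (is.null(parsed)) {
      raw_metadata <- meta_raw
      metadata_text <- meta_raw
    } else {
      raw_metadata <- parsed
      metadata_text <- flatten_metadata(parsed, include_keys)
    }
  }
  dataset_record(trimws(doc_id),
                 title = if (is.null(title)) "" else trimws(title),
                 repository = if (is.null(repository)) "" else trimws(repository),
                 raw_metadata = raw_metadata,
                 metadata_text = metadata_text)
}

#' Write a DOC-format dataset corpus
#'
#' @param records list of [dataset_record()] objects.
#' @param path output file.
#' @export
write_corpus <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in records) {
    meta <- if (is.character(rec$raw_metadata)) {
      rec$raw_metadata
    } else {
      jsonlite::toJSON(rec$raw_metadata, auto_unbox = TRUE)
    }
    writeLines(c("<DOC>",
                 paste0("<DOCNO>", rec$doc_id, "</DOCNO>"),
                 paste0("<TITLE>", rec$title, "</TITLE>"),
                 paste0("<REPOSITORY>", rec$repository, "</REPOSITORY>"),
                 paste0("<METADATA>", meta, "</METADATA>"),
                 "</DOC>"), con)
  }
  invisible(path)
}

# ---- qrels ------------------------------------------------------------------

#' Construct graded relevance judgments
#'
#' Grades follow the challenge convention: 2 relevant, 1 partially relevant,
#' 0 not relevant, -1 pooled but never judged.
#'
#' @param query_id,doc_id,grade parallel vectors.
#' @return a `graded_qrels` data.frame with one row per (query, doc) pair.
#' @export
graded_qrels <- function(query_id = character(0), doc_id = character(0),
                         grade = integer(0)) {
  grade <- as.integer(grade)
  if (any(!grade %in% c(-1L, 0L, 1L, 2L))) {
    stop("grades must lie in {-1, 0, 1, 2}")
  }
  df <- data.frame(query_id = as.character(query_id),
                   doc_id = as.character(doc_id),
                   grade = grade, stringsAsFactors = FALSE)
  key <- paste(df$query_id, df$doc_id)
  if (anyDuplicated(key)) {
    warning("duplicate (query, doc) judgments; keeping the last")
    df <- df[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("graded_qrels", "data.frame")
  df
}

#' Read TREC-style graded qrels
#'
#' Expects whitespace-separated lines `query_id 0 doc_id grade` with grades
#' in \{-1, 0, 1, 2\}.
#'
#' @param path qrels file.
#' @return a [graded_qrels()] data.frame.
#' @export
read_qrels <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(graded_qrels())
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 4L) {
      stop("qrels line ", i, " does not have 4 fields: ", lines[i])
    }
    g <- suppressWarnings(as.integer(p[4]))
    if (is.na(g) || g != as.numeric(p[4]) || !g %in% c(-1L, 0L, 1L, 2L)) {
      stop("qrels line ", i, " has invalid grade '", p[4],
           "' (must be -1, 0, 1 or 2)")
    }
  }
  m <- do.call(rbind, parts)
  graded_qrels(m[, 1], m[, 3], as.integer(m[, 4]))
}

#' Write graded qrels
#'
#' @param qrels a [graded_qrels()] data.frame.
#' @param path output file.
#' @export
write_qrels <- function(qrels, path) {
  writeLines(paste(qrels$query_id, 0L, qrels$doc_id, qrels$grade), path)
  invisible(path)
}

# ---- runs -------------------------------------------------------------------

#' Construct a ranked run
#'
#' Stores per-query ranked result lists in TREC run form. Ranks are derived
#' from the scores: within a query, documents are ordered by decreasing score
#' with ties broken by `doc_id` so the ordering is deterministic.
#'
#' @param query_id,doc_id,score parallel vectors.
#' @param tag run name.
#' @return a `ranked_run` data.frame with columns query_id, doc_id, rank,
#'   score.
#' @export
ranked_run <- function(query_id = character(0), doc_id = character(0),
                       score = numeric(0), tag = "run") {
  df <- data.frame(query_id = as.character(query_id),
                   doc_id = as.character(doc_id),
                   score = as.numeric(score), stringsAsFactors = FALSE)
  if (anyDuplicated(paste(df$query_id, df$doc_id))) {
    stop("duplicate doc_id within a query")
  }
  df <- df[order(df$query_id, -df$score, df$doc_id, method = "radix"), ,
           drop = FALSE]
  rank <- stats::ave(df$score, df$query_id, FUN = seq_along)
  df <- data.frame(query_id = df$query_id, doc_id = df$doc_id,
                   rank = as.integer(rank), score = df$score,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "tag") <- tag
  class(df) <- c("ranked_run", "data.frame")
  df
}

#' Read a TREC run file
#'
#' Expects six-column lines `query_id Q0 doc_id rank score tag`. Ranks are
#' re-derived from the scores on read; if the stored ranks disagree with the
#' score ordering a warning is raised and the scores win.
#'
#' @param path run file.
#' @return a [ranked_run()] data.frame.
#' @export
read_run <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(ranked_run())
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(parts) != 6L)
  if (length(bad)) stop("run line ", bad[1], " does not have 6 fields")
  m <- do.call(rbind, parts)
  run <- ranked_run(m[, 1], m[, 3], as.numeric(m[, 5]), tag = m[1, 6])
  stored <- as.integer(m[, 4])[order(m[, 1], -as.numeric(m[, 5]), m[, 3],
                                     method = "radix")]
  if (!identical(stored, run$rank)) {
    warning("stored ranks disagree with score order; scores win")
  }
  run
}

#' Write a TREC run file
#'
#' @param run a [ranked_run()] data.frame.
#' @param path output file.
#' @param tag run tag; defaults to the run's own tag attribute.
#' @export
write_run <- function(run, path, tag = NULL) {
  if (is.null(tag)) tag <- attr(run, "tag", exact = TRUE)
  if (is.null(tag)) tag <- "run"
  writeLines(sprintf("%s Q0 %s %d %.10g %s", run$query_id, run$doc_id,
                     run$rank, run$score, tag), path)
  invisible(path)
}

# ---- embeddings -------------------------------------------------------------

#' Read a word2vec-style text embedding table
#'
#' Format: a header line `V dim`, then one line per term,
#' `term v1 ... vdim`. Duplicate terms keep the last vector with a warning.
#'
#' @param path embedding file.
#' @return numeric matrix with one row per term; rownames are the terms.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty embedding file: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr)) {
    stop("malformed embedding header: ", lines[1])
  }
  dim <- hdr[2]
  rows <- strsplit(trimws(lines[-1]), "[[:space:]]+")
  bad <- which(lengths(rows) != dim + 1L)
  if (length(bad)) {
    stop("embedding line ", bad[1] + 1L, " has ", lengths(rows)[bad[1]] - 1L,
         " values; expected ", dim)
  }
  terms <- vapply(rows, `[`, character(1), 1L)
  mat <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(dim)))
  if (anyDuplicated(terms)) {
    warning("duplicate terms in embedding file; keeping the last")
    keep <- !duplicated(terms, fromLast = TRUE)
    mat <- mat[keep, , drop = FALSE]
    terms <- terms[keep]
  }
  rownames(mat) <- terms
  mat
}

#' Write a word2vec-style text embedding table
#'
#' @param emb numeric matrix with term rownames.
#' @param path output file.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(emb), ncol(emb)), con)
  for (i in seq_len(nrow(emb))) {
    writeLines(paste(rownames(emb)[i],
                     paste(formatC(emb[i, ], format = "g", digits = 8),
                           collapse = " ")), con)
  }
  invisible(path)
}
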