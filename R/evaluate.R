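# Evaluation stack: precision at k with and without partial relevance,
# NDCG at k, inferred AP and inferred NDCG for incompletely judged pools,
# and the unanimous improvement ratio for multi-measure system comparison.
#
# Grade conventions: 2 relevant, 1 partially relevant, 0 not relevant,
# -1 pooled but never judged. Documents absent from the qrels altogether
# (unpooled) are distinct from grade -1 and always count as not relevant.

# per-query ranked grade vectors: list(query_id -> data.frame(doc_id, grade))
# grade is NA for unpooled documents.
.judged <- function(run, qrels) {
  key <- stats::setNames(qrels$grade, paste(qrels$query_id, qrels$doc_id))
  out <- lapply(split(seq_len(nrow(run)), run$query_id), function(ii) {
    q <- run[ii, , drop = FALSE]
    q <- q[order(q$rank), , drop = FALSE]
    g <- key[paste(q$query_id, q$doc_id)]
    data.frame(doc_id = q$doc_id, grade = as.integer(unname(g)),
               stringsAsFactors = FALSE)
  })
  out
}

.qrels_by_query <- function(qrels) {
  split(qrels, qrels$query_id)
}

#' Precision at k
#'
#' Fraction of the top `k` retrieved documents that are relevant. With
#' `partial_mode = "include"` grade-1 (partially relevant) documents count
#' as relevant; with `"exclude"` only grade 2 counts. Unjudged (grade -1)
#' and unpooled documents count as not relevant; rankings shorter than `k`
#' still divide by `k`.
#'
#' @param run a [ranked_run()].
#' @param qrels a [graded_qrels()].
#' @param k cut-off (default 10).
#' @param partial_mode `"include"` or `"exclude"`.
#' @return named numeric vector, one value in \[0, 1\] per query in the run.
#' @export
p_at_k <- function(run, qrels, k = 10L, partial_mode = c("include", "exclude")) {
  partial_mode <- match.arg(partial_mode)
  stopifnot(k >= 1L)
  min_rel <- if (partial_mode == "include") 1L else 2L
  vapply(.judged(run, qrels), function(j) {
    top <- j$grade[seq_len(min(k, nrow(j)))]
    sum(!is.na(top) & top >= min_rel) / k
  }, numeric(1))
}

.dcg <- function(gains) {
  if (!length(gains)) return(0)
  sum(gains / log2(seq_along(gains) + 1))
}

#' NDCG at k
#'
#' DCG with linear gain equal to the grade (grade -1 and unpooled count 0)
#' and discount `1/log2(rank + 1)`, normalized by the ideal DCG computed
#' from the full qrels. Queries without any positive grade in the qrels are
#' returned as `NA` with a warning (and excluded from means downstream).
#'
#' @inheritParams p_at_k
#' @param k cut-off (default 10).
#' @param exponential use gain `2^grade - 1` instead of the linear grade.
#' @return named numeric vector, one value per query (possibly `NA`).
#' @export
ndcg_at_k <- function(run, qrels, k = 10L, exponential = FALSE) {
  gain <- function(g) {
    g <- ifelse(is.na(g) | g < 0, 0, g)
    if (exponential) 2^g - 1 else g
  }
  qq <- .qrels_by_query(qrels)
  judged <- .judged(run, qrels)
  out <- stats::setNames(numeric(length(judged)), names(judged))
  for (qid in names(judged)) {
    j <- judged[[qid]]
    if (is.null(qq[[qid]])) {
      warning("query ", qid, " absent from qrels; NDCG undefined")
      out[[qid]] <- NA_real_
      next
    }
    pos <- qq[[qid]]$grade[qq[[qid]]$grade > 0]
    if (!length(pos)) {
      warning("query ", qid, " has no positively graded documents; NDCG undefined")
      out[[qid]] <- NA_real_
      next
    }
    top <- gain(j$grade[seq_len(min(k, nrow(j)))])
    ideal <- gain(sort(pos, decreasing = TRUE))[seq_len(min(k, length(pos)))]
    out[[qid]] <- .dcg(top) / .dcg(ideal)
  }
  out
}

.exact_ap <- function(grades, n_rel, min_rel = 1L) {
  # grades: retrieved ranking, NA/unknown = nonrelevant; n_rel: total relevant
  if (n_rel == 0) return(NA_real_)
  rel <- !is.na(grades) & grades >= min_rel
  if (!any(rel)) return(0)
  prec <- cumsum(rel)[rel] / which(rel)
  sum(prec) / n_rel
}

#' Inferred average precision
#'
#' Estimates average precision when only a sample of the judgment pool was
#' assessed. In mode `"sampled"` (the default), grade -1 marks pooled but
#' unjudged documents; for each retrieved sampled relevant document at rank
#' k the expected precision is
#' `1/k + (k-1)/k * d/(k-1) * (r + eps)/(r + n + 2 eps)` where, among the
#' k-1 higher-ranked documents, `d` counts those in the pool, and `r`/`n`
#' count judged relevant/non-relevant; the estimate averages these over the
#' sampled relevant documents in the qrels (non-retrieved ones contribute
#' 0). Mode `"as-nonrelevant"` re-grades -1 documents as 0 and computes
#' exact AP; mode `"removed"` drops them from the ranking first. Under
#' complete judgments all modes reduce to exact AP.
#'
#' @inheritParams p_at_k
#' @param mode unjudged-document handling.
#' @param min_rel smallest grade counting as relevant (default 1, i.e.
#'   partially relevant counts).
#' @param eps smoothing constant of the estimator.
#' @return named numeric vector, one value per query (NA when the qrels hold
#'   no relevant document for the query).
#' @export
inf_ap <- function(run, qrels, mode = c("sampled", "as-nonrelevant", "removed"),
                   min_rel = 1L, eps = 1e-5) {
  mode <- match.arg(mode)
  qq <- .qrels_by_query(qrels)
  judged <- .judged(run, qrels)
  out <- stats::setNames(rep(NA_real_, length(judged)), names(judged))
  for (qid in names(judged)) {
    j <- judged[[qid]]
    qr <- qq[[qid]]
    if (is.null(qr)) {
      warning("query ", qid, " absent from qrels; skipped")
      next
    }
    if (mode == "as-nonrelevant") {
      g <- ifelse(is.na(j$grade) | j$grade == -1L, 0L, j$grade)
      n_rel <- sum(qr$grade >= min_rel)
      out[[qid]] <- .exact_ap(g, n_rel, min_rel)
    } else if (mode == "removed") {
      keep <- is.na(j$grade) | j$grade != -1L
      n_rel <- sum(qr$grade >= min_rel)
      out[[qid]] <- .exact_ap(j$grade[keep], n_rel, min_rel)
    } else {
      in_pool <- !is.na(j$grade)            # retrieved docs present in qrels
      sampled <- in_pool & j$grade != -1L   # judged subset of the pool
      rel <- sampled & j$grade >= min_rel
      n_rel_sampled <- sum(qr$grade >= min_rel & qr$grade != -1L)
      if (n_rel_sampled == 0) {
        warning("query ", qid, " has no sampled relevant documents; skipped")
        next
      }
      total <- 0
      for (k in which(rel)) {
        if (k == 1L) {
          total <- total + 1
          next
        }
        above <- seq_len(k - 1L)
        d <- sum(in_pool[above])
        r <- sum(sampled[above] & j$grade[above] >= min_rel)
        n <- sum(sampled[above] & j$grade[above] < min_rel)
        total <- total + 1 / k +
          ((k - 1) / k) * (d / (k - 1)) * ((r + eps) / (r + n + 2 * eps))
      }
      out[[qid]] <- total / n_rel_sampled
    }
  }
  out
}

#' Inferred NDCG
#'
#' Estimates NDCG under pool sampling. In mode `"sampled"`, the per-query
#' sampling rate `p` is the judged fraction of the pool; retrieved judged
#' documents contribute their gain at their discount, retrieved
#' pooled-but-unjudged documents contribute the mean judged gain, and the
#' ideal DCG uses the judged grade counts scaled by `1/p`. Under complete
#' judgments this reduces to exact NDCG. Modes `"as-nonrelevant"` and
#' `"removed"` behave as in [inf_ap()].
#'
#' @inheritParams inf_ap
#' @param k optional cut-off (default: the full ranking).
#' @return named numeric vector, one value per query.
#' @export
inf_ndcg <- function(run, qrels,
                     mode = c("sampled", "as-nonrelevant", "removed"),
                     k = NULL, eps = 1e-5) {
  mode <- match.arg(mode)
  qq <- .qrels_by_query(qrels)
  judged <- .judged(run, qrels)
  out <- stats::setNames(rep(NA_real_, length(judged)), names(judged))
  for (qid in names(judged)) {
    j <- judged[[qid]]
    qr <- qq[[qid]]
    if (is.null(qr)) {
      warning("query ", qid, " absent from qrels; skipped")
      next
    }
    if (!is.null(k)) j <- j[seq_len(min(k, nrow(j))), , drop = FALSE]
    if (mode == "removed") {
      keep_run <- is.na(j$grade) | j$grade != -1L
      j <- j[keep_run, , drop = FALSE]
      qr <- qr[qr$grade != -1L, , drop = FALSE]
    }
    if (mode %in% c("as-nonrelevant", "removed")) {
      g <- ifelse(is.na(j$grade) | j$grade < 0, 0, j$grade)
      pos <- qr$grade[qr$grade > 0]
      if (!length(pos)) {
        warning("query ", qid, " has no positively graded documents; skipped")
        next
      }
      ideal <- sort(pos, decreasing = TRUE)
      if (!is.null(k)) ideal <- ideal[seq_len(min(k, length(ideal)))]
      out[[qid]] <- .dcg(g) / .dcg(ideal)
      next
    }
    pool_n <- nrow(qr)
    judged_mask <- qr$grade != -1L
    p <- sum(judged_mask) / pool_n
    if (p == 0) {
      warning("query ", qid, " has an entirely unjudged pool; skipped")
      next
    }
    gbar <- mean(pmax(qr$grade[judged_mask], 0))
    g <- numeric(nrow(j))
    g[!is.na(j$grade) & j$grade >= 0] <-
      j$grade[!is.na(j$grade) & j$grade >= 0]
    g[!is.na(j$grade) & j$grade == -1L] <- gbar
    n2 <- round(sum(qr$grade == 2L) / p)
    n1 <- round(sum(qr$grade == 1L) / p)
    if (n2 + n1 == 0) {
      warning("query ", qid, " has no sampled relevant documents; skipped")
      next
    }
    ideal <- c(rep(2, n2), rep(1, n1))
    if (!is.null(k)) ideal <- ideal[seq_len(min(k, length(ideal)))]
    out[[qid]] <- .dcg(g) / .dcg(ideal)
  }
  out
}

#' Unanimous improvement ratio
#'
#' For each ordered system pair (A, B), counts the test cases (queries) where
#' A is at least as good as B on every measure with at least one strict win
#' (`N_A`), and symmetrically `N_B`; `UIR(A, B) = (N_A - N_B) / n_cases`. A
#' system's overall score is its mean UIR against every other system.
#'
#' @param systems named list: system tag -> data.frame of per-query measure
#'   values (rows = shared test cases in identical order, columns =
#'   measures).
#' @return list with `pairwise` (matrix of UIR(A, B)) and `score` (named
#'   vector of per-system means).
#' @export
uir <- function(systems) {
  stopifnot(length(systems) >= 2L)
  dims <- lapply(systems, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("all systems must share the same test cases and measures")
  }
  tags <- names(systems)
  n_cases <- nrow(systems[[1]])
  pw <- matrix(0, length(tags), length(tags), dimnames = list(tags, tags))
  wins <- function(a, b) {
    # unanimous wins of a over b, counted per test case
    sum(vapply(seq_len(n_cases), function(i) {
      va <- as.numeric(a[i, ])
      vb <- as.numeric(b[i, ])
      all(va >= vb) && any(va > vb)
    }, logical(1)))
  }
  for (i in seq_along(tags)) {
    for (j in seq_along(tags)) {
      if (i == j) next
      na <- wins(systems[[i]], systems[[j]])
      nb <- wins(systems[[j]], systems[[i]])
      pw[i, j] <- (na - nb) / n_cases
    }
  }
  score <- rowSums(pw) / (length(tags) - 1L)
  list(pairwise = pw, score = score)
}

#' Evaluate a run against graded qrels
#'
#' Computes inferred AP, inferred NDCG, P@10 with and without partial
#' relevance, and NDCG@10, per query and averaged over the queries where
#' each metric is defined.
#'
#' @inheritParams inf_ap
#' @param k cut-off for the precision and NDCG@k metrics.
#' @return an object of class `metric_report`: list with `per_query`
#'   (data.frame), `means` (named vector), `tag`, `unjudged_mode` and
#'   `n_excluded` (queries without relevant documents, excluded from means).
#' @export
evaluate_run <- function(run, qrels,
                         mode = c("sampled", "as-nonrelevant", "removed"),
                         k = 10L, eps = 1e-5) {
  mode <- match.arg(mode)
  missing_q <- setdiff(unique(run$query_id), unique(qrels$query_id))
  if (length(missing_q)) {
    warning("queries absent from qrels skipped: ",
            paste(missing_q, collapse = ", "))
    run <- run[!run$query_id %in% missing_q, , drop = FALSE]
  }
  per <- data.frame(
    query_id = sort(unique(run$query_id)),
    stringsAsFactors = FALSE)
  if (!nrow(per)) {
    return(structure(list(per_query = per, means = numeric(0),
                          tag = attr(run, "tag"), unjudged_mode = mode,
                          n_excluded = 0L),
                     class = "metric_report"))
  }
  vals <- list(
    infAP = inf_ap(run, qrels, mode = mode, eps = eps),
    infNDCG = inf_ndcg(run, qrels, mode = mode, eps = eps),
    P10_plus = p_at_k(run, qrels, k = k, partial_mode = "include"),
    P10_minus = p_at_k(run, qrels, k = k, partial_mode = "exclude"),
    NDCG10 = ndcg_at_k(run, qrels, k = k))
  for (m in names(vals)) per[[m]] <- unname(vals[[m]][per$query_id])
  means <- vapply(names(vals), function(m) mean(per[[m]], na.rm = TRUE),
                  numeric(1))
  structure(list(per_query = per, means = means,
                 tag = attr(run, "tag", exact = TRUE),
                 unjudged_mode = mode,
                 n_excluded = sum(is.na(per$infAP))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report", if (!is.null(x$tag)) paste0("'", x$tag, "'"),
      "| unjudged:", x$unjudged_mode, "|", nrow(x$per_query), "queries>\n")
  print(round(x$means, 4))
  invisible(x)
}

#' Paired two-tailed t-test between two per-query metric vectors
#'
#' Thin wrapper over [stats::t.test()] for comparing systems on a shared
#' query set.
#'
#' @param a,b numeric vectors of per-query metric values (same queries, same
#'   order).
#' @return the `htest` object.
#' @export
paired_ttest <- function(a, b) {
  stats::t.test(a, b, paired = TRUE)
}
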