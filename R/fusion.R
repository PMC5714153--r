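# Linear combination of two runs. The two scorers being fused (DFR and RTRL)
# live on different scales, so scores are min-max normalized per query by
# default before mixing; `normalize = "none"` reproduces raw summation.

#' Linearly combine two ranked runs
#'
#' Per query, `score = alpha * norm(scoreA) + (1 - alpha) * norm(scoreB)`
#' over the union of the two result lists; a document missing from one run
#' scores 0 in that run. Ties are broken by doc_id.
#'
#' @param run_a,run_b [ranked_run()] data.frames.
#' @param alpha mixing weight in \[0, 1\] (weight of `run_a`; the official
#'   configuration used 0.5).
#' @param normalize `"minmax"` (per query) or `"none"`.
#' @param tag tag for the combined run.
#' @return a [ranked_run()].
#' @export
combine_runs <- function(run_a, run_b, alpha = 0.5,
                         normalize = c("minmax", "none"),
                         tag = "fused") {
  normalize <- match.arg(normalize)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]")
  }
  norm_scores <- function(run) {
    if (normalize == "none" || !nrow(run)) return(run)
    run$score <- stats::ave(run$score, run$query_id, FUN = function(s) {
      rng <- range(s)
      if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1]) else rep(1, length(s))
    })
    run
  }
  a <- norm_scores(run_a)
  b <- norm_scores(run_b)
  key_a <- paste(a$query_id, a$doc_id)
  key_b <- paste(b$query_id, b$doc_id)
  keys <- union(key_a, key_b)
  sa <- stats::setNames(rep(0, length(keys)), keys)
  sb <- sa
  sa[key_a] <- a$score
  sb[key_b] <- b$score
  combined <- alpha * sa + (1 - alpha) * sb
  parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  ranked_run(parts[, 1], parts[, 2], combined, tag = tag)
}
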