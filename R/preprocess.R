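# Text normalization shared by indexing, querying and categorization.

# Snowball English stopword list (public domain).
.general_stopwords <- c(
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you", "your",
  "yours", "yourself", "yourselves", "he", "him", "his", "himself", "she",
  "her", "hers", "herself", "it", "its", "itself", "they", "them", "their",
  "theirs", "themselves", "what", "which", "who", "whom", "this", "that",
  "these", "those", "am", "is", "are", "was", "were", "be", "been", "being",
  "have", "has", "had", "having", "do", "does", "did", "doing", "would",
  "should", "could", "ought", "a", "an", "the", "and", "but", "if", "or",
  "because", "as", "until", "while", "of", "at", "by", "for", "with", "about",
  "against", "between", "into", "through", "during", "before", "after",
  "above", "below", "to", "from", "up", "down", "in", "out", "on", "off",
  "over", "under", "again", "further", "then", "once", "here", "there",
  "when", "where", "why", "how", "all", "any", "both", "each", "few", "more",
  "most", "other", "some", "such", "no", "nor", "not", "only", "own", "same",
  "so", "than", "too", "very", "can", "will", "just", "don", "now"
)

# Search-intent words stripped from queries only: scaffold words like
# "find ... data ... across all databases" that carry no topical content.
.query_stopwords <- c(
  "find", "search", "data", "datasets", "dataset", "databases", "database",
  "related", "types", "type", "mention", "regarding", "across", "all"
)

.greek_letters <- c(
  "α" = "alpha",   "β" = "beta",    "γ" = "gamma",
  "δ" = "delta",   "ε" = "epsilon", "ζ" = "zeta",
  "η" = "eta",     "θ" = "theta",   "ι" = "iota",
  "κ" = "kappa",   "λ" = "lambda",  "μ" = "mu",
  "ν" = "nu",      "ξ" = "xi",      "ο" = "omicron",
  "π" = "pi",      "ρ" = "rho",     "ς" = "sigma",
  "σ" = "sigma",   "τ" = "tau",     "υ" = "upsilon",
  "φ" = "phi",     "χ" = "chi",     "ψ" = "psi",
  "ω" = "omega",
  "Α" = "alpha",   "Β" = "beta",    "Γ" = "gamma",
  "Δ" = "delta",   "Ε" = "epsilon", "Ζ" = "zeta",
  "Η" = "eta",     "Θ" = "theta",   "Ι" = "iota",
  "Κ" = "kappa",   "Λ" = "lambda",  "Μ" = "mu",
  "Ν" = "nu",      "Ξ" = "xi",      "Ο" = "omicron",
  "Π" = "pi",      "Ρ" = "rho",     "Σ" = "sigma",
  "Τ" = "tau",     "Υ" = "upsilon", "Φ" = "phi",
  "Χ" = "chi",     "Ψ" = "psi",     "Ω" = "omega"
)

#' Stopword configuration
#'
#' Bundles the general stopword list with the query-stopword list of
#' search-intent words ("find", "data", "across", ...), which are removed from
#' queries only. Both lists are matched on lower-cased, unstemmed tokens.
#'
#' @param general character vector of general stopwords.
#' @param query character vector of additional query-only stopwords.
#' @return an object of class `stopword_config`.
#' @export
stopword_config <- function(general = .general_stopwords,
                            query = .query_stopwords) {
  structure(list(general = tolower(general), query = tolower(query)),
            class = "stopword_config")
}

#' Read a one-term-per-line stopword file
#'
#' @param path file with one term per line; blank lines and `#` comments
#'   are skipped.
#' @return lower-case character vector.
#' @export
read_stopwords <- function(path) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- trimws(x)
  tolower(x[nzchar(x) & !startsWith(x, "#")])
}

#' Normalize free text into retrieval tokens
#'
#' Applies, in order: Greek letters replaced by their literal names
#' (`β` to "beta"); lower-casing and tokenization on non-alphanumeric
#' boundaries; stopword removal (general list, plus the query-stopword list
#' when `mode = "query"`); Porter stemming; removal of residual
#' non-alphanumeric characters (empty tokens dropped); truncation to 20
#' characters; and replacement of purely numeric tokens with the literal
#' `_number_`. The numeric substitution runs last so its underscores survive
#' the non-alphanumeric strip.
#'
#' @param text character vector; elements are concatenated in order.
#' @param config a [stopword_config()].
#' @param mode `"corpus"` or `"query"`; query mode additionally removes
#'   search-intent stopwords.
#' @param stem apply Porter stemming (default `TRUE`).
#' @return character vector of normalized tokens (possibly empty), with
#'   attribute `mode` recording the provenance.
#' @examples
#' normalize_text(
#'   "Find protein sequencing data related to bacterial chemotaxis across all databases",
#'   mode = "query"
#' )
#' @export
normalize_text <- function(text, config = stopword_config(),
                           mode = c("corpus", "query"), stem = TRUE) {
  mode <- match.arg(mode)
  text <- paste(text, collapse = " ")
  if (!nzchar(text)) {
    return(structure(character(0), mode = mode))
  }
  for (g in names(.greek_letters)) {
    if (grepl(g, text, fixed = TRUE)) {
      text <- gsub(g, paste0(" ", .greek_letters[[g]], " "), text, fixed = TRUE)
    }
  }
  text <- tolower(text)
  tokens <- strsplit(text, "[^a-z0-9]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  stop_set <- config$general
  if (mode == "query") stop_set <- c(stop_set, config$query)
  tokens <- tokens[!tokens %in% stop_set]
  if (stem) tokens <- porter_stem(tokens)
  tokens <- gsub("[^a-z0-9]", "", tokens)
  tokens <- tokens[nzchar(tokens)]
  tokens <- substr(tokens, 1L, 20L)
  tokens[grepl("^[0-9]+$", tokens)] <- "_number_"
  structure(tokens, mode = mode)
}

#' Extract k-skip-n-grams from a token sequence
#'
#' Returns every in-order tuple of `n` tokens whose total positional gap
#' (skipped positions) is at most `k`. `n = 1` yields the unigrams regardless
#' of `k`.
#'
#' @param tokens character vector of tokens.
#' @param n gram size (>= 1).
#' @param k maximum total skip (>= 0).
#' @return character vector of grams, tokens joined by single spaces,
#'   duplicates removed.
#' @examples
#' skipgrams(c("a", "b", "c", "d"), n = 2, k = 2)
#' @export
skipgrams <- function(tokens, n, k = 0L) {
  stopifnot(n >= 1L, k >= 0L)
  m <- length(tokens)
  if (n > m) return(character(0))
  if (n == 1L) return(unique(tokens))
  idx <- utils::combn(m, n, simplify = FALSE)
  keep <- vapply(idx, function(ii) (ii[n] - ii[1]) - (n - 1L) <= k, logical(1))
  unique(vapply(idx[keep], function(ii) paste(tokens[ii], collapse = " "),
                character(1)))
}
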