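# End-to-end orchestration: normalize and (optionally) expand each query,
# rank with DFR or RTRL, boost category matches, optionally fuse two stage
# runs, and evaluate when qrels are supplied. The five shipped presets
# reproduce the sibtex run configurations:
#   sibtex-1  DFR baseline
#   sibtex-2  DFR + expansion model 1 + category boost
#   sibtex-3  DFR + expansion model 2 (loss factor l) + category boost
#   sibtex-4  RTRL + category boost
#   sibtex-5  linear fusion of sibtex-3 and sibtex-4

#' Pipeline configuration
#'
#' Either name a preset (`"sibtex-1"` ... `"sibtex-5"`) or give the stage
#' parameters explicitly. Presets expand to fully explicit configurations.
#'
#' @param preset optional preset name.
#' @param ranker `"dfr"` or `"rtrl"`.
#' @param expansion_model 0 (off), 1 or 2.
#' @param k expansion neighbours per term (default 10).
#' @param l loss factor for expansion model 2 (default 0.01).
#' @param c RTRL key-term gain (default 1).
#' @param c_norm DFR frequency normalization (documented operating points 1
#'   and 33).
#' @param g category boost gain (default 0.10; 0 disables boosting).
#' @param top_fraction boosted fraction of positions (default 0.5).
#' @param alpha fusion weight (default 0.5; used by `"sibtex-5"`).
#' @param cutoff ranked-list depth (default 1000).
#' @param fuse optional list of two `pipeline_config`s to fuse.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = NULL, ranker = "dfr",
                            expansion_model = 0L, k = 10L, l = 0.01,
                            c = 1, c_norm = 1, g = 0.10, top_fraction = 0.5,
                            alpha = 0.5, cutoff = 1000L, fuse = NULL) {
  if (!is.null(preset)) {
    base <- list(k = k, l = l, c = c, c_norm = c_norm, g = g,
                 top_fraction = top_fraction, alpha = alpha, cutoff = cutoff)
    cfg <- switch(preset,
      "sibtex-1" = c(list(ranker = "dfr", expansion_model = 0L,
                          g = 0), base[setdiff(names(base), "g")]),
      "sibtex-2" = c(list(ranker = "dfr", expansion_model = 1L), base),
      "sibtex-3" = c(list(ranker = "dfr", expansion_model = 2L), base),
      "sibtex-4" = c(list(ranker = "rtrl", expansion_model = 0L), base),
      "sibtex-5" = {
        cfg <- c(list(ranker = "fusion", expansion_model = 0L), base)
        cfg$fuse <- list(pipeline_config(preset = "sibtex-3", k = k, l = l,
                                         c = c, c_norm = c_norm, g = g,
                                         top_fraction = top_fraction,
                                         cutoff = cutoff),
                         pipeline_config(preset = "sibtex-4", k = k, l = l,
                                         c = c, c_norm = c_norm, g = g,
                                         top_fraction = top_fraction,
                                         cutoff = cutoff))
        cfg
      },
      stop("unknown preset: ", preset))
    cfg$preset <- preset
    class(cfg) <- "pipeline_config"
    return(cfg)
  }
  cfg <- list(preset = NULL, ranker = ranker,
              expansion_model = as.integer(expansion_model), k = k, l = l,
              c = c, c_norm = c_norm, g = g, top_fraction = top_fraction,
              alpha = alpha, cutoff = cutoff, fuse = fuse)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the retrieval pipeline
#'
#' @param index an `inverted_index` (see [build_index()]).
#' @param queries data.frame with columns `query_id` and `text`.
#' @param config a [pipeline_config()].
#' @param embeddings embedding matrix (required when
#'   `expansion_model > 0` and `k > 0`).
#' @param records the corpus records; required for category boosting
#'   (`g > 0`), to classify the retrieved datasets.
#' @param qrels optional [graded_qrels()]; when given, the result includes a
#'   [evaluate_run()] report.
#' @param scheme category scheme for boosting (default: packaged scheme).
#' @param classifier optional trained `dataset_classifier` used instead of
#'   keyword matching for dataset categorization.
#' @param config_stop a [stopword_config()].
#' @return list with `run` (a [ranked_run()]), `report` (or `NULL`),
#'   `config`, and `intermediate` (per-stage runs for fusion presets).
#' @export
run_pipeline <- function(index, queries, config = pipeline_config("sibtex-1"),
                         embeddings = NULL, records = NULL, qrels = NULL,
                         scheme = NULL, classifier = NULL,
                         config_stop = stopword_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  intermediate <- list()
  if (identical(config$ranker, "fusion")) {
    sub <- lapply(config$fuse, function(cfg) {
      run_pipeline(index, queries, cfg, embeddings = embeddings,
                   records = records, qrels = NULL, scheme = scheme,
                   classifier = classifier, config_stop = config_stop)$run
    })
    run <- combine_runs(sub[[1]], sub[[2]], alpha = config$alpha,
                        tag = if (is.null(config$preset)) "fused" else config$preset)
    intermediate <- sub
  } else {
    if (config$expansion_model > 0L && config$k > 0L && is.null(embeddings)) {
      stop("preset ", config$preset %||% config$ranker,
           " needs a word-embedding table; none was supplied")
    }
    pieces <- lapply(seq_len(nrow(queries)), function(i) {
      tokens <- normalize_text(queries$text[i], config = config_stop,
                               mode = "query")
      if (!length(tokens)) return(NULL)
      wq <- expand_query(tokens,
                         space = if (config$expansion_model > 0L) embeddings,
                         k = if (config$expansion_model > 0L) config$k else 0L,
                         model = max(1L, config$expansion_model),
                         l = config$l, index = index, config = config_stop)
      if (config$ranker == "rtrl") {
        rtrl_rank(wq, index, rtrl_params(c = config$c),
                  cutoff = config$cutoff, query_id = queries$query_id[i])
      } else {
        dfr_rank(wq, index, c_norm = config$c_norm,
                 cutoff = config$cutoff, query_id = queries$query_id[i])
      }
    })
    pieces <- Filter(Negate(is.null), pieces)
    pieces <- Filter(nrow, pieces)
    if (!length(pieces)) {
      run <- ranked_run(tag = config$preset %||% config$ranker)
    } else {
      all <- do.call(rbind, pieces)
      run <- ranked_run(all$query_id, all$doc_id, all$score,
                        tag = config$preset %||% config$ranker)
    }
    if (config$g > 0 && nrow(run)) {
      if (is.null(records)) {
        stop("category boosting (g > 0) needs the corpus records")
      }
      if (is.null(scheme)) scheme <- read_category_scheme(config = config_stop)
      qcls <- lapply(seq_len(nrow(queries)), function(i) {
        classify_query(queries$text[i], scheme = scheme, config = config_stop)
      })
      names(qcls) <- queries$query_id
      rec_by_id <- stats::setNames(records,
                                   vapply(records, `[[`, character(1), "doc_id"))
      dcls <- lapply(unique(run$doc_id), function(d) {
        rec <- rec_by_id[[d]]
        if (is.null(rec)) return(character(0))
        classify_dataset(rec, model = classifier,
                         keyword_only = is.null(classifier),
                         scheme = scheme, config = config_stop)
      })
      names(dcls) <- unique(run$doc_id)
      run <- boost_run(run, qcls, dcls, g = config$g,
                       top_fraction = config$top_fraction)
    }
  }
  report <- if (!is.null(qrels)) evaluate_run(run, qrels) else NULL
  list(run = run, report = report, config = config,
       intermediate = intermediate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
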