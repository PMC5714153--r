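scheme <- read_category_scheme()

test_that("query classification matches descriptor grams and clinical keywords", {
  expect_true("Sequences" %in%
    classify_query("Find protein sequencing data related to bacterial
                    chemotaxis across all databases", scheme))
  expect_true("Clinical trial" %in%
    classify_query("data on breast cancer patients", scheme))
  # skip-grams bridge an intervening token
  expect_true("Sequences" %in%
    classify_query("protein based sequencing assay", scheme))
  expect_length(classify_query("banana",
                               structure(list(), class = "category_scheme")),
                0)
  expect_length(classify_query("", scheme), 0)
})

test_that("query classification is monotone in the scheme", {
  small <- structure(list(Sequences = "sequenc"), class = "category_scheme")
  big <- structure(list(Sequences = "sequenc",
                        Expression = c("express", "gene express")),
                   class = "category_scheme")
  q <- "gene expression and sequencing study"
  expect_true(all(classify_query(q, small) %in% classify_query(q, big)))
})

test_that("keyword rule assigns the clinical-trial class to datasets", {
  rec <- dataset_record("d1", title = "phase III clinical trial of drug X")
  expect_true("Clinical trial" %in%
                classify_dataset(rec, keyword_only = TRUE, scheme = scheme))
  rec2 <- dataset_record("d2", title = "yeast growth curves")
  expect_false("Clinical trial" %in%
                 classify_dataset(rec2, keyword_only = TRUE, scheme = scheme))
  expect_error(classify_dataset(rec, model = NULL, keyword_only = FALSE),
               "keyword_only")
})

# two topically separable classes, disjoint vocabularies
classifier_fixture <- function(n_per = 25, seed = 31) {
  set.seed(seed)
  gene_words <- c("expression", "transcriptome", "microarray", "rnaseq",
                  "probe", "transcript")
  trial_words <- c("patients", "randomized", "placebo", "enrollment",
                   "dosage", "cohort")
  texts <- c(
    vapply(seq_len(n_per), function(i) {
      paste(sample(gene_words, 8, TRUE), collapse = " ")
    }, character(1)),
    vapply(seq_len(n_per), function(i) {
      paste(sample(trial_words, 8, TRUE), collapse = " ")
    }, character(1)))
  labels <- c(rep(list("Expression"), n_per), rep(list("Clinical"), n_per))
  list(texts = texts, labels = labels)
}

test_that("classifier separates planted classes and is reproducible", {
  fx <- classifier_fixture()
  train <- c(1:20, 26:45)
  test_idx <- setdiff(seq_along(fx$texts), train)
  m1 <- train_dataset_classifier(fx$texts[train], fx$labels[train],
                                 embed_dim = 10, seed = 7)
  m2 <- train_dataset_classifier(fx$texts[train], fx$labels[train],
                                 embed_dim = 10, seed = 7)
  preds <- lapply(fx$texts[test_idx], function(tx) predict_dataset_scores(m1, tx))
  preds2 <- lapply(fx$texts[test_idx], function(tx) predict_dataset_scores(m2, tx))
  expect_equal(preds, preds2) # seed-fixed retrain, identical scores

  f1_per_class <- vapply(c("Expression", "Clinical"), function(cl) {
    truth <- vapply(fx$labels[test_idx], function(l) cl %in% l, logical(1))
    called <- vapply(preds, function(p) p[[cl]] >= 0.5, logical(1))
    tp <- sum(truth & called)
    if (tp == 0) return(0)
    prec <- tp / sum(called)
    rec <- tp / sum(truth)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  expect_gte(mean(f1_per_class), 0.9)

  # save/load round-trip preserves scores
  tmp <- tempfile(fileext = ".rds")
  classifier_save(m1, tmp)
  m3 <- classifier_load(tmp)
  expect_equal(predict_dataset_scores(m3, fx$texts[test_idx[1]]),
               preds[[1]])

  # an impossible threshold leaves only keyword classes
  rec <- dataset_record("d9", title = fx$texts[1])
  expect_length(classify_dataset(rec, model = m1, threshold = 1.01), 0)

  expect_error(train_dataset_classifier(fx$texts[1:20], fx$labels[1:20]),
               "two classes")
})

test_that("boosting promotes matching top-half documents only", {
  run <- ranked_run(rep("T1", 4), c("A", "B", "C", "D"),
                    c(10, 9.5, 8, 7))
  qcls <- list(T1 = "Sequences")
  dcls <- list(A = character(0), B = "Sequences", C = character(0),
               D = "Sequences")
  boosted <- boost_run(run, qcls, dcls, g = 0.10, top_fraction = 0.5)
  expect_equal(boosted$doc_id[1:2], c("B", "A"))
  expect_equal(boosted$score[boosted$doc_id == "B"], 10.45)
  # D matches but sits in the bottom half: untouched
  expect_equal(boosted$score[boosted$doc_id == "D"], 7)
  # g = 0 is the identity
  same <- boost_run(run, qcls, dcls, g = 0)
  expect_equal(same$doc_id, run$doc_id)
  expect_equal(same$score, run$score)
  # empty query classes: identity
  none <- boost_run(run, list(T1 = character(0)), dcls, g = 0.10)
  expect_equal(none$score, run$score)
})

test_that("boosting never demotes a matching document", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    run <- ranked_run(rep("T1", n), sprintf("d%02d", 1:n),
                      sort(runif(n, 1, 10), decreasing = TRUE))
    dcls <- lapply(seq_len(n), function(j) {
      if (runif(1) < 0.4) "Sequences" else character(0)
    })
    names(dcls) <- run$doc_id
    boosted <- boost_run(run, list(T1 = "Sequences"), dcls, g = 0.10)
    for (d in run$doc_id) {
      if (length(dcls[[d]])) {
        expect_lte(boosted$rank[boosted$doc_id == d],
                   run$rank[run$doc_id == d])
      }
    }
    # bottom-half scores unchanged
    bottom <- run$doc_id[run$rank > ceiling(n / 2)]
    expect_equal(boosted$score[match(bottom, boosted$doc_id)],
                 run$score[match(bottom, run$doc_id)])
  }
})
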