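# planted embedding space with chosen cosines to one query vector
planted_space <- function(cosines, dim = 8) {
  q <- c(1, rep(0, dim - 1))
  rows <- list(q = q)
  for (i in seq_along(cosines)) {
    v <- c(cosines[i], sqrt(1 - cosines[i]^2) *
             as.numeric(seq_len(dim - 1) == (i %% (dim - 1)) + 1))
    rows[[names(cosines)[i]]] <- v
  }
  do.call(rbind, rows)
}

test_that("key-relevance uses the median document-frequency rule", {
  # dfs tcell 6, multipl 5, homeostasi 2, sclerosi 1 -> median 3.5
  toks <- c(
    list(d01 = c("homeostasi", "sclerosi", "sclerosi", "f01"),
         d02 = c("tcell", "tcell", "multipl", "homeostasi"),
         d03 = "tcell"),
    stats::setNames(lapply(1:4, function(i) c("tcell", "multipl")),
                    sprintf("d%02d", 4:7)),
    list(d08 = "f01", d09 = "f02", d10 = c("f01", "f03"))
  )
  idx <- build_index(oracle_records(toks))
  cls <- classify_key_relevance(c("tcell", "multipl", "homeostasi",
                                  "sclerosi"), idx)
  expect_equal(cls[["homeostasi"]], "key-relevant")
  expect_equal(cls[["sclerosi"]], "key-relevant")
  expect_equal(cls[["tcell"]], "relevant")
  expect_equal(cls[["multipl"]], "relevant")

  # rarer of two terms is key-relevant, the other merely relevant
  cls2 <- classify_key_relevance(c("multipl", "homeostasi"), idx)
  expect_equal(cls2[["homeostasi"]], "key-relevant")
  expect_equal(cls2[["multipl"]], "relevant")

  # single term is key-relevant by the median rule; unseen terms too
  expect_equal(unname(classify_key_relevance("tcell", idx)), "key-relevant")
  expect_equal(unname(classify_key_relevance(c("zzz", "tcell"), idx)["zzz"]),
               "key-relevant")
  expect_error(classify_key_relevance(character(0), idx), "empty")
})

test_that("expansion returns neighbours in descending cosine order", {
  sp <- planted_space(c(aa = 0.9, bb = 0.8, cc = 0.7, zz = 0.1))
  idx <- build_index(oracle_records(list(d1 = "q")))
  wq <- expand_query("q", space = sp, k = 3, model = 1, index = idx)
  exp_rows <- wq[wq$origin == "expanded", ]
  expect_equal(exp_rows$term, c("aa", "bb", "cc"))
  expect_equal(exp_rows$weight, c(0.9, 0.8, 0.7), tolerance = 1e-9)
  expect_true(all(diff(exp_rows$weight) < 0))
  expect_true(all(wq$weight[wq$origin == "original"] == 1))
  # originals come first
  expect_equal(wq$origin[1], "original")
})

test_that("k = 0 and out-of-vocabulary terms leave the query unexpanded", {
  sp <- planted_space(c(aa = 0.9))
  idx <- build_index(oracle_records(list(d1 = c("q", "oov"))))
  wq0 <- expand_query(c("q", "oov"), space = sp, k = 0, index = idx)
  expect_equal(nrow(wq0), 2)
  expect_true(all(wq0$weight == 1))
  wq <- expand_query(c("q", "oov"), space = sp, k = 1, index = idx)
  expect_true("oov" %in% wq$term)        # stays in the query
  expect_equal(sum(wq$origin == "expanded"), 1) # only q expands
})

test_that("kNN selection equals exhaustive cosine ranking on random spaces", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(10:40, 1)
    dim <- sample(3:10, 1)
    emb <- matrix(rnorm(n * dim), n, dim)
    rownames(emb) <- sprintf("w%02d", seq_len(n))
    term <- sample(rownames(emb), 1)
    k <- sample(1:8, 1)
    got <- nearest_terms(emb, term, k)
    # independent brute force
    sims <- apply(emb, 1, function(v) {
      sum(v * emb[term, ]) / sqrt(sum(v^2) * sum(emb[term, ]^2))
    })
    sims <- sims[names(sims) != term]
    want <- names(sort(sims, decreasing = TRUE))[seq_len(k)]
    expect_equal(got$term, want)
  }
})

test_that("model 2 reduces penalized weights by exactly the loss factor", {
  sp <- planted_space(c(aa = 0.9, bb = 0.8))
  # q frequent (relevant), rare term key-relevant
  toks <- c(stats::setNames(lapply(1:6, function(i) "q"),
                            sprintf("d%d", 1:6)),
            list(d7 = c("rare", "q")))
  idx <- build_index(oracle_records(toks))
  m1 <- expand_query(c("q", "rare"), space = sp, k = 2, model = 1, index = idx)
  m2_l0 <- expand_query(c("q", "rare"), space = sp, k = 2, model = 2, l = 0,
                        index = idx)
  expect_equal(m2_l0, m1)
  m2 <- expand_query(c("q", "rare"), space = sp, k = 2, model = 2, l = 0.01,
                     index = idx)
  penal <- m2$relevance_class != "key-relevant"
  expect_equal(m2$weight[penal], m1$weight[match(m2$term[penal], m1$term)] * 0.99)
  expect_equal(m2$weight[!penal], m1$weight[match(m2$term[!penal], m1$term)])
  # multiply mode scales by l instead
  m2m <- expand_query(c("q", "rare"), space = sp, k = 2, model = 2, l = 0.01,
                      index = idx, loss_mode = "multiply")
  expect_equal(m2m$weight[m2m$term == "q"], 0.01)
})

test_that("embedding training is seed-deterministic and finds co-occurrence", {
  docs <- c(rep(list(c("aa", "bb", "aa", "bb", "aa", "bb")), 30),
            rep(list(c("cc", "dd", "ee", "cc", "dd", "ee")), 30))
  e1 <- train_embeddings(docs, dim = 8, window = 2, seed = 9, epochs = 10)
  e2 <- train_embeddings(docs, dim = 8, window = 2, seed = 9, epochs = 10)
  expect_identical(e1, e2)
  expect_equal(ncol(e1), 8)
  cos <- function(a, b) sum(e1[a, ] * e1[b, ]) /
    sqrt(sum(e1[a, ]^2) * sum(e1[b, ]^2))
  # aa's nearest neighbour should be its constant companion bb
  sims <- cosine_similarities(e1, e1["aa", ])
  sims <- sims[names(sims) != "aa"]
  expect_equal(names(which.max(sims)), "bb")
  expect_error(train_embeddings(list("aa"), dim = 4, window = 5), "window")
})
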