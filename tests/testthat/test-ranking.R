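# fixture with document frequencies tcell 6, multipl 5, homeostasi 2,
# sclerosi 1 in a 10-document collection
rtrl_fixture <- function() {
  toks <- c(
    list(d01 = c("homeostasi", "sclerosi", "sclerosi", "f01"),
         d02 = c("tcell", "tcell", "multipl", "homeostasi"),
         d03 = "tcell"),
    stats::setNames(lapply(1:4, function(i) c("tcell", "multipl")),
                    sprintf("d%02d", 4:7)),
    list(d08 = "f01", d09 = "f02", d10 = c("f01", "f03"))
  )
  idx <- build_index(oracle_records(toks))
  terms <- c("tcell", "multipl", "homeostasi", "sclerosi")
  wq <- expand_query(terms, index = idx)
  list(toks = toks, idx = idx, wq = wq)
}

test_that("key weight is c(2L - 2) and satisfies the dominance inequality", {
  expect_equal(key_weight(4), 6)
  expect_equal(key_weight(2), 2)
  expect_equal(key_weight(4, rtrl_params(c = 2)), 12)
  expect_warning(w1 <- key_weight(1), "degenerate")
  expect_equal(w1, 1)
  for (L in 2:20) {
    for (cg in c(1, 2, 4)) {
      wq2 <- key_weight(L, rtrl_params(c = cg))
      k <- L / 2
      margin <- k * (1 + wq2) - (k - 1) * (2 + wq2) - (L - k) * (2 + 1)
      if (cg == 1) expect_equal(margin, 0) else expect_gte(margin, 0)
    }
  }
})

test_that("document and query weights are two-level step functions", {
  expect_equal(doc_weight(1), 1)
  expect_equal(doc_weight(2), 2)
  expect_equal(doc_weight(1000), 2)
  expect_error(doc_weight(0), "present")
  expect_equal(query_weight("relevant", 4), 1)
  expect_equal(query_weight("key-relevant", 4), 6)
  expect_equal(query_weight("key-relevant", 3), 4)
})

test_that("bin scores reproduce the hand-derived 15/12/2 example", {
  fx <- rtrl_fixture()
  expect_equal(rtrl_bin_score("d01", fx$wq, fx$idx), 15)
  expect_equal(rtrl_bin_score("d02", fx$wq, fx$idx), 12)
  expect_equal(rtrl_bin_score("d03", fx$wq, fx$idx), 2)
  # absent everything scores zero
  expect_equal(rtrl_bin_score("d09", fx$wq, fx$idx), 0)
  # two docs holding one distinct key term each land in the same bin
  toks2 <- list(da = "homeostasi", db = "sclerosi",
                dc = c("homeostasi", "f01"), dd = "f01")
  idx2 <- build_index(oracle_records(toks2))
  wq2 <- expand_query(c("tcell", "multipl", "homeostasi", "sclerosi"),
                      index = idx2)
  expect_equal(rtrl_bin_score("da", wq2, idx2),
               rtrl_bin_score("db", wq2, idx2))
})

test_that("tf and idf components follow the stated formulas", {
  # tf at the document maximum is 1; idf of an everywhere-term is 0
  toks <- list(d1 = c("t01", "t01", "t01", "t02"), d2 = c("t02", "t02"))
  idx <- build_index(oracle_records(toks))
  wq <- expand_query(c("t01", "t02"), index = idx)
  tie <- bin_tiebreak(c("d1"), wq, idx)
  expect_true(tie[["d1"]] > 0 && tie[["d1"]] <= 1)
  # tf at the doc maximum (ftd = 3 = max) is 1; idf of t02 (in both of 2
  # docs) is log(1) = 0, so t02 contributes nothing despite tf = 2/3
  raw_d1 <- 1 * log(2 / 1) + (0.5 + 0.5 * 1 / 3) * 0
  expect_equal(tie[["d1"]], raw_d1 / (raw_d1 + 1e-6))
  # tf off the maximum: ftd = 1 against doc max 4 -> 0.5 + 0.5/4
  toks4 <- list(da = c(rep("t01", 4), "t02"), db = "f01")
  idx4 <- build_index(oracle_records(toks4))
  wq4 <- expand_query("t02", index = idx4)
  tie4 <- bin_tiebreak("da", wq4, idx4)
  raw4 <- (0.5 + 0.5 * 1 / 4) * log(2 / 1)
  expect_equal(tie4[["da"]], raw4 / (raw4 + 1e-6))
})

test_that("rtrl ranking matches the brute-force oracle on the fixture", {
  fx <- rtrl_fixture()
  run <- rtrl_rank(fx$wq, fx$idx, query_id = "T1")
  want <- oracle_rtrl(fx$toks, fx$wq)
  expect_equal(run$doc_id, want$doc_id)
  expect_equal(run$score, want$final, tolerance = 1e-9)
  expect_equal(run$doc_id[1:2], c("d01", "d02"))
  expect_equal(floor(run$score[1:2]), c(15, 12))
})

test_that("empty queries and tie cases behave deterministically", {
  fx <- rtrl_fixture()
  empty <- expand_query(character(0), index = fx$idx)
  expect_equal(nrow(rtrl_rank(empty, fx$idx)), 0)
  # identical docs order by doc_id
  toks <- list(db = "t01", da = "t01", dc = "f01")
  idx <- build_index(oracle_records(toks))
  wq <- expand_query("t01", index = idx)
  expect_warning(run <- rtrl_rank(wq, idx), "degenerate")
  expect_equal(run$doc_id, c("da", "db"))
})

test_that("adding a query-term occurrence never lowers the final score", {
  set.seed(21)
  for (i in 1:20) {
    case <- random_oracle_case(2000 + i, max_docs = 15, max_terms = 10)
    idx1 <- build_index(oracle_records(case$doc_tokens))
    target <- names(case$doc_tokens)[1]
    qterm <- case$query$term[1]
    toks2 <- case$doc_tokens
    toks2[[target]] <- c(toks2[[target]], qterm)
    idx2 <- build_index(oracle_records(toks2))
    s1 <- rtrl_bin_score(target, case$query, idx1)
    s2 <- rtrl_bin_score(target, case$query, idx2)
    expect_gte(s2, s1)
  }
})

test_that("InL2 contributions match direct formula evaluation", {
  # N = 2, len = avg_len, ftd = 2, nt = 1, c_norm = 1
  toks <- list(d1 = c("t01", "t01"), d2 = c("t02", "t02"))
  idx <- build_index(oracle_records(toks))
  wq <- expand_query("t01", index = idx)
  run <- dfr_rank(wq, idx, c_norm = 1)
  expect_equal(nrow(run), 1) # absent from d2 -> contributes 0, not retrieved
  expect_equal(run$score[1], (2 / 3) * log2(3 / 1.5), tolerance = 1e-12)
  expect_error(dfr_rank(wq, idx, c_norm = 0), "c_norm")
})

test_that("query weights multiply both scorers' contributions", {
  toks <- list(d1 = "t01", d2 = "t02")
  idx <- build_index(oracle_records(toks))
  wq <- expand_query(c("t01", "t02"), index = idx)
  wq$weight[wq$term == "t02"] <- 0.5
  r <- dfr_rank(wq, idx)
  s <- stats::setNames(r$score, r$doc_id)
  expect_equal(unname(s["d2"] / s["d1"]), 0.5, tolerance = 1e-12)
  b1 <- rtrl_bin_score("d1", wq, idx)
  b2 <- rtrl_bin_score("d2", wq, idx)
  expect_equal(b2 / b1, 0.5, tolerance = 1e-12)
})
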