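qrels_of <- function(...) {
  df <- data.frame(...)
  graded_qrels(df$q, df$d, df$g)
}

run_of <- function(docs, qid = "T1") {
  ranked_run(rep(qid, length(docs)), docs,
             seq(length(docs), 1))
}

test_that("precision at k counts grades by partial mode", {
  qr <- qrels_of(q = "T1", d = c("d1", "d2", "d3"), g = c(2, 0, 2))
  run <- run_of(c("d1", "d2", "d3"))
  expect_equal(unname(p_at_k(run, qr, k = 3, partial_mode = "exclude")), 2 / 3)
  qr2 <- qrels_of(q = "T1", d = c("d1", "d2", "d3"), g = c(1, 1, 1))
  expect_equal(unname(p_at_k(run, qr2, k = 3, partial_mode = "include")), 1)
  expect_equal(unname(p_at_k(run, qr2, k = 3, partial_mode = "exclude")), 0)
  # short rankings still divide by k; unpooled docs count as not relevant
  expect_equal(unname(p_at_k(run_of("d1"), qr, k = 10)), 1 / 10)
  expect_equal(unname(p_at_k(run_of("zz"), qr, k = 10)), 0)
})

test_that("NDCG@k follows the closed form with ideal from full qrels", {
  qr <- qrels_of(q = "T1", d = "d1", g = 2)
  expect_equal(unname(ndcg_at_k(run_of("d1"), qr, k = 10)), 1)
  run2 <- run_of(c("d0", "d1"))
  expect_equal(unname(ndcg_at_k(run2, qr, k = 10)),
               (2 / log2(3)) / 2)
  qr0 <- qrels_of(q = "T1", d = c("d1", "d2"), g = c(0, 0))
  expect_warning(v <- ndcg_at_k(run_of("d1"), qr0), "no positively graded")
  expect_true(is.na(v[["T1"]]))
  qr3 <- qrels_of(q = "T1", d = c("d1", "d2", "d3"), g = c(2, 1, 0))
  expect_equal(unname(ndcg_at_k(run_of(c("d3", "d3x")), qr3, k = 10)), 0)
})

test_that("inferred AP reduces to exact AP under complete judgments", {
  qr <- qrels_of(q = "T1", d = c("d1", "d2", "d3"), g = c(2, 0, 2))
  run <- run_of(c("d1", "d2", "d3"))
  want <- (1 / 1 + 2 / 3) / 2
  for (mode in c("sampled", "as-nonrelevant", "removed")) {
    expect_equal(unname(inf_ap(run, qr, mode = mode)), want,
                 tolerance = 1e-3)
  }
})

test_that("unjudged-handling modes behave as specified", {
  # all retrieved unjudged, as-nonrelevant -> 0
  qr <- qrels_of(q = "T1", d = c("d1", "d2", "d3"), g = c(-1, -1, 2))
  run <- run_of(c("d1", "d2"))
  expect_equal(unname(inf_ap(run, qr, mode = "as-nonrelevant")), 0)
  # removed drops -1 docs, exact AP on the filtered ranking
  run2 <- run_of(c("d1", "d4", "d3", "d2"))
  got <- unname(inf_ap(run2, qr, mode = "removed"))
  # filtered ranking: d4 (unpooled), d3 (rel) -> AP = (1/2) / 1
  expect_equal(got, 0.5)
  # removing unjudged docs never lowers AP relative to grading them 0
  set.seed(51)
  for (i in 1:30) {
    n <- 12
    grades <- sample(c(-1, 0, 1, 2), n, TRUE)
    if (!any(grades >= 1)) grades[1] <- 2
    qr3 <- qrels_of(q = "T1", d = sprintf("d%02d", 1:n), g = grades)
    run3 <- run_of(sprintf("d%02d", sample(n)))
    expect_gte(unname(inf_ap(run3, qr3, mode = "removed")),
               unname(inf_ap(run3, qr3, mode = "as-nonrelevant")))
  }
})

test_that("inferred metrics equal their exact forms on 500 complete cases", {
  set.seed(52)
  for (i in 1:500) {
    n_pool <- sample(5:25, 1)
    grades <- sample(0:2, n_pool, TRUE, prob = c(0.5, 0.25, 0.25))
    if (!any(grades > 0)) grades[1] <- 2
    docs <- sprintf("d%03d", seq_len(n_pool))
    qr <- qrels_of(q = "T1", d = docs, g = grades)
    retrieved <- sample(docs, sample(2:n_pool, 1))
    run <- run_of(retrieved)
    g_in_order <- grades[match(retrieved, docs)]
    expect_equal(unname(inf_ap(run, qr, mode = "sampled")),
                 oracle_ap(g_in_order, sum(grades >= 1)),
                 tolerance = 1e-3)
    expect_equal(unname(inf_ndcg(run, qr, mode = "sampled")),
                 oracle_ndcg(g_in_order, grades),
                 tolerance = 1e-3)
  }
})

test_that("including partial relevance never lowers P@10", {
  set.seed(53)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    docs <- sprintf("d%03d", seq_len(n))
    qr <- qrels_of(q = "T1", d = docs, g = sample(c(-1, 0, 1, 2), n, TRUE))
    run <- run_of(sample(docs, sample(3:n, 1)))
    expect_gte(unname(p_at_k(run, qr, partial_mode = "include")),
               unname(p_at_k(run, qr, partial_mode = "exclude")))
  }
})

test_that("UIR is antisymmetric and counts unanimous wins", {
  # A strictly better everywhere
  A <- data.frame(m1 = c(0.9, 0.8), m2 = c(0.7, 0.6))
  B <- data.frame(m1 = c(0.5, 0.4), m2 = c(0.3, 0.2))
  u <- uir(list(A = A, B = B))
  expect_equal(u$pairwise["A", "B"], 1)
  expect_equal(u$pairwise["B", "A"], -1)
  expect_equal(unname(uir(list(A = A, B = A))$pairwise["A", "B"]), 0)

  # three systems against a brute-force pairwise count
  set.seed(54)
  systems <- lapply(1:3, function(i) {
    as.data.frame(matrix(runif(5 * 3), 5, 3,
                         dimnames = list(NULL, c("m1", "m2", "m3"))))
  })
  names(systems) <- c("s1", "s2", "s3")
  u3 <- uir(systems)
  for (a in names(systems)) for (b in names(systems)) {
    if (a == b) next
    na <- nb <- 0
    for (q in 1:5) {
      va <- as.numeric(systems[[a]][q, ])
      vb <- as.numeric(systems[[b]][q, ])
      if (all(va >= vb) && any(va > vb)) na <- na + 1
      if (all(vb >= va) && any(vb > va)) nb <- nb + 1
    }
    expect_equal(u3$pairwise[a, b], (na - nb) / 5)
    expect_equal(u3$pairwise[a, b], -u3$pairwise[b, a])
  }
  expect_error(uir(list(A = A)), "2")
})

test_that("evaluate_run aggregates all metrics and flags odd queries", {
  qr <- qrels_of(q = c("T1", "T1", "T2", "T2"),
                 d = c("d1", "d2", "d1", "d2"), g = c(2, 0, 1, 2))
  perfect <- ranked_run(c("T1", "T1", "T2", "T2"),
                        c("d1", "d2", "d2", "d1"), c(2, 1, 2, 1))
  rep1 <- evaluate_run(perfect, qr)
  expect_equal(unname(rep1$means["P10_plus"]), 0.15)
  expect_equal(unname(rep1$means["infAP"]), 1, tolerance = 1e-3)
  expect_equal(unname(rep1$means["NDCG10"]), 1)
  reversed <- ranked_run(c("T1", "T2"), c("d2", "d1"), c(1, 1))
  rep2 <- evaluate_run(reversed, qr)
  expect_lt(rep2$means["infAP"], rep1$means["infAP"])
  expect_warning(evaluate_run(ranked_run("T9", "d1", 1), qr), "absent")
  empty <- evaluate_run(ranked_run(), qr)
  expect_equal(nrow(empty$per_query), 0)
})
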