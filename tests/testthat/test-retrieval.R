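groups <- function(...) {
  lapply(list(...), function(x) {
    list(head_term = x[[1]], synonyms = x[-1])
  })
}

test_that("keyword score is the fraction of matched groups, synonyms included", {
  g2 <- groups(c("lung cancer", "pulmonary carcinoma"), c("EGFR"))
  expect_equal(keyword_match_score("EGFR mutations in lung cancer", g2), 1)
  expect_equal(keyword_match_score("pulmonary carcinoma cases", g2), 0.5)
  expect_equal(keyword_match_score("nothing relevant here", g2), 0)
  expect_equal(keyword_match_score("", g2), 0)
  # word-boundary, case-insensitive: no substring matches
  g1 <- groups(c("ras"))
  expect_equal(keyword_match_score("the RAS pathway", g1), 1)
  expect_equal(keyword_match_score("erasure of signal", g1), 0)
  expect_error(keyword_match_score("text", list()), "no keyword groups")
})

test_that("keyword scores agree with a regex-free scan oracle", {
  scan_match <- function(text, term) {
    # exhaustive lowercase substring scan with manual boundary checks
    t <- tolower(text); s <- tolower(term)
    L <- nchar(s); n <- nchar(t)
    if (L == 0 || L > n) return(FALSE)
    is_word <- function(ch) grepl("[a-z0-9]", ch)
    for (i in seq_len(n - L + 1)) {
      if (substr(t, i, i + L - 1) == s) {
        before_ok <- i == 1 || !is_word(substr(t, i - 1, i - 1))
        after_ok <- i + L - 1 == n || !is_word(substr(t, i + L, i + L))
        if (before_ok && after_ok) return(TRUE)
      }
    }
    FALSE
  }
  w <- fixture_world()
  gs <- groups(c("Velmora Syndrome", "Drexun Disease"), c("Zelvistat"),
               c("supportive therapy"))
  chunks <- vapply(w$index$chunks[1:30], function(ch) ch$text, character(1))
  for (txt in chunks) {
    oracle <- mean(vapply(gs, function(g) {
      any(vapply(c(g$head_term, g$synonyms), scan_match, logical(1),
                 text = txt))
    }, logical(1)))
    expect_equal(keyword_match_score(txt, gs), oracle)
  }
})

test_that("retrieval runs five strategies, or three when no virtual answer", {
  w <- fixture_world()
  q <- w$manifest$gold_qa[[1]]$question
  bundle <- run_preretrieval(q, w$llm)
  hits <- retrieve_all(bundle, w$index, w$emb, emb_index = w$emb_index)
  expect_setequal(unique(hits$strategy),
                  c("question_abstract", "virtual_abstract",
                    "question_fulltext", "virtual_fulltext", "keyword"))
  per <- table(hits$strategy)
  expect_true(all(per[c("question_abstract", "question_fulltext",
                        "virtual_abstract", "virtual_fulltext")] == 10))
  expect_true(all(hits$raw_score >= 0 & hits$raw_score <= 1))

  bundle$virtual_answer <- ""
  hits3 <- retrieve_all(bundle, w$index, w$emb, emb_index = w$emb_index)
  expect_setequal(unique(hits3$strategy),
                  c("question_abstract", "question_fulltext", "keyword"))
  expect_equal(formals(retrieve_all)$k_per_strategy, 10)
})

test_that("a planted-fact chunk is found by several strategies at once", {
  w <- fixture_world()
  g <- w$manifest$gold_qa[[1]]            # synonym-gated question
  bundle <- run_preretrieval(g$question, w$llm)
  hits <- retrieve_all(bundle, w$index, w$emb, emb_index = w$emb_index)
  doc_of <- vapply(w$index$chunks, function(ch) ch$doc_id, character(1))
  gold_hits <- hits[doc_of[hits$chunk_id] %in% g$gold_doc_ids, ]
  expect_gte(length(unique(gold_hits$strategy)), 2)
  expect_true("keyword" %in% gold_hits$strategy)
})

test_that("a single-candidate pool scores exactly w_S + w_M + w_R", {
  hits <- data.frame(chunk_id = "c1", strategy = "keyword", raw_score = 0.4,
                     rank_within_strategy = 1L)
  out <- fuse_candidates(hits, c(c1 = "d1"))
  expect_identical(out$fused_score, 9)
  out2 <- fuse_candidates(hits, c(c1 = "d1"), aggregator_weights(2, 7, 0.5))
  expect_identical(out2$fused_score, 9.5)
})

test_that("the fused three-candidate example reproduces the closed-form scores", {
  # pool A: S .9 M 2 R 1 | B: S .6 M 3 R 2 | C: S .3 M 1 R 2
  hits <- rbind(
    data.frame(chunk_id = "A", strategy = c("keyword", "question_fulltext"),
               raw_score = c(0.9, 0.2), rank_within_strategy = 1:2),
    data.frame(chunk_id = "B",
               strategy = c("keyword", "question_fulltext",
                            "virtual_fulltext"),
               raw_score = c(0.6, 0.5, 0.1), rank_within_strategy = 1:3),
    data.frame(chunk_id = "C", strategy = "keyword", raw_score = 0.3,
               rank_within_strategy = 1L))
  doc_of <- c(A = "dA", B = "dB", C = "dB")
  out <- fuse_candidates(hits, doc_of)
  expect_equal(out$chunk_id, c("A", "B", "C"))
  expect_equal(out$fused_score, c(7.5, 7 + 1/3, 3 + 2/3), tolerance = 1e-12)
  expect_equal(out$S_sim, c(0.9, 0.6, 0.3))
  expect_equal(out$M, c(2L, 3L, 1L))
  expect_equal(out$R, c(1L, 2L, 2L))
})

test_that("fusion matches the independent oracle and is scale-invariant and monotone", {
  set.seed(99)
  for (i in 1:40) {
    pool <- random_hit_pool(sample(2:20, 1))
    out <- fuse_candidates(pool$hits, pool$doc_of)
    oracle <- oracle_fuse(pool$hits, pool$doc_of)
    expect_equal(out$fused_score, unname(oracle[out$chunk_id]),
                 tolerance = 1e-9)
    expect_lte(max(out$fused_score), 9 + 1e-12)

    scaled <- pool$hits
    scaled$raw_score <- scaled$raw_score * 0.37
    expect_equal(fuse_candidates(scaled, pool$doc_of)$chunk_id,
                 out$chunk_id)

    below <- which(out$S_sim < max(out$S_sim))
    if (length(below)) {
      target <- out$chunk_id[below[1]]
      bumped <- pool$hits
      sel <- bumped$chunk_id == target
      bumped$raw_score[sel] <- bumped$raw_score[sel] +
        0.5 * (max(out$S_sim) - out$S_sim[below[1]])
      rank_after <- match(target, fuse_candidates(bumped, pool$doc_of)$chunk_id)
      expect_lte(rank_after, below[1])
    }
  }
  expect_warning(empty <- fuse_candidates(
    data.frame(chunk_id = character(), strategy = character(),
               raw_score = numeric(), rank_within_strategy = integer()),
    c(a = "d")), "no hits")
  expect_equal(nrow(empty), 0)
})
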