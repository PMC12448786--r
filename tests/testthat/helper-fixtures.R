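# Shared fixture world: generated once per test run, seed 7 throughout.
fixture_cache <- new.env(parent = emptyenv())

fixture_world <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(fixture_cache[[key]])) {
    manifest <- generate_corpus(seed)
    index <- fixture_index(manifest)
    backends <- mock_backends(manifest)
    fixture_cache[[key]] <- list(
      manifest = manifest, index = index,
      emb = backends$emb, llm = backends$llm,
      emb_index = embed_index(index, backends$emb))
  }
  fixture_cache[[key]]
}

# random strategy-hit pools for aggregator property tests
random_hit_pool <- function(n_cand, strategies = strategy_pool) {
  ids <- sprintf("c%02d", seq_len(n_cand))
  docs <- stats::setNames(sprintf("d%d", sample(1:4, n_cand, replace = TRUE)),
                          ids)
  rows <- lapply(ids, function(cid) {
    st <- sample(strategies, sample(1:3, 1))
    data.frame(chunk_id = cid, strategy = st,
               raw_score = round(runif(length(st)), 4),
               rank_within_strategy = seq_along(st),
               stringsAsFactors = FALSE)
  })
  list(hits = do.call(rbind, rows), doc_of = docs)
}

strategy_pool <- c("question_abstract", "virtual_abstract",
                   "question_fulltext", "virtual_fulltext", "keyword")

# independent one-line evaluation of the fusion score from first principles
oracle_fuse <- function(hits, doc_of, w = c(5, 3, 1)) {
  ids <- sort(unique(hits$chunk_id))
  S <- vapply(ids, function(i) max(hits$raw_score[hits$chunk_id == i]),
              numeric(1))
  M <- vapply(ids, function(i) {
    length(unique(hits$strategy[hits$chunk_id == i]))
  }, numeric(1))
  doc <- doc_of[ids]
  R <- as.numeric(table(doc)[doc])
  score <- w[1] * S / max(S) + w[2] * M / max(M) + w[3] * R / max(R)
  stats::setNames(score, ids)
}

# slow, character-by-character reimplementation of the boundary scan
slow_split <- function(text, size, ov, seps = c("\n\n", "\n", ". ", "! ",
                                               "? ", " ", "")) {
  n <- nchar(text)
  if (n == 0) return(matrix(numeric(), ncol = 2))
  out <- list()
  pos <- 0
  repeat {
    if (pos + size >= n) { out[[length(out) + 1]] <- c(pos, n); break }
    cut <- NA
    for (s in seps) {
      if (s == "") { cut <- pos + size; break }
      L <- nchar(s)
      best <- NA
      for (e in seq(pos + ov + 1, pos + size)) {   # candidate boundaries
        if (e - L >= 0 && substr(text, e - L + 1, e) == s) best <- e
      }
      if (!is.na(best)) { cut <- best; break }
    }
    out[[length(out) + 1]] <- c(pos, cut)
    pos <- cut - ov
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m
}

random_text <- function(len) {
  if (len == 0) return("")
  words <- c("alpha", "beta", "gamma", "delta", "cohort", "tissue", "assay",
             "signal", "marker", "growth", "cells", "pathway")
  out <- character()
  total <- 0
  while (total < len) {
    w <- sample(words, 1)
    p <- sample(c(" ", " ", " ", ". ", "\n", "\n\n"), 1,
                prob = c(0.6, 0.1, 0.1, 0.1, 0.05, 0.05))
    out <- c(out, w, p)
    total <- total + nchar(w) + nchar(p)
  }
  substr(paste(out, collapse = ""), 1, len)
}

# invariant checks shared by chunker tests
expect_valid_spans <- function(spans, text, size, ov, max_sep = 2) {
  n <- nchar(text)
  if (n == 0) {
    expect_equal(nrow(spans), 0)
    return(invisible())
  }
  expect_equal(spans$start[1], 0)
  expect_equal(spans$end[nrow(spans)], n)
  expect_true(all(spans$end - spans$start <= size))
  expect_true(all(spans$end > spans$start))
  if (nrow(spans) > 1) {
    i <- seq_len(nrow(spans) - 1)
    expect_true(all(spans$start[i + 1] < spans$end[i]))          # coverage
    expect_true(all(spans$end[i] - spans$start[i + 1] <= ov + max_sep))
  }
}
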