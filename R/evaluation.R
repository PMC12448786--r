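#' Document-retrieval precision, recall and F1 for one question
#'
#' Precision is the fraction of retrieved documents that are gold; recall the
#' fraction of gold documents retrieved; F1 their harmonic mean (0 when
#' precision + recall = 0).
#'
#' @param retrieved_doc_ids Character vector of retrieved document ids.
#' @param gold_doc_ids Non-empty character vector of gold document ids.
#' @return List `precision`, `recall`, `f1`, each in \[0, 1\].
#' @export
score_retrieval <- function(retrieved_doc_ids, gold_doc_ids) {
  gold <- unique(gold_doc_ids)
  if (!length(gold)) stop("score_retrieval: empty gold document set")
  retrieved <- unique(retrieved_doc_ids)
  hit <- length(intersect(retrieved, gold))
  precision <- if (length(retrieved)) hit / length(retrieved) else 0
  recall <- hit / length(gold)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Judge-based answer quality score
#'
#' The judge grades the final answer against the gold answer on a 5-point
#' scale; the grade is reported as a percentage, `(grade / 5) * 100`.
#' Unparseable grades score 0 with a warning.
#'
#' @param question,final_answer,gold_answer Non-empty texts.
#' @param judge An LLM backend providing `judge_answer`.
#' @return Score in \[0, 100\].
#' @export
score_answer <- function(question, final_answer, gold_answer, judge) {
  stopifnot(nzchar(question), nzchar(final_answer), nzchar(gold_answer))
  grade <- tryCatch(
    suppressWarnings(as.numeric(
      judge$judge_answer(question, final_answer, gold_answer))),
    error = function(e) NA_real_)
  if (is.na(grade) || grade < 1 || grade > 5) {
    warning("score_answer: unparseable judge grade; scored 0")
    return(0)
  }
  grade / 5 * 100
}

#' Load gold question-answer records from JSON Lines
#'
#' Each line: `question`, `gold_answer`, `gold_doc_ids`, optional
#' `question_type`.
#' @param path JSON Lines file.
#' @return List of gold records.
#' @export
read_gold_qa <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(lines[nzchar(lines)], function(ln) {
    rec <- jsonlite::fromJSON(ln)
    rec$gold_doc_ids <- as.character(unlist(rec$gold_doc_ids))
    if (!length(rec$gold_doc_ids)) {
      stop("gold record with empty gold_doc_ids: ", rec$question)
    }
    rec
  })
}

ablation_modes <- c("full", "no_progressive", "no_integrated", "no_retrieval")

answer_one <- function(mode, question, index, emb, llm, config, emb_index) {
  switch(
    mode,
    full = answer_question(question, index, emb, llm, config, emb_index),
    no_progressive = {
      # answer directly from the top-5 fused candidates, no relevance check,
      # no self-reflection
      bundle <- run_preretrieval(question, llm)
      hits <- retrieve_all(bundle, index, emb,
                           k_per_strategy = config$k_per_strategy,
                           keyword_cap = config$keyword_cap,
                           emb_index = emb_index)
      cand <- fuse_candidates(hits, index, config$weights)
      top <- cand[seq_len(min(config$target, nrow(cand))), , drop = FALSE]
      with_chunk_texts(index, {
        texts <- vapply(top$chunk_id, candidate_text, character(1))
        final <- llm$deep_answer(question, texts)
        top$score <- NA_integer_
        structure(list(question = question, draft_answer = "",
                       final_answer = final, evidence = top,
                       selection_mode = "no_progressive"),
                  class = "answer_record")
      })
    },
    no_integrated = {
      # flat top-50 retrieval by question embedding only, then the full
      # progressive generation stage
      if (is.null(emb_index)) emb_index <- embed_index(index, emb)
      mat <- do.call(rbind, emb_index)
      qv <- emb$embed(question)[1, ]
      top <- top_k_by_similarity(qv, mat, k = 50)
      doc_of <- vapply(index$chunks, function(ch) ch$doc_id, character(1))
      cand <- data.frame(
        chunk_id = top$id, doc_id = unname(doc_of[top$id]),
        S_sim = pmin(1, pmax(0, top$similarity)), M = 1L, R = 1L,
        fused_score = pmin(1, pmax(0, top$similarity)),
        strategies = "question_flat", stringsAsFactors = FALSE)
      with_chunk_texts(index, {
        sel <- relevance_check(cand, question, llm, target = config$target,
                               max_examined = config$max_examined)
        draft <- construct_draft(question, sel$selected, llm)
        scores <- self_reflect(question, draft, sel$selected, llm)
        scored <- merge(sel$selected, scores, by = "chunk_id", sort = FALSE)
        deep_answer(question, scored, llm, draft = draft,
                    selection_mode = sel$selection_mode)
      })
    },
    no_retrieval = {
      final <- llm$deep_answer(question, character(0))
      structure(list(question = question, draft_answer = "",
                     final_answer = final,
                     evidence = data.frame(chunk_id = character(),
                                           doc_id = character(),
                                           score = integer()),
                     selection_mode = "no_retrieval"),
                class = "answer_record")
    },
    stop("unknown ablation mode: ", mode)
  )
}

#' Run the evaluation harness in one ablation configuration
#'
#' Modes: `full` (entire pipeline), `no_progressive` (answer directly from
#' the top-5 fused candidates), `no_integrated` (flat top-50 chunks by
#' question embedding, then progressive generation), `no_retrieval` (backend
#' answers with no context; retrieval metrics are undefined). The retrieved
#' document set scored against gold is the set of unique source documents of
#' the evidence chunks used for final generation.
#'
#' @param mode One of the four ablation modes.
#' @param gold List of gold records (see [read_gold_qa()]).
#' @param index Chunked [corpus_index()].
#' @param emb,llm Backends.
#' @param config A [run_config()].
#' @param emb_index Optional precomputed [embed_index()].
#' @return An `ablation_result`: `per_question` data.frame (question,
#'   precision, recall, f1, answer_score) and `means` (mean of each metric;
#'   retrieval means are `NA` for `no_retrieval`).
#' @export
run_ablation <- function(mode = ablation_modes, gold, index, emb, llm,
                         config = run_config(), emb_index = NULL) {
  mode <- match.arg(mode)
  if (is.null(emb_index) && mode != "no_retrieval") {
    emb_index <- embed_index(index, emb)
  }
  rows <- lapply(gold, function(rec) {
    ans <- answer_one(mode, rec$question, index, emb, llm, config, emb_index)
    if (mode == "no_retrieval") {
      p <- r <- f <- NA_real_
    } else {
      m <- score_retrieval(unique(ans$evidence$doc_id), rec$gold_doc_ids)
      p <- m$precision; r <- m$recall; f <- m$f1
    }
    data.frame(question = rec$question, precision = p, recall = r, f1 = f,
               answer_score = score_answer(rec$question, ans$final_answer,
                                           rec$gold_answer, llm),
               stringsAsFactors = FALSE)
  })
  per_question <- do.call(rbind, rows)
  means <- list(
    precision = mean(per_question$precision),
    recall = mean(per_question$recall),
    f1 = mean(per_question$f1),
    answer_score = mean(per_question$answer_score)
  )
  structure(list(mode = mode, per_question = per_question, means = means),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result> mode=", x$mode, " (", nrow(x$per_question),
      " questions)\n", sep = "")
  fmt <- function(v) if (is.na(v)) "/" else sprintf("%.2f", v * 100)
  cat(sprintf("  mean precision %s%%  recall %s%%  F1 %s%%  answer %.2f%%\n",
              fmt(x$means$precision), fmt(x$means$recall), fmt(x$means$f1),
              x$means$answer_score))
  invisible(x)
}

#' Per-strategy and cumulative document-level recall decomposition
#'
#' For each gold question, each retrieval strategy is run in isolation and
#' its document-level recall recorded per corpus level and multilevel
#' (union of the two levels); cumulative recall adds strategies in the order
#' question-based, + virtual-answer-based, + keyword-based.
#'
#' @inheritParams run_ablation
#' @return Data.frame with one row per granularity (`question`, `virtual`,
#'   `keyword`) and columns `abstract`, `fulltext`, `multilevel`,
#'   `cumulative` — mean recalls in percent.
#' @export
recall_decomposition <- function(gold, index, emb, llm,
                                 config = run_config(), emb_index = NULL) {
  if (is.null(emb_index)) emb_index <- embed_index(index, emb)
  doc_of <- vapply(index$chunks, function(ch) ch$doc_id, character(1))
  per_q <- lapply(gold, function(rec) {
    bundle <- run_preretrieval(rec$question, llm)
    hits <- retrieve_all(bundle, index, emb,
                         k_per_strategy = config$k_per_strategy,
                         keyword_cap = config$keyword_cap,
                         emb_index = emb_index)
    docs_of_strategy <- function(strategies) {
      unique(unname(doc_of[hits$chunk_id[hits$strategy %in% strategies]]))
    }
    rec_frac <- function(docs) {
      length(intersect(docs, rec$gold_doc_ids)) / length(unique(rec$gold_doc_ids))
    }
    levels <- list(
      question = c(abstract = "question_abstract",
                   fulltext = "question_fulltext"),
      virtual = c(abstract = "virtual_abstract",
                  fulltext = "virtual_fulltext"),
      keyword = c(fulltext = "keyword")
    )
    out <- list()
    cum <- character()
    for (gran in names(levels)) {
      st <- levels[[gran]]
      abs_r <- if ("abstract" %in% names(st)) {
        rec_frac(docs_of_strategy(st[["abstract"]]))
      } else 0
      ful_r <- if ("fulltext" %in% names(st)) {
        rec_frac(docs_of_strategy(st[["fulltext"]]))
      } else 0
      multi <- rec_frac(docs_of_strategy(unname(st)))
      cum <- c(cum, unname(st))
      out[[gran]] <- c(abstract = abs_r, fulltext = ful_r, multilevel = multi,
                       cumulative = rec_frac(docs_of_strategy(cum)))
    }
    out
  })
  grans <- c("question", "virtual", "keyword")
  tab <- t(vapply(grans, function(g) {
    colMeans(do.call(rbind, lapply(per_q, `[[`, g))) * 100
  }, numeric(4)))
  data.frame(strategy = grans, tab, row.names = NULL, check.names = FALSE)
}
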