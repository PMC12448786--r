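#' Sequential relevance check over ranked candidates
#'
#' Candidates are examined in fused-score order. Examination stops as soon as
#' `target` chunks are judged relevant. If the list (or the examination
#' budget) is exhausted with between 1 and `target - 1` relevant chunks, only
#' those are kept (mode `"partial"`); if none are relevant, the `target`
#' highest-scoring candidates are kept regardless of the verdicts (mode
#' `"fallback_top5"`).
#'
#' @param candidates Ranked candidate data.frame from [fuse_candidates()].
#' @param question Question text.
#' @param llm An LLM backend.
#' @param target Number of relevant chunks sought (default 5).
#' @param max_examined Examination budget (default 30 candidates).
#' @return A list: `selected` (candidate rows kept, in examination order for
#'   relevant modes, score order for the fallback), `verdicts` (data.frame
#'   `chunk_id`, `relevant`, `rationale`, `position_examined`), and
#'   `selection_mode` in `{"relevant_found", "partial", "fallback_top5"}`.
#' @export
relevance_check <- function(candidates, question, llm, target = 5,
                            max_examined = 30) {
  if (is.null(candidates) || !nrow(candidates)) {
    stop("relevance_check: empty candidate list")
  }
  stopifnot(target >= 1)
  n_exam <- min(nrow(candidates), max_examined)
  verdicts <- vector("list", n_exam)
  relevant_idx <- integer()
  examined <- 0L
  for (i in seq_len(n_exam)) {
    examined <- i
    v <- llm$judge_relevance(question, candidate_text(candidates$chunk_id[i]))
    verdicts[[i]] <- data.frame(
      chunk_id = candidates$chunk_id[i], relevant = isTRUE(v$relevant),
      rationale = as.character(v$rationale %||% ""), position_examined = i,
      stringsAsFactors = FALSE)
    if (isTRUE(v$relevant)) relevant_idx <- c(relevant_idx, i)
    if (length(relevant_idx) >= target) break
  }
  verdicts <- do.call(rbind, verdicts[seq_len(examined)])
  if (length(relevant_idx) >= target) {
    mode <- "relevant_found"
    sel <- candidates[relevant_idx, , drop = FALSE]
  } else if (length(relevant_idx) >= 1L) {
    mode <- "partial"
    sel <- candidates[relevant_idx, , drop = FALSE]
  } else {
    mode <- "fallback_top5"
    sel <- candidates[seq_len(min(target, nrow(candidates))), , drop = FALSE]
  }
  rownames(sel) <- NULL
  list(selected = sel, verdicts = verdicts, selection_mode = mode)
}

# relevance_check reads chunk text through this hook so it can be driven
# either by a corpus index (set via with_chunk_texts) or by tests.
the <- new.env(parent = emptyenv())
the$chunk_texts <- NULL

candidate_text <- function(chunk_id) {
  if (is.null(the$chunk_texts)) return(chunk_id)
  the$chunk_texts[[chunk_id]] %||% chunk_id
}

#' Evaluate an expression with chunk texts resolvable by id
#'
#' Installs a chunk_id -> text mapping (a named list/vector or a chunked
#' [corpus_index()]) for the duration of `expr`, so that selection and
#' generation phases can fetch chunk texts by id.
#'
#' @param texts Named character vector/list, or a chunked [corpus_index()].
#' @param expr Expression to evaluate.
#' @export
with_chunk_texts <- function(texts, expr) {
  if (inherits(texts, "corpus_index")) {
    texts <- lapply(texts$chunks, function(ch) ch$text)
  }
  old <- the$chunk_texts
  the$chunk_texts <- texts
  on.exit(the$chunk_texts <- old)
  force(expr)
}

#' Construct the draft answer from the selected chunks
#'
#' @param question Question text.
#' @param selected_chunks Candidate rows selected by [relevance_check()]
#'   (passed to the backend in fused-score order).
#' @param llm An LLM backend.
#' @return Non-empty draft answer text.
#' @export
construct_draft <- function(question, selected_chunks, llm) {
  if (is.null(selected_chunks) || !nrow(selected_chunks)) {
    stop("construct_draft: no selected chunks")
  }
  ord <- order(-selected_chunks$fused_score, selected_chunks$chunk_id)
  texts <- vapply(selected_chunks$chunk_id[ord], candidate_text, character(1))
  draft <- llm$draft_answer(question, texts)
  if (!nzchar(draft)) stop("construct_draft: backend returned an empty draft")
  draft
}

#' Self-reflective support scoring of the evidence
#'
#' Each selected chunk is scored 0-100 for how strongly it supports the draft
#' answer (100 = maximum support, 0 = irrelevant or contradictory).
#' Out-of-range backend values are clamped with a warning; unparseable values
#' become 0.
#'
#' @param question Question text.
#' @param draft Draft answer (non-empty).
#' @param selected_chunks Candidate rows from [relevance_check()].
#' @param llm An LLM backend.
#' @return Data.frame `chunk_id`, `score` (integer 0-100), one row per chunk.
#' @export
self_reflect <- function(question, draft, selected_chunks, llm) {
  stopifnot(nzchar(draft))
  scores <- vapply(selected_chunks$chunk_id, function(cid) {
    s <- tryCatch(llm$score_support(question, draft, candidate_text(cid)),
                  error = function(e) NA)
    s <- suppressWarnings(as.numeric(s))
    if (is.na(s)) {
      warning("self_reflect: unparseable support score for ", cid,
              "; treated as 0")
      s <- 0
    }
    if (s < 0 || s > 100) {
      warning("self_reflect: support score ", s, " for ", cid,
              " clamped to [0, 100]")
      s <- min(100, max(0, s))
    }
    as.integer(round(s))
  }, integer(1))
  data.frame(chunk_id = selected_chunks$chunk_id, score = unname(scores),
             stringsAsFactors = FALSE)
}

#' Deep-reasoning final answer over the scored evidence
#'
#' Chunks with support score > 0 are forwarded to the deep-reasoning
#' capability in descending score order (ties by chunk id); if every score is
#' 0, all chunks are forwarded in fused-score order instead.
#'
#' @param question Question text.
#' @param scored_chunks Candidate rows joined with their support scores
#'   (columns of [fuse_candidates()] plus `score`).
#' @param llm An LLM backend.
#' @param draft Draft answer to record alongside the final answer.
#' @param selection_mode Selection mode reported by [relevance_check()].
#' @return An `answer_record`: `question`, `draft_answer`, `final_answer`,
#'   `evidence` (chunk rows with scores, in the order forwarded),
#'   `selection_mode`.
#' @export
deep_answer <- function(question, scored_chunks, llm, draft = "",
                        selection_mode = "relevant_found") {
  if (is.null(scored_chunks) || !nrow(scored_chunks)) {
    stop("deep_answer: no scored chunks")
  }
  if (any(scored_chunks$score > 0)) {
    fwd <- scored_chunks[scored_chunks$score > 0, , drop = FALSE]
    fwd <- fwd[order(-fwd$score, fwd$chunk_id), , drop = FALSE]
  } else {
    fwd <- scored_chunks[order(-scored_chunks$fused_score,
                               scored_chunks$chunk_id), , drop = FALSE]
  }
  texts <- vapply(fwd$chunk_id, candidate_text, character(1))
  final <- llm$deep_answer(question, texts)
  rownames(fwd) <- NULL
  structure(
    list(question = question, draft_answer = draft, final_answer = final,
         evidence = fwd, selection_mode = selection_mode),
    class = "answer_record"
  )
}

#' @export
print.answer_record <- function(x, ...) {
  cat("<answer_record> mode=", x$selection_mode, ", ",
      nrow(x$evidence), " evidence chunk(s)\n", sep = "")
  cat("Q: ", x$question, "\n", sep = "")
  cat("A: ", x$final_answer, "\n", sep = "")
  cat("evidence: ", paste(x$evidence$chunk_id, " (", x$evidence$score, ")",
                          sep = "", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Answer a question with the full retrieval + generation pipeline
#'
#' Runs pre-retrieval reasoning, the five-strategy multilevel retrieval with
#' weighted fusion, sequential relevance checking, draft construction,
#' self-reflective scoring and the final deep-reasoning pass.
#'
#' @param question Question text.
#' @param index A chunked [corpus_index()].
#' @param emb Embedding backend.
#' @param llm LLM backend.
#' @param config A [run_config()] list (defaults used when `NULL`).
#' @param emb_index Optional precomputed [embed_index()].
#' @return An `answer_record` with an extra `candidates` attribute holding
#'   the full fused candidate table.
#' @export
answer_question <- function(question, index, emb, llm, config = run_config(),
                            emb_index = NULL) {
  bundle <- run_preretrieval(question, llm)
  hits <- retrieve_all(bundle, index, emb,
                       k_per_strategy = config$k_per_strategy,
                       keyword_cap = config$keyword_cap,
                       emb_index = emb_index)
  cand <- fuse_candidates(hits, index, config$weights)
  with_chunk_texts(index, {
    sel <- relevance_check(cand, question, llm, target = config$target,
                           max_examined = config$max_examined)
    draft <- construct_draft(question, sel$selected, llm)
    scores <- self_reflect(question, draft, sel$selected, llm)
    scored <- merge(sel$selected, scores, by = "chunk_id", sort = FALSE)
    rec <- deep_answer(question, scored, llm, draft = draft,
                       selection_mode = sel$selection_mode)
    attr(rec, "candidates") <- cand
    attr(rec, "verdicts") <- sel$verdicts
    rec
  })
}
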