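strategy_names <- c("question_abstract", "virtual_abstract",
                    "question_fulltext", "virtual_fulltext", "keyword")

#' Fraction of keyword groups matched in a chunk
#'
#' A group matches iff its head term or any synonym occurs case-insensitively
#' on word boundaries in the text.
#'
#' @param chunk_text Text to scan.
#' @param keyword_groups List of `list(head_term, synonyms)` groups.
#' @return Fraction in \[0, 1\] of groups matched (0 for empty text).
#' @export
keyword_match_score <- function(chunk_text, keyword_groups) {
  if (!length(keyword_groups)) stop("keyword_match_score: no keyword groups")
  if (!nzchar(chunk_text)) return(0)
  matched <- vapply(keyword_groups, function(g) {
    terms <- c(g$head_term, g$synonyms)
    any(vapply(terms, function(t) {
      grepl(paste0("\\b", escape_regex(t), "\\b"), chunk_text,
            ignore.case = TRUE, perl = TRUE)
    }, logical(1)))
  }, logical(1))
  mean(matched)
}

#' Run the five retrieval strategies over both corpus levels
#'
#' Multilevel (abstract + full text) and multigranularity (question, virtual
#' answer, keywords) retrieval: top-`k_per_strategy` abstract chunks for the
#' question and for the virtual answer, top-`k_per_strategy` fulltext chunks
#' for each of the two, plus keyword-matched fulltext chunks scored by
#' keyword-group coverage (all score > 0, capped at `keyword_cap` by score).
#' Negative similarities are clamped to 0 so all raw scores live in \[0, 1\].
#'
#' @param bundle A [run_preretrieval()] bundle.
#' @param index A chunked [corpus_index()].
#' @param emb An embedding backend.
#' @param k_per_strategy Retrieval depth per embedding strategy (default 10).
#' @param keyword_cap Maximum keyword-strategy hits (default 50).
#' @param emb_index Optional precomputed [embed_index()] result.
#' @return A data.frame of strategy hits: `chunk_id`, `strategy`, `raw_score`,
#'   `rank_within_strategy`.
#' @export
retrieve_all <- function(bundle, index, emb, k_per_strategy = 10,
                         keyword_cap = 50, emb_index = NULL) {
  stopifnot(inherits(index, "corpus_index"))
  if (!length(index$chunks)) stop("retrieve_all: index has no chunks")
  if (is.null(emb_index)) emb_index <- embed_index(index, emb)

  hits <- list()
  add_embedding_hits <- function(query_text, level, strategy) {
    mat <- emb_index[[level]]
    if (is.null(mat) || nrow(mat) == 0L) return()
    qv <- emb$embed(query_text)[1, ]
    top <- top_k_by_similarity(qv, mat, k = k_per_strategy)
    if (!nrow(top)) return()
    hits[[strategy]] <<- data.frame(
      chunk_id = top$id, strategy = strategy,
      raw_score = pmin(1, pmax(0, top$similarity)),
      rank_within_strategy = seq_len(nrow(top)),
      stringsAsFactors = FALSE)
  }

  add_embedding_hits(bundle$question, "abstract", "question_abstract")
  add_embedding_hits(bundle$question, "fulltext", "question_fulltext")
  if (nzchar(bundle$virtual_answer)) {
    add_embedding_hits(bundle$virtual_answer, "abstract", "virtual_abstract")
    add_embedding_hits(bundle$virtual_answer, "fulltext", "virtual_fulltext")
  }

  if (length(bundle$keyword_groups)) {
    ids <- index$by_level$fulltext
    if (length(ids)) {
      scores <- vapply(ids, function(cid) {
        keyword_match_score(index$chunks[[cid]]$text, bundle$keyword_groups)
      }, numeric(1))
      keep <- ids[scores > 0]
      if (length(keep)) {
        ord <- order(-scores[keep], keep)
        keep <- keep[ord][seq_len(min(keyword_cap, length(keep)))]
        hits[["keyword"]] <- data.frame(
          chunk_id = keep, strategy = "keyword",
          raw_score = unname(scores[keep]),
          rank_within_strategy = seq_along(keep),
          stringsAsFactors = FALSE)
      }
    }
  }

  if (!length(hits)) {
    return(data.frame(chunk_id = character(), strategy = character(),
                      raw_score = numeric(),
                      rank_within_strategy = integer()))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Default fusion weights
#'
#' Weights of the three fusion factors: similarity (`w_S = 5`), strategy
#' diversity (`w_M = 3`) and intradocument repetition (`w_R = 1`).
#' @param w_S,w_M,w_R Non-negative weights, not all zero.
#' @export
aggregator_weights <- function(w_S = 5, w_M = 3, w_R = 1) {
  stopifnot(w_S >= 0, w_M >= 0, w_R >= 0, w_S + w_M + w_R > 0)
  list(w_S = w_S, w_M = w_M, w_R = w_R)
}

#' Fuse strategy hits into one ranked candidate list
#'
#' Deduplicates hits by chunk and scores each candidate chunk i as
#' \deqn{S_i = w_S \frac{S_{sim,i}}{S_{sim,max}} + w_M \frac{M_i}{M_{max}} +
#'   w_R \frac{R_i}{R_{max}}}
#' where `S_sim` is the maximum raw score over the strategies that hit the
#' chunk, `M` the number of distinct such strategies, and `R` the number of
#' candidate chunks (self included) from the same document; each factor is
#' normalized by its maximum over the candidate pool (a zero maximum makes
#' that term contribute 0). Output is sorted by fused score descending, ties
#' broken by chunk id.
#'
#' @param hits Strategy-hit data.frame from [retrieve_all()].
#' @param index A [corpus_index()], or a named character vector mapping
#'   chunk_id -> doc_id.
#' @param weights An [aggregator_weights()] list.
#' @return A data.frame of candidates: `chunk_id`, `doc_id`, `S_sim`, `M`,
#'   `R`, `fused_score`, `strategies` (comma-joined).
#' @export
fuse_candidates <- function(hits, index, weights = aggregator_weights()) {
  if (is.null(hits) || !nrow(hits)) {
    warning("fuse_candidates: no hits to aggregate")
    return(data.frame(chunk_id = character(), doc_id = character(),
                      S_sim = numeric(), M = integer(), R = integer(),
                      fused_score = numeric(), strategies = character()))
  }
  doc_of <- if (inherits(index, "corpus_index")) {
    vapply(index$chunks, function(ch) ch$doc_id, character(1))
  } else {
    index
  }
  unknown <- setdiff(unique(hits$chunk_id), names(doc_of))
  if (length(unknown)) {
    stop("fuse_candidates: hits reference unknown chunk_id(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  sp <- split(hits, hits$chunk_id)
  cand <- data.frame(
    chunk_id = names(sp),
    doc_id = unname(doc_of[names(sp)]),
    S_sim = vapply(sp, function(h) max(h$raw_score), numeric(1)),
    M = vapply(sp, function(h) length(unique(h$strategy)), integer(1)),
    strategies = vapply(sp, function(h) {
      paste(sort(unique(h$strategy)), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  cand$R <- as.integer(table(cand$doc_id)[cand$doc_id])
  s_max <- max(cand$S_sim); m_max <- max(cand$M); r_max <- max(cand$R)
  term <- function(x, xmax, w) if (xmax > 0) w * x / xmax else 0
  cand$fused_score <- term(cand$S_sim, s_max, weights$w_S) +
    term(cand$M, m_max, weights$w_M) + term(cand$R, r_max, weights$w_R)
  cand <- cand[order(-cand$fused_score, cand$chunk_id),
               c("chunk_id", "doc_id", "S_sim", "M", "R", "fused_score",
                 "strategies")]
  rownames(cand) <- NULL
  cand
}
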