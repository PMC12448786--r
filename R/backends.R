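#' Cosine similarity between two vectors
#'
#' Zero-norm vectors are defined to have similarity 0 with everything.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A scalar in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop("cosine_similarity: dimension mismatch (", length(a), " vs ",
         length(b), ")")
  }
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Rank candidates by cosine similarity to a query vector
#'
#' @param query_vector Numeric query embedding.
#' @param candidates Numeric matrix, one row per candidate; row names are the
#'   candidate ids.
#' @param k Maximum number of results (default 10, the per-strategy depth).
#' @return A data.frame `(id, similarity)` sorted by descending similarity,
#'   ties broken lexicographically by id; empty (with a warning) when the
#'   candidate set is empty.
#' @export
top_k_by_similarity <- function(query_vector, candidates, k = 10) {
  stopifnot(k >= 1)
  if (is.null(candidates) || nrow(candidates) == 0L) {
    warning("top_k_by_similarity: empty candidate set")
    return(data.frame(id = character(), similarity = numeric()))
  }
  if (ncol(candidates) != length(query_vector)) {
    stop("top_k_by_similarity: dimension mismatch")
  }
  qn <- sqrt(sum(query_vector^2))
  rn <- sqrt(rowSums(candidates^2))
  sims <- if (qn == 0) rep(0, nrow(candidates)) else {
    num <- as.numeric(candidates %*% query_vector)
    ifelse(rn == 0, 0, num / (rn * qn))
  }
  ids <- rownames(candidates)
  ord <- order(-sims, ids)
  take <- ord[seq_len(min(k, length(ord)))]
  data.frame(id = ids[take], similarity = sims[take],
             stringsAsFactors = FALSE)
}

#' Deterministic hashing text-embedding backend
#'
#' Embeds a text as its character 3-gram term-frequency vector hashed into a
#' fixed dimension and length-normalized. Seed-free and deterministic:
#' identical strings embed identically; texts sharing no 3-grams (and no hash
#' collisions) have similarity 0.
#'
#' @param dimension Embedding dimension (default 256).
#' @return An embedding backend: a list with `$embed(texts)` returning a
#'   matrix (one row per text, rows named by the input when named) and
#'   `$dimension`.
#' @export
mock_embedding <- function(dimension = 256L) {
  dimension <- as.integer(dimension)
  stopifnot(dimension > 0L)
  embed_one <- function(text) {
    v <- numeric(dimension)
    s <- tolower(text)
    n <- nchar(s)
    if (n > 0L) {
      codes <- utf8ToInt(s)
      if (n < 3L) codes <- c(codes, rep(32L, 3L - n))  # pad short strings
      m <- length(codes) - 2L
      # polynomial 3-gram hash, bucketed into the dimension
      h <- (codes[seq_len(m)] * 961L + codes[seq_len(m) + 1L] * 31L +
              codes[seq_len(m) + 2L]) %% dimension + 1L
      tab <- tabulate(h, nbins = dimension)
      nrm <- sqrt(sum(tab^2))
      if (nrm > 0) v <- tab / nrm
    }
    v
  }
  backend <- list(
    dimension = dimension,
    embed = function(texts) {
      out <- t(vapply(texts, embed_one, numeric(dimension)))
      rownames(out) <- names(texts)
      out
    }
  )
  class(backend) <- c("mock_embedding", "embedding_backend")
  backend
}

#' Embed every chunk of an index once, for reuse across queries
#'
#' @param index A chunked [corpus_index()].
#' @param emb An embedding backend.
#' @return A list with one similarity-search matrix per level
#'   (`abstract`, `fulltext`), rows named by chunk id.
#' @export
embed_index <- function(index, emb) {
  lapply(index$by_level, function(ids) {
    if (!length(ids)) {
      return(matrix(numeric(), nrow = 0, ncol = emb$dimension))
    }
    texts <- vapply(index$chunks[ids], function(ch) ch$text, character(1))
    names(texts) <- ids
    emb$embed(texts)
  })
}

#' Validate an LLM backend contract
#'
#' A reasoning backend is a list providing the five pipeline capabilities plus
#' the structured-extraction and judging hooks used by the knowledge-graph and
#' evaluation modules. [mock_llm()] is the reference implementation.
#'
#' @param x Object to check.
#' @return `TRUE` invisibly, or an error naming the missing capability.
#' @export
check_llm_backend <- function(x) {
  needed <- c("preretrieve", "judge_relevance", "draft_answer",
              "score_support", "deep_answer")
  for (fn in needed) {
    if (!is.function(x[[fn]])) {
      stop("LLM backend is missing capability '", fn, "'")
    }
  }
  invisible(TRUE)
}
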