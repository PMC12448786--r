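#' Pre-retrieval reasoning: keywords, synonyms and a virtual answer
#'
#' Phase 1 of the pipeline. The backend proposes keyword groups (head term +
#' synonyms) and a virtual answer — a hypothesized answer used as an
#' additional retrieval query. Backend output is validated and repaired:
#' empty terms are stripped, synonyms are deduplicated case-insensitively and
#' never repeat the head term, and groups are truncated at 10 groups of 10
#' synonyms. If the backend yields neither keywords nor a virtual answer the
#' whole question becomes the single head term (degraded mode).
#'
#' @param question Free-text question.
#' @param llm An LLM backend (see [check_llm_backend()]).
#' @return A `preretrieval_bundle`: `question`, `keyword_groups`
#'   (list of `list(head_term, synonyms)`), `virtual_answer`, `degraded` flag.
#' @export
run_preretrieval <- function(question, llm) {
  question <- trimws(gsub("\\s+", " ", question))
  if (!nzchar(question)) stop("run_preretrieval: empty question")
  check_llm_backend(llm)
  raw <- llm$preretrieve(question)

  groups <- list()
  for (g in raw$keyword_groups %||% list()) {
    head <- trimws(as.character(g$head_term %||% ""))
    if (!nzchar(head)) next
    syn <- trimws(as.character(g$synonyms %||% character()))
    syn <- syn[nzchar(syn)]
    syn <- syn[!duplicated(tolower(syn))]
    syn <- syn[tolower(syn) != tolower(head)]
    if (length(syn) > 10L) syn <- syn[seq_len(10L)]
    groups[[length(groups) + 1L]] <- list(head_term = head, synonyms = syn)
  }
  if (length(groups) > 10L) groups <- groups[seq_len(10L)]
  virtual <- trimws(as.character(raw$virtual_answer %||% ""))

  degraded <- FALSE
  if (!length(groups) && !nzchar(virtual)) {
    groups <- list(list(head_term = question, synonyms = character()))
    degraded <- TRUE
  }
  structure(
    list(question = question, keyword_groups = groups,
         virtual_answer = virtual, degraded = degraded),
    class = "preretrieval_bundle"
  )
}

#' @export
print.preretrieval_bundle <- function(x, ...) {
  cat("<preretrieval_bundle> ", length(x$keyword_groups), " keyword group(s)",
      if (x$degraded) " [degraded]", "\n", sep = "")
  for (g in x$keyword_groups) {
    cat("  - ", g$head_term,
        if (length(g$synonyms)) paste0(" (", paste(g$synonyms, collapse = "; "), ")"),
        "\n", sep = "")
  }
  if (nzchar(x$virtual_answer)) {
    cat("  virtual answer: ", substr(x$virtual_answer, 1, 70), "...\n", sep = "")
  }
  invisible(x)
}
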