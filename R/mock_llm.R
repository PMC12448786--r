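## Deterministic reasoning backend used by the test suite and the offline CLI.
## Every capability is a pure function of its inputs plus the fixture tables it
## was constructed with; no randomness, no state.

stopword_set <- c(
  "the", "and", "for", "are", "was", "were", "with", "that", "this", "from",
  "into", "has", "have", "had", "not", "its", "their", "which", "what", "who",
  "does", "can", "may", "our", "these", "those", "between", "based", "using"
)

#' Split a text into lowercase content words
#'
#' Words of length >= 3 that are not common function words; the unit of the
#' mock backend's overlap scoring.
#' @param text Character scalar.
#' @return Character vector (possibly empty).
#' @export
content_words <- function(text) {
  w <- tolower(unlist(strsplit(text, "[^A-Za-z0-9-]+")))
  w <- w[nchar(w) >= 3]
  w[!w %in% stopword_set]
}

normalize_question <- function(q) tolower(trimws(gsub("\\s+", " ", q)))

split_sentences <- function(text) {
  s <- unlist(strsplit(text, "(?<=[.!?])\\s+", perl = TRUE))
  trimws(s[nzchar(trimws(s))])
}

entity_pattern <- "[A-Z][A-Za-z0-9-]*(?:[ ][A-Z][A-Za-z0-9-]*)*"

default_relation_map <- c(
  "treats" = "treats",
  "inhibits" = "inhibits",
  "promotes" = "promotes",
  "is associated with" = "associated_with",
  "interacts with" = "interacts_with"
)

#' Deterministic mock language-model backend
#'
#' Stands in for the reasoning model behind all pipeline capabilities. Its
#' rules are simple and auditable: keywords are capitalized or
#' thesaurus-known question terms; the virtual answer concatenates the
#' question with its keywords and synonyms; a chunk is judged relevant iff it
#' contains a fact token associated with the question; support scores are the
#' rounded percentage of draft content words present in the chunk; answers
#' quote the evidence sentences that contain known fact tokens; the 5-point
#' answer judge thresholds content-word overlap with the gold answer.
#'
#' @param thesaurus Named list: term -> character vector of synonyms
#'   (case-insensitive lookup).
#' @param question_facts Named list: normalized question text -> character
#'   vector of fact tokens whose presence marks a chunk as relevant.
#' @param fact_table Named character vector: doc_id -> planted fact token
#'   (used only for bookkeeping and diagnostics).
#' @param entity_types Named character vector: lowercased entity mention ->
#'   type, consulted by the triplet-extraction capability.
#' @param relation_map Named character vector: surface relation phrase ->
#'   relation label.
#' @return An LLM backend (see [check_llm_backend()]).
#' @export
mock_llm <- function(thesaurus = list(), question_facts = list(),
                     fact_table = character(), entity_types = character(),
                     relation_map = default_relation_map) {
  names(thesaurus) <- tolower(names(thesaurus))
  names(question_facts) <- vapply(names(question_facts) %||% character(),
                                  normalize_question, character(1))
  names(entity_types) <- tolower(names(entity_types))
  all_tokens <- unique(c(unlist(question_facts, use.names = FALSE),
                         unname(fact_table)))

  facts_for <- function(question) {
    question_facts[[normalize_question(question)]] %||% character()
  }
  contains_token <- function(text, token) {
    grepl(token, text, fixed = TRUE) ||
      grepl(tolower(token), tolower(text), fixed = TRUE)
  }
  evidence_sentences <- function(chunk_texts, tokens) {
    hits <- character()
    for (txt in chunk_texts) {
      for (s in split_sentences(txt)) {
        if (any(vapply(tokens, contains_token, logical(1), text = s))) {
          hits <- c(hits, s)
        }
      }
    }
    unique(hits)
  }

  backend <- list(
    thesaurus = thesaurus,
    fact_table = fact_table,

    preretrieve = function(question) {
      toks <- unlist(strsplit(question, "\\s+"))
      toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
      # capitalized runs, ignoring the sentence-initial token unless all-caps
      capped <- grepl("^[A-Z]", toks) & nchar(toks) > 1
      if (length(capped)) capped[1] <- capped[1] && grepl("^[A-Z0-9-]+$", toks[1])
      phrases <- character()
      run <- character()
      for (i in seq_along(toks)) {
        if (isTRUE(capped[i])) {
          run <- c(run, toks[i])
        } else if (length(run)) {
          phrases <- c(phrases, paste(run, collapse = " ")); run <- character()
        }
      }
      if (length(run)) phrases <- c(phrases, paste(run, collapse = " "))
      known <- names(thesaurus)[vapply(names(thesaurus), function(term) {
        grepl(paste0("\\b", escape_regex(term), "\\b"), question,
              ignore.case = TRUE, perl = TRUE)
      }, logical(1))]
      heads <- unique(c(phrases, known))
      heads <- heads[!duplicated(tolower(heads))]
      groups <- lapply(heads, function(h) {
        list(head_term = h, synonyms = thesaurus[[tolower(h)]] %||% character())
      })
      virtual <- if (length(heads)) {
        paste(question, paste(
          unlist(lapply(groups, function(g) c(g$head_term, g$synonyms))),
          collapse = " "))
      } else ""
      list(question = question, keyword_groups = groups,
           virtual_answer = virtual)
    },

    judge_relevance = function(question, chunk_text) {
      tokens <- facts_for(question)
      hit <- tokens[vapply(tokens, contains_token, logical(1),
                           text = chunk_text)]
      list(
        relevant = length(hit) > 0,
        rationale = if (length(hit)) {
          paste("chunk states fact token:", paste(hit, collapse = ", "))
        } else "no question-associated fact found in chunk"
      )
    },

    draft_answer = function(question, chunk_texts) {
      ev <- evidence_sentences(chunk_texts, all_tokens)
      if (length(ev)) {
        paste(question, "Draft evidence:", paste(ev, collapse = " "))
      } else {
        paste(question,
              "No direct evidence was located in the provided passages.")
      }
    },

    score_support = function(question, draft_answer, chunk_text) {
      dw <- content_words(draft_answer)
      if (!length(dw)) return(0L)
      cw <- unique(content_words(chunk_text))
      as.integer(round(100 * mean(dw %in% cw)))
    },

    deep_answer = function(question, ranked_chunk_texts) {
      ev <- evidence_sentences(ranked_chunk_texts, all_tokens)
      if (length(ev)) {
        paste("Based on the retrieved evidence:", paste(ev, collapse = " "))
      } else {
        paste("No grounded evidence is available to answer:", question)
      }
    },

    # 5-point answer judge: content-word overlap with the gold answer,
    # thresholded to the grade bands 1..5.
    judge_answer = function(question, final_answer, gold_answer) {
      gw <- content_words(gold_answer)
      if (!length(gw)) return(1L)
      frac <- mean(gw %in% unique(content_words(final_answer)))
      if (frac >= 0.8) 5L else if (frac >= 0.6) 4L else if (frac >= 0.4) 3L
      else if (frac >= 0.2) 2L else 1L
    },

    # entity-layer triplet extraction: "<Entity> <relation> <Entity>" clauses
    extract_entity_triplets = function(text) {
      out <- list()
      for (s in split_sentences(text)) {
        for (phrase in names(relation_map)) {
          pat <- paste0("(", entity_pattern, ")\\s+", escape_regex(phrase),
                        "\\s+(", entity_pattern, ")")
          m <- regmatches(s, regexec(pat, s, perl = TRUE))[[1]]
          if (length(m) == 3L) {
            out[[length(out) + 1L]] <- list(
              e1 = m[2], r = unname(relation_map[[phrase]]), e2 = m[3],
              e1_type = unname(entity_types[tolower(m[2])]),
              e2_type = unname(entity_types[tolower(m[3])])
            )
          }
        }
      }
      out
    },

    # document-layer summarization: methods, datasets, research domains
    extract_document_triplets = function(title, text) {
      out <- list()
      grab <- function(pat, relation, type) {
        for (m in regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]) {
          obj <- sub(pat, "\\1", m, perl = TRUE)
          out[[length(out) + 1L]] <<- list(
            e1 = title, e1_type = "paper", r = relation,
            e2 = obj, e2_type = type)
        }
      }
      grab(paste0("uses the (", entity_pattern, ") method"),
           "uses_method", "method")
      grab(paste0("uses the (", entity_pattern, ") dataset"),
           "uses_dataset", "dataset")
      grab(paste0("in the domain of (", entity_pattern, ")"),
           "in_domain", "research_domain")
      out
    },

    # normalization adjudicator: confirm a candidate only when it matches the
    # mention exactly (case-insensitive) or through a thesaurus link
    adjudicate = function(mention, candidates) {
      ml <- tolower(mention)
      for (cand in candidates) {
        cl <- tolower(cand)
        if (cl == ml) return(cand)
        if (ml %in% tolower(thesaurus[[cl]] %||% character())) return(cand)
        if (cl %in% tolower(thesaurus[[ml]] %||% character())) return(cand)
      }
      NA_character_
    }
  )
  class(backend) <- c("mock_llm", "llm_backend")
  backend
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
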