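## Self-contained synthetic test worlds: a toy literature corpus with planted
## drug-disease facts, a static synonym thesaurus, reference vocabularies and
## gold QA records. All names are invented; no real biomedical claim is made.

fixture_pools <- function() {
  list(
    diseases = data.frame(
      canonical = c("Velmora Syndrome", "Cortellia Fibrosis",
                    "Marvane Carcinoma", "Ostrevia Colitis",
                    "Pellusk Anemia", "Gravene Myopathy"),
      synonym = c("Drexun Disease", "Quellan Disorder", "Telvic Neoplasm",
                  "Brenhal Enteritis", "Varnic Cytopenia", "Soltair Weakness"),
      stringsAsFactors = FALSE),
    drugs = c("Zelvistat", "Morquinol", "Tavrixen", "Beldramab",
              "Quorlafen", "Histrelone"),
    genes = c("VLK9", "CRT4", "MBX2", "OSR7", "PLK5", "GRV1"),
    methods = c("Single-Cell Profiling", "Cohort Screening",
                "Tissue Microassay"),
    datasets = c("Orvala Registry", "Pellin Atlas", "Trestle Cohort"),
    domains = c("Oncology", "Immunology", "Pharmacology"),
    filler = c(
      "Longitudinal follow-up remains essential for outcome assessment.",
      "Adverse events were generally mild and self-limiting.",
      "Standardized reporting improves comparability across centres.",
      "Sample handling followed routine laboratory procedure.",
      "Further validation in independent cohorts is warranted.")
  )
}

#' Generate a synthetic literature corpus with planted facts
#'
#' Builds a toy corpus for exercising the whole pipeline offline. Each
#' question asks which drug treats one invented disease; its fact token (the
#' drug name) is planted, as the sentence "<Drug> treats <Disease>.", in 1-3
#' gold documents whose full texts are short enough to yield a single
#' fulltext chunk. Distractor documents are long (multi-chunk) and repeat the
#' surface vocabulary of every question without any fact token. Half of the
#' questions reference their disease by a synonym that gold documents never
#' use, so those facts are reachable only through synonym-aware keyword or
#' virtual-answer expansion — not through flat question-embedding retrieval.
#' Gold abstracts carry gene-disease sentences for entity-layer triplet
#' extraction, and full texts carry method/dataset/domain statements for the
#' document layer.
#'
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @param n_docs Total documents (default 12; at most 6 + 3 per question).
#' @param n_questions Number of gold questions (default 4, max 6).
#' @param distractor_ratio Fraction of documents that are distractors
#'   (default 0.5; 0 means every document carries a planted fact).
#' @param dir Optional directory; when given, writes `records.jsonl`,
#'   `texts/<doc_id>.md`, `gold_qa.jsonl`, `vocabulary.tsv`,
#'   `thesaurus.json` and `manifest.json`.
#' @return The fixture manifest: `seed`, `documents` (list of [document()]s),
#'   `thesaurus`, `question_facts`, `fact_table`, `entity_types`,
#'   `vocabulary` (data.frame), `gold_qa`.
#' @export
generate_corpus <- function(seed, n_docs = 12, n_questions = 4,
                            distractor_ratio = 0.5, dir = NULL) {
  stopifnot(n_questions >= 1, distractor_ratio >= 0)
  pools <- fixture_pools()
  if (n_questions > nrow(pools$diseases)) {
    stop("generate_corpus: at most ", nrow(pools$diseases), " questions")
  }
  n_distract <- round(n_docs * distractor_ratio)
  n_fact <- n_docs - n_distract
  if (n_fact < n_questions) {
    stop("generate_corpus: need at least one fact document per question ",
         "(n_docs too small for this distractor_ratio)")
  }
  if (n_fact > 3 * n_questions) {
    stop("generate_corpus: more fact documents than 3 per question")
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)

  qs <- seq_len(n_questions)
  gated <- qs %% 2L == 1L        # odd questions use the synonym surface form
  surface <- ifelse(gated, pools$diseases$synonym[qs],
                    pools$diseases$canonical[qs])
  canonical <- pools$diseases$canonical[qs]
  drugs <- pools$drugs[qs]
  genes <- pools$genes[qs]

  # distribute fact documents: one per question, extras round-robin (max 3)
  gold_count <- rep(1L, n_questions)
  extra <- n_fact - n_questions
  i <- 1L
  while (extra > 0L) {
    if (gold_count[i] < 3L) { gold_count[i] <- gold_count[i] + 1L
      extra <- extra - 1L }
    i <- if (i == n_questions) 1L else i + 1L
  }

  doc_ids <- sprintf("D%02d", seq_len(n_docs))
  slots <- sample(doc_ids)       # placement of specs across ids
  specs <- list()
  k <- 0L
  for (q in qs) {
    for (g in seq_len(gold_count[q])) {
      k <- k + 1L
      specs[[slots[k]]] <- list(kind = "gold", q = q, variant = g)
    }
  }
  for (d in seq_len(n_distract)) {
    k <- k + 1L
    specs[[slots[k]]] <- list(kind = "distractor", variant = d)
  }

  distractor_paragraph <- function(variant, rep_i) {
    lines <- vapply(qs, function(q) {
      sprintf("Patients presenting with %s often receive supportive therapy in routine practice (series %d-%d).",
              surface[q], variant, rep_i)
    }, character(1))
    paste(c(lines, sample(pools$filler, 1)), collapse = " ")
  }

  documents <- list()
  fact_table <- character()
  for (id in doc_ids) {
    sp <- specs[[id]]
    if (sp$kind == "gold") {
      q <- sp$q
      method <- sample(pools$methods, 1)
      dataset <- sample(pools$datasets, 1)
      domain <- sample(pools$domains, 1)
      title <- sprintf("Evaluation of %s in %s (study %d)",
                       drugs[q], canonical[q], sp$variant)
      abstract <- paste0(
        "This study investigates therapeutic response in ", canonical[q],
        ". ", genes[q], " is associated with ", canonical[q],
        ". ", drugs[q], " inhibits ", genes[q],
        ". Response rates were assessed prospectively.")
      full_text <- paste0(
        canonical[q], " is a chronic progressive condition. ",
        drugs[q], " treats ", canonical[q],
        ". Clinical observations in this cohort support a durable effect. ",
        "This paper uses the ", method, " method. ",
        "It uses the ", dataset, " dataset. ",
        "The work is in the domain of ", domain, ".")
      fact_table[[id]] <- drugs[q]
      keywords <- c(canonical[q], drugs[q])
    } else {
      n_par <- sample(4:5, 1)
      title <- sprintf("Management strategies across chronic conditions: a narrative review (%d)",
                       sp$variant)
      abstract <- paste0(
        "This review summarizes supportive management for ",
        paste(surface, collapse = ", "),
        ". No disease-modifying agent is evaluated here.")
      full_text <- paste(vapply(seq_len(n_par), function(rp) {
        distractor_paragraph(sp$variant, rp)
      }, character(1)), collapse = "\n\n")
      keywords <- surface
    }
    documents[[id]] <- list(id = id, title = title, abstract = abstract,
                            full_text = full_text, keywords = keywords)
  }
  # citation links among corpus documents (and one dangling external id)
  for (id in doc_ids) {
    others <- setdiff(doc_ids, id)
    documents[[id]]$cited <- sort(sample(others, min(2, length(others))))
  }
  documents[[doc_ids[1]]]$cited <- c(documents[[doc_ids[1]]]$cited, "EXT999")

  docs <- lapply(documents, function(d) {
    document(doc_id = d$id, title = d$title, abstract = d$abstract,
             full_text = d$full_text,
             year = sample(2014:2023, 1), keywords = d$keywords,
             cited_doc_ids = d$cited)
  })

  thesaurus <- list()
  for (q in qs) {
    thesaurus[[tolower(canonical[q])]] <- pools$diseases$synonym[q]
    thesaurus[[tolower(pools$diseases$synonym[q])]] <- canonical[q]
  }

  gold_qa <- lapply(qs, function(q) {
    list(
      question = sprintf("Which drug treats %s?", surface[q]),
      gold_answer = sprintf("%s treats %s.", drugs[q], canonical[q]),
      gold_doc_ids = names(Filter(function(sp) {
        sp$kind == "gold" && sp$q == q
      }, specs)),
      question_type = if (gated[q]) "synonym_gated" else "direct",
      fact_token = drugs[q])
  })
  question_facts <- stats::setNames(
    lapply(gold_qa, function(g) g$fact_token),
    vapply(gold_qa, function(g) g$question, character(1)))

  entity_types <- c(
    stats::setNames(rep("disease", nrow(pools$diseases)),
                    tolower(pools$diseases$canonical)),
    stats::setNames(rep("disease", nrow(pools$diseases)),
                    tolower(pools$diseases$synonym)),
    stats::setNames(rep("drug", length(pools$drugs)), tolower(pools$drugs)),
    stats::setNames(rep("gene", length(pools$genes)), tolower(pools$genes)))

  vocabulary <- rbind(
    data.frame(term = pools$diseases$canonical, type = "disease",
               source = "synthetic_mesh", stringsAsFactors = FALSE),
    data.frame(term = pools$drugs, type = "drug",
               source = "synthetic_mesh", stringsAsFactors = FALSE),
    data.frame(term = pools$genes, type = "gene",
               source = "synthetic_uniprot", stringsAsFactors = FALSE))

  manifest <- list(seed = as.integer(seed), n_docs = n_docs,
                   n_questions = n_questions,
                   distractor_ratio = distractor_ratio,
                   documents = docs, thesaurus = thesaurus,
                   question_facts = question_facts, fact_table = fact_table,
                   entity_types = entity_types, vocabulary = vocabulary,
                   gold_qa = gold_qa)

  if (!is.null(dir)) write_fixture(manifest, dir)
  manifest
}

write_fixture <- function(manifest, dir) {
  dir.create(file.path(dir, "texts"), recursive = TRUE, showWarnings = FALSE)
  rec_con <- file(file.path(dir, "records.jsonl"), "wt", encoding = "UTF-8")
  for (d in manifest$documents) {
    rec <- unclass(d)
    rec$full_text <- NULL
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"),
               rec_con)
    writeLines(d$full_text,
               file.path(dir, "texts", paste0(d$doc_id, ".md")))
  }
  close(rec_con)
  qa_con <- file(file.path(dir, "gold_qa.jsonl"), "wt", encoding = "UTF-8")
  for (g in manifest$gold_qa) {
    writeLines(jsonlite::toJSON(g, auto_unbox = TRUE), qa_con)
  }
  close(qa_con)
  utils::write.table(manifest$vocabulary,
                     file.path(dir, "vocabulary.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(jsonlite::toJSON(manifest$thesaurus, auto_unbox = FALSE),
             file.path(dir, "thesaurus.json"))
  keep <- manifest[c("seed", "n_docs", "n_questions", "distractor_ratio",
                     "thesaurus", "question_facts", "fact_table",
                     "entity_types")]
  writeLines(jsonlite::toJSON(keep, auto_unbox = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Mock backends wired to a fixture manifest
#'
#' @param manifest A [generate_corpus()] manifest.
#' @param dimension Embedding dimension (default 256).
#' @return List with `emb` ([mock_embedding()]) and `llm` ([mock_llm()]
#'   carrying the fixture's thesaurus, fact tables and entity types).
#' @export
mock_backends <- function(manifest, dimension = 256L) {
  list(
    emb = mock_embedding(dimension),
    llm = mock_llm(thesaurus = manifest$thesaurus,
                   question_facts = manifest$question_facts,
                   fact_table = manifest$fact_table,
                   entity_types = manifest$entity_types)
  )
}

#' Corpus index built directly from a fixture manifest
#'
#' @param manifest A [generate_corpus()] manifest.
#' @param config A [run_config()] supplying the chunking parameters.
#' @return A chunked [corpus_index()].
#' @export
fixture_index <- function(manifest, config = run_config()) {
  chunk_corpus(corpus_index(manifest$documents),
               chunk_size = config$chunk_size, overlap = config$overlap)
}
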