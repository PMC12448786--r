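entity_layer_types <- c("gene", "protein", "drug", "disease")
document_layer_types <- c("paper", "method", "dataset", "research_domain")

#' Construct a provenance-carrying triplet
#'
#' @param e1,e2 Entity mention texts.
#' @param r Relation label.
#' @param e1_type,e2_type Entity types; `gene`/`protein`/`drug`/`disease` at
#'   the entity layer, `paper`/`method`/`dataset`/`research_domain` at the
#'   document layer.
#' @param evidence_source doc_id of the paper the assertion came from.
#' @param layer `"entity"` or `"document"`.
#' @export
triplet <- function(e1, r, e2, e1_type, e2_type, evidence_source,
                    layer = c("entity", "document")) {
  layer <- match.arg(layer)
  allowed <- if (layer == "entity") entity_layer_types else document_layer_types
  if (!e1_type %in% allowed || !e2_type %in% allowed) {
    stop("triplet: type outside the ", layer, "-layer vocabulary")
  }
  stopifnot(nzchar(e1), nzchar(e2), nzchar(r), nzchar(evidence_source))
  structure(list(e1 = e1, e1_type = e1_type, r = r, e2 = e2,
                 e2_type = e2_type, evidence_source = evidence_source,
                 layer = layer),
            class = "lr_triplet")
}

#' Extract triplets from one document
#'
#' Entity-layer extraction reads the abstract and returns typed
#' `(e1, r, e2)` assertions over genes, proteins, drugs and diseases.
#' Document-layer extraction summarizes the paper itself: methods used,
#' datasets used and research domains, each linked from the paper node.
#' Backend items with unknown types or layers are dropped and counted in the
#' `dropped` attribute.
#'
#' @param doc A [document()].
#' @param llm An LLM backend providing `extract_entity_triplets` /
#'   `extract_document_triplets`.
#' @param layer `"entity"` or `"document"`.
#' @return List of [triplet()]s with attribute `dropped` (count of rejected
#'   backend items).
#' @export
extract_triplets <- function(doc, llm, layer = c("entity", "document")) {
  layer <- match.arg(layer)
  raw <- if (layer == "entity") {
    if (!nzchar(doc$abstract)) stop("entity-layer extraction needs an abstract")
    llm$extract_entity_triplets(doc$abstract)
  } else {
    text <- if (nzchar(doc$full_text)) doc$full_text else doc$abstract
    llm$extract_document_triplets(doc$title, text)
  }
  out <- list()
  dropped <- 0L
  for (item in raw) {
    t <- tryCatch(
      triplet(item$e1, item$r, item$e2,
              e1_type = item$e1_type %||% NA_character_,
              e2_type = item$e2_type %||% NA_character_,
              evidence_source = doc$doc_id, layer = layer),
      error = function(e) NULL)
    if (is.null(t)) dropped <- dropped + 1L else out[[length(out) + 1L]] <- t
  }
  attr(out, "dropped") <- dropped
  out
}

#' Load a reference vocabulary from TSV
#'
#' Format: `canonical_term <TAB> type <TAB> source_tag`, standing in for
#' curated term lists such as MeSH (drugs, diseases) and UniProt
#' (genes, proteins).
#'
#' @param path TSV file.
#' @param emb Embedding backend used to vectorize the terms.
#' @return A `vocabulary_index`: data.frame of entries plus an embedding
#'   matrix row-aligned with it.
#' @export
read_vocabulary <- function(path, emb) {
  entries <- utils::read.delim(path, header = FALSE, sep = "\t",
                               col.names = c("term", "type", "source"),
                               stringsAsFactors = FALSE, quote = "")
  if (any(duplicated(entries[c("term", "type")]))) {
    stop("vocabulary has duplicate (term, type) entries")
  }
  vecs <- emb$embed(stats::setNames(entries$term, entries$term))
  structure(list(entries = entries, vectors = vecs),
            class = "vocabulary_index")
}

#' Two-stage entity normalization
#'
#' Stage 1 retrieves the `n_candidates` (default 5) nearest vocabulary terms
#' of the mention's type by embedding similarity; stage 2 asks the backend's
#' adjudicator to pick the semantically matching candidate. If the
#' adjudicator rejects all candidates (or the vocabulary has no terms of this
#' type) the mention itself is returned as canonical, flagged
#' out-of-vocabulary via the `"oov"` attribute.
#'
#' @param mention Surface mention text.
#' @param type Entity type of the mention.
#' @param vocab A [read_vocabulary()] index.
#' @param emb Embedding backend.
#' @param llm Backend providing `adjudicate(mention, candidates)`.
#' @param n_candidates Candidate list size (default 5).
#' @return Canonical term (character scalar) with attribute `oov`.
#' @export
normalize_entity <- function(mention, type, vocab, emb, llm,
                             n_candidates = 5) {
  rows <- which(vocab$entries$type == type)
  if (!length(rows)) {
    warning("normalize_entity: empty vocabulary for type '", type,
            "'; mention passes through")
    return(structure(mention, oov = TRUE))
  }
  mat <- vocab$vectors[rows, , drop = FALSE]
  rownames(mat) <- vocab$entries$term[rows]
  qv <- emb$embed(mention)[1, ]
  top <- top_k_by_similarity(qv, mat, k = n_candidates)
  choice <- llm$adjudicate(mention, top$id)
  if (is.na(choice)) {
    structure(mention, oov = TRUE)
  } else {
    structure(choice, oov = FALSE)
  }
}

#' Create an empty document-level merge registry
#'
#' Mutable (environment-backed) registry of canonical entity names with their
#' embedding vectors and a mention -> canonical map; grows append-only while
#' a graph is built.
#' @param emb Embedding backend the registry will vectorize names with.
#' @export
merge_registry <- function(emb) {
  reg <- new.env(parent = emptyenv())
  reg$emb <- emb
  reg$canon <- character()
  reg$vectors <- matrix(numeric(), nrow = 0, ncol = emb$dimension)
  reg$mapping <- character()      # named: mention -> canonical
  class(reg) <- "merge_registry"
  reg
}

#' Sequential insert-or-merge of a document-level entity name
#'
#' The registry is scanned for the most similar existing canonical entry; if
#' its cosine similarity exceeds 0.5 (strictly) the name is merged into that
#' entry, otherwise the name is inserted as a new canonical entry. A name
#' already mapped returns its existing canonical id without growing the
#' registry. The procedure is order-dependent by construction, so callers
#' should fix the submission order (the graph builder uses doc_id order).
#'
#' @param name Entity name.
#' @param registry A [merge_registry()].
#' @return The canonical id the name maps to.
#' @export
merge_document_entity <- function(name, registry) {
  stopifnot(nzchar(name))
  if (name %in% names(registry$mapping)) {
    return(unname(registry$mapping[[name]]))
  }
  v <- registry$emb$embed(name)[1, ]
  canonical <- NULL
  if (nrow(registry$vectors) > 0L) {
    sims <- vapply(seq_len(nrow(registry$vectors)), function(i) {
      cosine_similarity(v, registry$vectors[i, ])
    }, numeric(1))
    best <- which.max(sims)
    if (sims[best] > 0.5) canonical <- registry$canon[best]
  }
  if (is.null(canonical)) {
    registry$canon <- c(registry$canon, name)
    registry$vectors <- rbind(registry$vectors, v)
    canonical <- name
  }
  registry$mapping[[name]] <- canonical
  canonical
}

#' Assemble the dual-layer knowledge graph from triplets
#'
#' Nodes are created once per (canonical name, type); edges are directed,
#' relation-labeled and carry their `evidence_source` doc_id. Parallel edges
#' between the same node pair are kept when they differ in relation or
#' evidence; exact duplicates (same endpoints, relation and evidence) are
#' skipped. When `documents` are supplied, two cross-document link families
#' are added at the document layer: citation edges (`cites`, restricted to
#' in-corpus targets) and entity co-occurrence edges (`shares_entity`)
#' between papers whose entity-layer triplets share at least one canonical
#' entity node, with the shared-entity count as an edge attribute.
#'
#' @param triplets List of [triplet()]s (already normalized).
#' @param documents Optional named list of [document()]s (a
#'   [corpus_index()]'s `documents`); enables doc_id validation and
#'   cross-document links.
#' @param cross_links Add citation and co-occurrence links (default TRUE
#'   when `documents` given).
#' @return An igraph multigraph with vertex attributes `name`
#'   (`"<type>|<canonical>"`), `label`, `type`, and edge attributes
#'   `relation`, `evidence_source`, `layer`. Rejected triplets (unknown
#'   evidence doc) are counted in the `rejected` graph attribute.
#' @export
assemble_graph <- function(triplets, documents = NULL,
                           cross_links = !is.null(documents)) {
  node_key <- function(name, type) paste0(type, "|", name)
  nodes <- new.env(parent = emptyenv())
  edges_seen <- new.env(parent = emptyenv())
  from <- character(); to <- character()
  relation <- character(); evidence <- character(); layer <- character()
  shared_cnt <- integer()
  rejected <- 0L

  add_node <- function(name, type) {
    k <- node_key(name, type)
    if (is.null(nodes[[k]])) nodes[[k]] <- list(label = name, type = type)
    k
  }
  add_edge <- function(f, t, r, ev, ly, shared = NA_integer_) {
    ek <- paste(f, t, r, ev, sep = "\r")
    if (!is.null(edges_seen[[ek]])) return(invisible(FALSE))
    edges_seen[[ek]] <- TRUE
    from <<- c(from, f); to <<- c(to, t)
    relation <<- c(relation, r); evidence <<- c(evidence, ev)
    layer <<- c(layer, ly); shared_cnt <<- c(shared_cnt, shared)
    invisible(TRUE)
  }

  for (t in triplets) {
    if (!is.null(documents) && !t$evidence_source %in% names(documents)) {
      rejected <- rejected + 1L
      next
    }
    f <- add_node(t$e1, t$e1_type)
    g <- add_node(t$e2, t$e2_type)
    add_edge(f, g, t$r, t$evidence_source, t$layer)
  }

  if (isTRUE(cross_links) && !is.null(documents)) {
    ids <- sort(names(documents))
    # citation edges between in-corpus papers
    paper_key <- function(id) {
      add_node(documents[[id]]$title, "paper")
    }
    has_doc_triplet <- function(id) {
      any(vapply(triplets, function(t) {
        t$layer == "document" && t$evidence_source == id
      }, logical(1)))
    }
    for (id in ids) {
      targets <- intersect(documents[[id]]$cited_doc_ids, ids)
      for (tg in targets) {
        add_edge(paper_key(id), paper_key(tg), "cites", id, "document")
      }
    }
    # entity co-occurrence: papers sharing >= 1 canonical entity node
    ents_by_doc <- lapply(stats::setNames(ids, ids), function(id) {
      unique(unlist(lapply(triplets, function(t) {
        if (t$layer == "entity" && t$evidence_source == id) {
          c(node_key(t$e1, t$e1_type), node_key(t$e2, t$e2_type))
        } else character()
      })))
    })
    if (length(ids) >= 2L) {
      for (i in seq_len(length(ids) - 1L)) {
        for (j in seq((i + 1L), length(ids))) {
          shared <- length(intersect(ents_by_doc[[ids[i]]],
                                     ents_by_doc[[ids[j]]]))
          if (shared > 0L) {
            add_edge(paper_key(ids[i]), paper_key(ids[j]), "shares_entity",
                     ids[i], "document", shared = shared)
          }
        }
      }
    }
  }

  keys <- ls(nodes)
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  if (length(keys)) {
    g <- igraph::add_vertices(
      g, length(keys), name = keys,
      label = vapply(keys, function(k) nodes[[k]]$label, character(1)),
      type = vapply(keys, function(k) nodes[[k]]$type, character(1)))
  }
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to),
                           relation = relation, evidence_source = evidence,
                           layer = layer, shared_entities = shared_cnt)
  }
  g <- igraph::set_graph_attr(g, "rejected", rejected)
  g
}

#' Summary statistics of a knowledge graph
#'
#' Average degree is `2E/N` (each directed edge contributes to both
#' endpoints' degree), reported truncated to 2 decimals; the histogram is
#' over total (in + out) degree.
#'
#' @param kg An igraph graph, or `NULL` to use explicit counts.
#' @param node_count,edge_count Explicit counts (used when `kg` is `NULL`).
#' @return List: `node_count`, `edge_count`, `average_degree`,
#'   `degree_histogram` (named vector, absent for explicit counts).
#' @export
graph_stats <- function(kg = NULL, node_count = NULL, edge_count = NULL) {
  if (!is.null(kg)) {
    node_count <- igraph::vcount(kg)
    edge_count <- igraph::ecount(kg)
    hist <- if (node_count > 0) table(igraph::degree(kg, mode = "all")) else NULL
  } else {
    hist <- NULL
  }
  avg <- if (node_count > 0) trunc(200 * edge_count / node_count) / 100 else 0
  list(node_count = node_count, edge_count = edge_count,
       average_degree = avg, degree_histogram = hist)
}

#' Export a knowledge graph to bulk-import CSVs and GraphML
#'
#' Writes `nodes.csv` (`id:ID`, `label`, `type:LABEL`) and
#' `relationships.csv` (`:START_ID`, `:END_ID`, `:TYPE`, `evidence_source`,
#' `layer`) in graph-database bulk-import layout, plus `graph.graphml`.
#' Parallel edges occupy one row each.
#'
#' @param kg An igraph graph from [assemble_graph()].
#' @param destination Output directory (created if missing).
#' @return The destination path, invisibly.
#' @export
export_graph <- function(kg, destination) {
  dir.create(destination, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(destination)) stop("cannot create directory ", destination)
  nodes <- data.frame(
    `id:ID` = igraph::V(kg)$name %||% character(),
    label = igraph::V(kg)$label %||% character(),
    `type:LABEL` = igraph::V(kg)$type %||% character(),
    check.names = FALSE, stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(kg, names = TRUE)
  rels <- data.frame(
    `:START_ID` = if (nrow(el)) el[, 1] else character(),
    `:END_ID` = if (nrow(el)) el[, 2] else character(),
    `:TYPE` = igraph::E(kg)$relation %||% character(),
    evidence_source = igraph::E(kg)$evidence_source %||% character(),
    layer = igraph::E(kg)$layer %||% character(),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(nodes, file.path(destination, "nodes.csv"),
                   row.names = FALSE)
  utils::write.csv(rels, file.path(destination, "relationships.csv"),
                   row.names = FALSE)
  igraph::write_graph(kg, file.path(destination, "graph.graphml"),
                      format = "graphml")
  invisible(destination)
}

#' Re-import a knowledge graph from the bulk-import CSVs
#'
#' @param source Directory written by [export_graph()].
#' @return An igraph graph isomorphic to the exported one.
#' @export
import_graph <- function(source) {
  nodes <- utils::read.csv(file.path(source, "nodes.csv"),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  rels <- utils::read.csv(file.path(source, "relationships.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  if (nrow(nodes)) {
    g <- igraph::add_vertices(g, nrow(nodes), name = nodes$`id:ID`,
                              label = nodes$label, type = nodes$`type:LABEL`)
  }
  if (nrow(rels)) {
    g <- igraph::add_edges(g, rbind(rels$`:START_ID`, rels$`:END_ID`),
                           relation = rels$`:TYPE`,
                           evidence_source = rels$evidence_source,
                           layer = rels$layer)
  }
  g
}
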