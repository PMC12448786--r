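kg_llm <- function() {
  mock_llm(entity_types = c("drugx" = "drug", "diseasey" = "disease",
                            "genez" = "gene"),
           thesaurus = list("nsclc" = "Nonsmall Cell Carcinoma"))
}

test_that("entity-layer extraction parses planted relational sentences", {
  doc <- document("p1", "T", abstract = paste(
    "Background sentences come first.",
    "DrugX treats DiseaseY.",
    "GeneZ is associated with DiseaseY."))
  tt <- extract_triplets(doc, kg_llm(), "entity")
  expect_length(tt, 2)
  expect_equal(tt[[1]]$e1, "DrugX")
  expect_equal(tt[[1]]$r, "treats")
  expect_equal(tt[[1]]$e2, "DiseaseY")
  expect_equal(tt[[1]]$e1_type, "drug")
  expect_equal(tt[[2]]$r, "associated_with")
  expect_true(all(vapply(tt, function(t) t$evidence_source == "p1",
                         logical(1))))
  expect_equal(attr(tt, "dropped"), 0)
})

test_that("triplets with out-of-vocabulary types are dropped and counted", {
  doc <- document("p1", "T",
                  abstract = "MysteryThing treats DiseaseY. DrugX treats DiseaseY.")
  tt <- extract_triplets(doc, kg_llm(), "entity")
  expect_length(tt, 1)                  # MysteryThing has no known type
  expect_equal(attr(tt, "dropped"), 1)
  expect_error(triplet("a", "treats", "b", "cell_line", "disease", "p1",
                       "entity"), "type outside")
})

test_that("document-layer extraction yields method, dataset and domain links", {
  doc <- document("p2", "A Study", full_text = paste(
    "Intro text. This paper uses the Cohort Screening method.",
    "It uses the Orvala Registry dataset.",
    "The work is in the domain of Oncology."))
  tt <- extract_triplets(doc, kg_llm(), "document")
  rels <- vapply(tt, function(t) t$r, character(1))
  expect_setequal(rels, c("uses_method", "uses_dataset", "in_domain"))
  expect_true(all(vapply(tt, function(t) t$e1 == "A Study", logical(1))))
  expect_setequal(vapply(tt, function(t) t$e2, character(1)),
                  c("Cohort Screening", "Orvala Registry", "Oncology"))
})

test_that("normalization picks the vocabulary term, thesaurus links resolve aliases", {
  w <- fixture_world()
  llm <- kg_llm()
  vf <- withr::local_tempfile(fileext = ".tsv")
  vocab_df <- data.frame(
    term = c("Nonsmall Cell Carcinoma", "Cortellia Fibrosis",
             "Velmora Syndrome", "Zelvistat"),
    type = c("disease", "disease", "disease", "drug"),
    source = "synthetic_mesh")
  write.table(vocab_df, vf, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  vocab <- read_vocabulary(vf, w$emb)

  exact <- normalize_entity("Velmora Syndrome", "disease", vocab, w$emb, llm)
  expect_equal(as.character(exact), "Velmora Syndrome")
  expect_false(attr(exact, "oov"))

  alias <- normalize_entity("NSCLC", "disease", vocab, w$emb, llm)
  expect_equal(as.character(alias), "Nonsmall Cell Carcinoma")

  oov <- normalize_entity("Zyxxat", "disease", vocab, w$emb, llm)
  expect_equal(as.character(oov), "Zyxxat")
  expect_true(attr(oov, "oov"))
  expect_warning(
    normalize_entity("Zyxxat", "gene", vocab, w$emb, llm), "empty vocabulary")
  expect_equal(formals(normalize_entity)$n_candidates, 5)
})

test_that("document-entity merging is strict-threshold, sequential and idempotent", {
  w <- fixture_world()
  reg <- merge_registry(w$emb)
  names6 <- c("Cohort Screening", "Cohort Screening",
              "Cohort Screening Assay", "Tissue Microassay",
              "tissue microassay", "Orvala Registry")
  got <- vapply(names6, merge_document_entity, character(1),
                registry = reg, USE.NAMES = FALSE)

  # independent sequential hand-run of the insert-or-merge procedure
  canon <- character(); expected <- character()
  for (nm in names6) {
    sims <- vapply(canon, function(cn) {
      cosine_similarity(w$emb$embed(nm)[1, ], w$emb$embed(cn)[1, ])
    }, numeric(1))
    if (length(sims) && max(sims) > 0.5) {
      expected <- c(expected, canon[which.max(sims)])
    } else {
      canon <- c(canon, nm)
      expected <- c(expected, nm)
    }
  }
  expect_equal(got, expected)
  expect_equal(reg$canon, canon)
  # the near-duplicate and case variants merged; distinct names did not
  expect_equal(got[2], "Cohort Screening")
  expect_equal(got[5], got[4])
  expect_gt(length(unique(got)), 1)

  # idempotence: resubmission returns the same id, registry does not grow
  n_before <- length(reg$canon)
  expect_equal(merge_document_entity("Cohort Screening Assay", reg),
               got[3])
  expect_equal(length(reg$canon), n_before)
})

test_that("similarity exactly at the threshold inserts rather than merges", {
  # integer-coordinate stub vectors: cosine(a, probe) = 2/(2*2) = 0.5 exactly
  emb <- list(dimension = 4L,
              embed = function(texts) {
                vecs <- list(a = c(2, 0, 0, 0), probe = c(1, 1, 1, 1),
                             near = c(1, 0, 0, 1))
                out <- t(vapply(texts, function(t) vecs[[t]], numeric(4)))
                rownames(out) <- texts
                out
              })
  reg <- merge_registry(emb)
  merge_document_entity("a", reg)
  merge_document_entity("probe", reg)
  expect_equal(reg$canon, c("a", "probe"))     # 0.5 is not > 0.5
  expect_equal(merge_document_entity("near", reg), "a")
  expect_equal(length(reg$canon), 2)
})

test_that("graph assembly deduplicates evidence-identical edges only", {
  t1 <- triplet("DrugX", "treats", "DiseaseY", "drug", "disease", "p1")
  t1b <- triplet("DrugX", "treats", "DiseaseY", "drug", "disease", "p1")
  t2 <- triplet("DrugX", "treats", "DiseaseY", "drug", "disease", "p2")
  t3 <- triplet("DrugX", "inhibits", "GeneZ", "drug", "gene", "p1")
  kg <- assemble_graph(list(t1, t1b, t2, t3))
  expect_equal(igraph::vcount(kg), 3)
  expect_equal(igraph::ecount(kg), 3)       # duplicate from p1 skipped
  rel <- igraph::E(kg)$relation
  expect_equal(sum(rel == "treats"), 2)     # parallel edges, distinct evidence
  expect_setequal(igraph::E(kg)$evidence_source[rel == "treats"],
                  c("p1", "p2"))
})

test_that("a ten-triplet fixture assembles to hand-counted nodes and edges", {
  mk <- function(e1, r, e2, t1, t2, ev) triplet(e1, r, e2, t1, t2, ev)
  trips <- list(
    mk("DrugA", "treats", "DisA", "drug", "disease", "p1"),
    mk("DrugA", "treats", "DisA", "drug", "disease", "p2"),
    mk("DrugA", "treats", "DisA", "drug", "disease", "p2"),   # dup
    mk("GeneB", "associated_with", "DisA", "gene", "disease", "p1"),
    mk("GeneB", "associated_with", "DisB", "gene", "disease", "p3"),
    mk("DrugC", "inhibits", "GeneB", "drug", "gene", "p3"),
    mk("ProtD", "interacts_with", "GeneB", "protein", "gene", "p4"),
    mk("DrugA", "inhibits", "GeneB", "drug", "disease", "p4"),
    mk("DisA", "associated_with", "DisB", "disease", "disease", "p2"),
    mk("DrugC", "treats", "DisB", "drug", "disease", "p4"))
  # hand count: nodes {DrugA, DisA, GeneB, DisB, DrugC, ProtD, GeneB(disease)}
  # edges: 10 triplets - 1 duplicate = 9
  kg <- assemble_graph(trips)
  expect_equal(igraph::ecount(kg), 9)
  expect_equal(igraph::vcount(kg), 7)       # GeneB appears as gene and disease
  expect_true(all(nzchar(igraph::E(kg)$evidence_source)))
})

test_that("triplets citing unknown documents are rejected and counted", {
  w <- fixture_world()
  good <- triplet("DrugX", "treats", "DiseaseY", "drug", "disease",
                  names(w$manifest$documents)[1])
  bad <- triplet("DrugX", "treats", "DiseaseY", "drug", "disease", "ghost")
  kg <- assemble_graph(list(good, bad), documents = w$manifest$documents,
                       cross_links = FALSE)
  expect_equal(igraph::ecount(kg), 1)
  expect_equal(igraph::graph_attr(kg, "rejected"), 1)
})

test_that("cross-document links add citation and shared-entity edges", {
  w <- fixture_world()
  man <- w$manifest
  trips <- list()
  for (id in sort(names(man$documents))) {
    trips <- c(trips, extract_triplets(man$documents[[id]], w$llm, "entity"),
               extract_triplets(man$documents[[id]], w$llm, "document"))
  }
  kg <- assemble_graph(trips, documents = man$documents)
  rel <- igraph::E(kg)$relation
  expect_true("cites" %in% rel)
  # citation edges restricted to in-corpus ids (EXT999 never becomes a node)
  expect_false(any(grepl("EXT999", igraph::V(kg)$label)))
  shares <- which(rel == "shares_entity")
  expect_gt(length(shares), 0)
  expect_true(all(igraph::E(kg)$shared_entities[shares] >= 1))
  # provenance totality
  expect_true(all(igraph::E(kg)$evidence_source %in% names(man$documents)))
})

test_that("graph statistics use total degree 2E/N to two decimals", {
  expect_equal(graph_stats(node_count = 2, edge_count = 1)$average_degree, 1)
  expect_equal(graph_stats(node_count = 0, edge_count = 0)$average_degree, 0)
  set.seed(5)
  for (i in 1:5) {
    g <- igraph::sample_gnm(sample(5:20, 1), sample(4:30, 1), directed = TRUE)
    st <- graph_stats(g)
    expect_equal(sum(st$degree_histogram), st$node_count)
    hist_mean <- sum(as.numeric(names(st$degree_histogram)) *
                       st$degree_histogram) / st$node_count
    expect_equal(st$average_degree, trunc(hist_mean * 100) / 100)
    expect_equal(st$average_degree,
                 trunc(200 * st$edge_count / st$node_count) / 100)
  }
})

test_that("export and re-import preserve the multigraph and its provenance", {
  t1 <- triplet("DrugX", "treats", "DiseaseY", "drug", "disease", "p1")
  t2 <- triplet("DrugX", "treats", "DiseaseY", "drug", "disease", "p2")
  kg <- assemble_graph(list(t1, t2))
  dir <- withr::local_tempdir()
  export_graph(kg, dir)
  rels <- read.csv(file.path(dir, "relationships.csv"), check.names = FALSE)
  expect_equal(nrow(rels), 2)               # one row per parallel edge
  kg2 <- import_graph(dir)
  expect_equal(igraph::vcount(kg2), igraph::vcount(kg))
  expect_equal(igraph::ecount(kg2), igraph::ecount(kg))
  expect_setequal(igraph::E(kg2)$evidence_source,
                  igraph::E(kg)$evidence_source)
  expect_true(file.exists(file.path(dir, "graph.graphml")))
  gml <- igraph::read_graph(file.path(dir, "graph.graphml"),
                            format = "graphml")
  expect_equal(igraph::ecount(gml), 2)

  empty_dir <- withr::local_tempdir()
  export_graph(assemble_graph(list()), empty_dir)
  nodes <- read.csv(file.path(empty_dir, "nodes.csv"), check.names = FALSE)
  expect_equal(nrow(nodes), 0)
  expect_equal(names(nodes), c("id:ID", "label", "type:LABEL"))
})

test_that("rebuilding from the same triplet stream yields an identical graph", {
  w <- fixture_world()
  build <- function() {
    trips <- list()
    reg <- merge_registry(w$emb)
    for (id in sort(names(w$manifest$documents))) {
      doc <- w$manifest$documents[[id]]
      trips <- c(trips, extract_triplets(doc, w$llm, "entity"))
      td <- extract_triplets(doc, w$llm, "document")
      td <- lapply(td, function(t) {
        t$e1 <- merge_document_entity(t$e1, reg)
        t$e2 <- merge_document_entity(t$e2, reg)
        t
      })
      trips <- c(trips, td)
    }
    assemble_graph(trips, documents = w$manifest$documents)
  }
  g1 <- build(); g2 <- build()
  expect_identical(igraph::as_data_frame(g1, "both"),
                   igraph::as_data_frame(g2, "both"))
})
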