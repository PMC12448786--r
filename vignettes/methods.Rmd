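---
title: "Methods: integrated retrieval, progressive generation and the dual-layer knowledge graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated retrieval, progressive generation and the dual-layer knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(literag)
```

`literag` answers free-text questions from a local corpus of research
documents and builds a provenance-carrying knowledge graph from the same
corpus. This vignette explains the model behind each stage, the parameters
that matter, the numerical and design choices made where the design was
genuinely open, what the synthetic test corpus does and does not emulate,
and the known limitations.

## The retrieval corpus

A corpus is a set of documents, each with a title, optional abstract,
optional full text, and metadata (year, keywords, citation links). Retrieval
operates on two levels of addressable fragments:

* **abstract level** — each non-empty abstract is one chunk, never split,
  because abstract retrieval ranks whole abstracts;
* **full-text level** — the body is segmented into chunks of at most
  `chunk_size = 500` characters with `overlap = 100` characters carried over
  between consecutive chunks.

Lengths are measured in characters, not tokens. The splitter aims to
preserve sentence integrity: for each 500-character window it cuts at the
last occurrence of the highest-priority separator — paragraph break, line
break, sentence-ending punctuation followed by a space, single space — that
still leaves more than `overlap` characters of new content (so every chunk
advances the scan), and falls back to a hard character cut for unbroken
runs. This boundary-priority scan is the iterative equivalent of recursively
descending the separator hierarchy, and is easier to verify: chunk spans
carry explicit `[char_start, char_end)` offsets, the union of a document's
spans is exactly `[0, nchar(text))`, consecutive spans overlap by exactly
100 characters wherever a split occurred, and splitting is deterministic.
Degenerate inputs are handled explicitly: empty text yields no chunks, text
at or below 500 characters yields one chunk, and `overlap >= chunk_size` is
rejected at configuration time (it would stall the scan).

An open point is whether abstracts should also appear in the full-text
chunk pool; here they are kept in a separate abstract level only, so a
document's abstract and body chunks are distinct retrieval units that both
count toward the document's intradocument repetition factor.

## Backend contracts and the mock implementations

Two capabilities are model-dependent and sit behind contracts:

* an **embedding backend** — `embed(texts)` returning fixed-dimension
  vectors compared by cosine similarity;
* an **LLM backend** — pre-retrieval reasoning, chunk relevance judgment,
  draft answering, support scoring, deep answering, plus adjudication and
  extraction hooks for the knowledge-graph workflow and a 5-point answer
  judge for evaluation.

The bundled mocks are deterministic and seed-free so every pipeline result
is exactly reproducible. `mock_embedding()` hashes character 3-grams into a
256-dimensional term-frequency vector and length-normalizes it; identical
strings embed identically and texts sharing no 3-grams are orthogonal (up
to hash collisions, which a 256-bucket table makes rare but not
impossible). `mock_llm()` extracts capitalized and thesaurus-known terms as
keywords, concatenates the question with its keywords as the virtual
answer, judges a chunk relevant when it contains a fact token associated
with the question, scores support as the rounded percentage of draft
content words present in the chunk, and answers by quoting the evidence
sentences that contain known fact tokens. Ranking ties are always broken
lexicographically by id — a convention chosen purely to make rankings
well-defined and testable.

These mocks are caricatures of real models: they have no semantics beyond
surface overlap. They are the right instrument for testing the *pipeline
logic* (ranking, fusion, stopping rules, provenance plumbing), and the wrong
instrument for estimating how well the method would answer real questions;
the corpus-scale benchmark numbers reported for systems of this design
require live embedding and reasoning models and are out of scope here.

## Integrated retrieval

Phase 1 (`run_preretrieval`) normalizes the backend's keyword groups
(deduplication, empty-string stripping, head term excluded from its own
synonyms, truncation at 10 groups of 10 synonyms — an uncapped backend
could otherwise make keyword matching quadratic) and keeps the virtual
answer as an internal query string only; it is never shown to the user. If
the backend produces neither keywords nor a virtual answer, the whole
question becomes the single head term, flagged as degraded.

Phase 2 (`retrieve_all`) runs five strategies: question vs. abstracts,
virtual answer vs. abstracts, question vs. full-text chunks, virtual answer
vs. full-text chunks (each top `k_per_strategy = 10`), and keyword matching
over full-text chunks. A keyword group matches a chunk when its head term or
any synonym occurs case-insensitively on word boundaries; the chunk's score
is the fraction of groups matched, and all chunks with positive score enter,
capped at 50 by score to bound the pool. The keyword pass is not run at the
abstract level: keyword hits on short abstracts contribute almost nothing,
and the abstract level is already covered by two embedding strategies.
Negative cosine similarities are clamped to zero on entry so all raw scores
live in [0, 1] and the fusion terms stay non-negative.

`fuse_candidates` deduplicates hits by chunk and scores each candidate as

$$S_i = w_S \frac{S_{sim,i}}{S_{sim,max}} + w_M \frac{M_i}{M_{max}} +
  w_R \frac{R_i}{R_{max}},$$

with defaults $w_S = 5, w_M = 3, w_R = 1$. Three choices here were open:

* $S_{sim,i}$ for a chunk found by several strategies is the **maximum**
  raw score over them — the strongest signal should speak; a mean would
  penalize chunks for also being found by the coverage-oriented keyword
  pass.
* $M_i$ and $R_i$ are counted **after** deduplicating the five hit lists,
  so $R_i$ is the number of distinct candidate chunks (across both levels,
  self included) from the same document.
* A factor whose pool maximum is zero contributes zero rather than
  dividing by zero.

The score is invariant to rescaling all similarities by a positive
constant, bounded by $w_S + w_M + w_R = 9$ with equality exactly when a
candidate attains all three maxima (any single-candidate pool therefore
scores exactly 9), and monotone in each factor. The test suite checks all
three properties against an independent evaluation of the formula on
hundreds of random pools.

## Progressive generation

`relevance_check` walks the fused ranking in order and stops as soon as
`target = 5` chunks are judged relevant. Two fallbacks mirror the stopping
rule: with 1–4 relevant chunks only those are used (`partial`); with none,
the top 5 by fused score are used regardless of the verdicts
(`fallback_top5`). The examination budget (`max_examined = 30`) is a
package choice — an unbounded scan is pointless under a judge that rejects
everything — and each chunk is judged independently, without seeing
previously accepted chunks.

`construct_draft` passes the selected chunks, in fused-score order, to the
draft capability. `self_reflect` then scores each chunk 0–100 for support
of the draft (out-of-range backend values are clamped with a warning;
unparseable values become 0). `deep_answer` forwards the chunks with
positive support, in descending score order, to the deep-reasoning
capability — dropping only chunks flagged irrelevant or contradictory,
since no support threshold beyond zero is principled here — and falls back
to all chunks in fused-score order when every score is zero. The draft
itself is not shown to the final pass; its only role is to anchor the
support scores. The returned record carries the full evidence trail
(chunk ids, documents, spans, scores) for auditability.

## The dual-layer knowledge graph

Entity-layer triplets `(e1, r, e2)` over the types gene, protein, drug and
disease are extracted from abstracts; document-layer triplets link each
paper node to its methods, datasets and research domains. Items with types
outside the layer's vocabulary are dropped and counted rather than guessed
at. The relation vocabulary defaults to common biomedical relations
(treats, inhibits, promotes, associated_with, interacts_with, uses_method,
uses_dataset, in_domain, cites) and is configurable — it is a placeholder,
not a curated ontology.

Entity normalization is two-stage: the 5 nearest vocabulary terms of the
mention's type by embedding similarity are offered to an adjudicator, which
either confirms one (exact case-insensitive match or a thesaurus link,
under the mock) or rejects all, in which case the mention passes through as
canonical and is flagged out-of-vocabulary. Note the recall limitation this
inherits from the embedding: if the vocabulary holds many same-type terms
and the true canonical form shares little surface text with the mention,
it may not reach the top-5 candidate list at all — with the 3-gram mock
embedding this happens for alias pairs with disjoint spellings unless the
thesaurus provides the link.

Document-level names are merged sequentially: each incoming name is
compared against the registry and merged into the most similar entry if
cosine similarity is **strictly** greater than 0.5, else inserted as new.
The procedure is order-dependent by construction, so the graph builder
fixes the submission order to sorted document ids; resubmitting a known
name returns its existing canonical id without growing the registry.
Similarity exactly 0.5 inserts — the threshold is strict, and the tests pin
this with exact-arithmetic vectors.

The assembled graph is a directed igraph multigraph: one node per
(canonical name, type); one edge per distinct (source, target, relation,
evidence) — the same assertion from two papers yields two parallel edges
with different `evidence_source`, the same assertion twice from one paper
yields one. Cross-document structure at the document layer comprises
citation edges (restricted to in-corpus targets) and `shares_entity` edges
between papers whose entity-layer triplets share at least one canonical
node, with the shared count as an attribute; since every edge must carry a
resolvable `evidence_source`, a co-occurrence edge is anchored to the
lexicographically smaller document id. Average degree is $2E/N$ (every
directed edge contributes to both endpoints), reported truncated — not
rounded — to two decimals, the convention under which the statistic
reproduces published corpus-scale values. Export writes bulk-import-style
`nodes.csv` / `relationships.csv` (`:ID`, `:LABEL`, `:START_ID`, `:END_ID`,
`:TYPE` headers) plus GraphML; re-import reproduces an isomorphic graph,
parallel edges and provenance included.

## Evaluation protocol

Per question, document retrieval is scored by precision, recall and F1
against the gold source documents, with the 0/0 guard on F1. The paper set
actually *retrieved* is deliberately defined as the unique source documents
of the evidence chunks used for final generation — the evidence the answer
rests on — rather than everything any strategy touched; every results file
records this convention. Answer quality is a 5-point judge grade reported
as a percentage (`grade / 5 * 100`; the mock judge thresholds content-word
overlap with the gold answer).

Four ablation modes isolate the two stages: `full`; `no_progressive`
(answer directly from the top-5 fused candidates); `no_integrated` (flat
top-50 chunks by question embedding only, then progressive generation);
`no_retrieval` (no context; retrieval metrics undefined). A recall
decomposition table reports document-level recall per strategy, per corpus
level, multilevel, and cumulatively as granularities are added
(question-based, + virtual-answer-based, + keyword-based); cumulative
recall is a set union and therefore monotone.

## The synthetic corpus

`generate_corpus(seed)` builds a fully self-contained test world: 12
documents, 4 questions, half the documents distractors. Every name in it is
invented. Each question's fact ("&lt;Drug&gt; treats &lt;Disease&gt;") is
planted in 1–3 gold documents; these have short full texts (single chunk),
so the 5-acceptance stopping rule can never truncate gold coverage, and
their abstracts carry gene–disease sentences for the entity layer.
Distractor documents are long (multi-chunk, straddling the 500-character
boundary so both chunking paths are exercised) and repeat the surface
vocabulary of every question without any fact token. Odd-numbered questions
reference their disease by a thesaurus synonym that gold documents never
use: those facts are unreachable by flat question-embedding retrieval but
reachable through synonym keyword matching and the virtual answer. This
construction is what makes the end-to-end contrast meaningful — the full
pipeline recovers every planted fact (recall 1.0) while the `no_integrated`
ablation cannot — and it is a *construction*, not an empirical finding:
passing it shows the pipeline logic routes synonym evidence correctly, not
that any particular recall level would be attained on real literature,
where relevance is graded, synonymy is open-ended, and embeddings carry
actual semantics.

Problem sizes throughout the test suite (a 12-document corpus, pools of at
most 20 candidates, a few hundred random texts and pools) are chosen so
the whole suite exercises every code path in well under a minute; all
stochastic tests fix their seeds.

## Known limitations

* The mock backends measure surface overlap only; no conclusion about
  answer quality on real corpora follows from their scores.
* Keyword matching is exact (word-boundary, case-insensitive); no
  stemming, spelling correction or ontology expansion.
* The two-stage normalizer cannot recover canonical terms absent from its
  top-5 candidate list (see above).
* Entity co-occurrence links are binary with a count attribute; no
  weighting or significance testing.
* Retrieval is exact exhaustive cosine search — appropriate at package
  scale; corpus sizes in the millions of chunks would need an ANN index
  behind the same embedding contract.
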