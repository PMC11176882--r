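---
title: "Methods: co-occurrence networks and graph-query search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks and graph-query search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litgraph)
```

`litgraph` implements a literature-search method in which a corpus of
publication abstracts is summarized as an ontology-annotated co-occurrence
network and searched with small graph queries. This vignette is the package's
account of the method: the model and its assumptions, the parameters that
matter, the numerical and design choices, and what the synthetic test
conditions do and do not demonstrate.

## Corpus model and cleaning

The input is a publication-metadata table in the CORD-19 `metadata.csv`
dialect: one row per record, records clustered by `cord_uid`, with title,
abstract, publication date, journal, authors, DOI and an optional citation
count. The method operates on titles and abstracts only; full-text parsing is
out of scope because, in corpora of this kind, abstract-bearing records cover
the overwhelming majority of the usable text.

Cleaning applies, in order: rows without a record id or a parseable 4-digit
year are dropped with warnings; year-only dates are retained as January 1 with
a `date_precision = "year"` marker (so date-based ranking remains total
without inventing precision); rows without an abstract are dropped; titles
failing an English-language check are dropped; records dated before
`min_year` (default 2020) whose title or abstract matches an exclusion term
(default: earlier-coronavirus vocabulary — "MERS", "SARS", "coronavirus" and
their long forms) are dropped; finally each cluster keeps exactly one row —
the peer-reviewed one (journal present) if any, else the row *richest in
metadata*.

Two of these rules required definitions the source material leaves open, and
both are deliberately simple and pluggable:

* **Richness** is the count of non-missing fields among title, abstract,
  publish time, journal, authors, DOI and citation count, with ties broken by
  input order. Any monotone notion of "more complete metadata" would do; this
  one is transparent and cheap.
* **Language detection** defaults to an ASCII-letter-ratio heuristic (≥ 90%
  of alphabetic characters ASCII). It is intentionally crude: it cannot
  separate English from, say, Dutch, but it reliably removes the non-Latin
  scripts that dominate real non-English contamination, and any
  `character -> logical` predicate (e.g. a statistical detector) can be
  substituted via `language_filter`.
* The exclusion filter is applied to title *and* abstract; restricting it to
  titles alone is possible by passing the text columns accordingly, but the
  wider net matches the filter's intent (removing earlier-epidemic
  literature, not merely earlier-epidemic titles).

Cleaning is idempotent, which the tests assert directly.

## Entity mining, linking and curation

The default mention extractor is a deterministic dictionary matcher over a
lexicon of concept surface forms (UMLS/CIDO-style extracts serialized as TSV,
plus utility terms). Text and surfaces are NFKC-normalized and case-folded;
tokens keep internal hyphens, parentheses and commas so concept labels like
`sars-cov-2` survive tokenization. Stopwords are removed unless they occur
inside a lexicon surface; remaining tokens are lemmatized by a small
suffix-stripping rule set. Candidate n-grams are matched longest-first and
non-overlapping, so "cystic fibrosis" yields one 2-gram concept rather than
two fragments. A raw hit scores similarity 1; a hit through the lemmatized
form scores the normalized Levenshtein similarity between the raw span and the
matched surface.

A statistical NER model would recover paraphrases the dictionary cannot; the
package therefore treats the extractor as a pluggable backend (any function
producing the same mention-record shape), while the dictionary default keeps
every test deterministic and dependency-free.

Curation aggregates mentions per concept and discards mentions whose
similarity falls below the gate — **threshold 0.7, inclusive**, so a mention
at exactly 0.7 survives; utility terms are exempt since they carry no ontology
string to compare against. Similarity is computed against the raw span rather
than the lemmatized one (the raw span is what the reader sees; the choice is
configurable in the extractor). An entity's frequency is the number of
*distinct documents* mentioning it: a concept mentioned five times in one
abstract counts once, which is the quantity the association statistics below
need.

## The co-occurrence network

Link mining is a single greedy pass over documents: a document with `k`
curated entities contributes its `choose(k, 2)` unordered pairs, so the work
is proportional to the total number of per-document pairs rather than to the
square of the vocabulary. Edge names concatenate the endpoint names in
alphabetical order around an em dash ("X—Y", ASCII `--` available via
`separator`); names are display identifiers only — endpoints are always
stored as a pair and never re-parsed, so concept names containing the
separator are safe. Alphabetical order means C-locale byte order everywhere,
so artifacts are byte-identical across machine locales.

Each edge carries PMI, NPMI and Cramér's V computed from the 2×2 document
contingency table. Numerical conventions:

* Logarithms are natural internally; NPMI is a ratio of logarithms and hence
  base-invariant (asserted in tests), and the base used for reported PMI is
  recorded in the network metadata.
* `NPMI = 1` is taken by limit when `p(x,y) = 1` (the denominator
  `−log p(x,y)` vanishes); the case is logged, since a pair present in every
  document usually signals a degenerate corpus.
* Cramér's V on a 2×2 table uses `V = sqrt(χ²/N)` with Pearson χ² and no
  continuity correction (`min(r−1, c−1) = 1`); when a marginal fills the
  whole corpus the table is degenerate and V is defined as 0. V is computed
  and stored for inspection but the query engine ranks by NPMI only.

Consolidation excludes edges with `NPMI ≤ 0` — strictly, so an edge at exact
independence is removed. Pruning leaves the node set unchanged;
`connectivity_report()` computes the connected components and warns when the
graph is not a single component, because only a connected network guarantees
that every formulated query can be matched. Search over a multi-component
network is still permitted: an unreachable query edge simply yields an empty
expansion and a zero addend.

The inverted index maps each retained relationship to the sorted list of
documents co-mentioning its endpoints; posting-list lengths equal edge
frequencies by construction, and the tests recount them by brute scan.

## Graph-query search

A query is a connected undirected graph whose nodes resolve to network
concepts (unknown names produce an error listing near matches by normalized
similarity). For each query relationship absent from the network, the engine
enumerates **all simple paths of minimal hop count** between the endpoints
(igraph's all-geodesics enumeration, cross-checked in the tests against an
exhaustive DFS oracle), ranks them by average NPMI and retains the top 10.
Design choices around this expansion:

* **Path length is the number of edges.** The source material counts lengths
  both as intermediate-node counts and as edge counts in different places;
  the edge-count convention is adopted uniformly because the described
  "3 paths of length 3, each with 2 intermediate nodes" is only consistent
  with hop counting.
* NPMI ranks among equal-length candidates; it never defines length (no
  weighted-shortest-path semantics).
* Ties in average NPMI break on the lexicographic node-name sequence, making
  expansion output deterministic.
* When fewer than 10 minimal-length paths exist the quota is *not* backfilled
  with longer paths — a strict reading of "shortest"; backfilling would make
  an addend's denominator depend on unrelated paths.
* A query edge present in the network is its own single candidate of
  length 1, regardless of longer alternatives.

One path per expansion is *selected* — by default the top-ranked one,
overridable per edge via `select_path()`, mirroring the interactive selection
step of the original workflow.

Scoring: for a publication P and a query edge with selected path of length L,
the addend is m/L where m counts the path relationships whose posting list
contains P; the publication's score is the sum of addends over query edges
("number of explained relationships", in [0, |rels(Q)|]). The candidate set
for retrieval is the **union** of the selected-path posting lists —
intersection would hide exactly the partially-explaining publications the
fractional addends exist to surface. `npmi_sum` adds the NPMI of mentioned
relationships, counting each distinct network edge once even when selected
paths share edges (double-counting would reward redundant expansions).
Ranking is by score, then `npmi_sum`, then publication date — most recent
first, matching literature-search convention, and flag-reversible — then
record id ascending so the ranking is total and runs are byte-identical. An
optional mode prepends the citation count as the primary key.

## Synthetic fixtures: what they emulate and what they do not

`generate_corpus()` draws per-document entity sets from a baseline mention
probability (default 0.05 per entity, a density at which a few hundred
documents produce networks with tens of edges, comparable in sparsity to
abstract-level co-mention data) plus per-pair affinities that inflate joint
mentions; abstracts are bags of surface forms joined by filler words, so the
dictionary matcher recovers the planted sets exactly, and the empirical joint
frequency of an affine pair converges to
`affinity + (1 − affinity)·baseline²` (asserted within three binomial
standard errors at 2,000 documents).

`figure6_fixture()` hand-designs the running example: 76 documents, 13
concepts, a 14-edge designed network, and a 6-node, 5-edge query in which the
SARS-CoV-2—ACE2 relationship expands into three length-3 candidates, the
AngII—Vascular Permeability relationship into one length-2 path through
"(1,0)", and three relationships match directly. Coordinate-style labels
follow the figure conventions of the running example but are expansion-local
there, so globally unique variants are used and all ids are synthetic. The
document design places `pub001` on every relevant posting list except the
tail of the AngII path (addends 1, 1, 1, 1, ½ → 4.5) and `pub002` off the
AngII path and the head of the selected left path (addends 1, 1, 1, ⅔, 0 →
11/3). Background pair-documents give every designed edge a positive NPMI,
and singleton documents depress the NPMI of the alternative paths'
intermediates so the designed candidate ordering is a consequence of honestly
computed statistics, not of assigned weights. Pushing the fixture's abstracts
through the full pipeline regenerates the designed posting lists and the same
two scores — the pipeline also discovers a handful of incidental
co-mention edges (within-publication pairs), which is expected and harmless
because they are either pruned at `NPMI ≤ 0` or rank below the designed
paths.

What passing these tests shows: the cleaning rules, matcher, statistics,
pruning, expansion, scoring and ranking behave exactly as specified on
corpora whose ground truth is known. What they do not show: performance or
recall on a real, noisy corpus — real abstracts contain paraphrases the
dictionary matcher misses (a statistical NER backend is the intended remedy),
real metadata contains date and encoding pathologies beyond the emulated
ones, and full-corpus network sizes (hundreds of thousands of entities, tens
of millions of relationships) are orders of magnitude beyond these fixtures,
so scalability claims are limited to the algorithmic complexity arguments
above.

## Problem sizes and runtime choices

The shipped test suite runs the running-example fixture (76 documents), a
300-document generated corpus for the pipeline-invariant checks, convergence
checks at 2,000 documents, and oracle sweeps over 100 random connected
networks of up to 14 nodes (plus a second sweep up to 30 nodes) with every
node pair compared against exhaustive DFS enumeration — sizes chosen so the
exhaustive oracles remain exact rather than sampled. The acceptance script
rebuilds the fixture and a 10-document calibration corpus from scratch at
each run.

## Known limitations

* Relationship semantics: edges are co-occurrence only; the engine captures
  *that* two concepts relate in a document, never *how*.
* The dictionary matcher cannot link paraphrases or misspellings beyond what
  the lemmatizer and the 0.7 gate admit.
* The greedy pair pass materializes each document's pair set; documents
  mentioning thousands of distinct concepts would need chunking.
* No incremental network updates: adding documents means rebuilding.
* Storage is plain text (TSV/JSON-lines) by design; a graph database would be
  the natural backend at full-corpus scale.
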