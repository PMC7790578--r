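---
title: "Methods: network-pharmacology inference with netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-pharmacology inference with netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

# The inference chain

`netpharm` implements the inference chain that multi-herb
network-pharmacology studies use to go from database exports to a ranked
list of candidate mechanism genes:

1. **ADME screen** — keep candidate compounds with oral bioavailability
   `OB >= 30 %` and drug-likeness `DL >= 0.18`.
2. **Target mapping** — union the looked-up protein targets per herb;
   intersect herbs with each other and the combined drug target set with a
   disease gene collection.
3. **Network construction** — a compound–target bipartite network over the
   drug–disease overlap genes, and a PPI graph over the same genes ingested
   from a STRING-style edge list.
4. **Hub selection** — six node centralities, a median-consensus filter,
   and a maximal-clique-centrality (MCC) ranking of the survivors.
5. **Enrichment** — hypergeometric over-representation of the hub list
   against GO/KEGG-like annotation collections with BH correction.

Each stage is a pure function over explicit containers (compound tables,
`gene_set`s, `target_map`s, `ppi_graph`s, `annotation_collection`s), so the
chain can be run whole (`run_pipeline()`) or stage by stage.

# Screening model and its assumptions

OB (percent reaching systemic circulation after oral dosing) and DL (a
dimensionless similarity to known drugs) are *inputs*: the package never
computes them from structure. Both thresholds are inclusive. This matters
at the boundary — the packaged 39-compound herb-pair table contains two
compounds with DL exactly 0.18, and the published count of 34 active
compounds is only reproduced when boundary rows pass.

Some studies re-add pharmacologically important compounds that fail the
numeric screen. The compound-table format carries this as a `manual_add`
flag: flagged rows are outside the numeric screen entirely and pass only
when `include_manual = TRUE`. They typically contribute no targets (they
failed the lookup too), which is why the default pipeline leaves them out.

# Set algebra

Gene identity is the uppercased, trimmed symbol string; no alias resolution
is attempted, because the upstream databases the inputs come from already
emit symbols and silent alias mapping would make counts irreproducible.
Disease gene collections are read verbatim — deliberately no score
threshold — matching how such collections are assembled from gene–disease
databases. Every `set_intersection_report()` asserts
`|A| + |B| = |A ∪ B| + |A ∩ B|`; `intersection_from_counts()` applies the
same identity when only published sizes are available.

# Graph model and centrality conventions

The PPI graph is simple and undirected: self-loops are dropped, both edge
orientations collapse to one canonical (sorted-endpoint) edge, and the
handshake lemma is asserted at construction. Confidence scores are used
only for ingest filtering (default `score_min = 400`, STRING's
conventional medium-confidence cut — the threshold is exposed because
source studies rarely state theirs); all centrality work is unweighted,
consistent with integer degrees in published hub tables.

Conventions that genuinely had more than one defensible choice:

* **Betweenness** is unnormalized and counts each unordered pair once
  (`ordered_pairs = TRUE` doubles every value). Published tables are
  consistent with either convention, so the flag exists and the default is
  documented rather than hidden.
* **Closeness** is normalized per connected component,
  `(n_c − 1)/Σ d`, with isolated nodes at 0. After restriction to overlap
  genes and isolate removal the analysis graph is usually connected, but
  the per-component definition keeps the measure finite on anything.
* **Eigenvector centrality** is computed by power iteration on `A + I`.
  The shift leaves eigenvectors unchanged while making the top eigenvalue
  strictly dominant, so the iteration also converges on bipartite graphs
  (e.g. stars), whose extreme adjacency eigenvalues are `±λ`. Defaults:
  tolerance `1e-10` (successive-iterate max difference), cap 10,000
  iterations, uniform non-negative start; hitting the cap is an explicit
  error because a silently unconverged vector would corrupt the consensus
  filter downstream. Output is non-negative with unit Euclidean norm.
* **NC's edge clustering coefficient** divides the triangle count on an
  edge by `min(deg u − 1, deg w − 1)`; when an endpoint has degree 1 the
  denominator is 0 and the ECC is taken as 0 by default
  (`ecc_degenerate = "one"` selects the alternative convention). Zero was
  chosen because a pendant edge supports no triangles and should not
  certify clustering.
* **MCC** enumerates maximal cliques with Bron–Kerbosch plus pivoting and
  sums `(|C| − 1)!`. Single vertices are not counted as cliques, so an
  isolated node scores 0 while a node whose neighborhood induces no edges
  scores exactly its degree. Factorials up to `18!` are exact in doubles;
  PPI cliques are far smaller. A configurable cap (default `1e6` cliques)
  turns pathological inputs into an explicit failure instead of a hang.
* **Median-consensus filter**: even-count medians are the mean of the two
  middle values; the comparison defaults to inclusive `>=` ("meets the
  median") with a strict `>` alternative — on the packaged reference table
  both rules retain the same 13 rows, so the default is benign.
  `median_filter()` accepts externally supplied medians because published
  medians are typically computed over the full network while only the
  retained rows are printed.
* **Top-k tie-break** (MCC, then degree, then name) is a stable invented
  order; the `tied` column flags selections that depended on it.

# Enrichment

`hypergeom_tail()` evaluates `P(X ≥ k)` through the survival function of
the hypergeometric distribution (no naive summation), and `bh_adjust()`
applies the Benjamini–Hochberg step-up rule. The background universe
defaults to the union of all annotation-term genes, because source studies
rarely state their background; an explicit universe can be supplied, and
changing it changes every p-value, which is why the choice is surfaced in
the API rather than buried. Terms with zero query hits are suppressed
(matching common enrichment tools), q-values are computed across the
reported terms, and the published-style cutoffs `p ≤ 0.05`, `q ≤ 0.05`
flag significance. The q-value is BH FDR; if a Storey-style q were wanted
it would have to be added explicitly.

# What the synthetic generators emulate

The generators replace five database pulls with distributions whose ground
truth is recorded in manifests:

* **Compound tables**: OB ~ Uniform(0, 100), DL ~ Uniform(0, 1), giving a
  pass fraction of `0.70 × 0.82 = 0.574` at the default thresholds —
  comparable to real screens. Candidate counts default to 65 + 116 per
  herb, typical pull sizes for a root/rhizome herb pair; the published
  counts in such studies are post-screen, so the generator's candidates
  are pre-screen by design.
* **Target maps**: per-herb target pools of 13 and 41 genes sharing 7,
  assigned to 6 + 10 mapped compounds (drawn only from screen-passing
  records, since lookup follows screening) with zero-truncated Poisson
  sizes, every pool gene covered by at least one compound. The remaining
  compounds map to nothing, emulating lookup misses.
* **Disease collections**: 7,153 genes containing exactly 44 planted drug
  targets; filler genes are drawn outside the drug target union so the
  planted overlap is exact.
* **PPI graphs**: a preferential-attachment backbone (heavy-tailed degrees;
  attachment 1 gives a triangle-free tree) with one planted clique
  (default size 6) wired in by adding all pairwise edges among random
  backbone nodes.
* **Annotations**: 50 terms of size 10–60 drawn uniformly from a
  2,000-gene universe containing the query, plus one planted term (size
  40) holding 10 of the 15 query genes.

What passing closed-loop tests on these data shows: the pipeline's
arithmetic is correct and its statistics have the intended operating
characteristics (the planted clique tops the MCC ranking in effectively
every replicate; the planted term is detected at `q ≤ 0.05` with power
≈ 1 at the stated effect size; random queries flag well under 5 % of
terms). What it does not show: anything about the biological fidelity of
real compound–target or interaction databases — uniform OB/DL, Poisson
target counts and preferential attachment are stylized stand-ins, not fits
to real data, and real PPI confidence structure, annotation redundancy and
gene-multifunctionality biases are absent.

# Numerical choices and degenerate inputs

Empty filter results, empty networks and edgeless graphs are legal
everywhere except where the science forbids them: eigenvector centrality
requires an edge, and ORA requires a non-empty effective query — both are
explicit errors. Degree-0 nodes ("discrete points") are removed after
restriction to the overlap genes, never before, so the restriction itself
can create the isolates that are then dropped. Medians, set operations and
rankings are deterministic with stated tie-breaks; the only randomness in
the package lives in the generators, which are pure functions of their
config seed (stage seeds derive as `seed + 0..4`).

# Test-suite design

Each centrality, MCC and the hypergeometric tail are verified against
independent brute-force oracles written in the test helpers:
Floyd–Warshall distances, exhaustive simple-path enumeration for
betweenness, dense symmetric eigendecomposition for the eigenvector (skipped
when the top eigenvalue is numerically degenerate and the principal
direction not unique), adjacency recounts for LAC/NC, subset enumeration
for maximal cliques, and enumeration of every draw for the hypergeometric
tail (universes up to 15). Oracle agreement is checked exhaustively over
all 64 labelled four-node graphs and over random graphs of five to eight
nodes under fixed seeds — sizes chosen so the whole suite stays
interactive while the exhaustive part still covers every structural case a
four-node graph can present (disconnection, isolated vertices, trees,
triangles, the complete graph). Stochastic guarantees use 50 graph
replicates (clique recovery) and 200 enrichment replicates (power and
null behavior). igraph provides an additional independent cross-check for
betweenness, closeness and eigenvector centrality on connected graphs.

# Known limitations

* No alias/ID mapping: inputs must already use consistent gene symbols.
* The OB/DL screen is a hard threshold box, not a pharmacokinetic model.
* MCC's factorial weighting is dominated by the largest clique; in graphs
  with one huge clique the ranking carries little information beyond
  membership.
* BH q-values assume exchangeable tests; heavily overlapping annotation
  terms violate independence, as they do in every ORA tool.
* The synthetic PPI generator plants exactly one clique; overlapping
  planted structures are not supported.
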