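---
title: "Network pharmacology with netpharm: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network pharmacology with netpharm: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

# The analysis

`netpharm` implements the canonical network-pharmacology chain: build a
high-confidence protein–protein interaction (PPI) network around a disease
gene set, find its topologically central (hub) genes and its dense modules,
intersect the disease genes with a compound's protein targets, and test the
shared genes for annotation-term enrichment. Each stage is an exported
function; `run_pipeline()` chains them; the numbered scripts under
`analysis/` narrate a full simulated study.

# Network model and cleaning

A network is a simple undirected graph with a confidence score per edge.
Scores are interaction-evidence probabilities in [0, 1], as exported by
STRING-style resources. Cleaning is opinionated and happens at parse time:

- **Self-loops are dropped.** Exported interaction tables can carry them;
  every downstream definition here (density, cores, MCODE weights) assumes
  loop-free graphs, so we standardize once.
- **Duplicate edges collapse to the maximum confidence.** With a strict
  `> t` filter downstream this is the conservative choice: an interaction
  survives if any of its records would.
- **Filtering is strictly greater-than** (`confidence > 0.7` by default),
  and nodes left without edges are removed unless `keep_isolated = TRUE`
  (the view behavior of Cytoscape).

`network_summary()` reports both whole-graph statistics and the largest
connected component, because "the network" in GUI-driven studies can mean
either; with both reported, downstream claims are testable under either
reading.

# Centralities

Three per-node statistics drive hub selection, with the conventions of
Cytoscape's NetworkAnalyzer:

- **Degree** is the raw neighbor count, not divided by $n-1$: published hub
  tables show integers (a hub in a ~900-node disease network typically has
  degree 100–170), so the raw convention is kept.
- **Closeness** of $v$ is $(m-1)/\sum_u d(v,u)$ over the $m$ nodes of $v$'s
  connected component — the reciprocal mean geodesic distance, computed per
  component rather than harmonically; isolated nodes score 0. In a ~900-node
  disease network this lands around 0.4–0.5 for central proteins.
- **Betweenness** is shortest-path betweenness (Brandes' algorithm via
  igraph), endpoints excluded, normalized by $2/((m-1)(m-2))$ with $m$ the
  component size. Whether a GUI run normalized per component or per whole
  graph is not always knowable; per-component is the default and
  `scope = "graph"` is available. On connected graphs the two coincide.

Rows are emitted in sorted node order so floating-point accumulation, and
hence every downstream ranking, is bit-reproducible.

# Two-stage hub selection

*Hub candidates* are the nodes ranking in the top fraction (default 20%) on
**all three** centralities; *hub genes* are the intersection of the
per-centrality top-$k$ lists (default $k = 20$). The intersection reading of
"20% filtering on three centralities" is deliberate: requiring all three
filters reduces ~900 nodes to a few dozen candidates, which matches how
such candidate counts are reported in practice (a union would retain
hundreds). A `combine = "union"` flag provides the permissive variant.

Ranking ties break deterministically (higher value, then lexicographic id),
and fractional cutoffs use the ceiling so small networks never produce empty
lists. The default takes *exactly* $\lceil fn \rceil$ (or $k$) nodes;
`include_ties = TRUE` expands the cut to all tied values when an
all-ties-in semantics is wanted.

# MCODE

The molecular-complex-detection algorithm is implemented from scratch in
three stages.

**Vertex weighting.** For each node $v$, take the subgraph induced by $v$
and its neighbors ($N[v]$), find its highest $k$-core, and set
$w(v) = k_{\max} \cdot \mathrm{density}$ of that core (loop-free density
$2E/(n(n-1))$). Nodes with degree below `degree_cutoff` (default 4) get
weight 0 — they cannot seed or be scored into complexes, which suppresses
sparse periphery.

**Complex prediction.** Seeds are taken in order of decreasing weight
(ties by id). From a seed of weight $w_s$, the complex grows breadth-first,
admitting any neighbor whose weight is at least $w_s(1 - c)$ where $c$ is
the `node_score_cutoff` (default 0.2), to at most `max_depth` (default 100)
steps from the seed. A node joins at most one complex, so complexes are
vertex-disjoint; a node rejected by one complex's threshold remains
available to later seeds.

**Post-processing.** Complexes lacking a 2-core (parameter `k_core`) are
discarded. `haircut` iteratively shaves members with fewer than two
intra-complex neighbors; it defaults to off, the literal reading of the
reference configuration, and both behaviors are tested. `fluff` is not
implemented (the reference analyses run without it); the flag errors rather
than silently doing nothing.

**Scoring.** A complex with $n$ nodes and $E$ induced edges scores
$\frac{2E}{n(n-1)} \cdot n = \frac{2E}{n-1}$ — density × size. A clique of
size $n$ scores exactly $n$. Worked values: (79 nodes, 881 edges) → 22.59;
(44, 404) → 18.79; (59, 287) → 9.90 at two decimals. Display conventions
differ across tools — some truncate rather than round the last digit — so
the test suite checks these reference scores to within one unit in the last
printed place; reported percentages and scores in this package always round
half-up.

**What MCODE finds.** On near-clique modules over a sparse background
(background degree below `degree_cutoff`), recovery is exact: all members of
a planted clique share the same weight (the clique core dominates every
member's neighborhood), so the growth threshold admits exactly the clique.
On modules of moderate density (~0.2–0.4) the neighborhood cores are
heterogeneous and MCODE reports the dense *cores* of modules rather than the
whole planted blocks — visible in `analysis/04_mcode.R`, and the reason the
planted-recovery guarantees in the test suite are stated for cliques.

# Identifier sets, Venn partitions, coverage

Gene identity is the raw symbol until `normalize_ids()` substitutes
canonical accessions from a user-supplied two-column table (emulating
symbol→UniProt conversion; no live mapping service is called). Unmapped ids
are kept verbatim by default — conservative for cardinalities — and
reported; `strict = TRUE` drops them. Conflicting duplicate keys error.

`venn_regions()` partitions the union of two or three sets into disjoint
membership regions keyed by bitmask signatures ("110" = in sets 1 and 2
only); counts therefore always sum to the union size, a tested invariant.
`coverage(shared, reference)` is $100 \cdot |shared \cap reference| /
|reference|$, rounded **half-up** to two decimals (so 96/1155 = 8.3116…
prints 8.31 and 0.125 prints 0.13). `cluster_coverage()` applies the same
statistic per MCODE complex.

# Enrichment

`hypergeometric_enrich()` is a one-sided over-representation test: with
background size $N$, term size $K$, query size $n$ and overlap $k$,
$p = P[X \ge k]$, $X \sim \mathrm{Hypergeom}(N, K, n)$. Depletion is out of
scope. The query is restricted to the background (drops reported);
terms under `min_overlap` (default 3, a common GUI default) are omitted
*before* adjustment, mirroring how interactive tools report. The default
adjustment is Holm — Bonferroni step-down, the family-wise default of
ClueGO-style tools — with Bonferroni and Benjamini–Hochberg available. The
associated-genes statistic is $100\,k/K$, the share of the *term* captured
by the query (the natural reading; a percentage of the query would not be
comparable across terms of different sizes).

Because the test statistic is discrete, null p-values are super-uniform
rather than exactly uniform. The calibration test draws 1000 null queries in
a regime where the p-value lattice is fine (background 10,000, term 5,000,
query 1,000; maximum point mass ≈ 0.027 against a KS critical deviation of
≈ 0.052 at $\alpha = 0.01$), where a Kolmogorov–Smirnov uniformity check is
a valid approximation. In coarse regimes (small terms), p-values remain
valid but conservative.

# The synthetic-data generators

The generators exist so every stage can be tested against known ground
truth without any database access. Defaults emulate one regime throughout:
a disease interactome of **906 nodes and 9,647 edges** containing three
dense modules (79, 44 and 59 nodes with 881, 404 and 287 intra-module
edges), a **1,155-gene disease list**, a **318-gene target list sharing
exactly 96 genes** with it, and annotation terms over the node universe.

- **Background**: preferential attachment (scale-free degree tail, like
  real PPI networks), optionally degree-capped (`max_degree`) — the capped
  setting produces the sparse, low-degree backgrounds used for exact
  planted-clique recovery tests. Random edges are added or removed (never
  module edges) to hit the target count exactly when feasible; top-up is
  retry-bounded, so an extreme target can fall short but stays within 2%.
- **Planted modules** are Erdős–Rényi blocks on disjoint node sets with an
  *exact* edge count per block. Collision policy: background edges inside a
  module or directly bridging two modules are rejected, deterministically —
  planted densities stay exact and two same-density modules cannot be
  merged by a single chance bridge.
- **Edge confidences** default to Uniform(0.7, 1) for background and module
  edges alike: the generated file emulates a STRING export *after* the
  high-confidence cutoff, so the pipeline's own `> 0.7` filter is the
  identity on defaults and planted structure is never destroyed by it.
  Full-range or Beta distributions are available where filtering itself is
  under test.
- **Gene lists**: the disease list samples network nodes with probability
  proportional to degree (literature-mined disease genes over-represent
  hubs — a tested sanity property) and is padded with off-network
  identifiers up to the requested size, since real disease lists exceed the
  network that can be built from them. The target list contains an exactly
  planted overlap with the disease list; the remainder prefers non-disease
  network nodes, then off-network identifiers.
- **Annotations**: uniform term samples from the node universe; a query set
  is drawn with weight `oversample_factor` on the members of designated
  terms, making those terms planted positives.

Determinism: every generator seeds its own RNG stream derived from the
config seed, so outputs are identical across runs and independent of call
order; the pipeline determinism test asserts byte-identical artifacts.

**What the generators do not emulate** — and therefore what passing tests
do not show about real data: STRING's evidence-channel score composition
(confidences here are i.i.d., not correlated with topology), degree
correlations beyond preferential attachment, overlapping or hierarchical
modules, annotation correlation structure (real GO terms nest and overlap),
and identifier pathologies beyond simple aliasing. Results on real exports
depend on database versions and are expected to differ in identity, not in
mechanics.

# Numerical and design choices

- **Rounding**: percentages and reported 2-d.p. scores round half-up
  (`round_half_up()`), not banker's; an epsilon guards binary-representation
  shortfalls.
- **Tie-breaking**: everywhere deterministic — (value desc, id asc) in
  rankings, (score desc, size desc, seed id asc) for complexes, sorted node
  order in iteration.
- **Degenerate inputs**: density of graphs with < 2 nodes is 0 by
  convention; closeness of isolates is 0; betweenness normalization of
  components smaller than 3 is 0; `score_cluster` errors on edge counts
  above the simple-graph maximum; empty queries, empty references and empty
  GMT files error rather than returning vacuous results.
- **Test problem sizes** were chosen to exercise each oracle meaningfully at
  interactive run times: brute-force betweenness on 50 graphs of 8–40
  nodes, exhaustive hypergeometric enumeration in universes up to 30,
  planted-clique recovery over 20 replicates, and the full 906-node
  pipeline run twice for the determinism check.
- **Power-designed recovery benchmark**: the planted-enrichment recovery
  test (5× oversampling recovered as the top hit in ≥ 95% of replicates)
  runs at a regime chosen by an analytic power calculation — 30 terms of
  30–60 genes, query 200 of 906, giving ≈ 1% expected misses — because at
  small term sizes or small queries a 5× weighting is genuinely
  underpowered and the test would measure sampling noise, not the method.

# Known limitations

- MCODE here is the standard single-membership variant: no fluff, no
  overlapping complexes; results on moderate-density modules are cores, not
  blocks (see above).
- Closeness uses the per-component convention; harmonic closeness (the
  better-behaved statistic on very fragmented graphs) is not offered.
- Enrichment reimplements the over-representation test only — no term
  grouping, no kappa-score networks, no annotation downloads.
- Identifier normalization is table-driven; it cannot resolve aliases the
  table does not contain, and isoform-level accession handling is the
  caller's policy choice.
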