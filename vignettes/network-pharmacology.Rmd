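---
title: "Network pharmacology with netpharm: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network pharmacology with netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

Multi-compound remedies — herbal preparations above all — act through many
constituents hitting many protein targets at once. Network pharmacology
studies such remedies by assembling three graphs and reading mechanisms off
their topology:

1. a **compound–target network**: a bipartite graph connecting each chemical
   constituent to its predicted protein targets;
2. a **disease PPI network**: the confidence-filtered protein–protein
   interaction (PPI) neighbourhood anchored at curated disease-associated
   "seed" genes;
3. a **merged network** joining the compounds, the *intersection targets*
   (compound targets that also appear in the disease network), and the
   proteins interacting with those intersection targets.

Hub proteins of the merged network are read as candidate therapeutic
targets, and their functional context is characterised by gene-set
overrepresentation analysis (ORA).

`netpharm` implements this pipeline as tested, composable functions, along
with seeded generators that produce inputs with the statistical and
structural shape such a study assumes — so every stage can be exercised and
validated without access to the proprietary databases (pharmacophore target
predictors, curated gene–disease scores, PPI confidence exports, annotation
services) that real studies query.

## Input filters

The loaders apply the conventional pre-filters of this study design, all as
**strict** inequalities (boundary values are excluded, and tests pin each
boundary):

* `load_compound_targets(path, top_k = 30)` — keeps each compound's
  `top_k` best-ranked predicted targets. Ranks must be unique per compound;
  duplicate (compound, target) pairs collapse to the best rank. The top-k
  filter is applied per compound by rank, before any cross-compound
  deduplication of target names.
* `load_disease_genes(path, min_score = 0.1)` — keeps genes with a
  gene–disease association score strictly above `min_score`.
* `load_ppi(path, min_combined_score = 0.7)` — keeps PPI edges with a
  combined confidence score strictly above the high-confidence boundary
  (`ppi_confidence_bands()` records the conventional low < 0.4,
  medium 0.4–0.7, high > 0.7 bands). Self-loops are dropped with a logged
  count; unordered duplicates collapse to the maximum score.

Gene identity is a plain uppercase symbol string: matching is
case-insensitive at ingestion and case-normalised everywhere after. No
identifier-mapping service is consulted; inputs mixing namespaces must be
harmonised upstream.

## Network constructions

`build_compound_target_network()` is the bipartite graph of distinct
(compound, target) pairs.

`build_disease_ppi_network(seeds, ppi, shell = 1)` takes the **induced
subgraph** of the filtered PPI on the seeds plus every protein within
`shell` hops of a seed. "Directly or indirectly interacting" is an
under-specified phrase in this field; we realise it as the first-shell
neighbourhood *with all induced edges retained*, so indirect interaction
between two seeds is visible through shared neighbours inside the
subgraph. That is the default workflow of the common PPI web exports and
viewers, and it reproduces the seed + first-shell composition such studies
report. A second shell is available via `shell = 2`; enlarging the shell
can only add nodes and edges (tested as a monotonicity property).

`build_merged_network(records, intersection, ppi, shell = 1)` includes only
compounds adjacent to at least one intersection target, the intersection
targets, and the PPI shell around them, again with induced PPI edges. When
a symbol qualifies for more than one role the precedence is
`intersection_target > disease_seed > compound_target > other_protein`;
each node carries exactly one role, and every build cross-checks that the
role counts sum to the node count.

All node and edge orderings are lexicographic, so identical inputs export
byte-identically (SIF, GraphML with a `role` attribute, or node-attribute
TSV; interaction labels are `ct` for compound–target edges and `pp` for
protein–protein edges).

## Topological indices and major nodes

For each node the package computes:

* **degree** — the number of incident edges;
* **betweenness** — the fraction of pairwise shortest paths passing
  through the node, computed by breadth-first search with dependency
  accumulation (Brandes' algorithm) and normalised by `(n−1)(n−2)/2`;
* **closeness** — the inverse of the summed shortest-path distances,
  normalised as `(|R|/Σd) · (|R|/(n−1))` with `R` the reachable set: the
  within-component closeness scaled by relative component size.

The verbal definition of closeness in this literature is the raw inverse
distance sum, but the magnitudes such studies print (thresholds like 0.32
or 0.61) are only attainable on the normalised scale used by the standard
viewers; `netpharm` therefore defaults to `normalized = TRUE` for both
betweenness and closeness and keeps the raw variants behind the flag.
Betweenness pairs in different components contribute zero; graphs with
fewer than 3 nodes have normalised betweenness 0 by convention; isolated
nodes have closeness 0. Shortest paths are unweighted throughout — the
confidence score gates an edge's existence but is not a length.

`select_major_nodes()` applies the mean-threshold rule: a node is a
**major node (hub)** when its degree, betweenness, and closeness are all at
or above the corresponding network means (inclusive `≥`). Means are always
computed over *all* nodes; the `scope` argument restricts which roles are
eligible for selection (the pipeline selects among protein roles, since
compounds are not candidate gene targets), without changing the means. Mean-degree
thresholds reported from interactive viewer sessions do not always equal
`2|E|/|V|` for the stated node and edge counts (sessions may count
multi-edges or a different node universe); `netpharm` computes means from
the constructed network only, so the identity `mean_degree = 2|E|/|V|`
holds exactly by construction.

The betweenness implementation is validated against a brute-force oracle
that counts shortest paths through adjacency-matrix powers, exhaustively
over every labelled graph on 3–5 nodes and on 200 random graphs of 6–8
nodes, to 1e−9, plus an independent library cross-check.

## Overrepresentation analysis

`run_enrichment(query, db, fdr_cutoff = 0.01)` tests the query gene set
against every term of an `annotation_db` (GMT-style file: term id, a
`name|category` description, then member genes). For a term of size `K` in
a background of size `N`, with `n` retained query genes and overlap `k`,
the p-value is the one-sided upper tail `P(X ≥ k)`,
`X ~ Hypergeometric(N, K, n)` — overrepresentation only. The FDR column is
the Benjamini–Hochberg step-up adjustment over **all** tested terms, not
only the reported ones; "FDR" is unnamed in much of this literature and BH
is the standard, fully specified reading. The **rich factor** `k/K` is the
reported effect size, and `categorize_enrichment()` tallies enriched terms
per category. The EASE variant (tail evaluated at `k−1`) is available via
`ease = TRUE` and off by default.

The background defaults to the union of all term member sets; an explicit
background file may override it (it must cover all members). Query genes
outside the background are dropped with a warning, and `n` reflects the
retained set. Because the hypergeometric null is discrete, the fraction of
null terms with `p < α` is *at most* α and typically below it; the test
suite checks the empirical null rejection rate against the exact discrete
expectation computed from the null distribution itself, rather than
against the nominal level.

## The synthetic-data generators

`pharm_sim_config()` fixes the study conditions. The defaults are the
composition a typical study of this design reports: 43 compounds × top-30
targets over a pool of 266 distinct targets (so the bipartite network has
309 nodes), 14 disease seed genes with 96 first-shell interactors (a
110-node disease network), and an annotation universe of 100 terms over
1500 background genes with 5 planted enriched terms at 80% query overlap.
Category labels follow the 19 : 10 : 6 : 4 proportions of the four
top-level pathway categories (human diseases, organismal systems,
environmental information processing, cellular processes). All randomness
flows from the single `rng_seed`; generators restore the caller's RNG
state.

* `gen_compound_target_table()` guarantees pool coverage by dealing each
  target once, then fills the remaining rank slots with a rich-get-richer
  bias so some targets are hit by many compounds, the qualitative
  structure real pharmacophore predictions show.
* `gen_ppi()` anchors every first-shell protein to a seed with a score
  above 0.7, joins the seeds by a backbone path (so seeds plus first shell
  form one connected analysis network), adds extra edges at
  `ppi_extra_density` (default 0.055, chosen once to put the filtered
  edge count in the ~430 range implied by the study shape), and plants
  low-confidence decoy edges — some touching external proteins — that the
  filter must remove. With `ppi_extra_density = 0` the filtered network is
  a tree of seed-rooted stars on the backbone.
* `gen_annotation_db()` plants terms containing a fixed fraction of the
  query and samples null terms from the background independently of it,
  returning the ground truth for recovery tests.
* `gen_merged_fixture()` is a dedicated preset wiring 17 intersection
  targets (5 of them seed genes that double as planted hubs), 14
  qualifying compounds, and 53 first-shell "other proteins" such that the
  merged network has exactly 84 nodes and 306 edges — hence a mean degree
  of 2·306/84 ≈ 7.29 — while the full inputs still reproduce the 309- and
  110-node networks upstream. It is a convenience preset about the study
  *shape*, not a claim about any real remedy's network. Its planted hubs
  receive a disproportionate share of compound and PPI edges; recovering
  them through the mean-threshold rule is a test, not an assumption.

What the generators deliberately do **not** emulate: real PPI
confidence-score distributions, real term-size distributions beyond coarse
shape, correlated target prediction errors, or literature-biased
gene–disease scores. Passing tests on these fixtures demonstrates that the
pipeline's arithmetic, filters, graph constructions, and statistics are
correct under the stated structural assumptions — not that any biological
conclusion drawn from real inputs is valid.

## Numerical and degenerate-input conventions

* Filters are strict (`>`), selection thresholds inclusive (`≥`), exactly
  as the conventional phrasing has them.
* Duplicate policy: best (lowest) rank for compound–target pairs, maximum
  score for PPI edges and disease genes; collapsed counts are logged.
* Empty compound-target input or an empty intersection is an error, not a
  silent empty network; an empty disease-gene result or an empty
  intersection *set* from `intersect_targets()` is a warning.
* Seeds absent from the PPI stay in the disease network as isolated
  disease-seed nodes (warned), so the seed count is never silently wrong.
* `P(X ≥ 0) = 1` exactly; BH values are capped at 1 and order-preserving;
  ties in hub ordering break lexicographically by node id.

## The pipeline and reproducibility

`run_pipeline(out_dir, seed)` chains the whole analysis on a simulated
study and writes networks, the centrality table (with the three mean
thresholds echoed as header comments), the major-node list, the enrichment
and category tables, a merge report, and a `manifest.txt` echoing the
configuration, per-stage counts, thresholds, and MD5 digests of every
artifact. Two runs with the same seed produce byte-identical artifacts;
the manifest differs only in its timestamp line (it records when the run
happened), so determinism is checked on all other artifacts plus the
digest table *inside* the manifest. A thin command-line front end
(`inst/cli/netpharm.R`) exposes the stages as subcommands with the same
defaults (top-k 30, score cutoffs 0.1 and 0.7, shell 1, FDR 0.01) and exit
codes 0 / 1 / 2 for success / validation error / usage error.

Problem sizes used by the test suite — exhaustive centrality checking up
to 5 nodes with 200 random 6–8-node graphs, full-support hypergeometric
verification up to a background of 60, a 1000-replicate null simulation,
and 100-seed recovery runs — were chosen as the smallest sizes at which
each property is convincingly exercised.

## Known limitations

* No identifier mapping: symbol collisions or synonyms in real inputs are
  the user's responsibility.
* Shortest-path computations are exact and in plain R; they are sized for
  the few-hundred-node networks of this study design, not for
  proteome-scale graphs.
* ORA treats genes as exchangeable; no gene-length, expression, or
  topology-aware bias correction is attempted.
* The generators guarantee structural shape, not biological realism; see
  above.
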