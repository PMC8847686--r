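---
title: "Centrality-based target screening on PPI networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centrality-based target screening on PPI networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiscreen)
```

## The procedure

Network-pharmacology target screening asks which proteins mediate the
action of a compound on a disease. Given a protein–protein interaction
(PPI) network, a list of predicted compound targets and a list of known
disease targets, the screen proceeds in five steps:

1. **Seeded subnetwork construction.** Each seed list is expanded by
   exactly one hop: the subnetwork contains the mappable seeds, all of
   their direct interactors, and every interactome edge between members of
   that node set (the induced subgraph).
2. **Intersection.** The two subnetworks are intersected on *both* nodes
   and edges (Cytoscape Merge-intersection semantics). Nodes left isolated
   by the edge intersection are retained, because they contribute to the
   degree median that the next step depends on.
3. **Hit-hub filter.** Nodes whose degree strictly exceeds **twice the
   median degree** of the intersection network (isolates included) are
   kept, and the induced subgraph on them forms the hit-hub network.
4. **Core-target filter.** All five topology metrics are recomputed on the
   hit-hub network; a node is a core target if it strictly exceeds the
   **median of every metric simultaneously**.
5. **Enrichment and C-T-P-D assembly.** The core targets are tested for
   term over-representation (hypergeometric upper tail, Benjamini–Hochberg
   FDR, significance at q < 0.05), and the tetrapartite
   compound–target–pathway–disease network links the compound to the
   targets, targets to the significant terms containing them, and every
   significant term to the disease.

## The five metrics

All metrics follow the raw (unnormalized) conventions of the CytoNCA
Cytoscape plug-in, on simple undirected graphs:

* **degree** — number of distinct neighbors;
* **betweenness** — Brandes' unnormalized betweenness, each unordered pair
  counted once; pairs in different components contribute nothing;
* **closeness** — computed within connected components:
  $C(v) = (c-1)/\sum_u d(v,u)$ for a component of size $c \ge 2$, so values
  lie in $(0, 1]$; this is the variant consistent with published screening
  thresholds of the form 0.54 on large networks;
* **neighborhood connectivity (NC)** — mean degree of a node's neighbors;
* **local average connectivity (LAC)** — mean degree of a node's neighbors
  *within the subgraph induced by those neighbors*, equivalently
  $2\,e(N(v))/|N(v)|$.

Isolated nodes score 0 on every metric, so stage medians are always well
defined. Degree/betweenness/closeness are delegated to igraph (whose
normalized closeness is exactly the component-wise definition above; this
was verified numerically); NC and LAC are implemented directly, as no
installed package provides the LAC definition. The test suite checks all
five against brute-force reimplementations (betweenness by literal
enumeration of every shortest path) on dozens of random graphs.

## Numerical and procedural choices

* **Strict inequalities everywhere.** The filters use `>`, matching the
  "more than two times of the median" / "greater than" phrasing standard
  in this literature. A vertex-transitive graph (all metrics tied)
  therefore screens to an empty set — a warning, not an error, so that
  parameter sweeps do not abort.
* **Medians are stage-input quantities.** Stage 2's cuts default to
  medians over the hit-hub network itself (`median_scope = "stage"`),
  which is the reading most consistent with descriptions of the procedure;
  published reports are ambiguous about whether the medians came from the
  hit-hub or the intersection network, so `median_scope = "intersection"`
  is available as a switch. A consequence of per-stage medians is that
  re-running a filter on its own output is *not* idempotent; a regression
  test documents this on a star graph.
* **Median convention.** `stats::median`: the middle order statistic for
  odd counts, the mean of the two middle order statistics for even counts.
* **Deterministic ordering.** Graphs are canonicalized to lexicographic
  vertex order before any metric computation, so floating-point
  accumulation order — and therefore every output file — is reproducible
  bit for bit.
* **Enrichment testing set.** Terms with zero query overlap are excluded
  *before* BH correction (the behavior of common ORA tools); an option
  includes them. When term descriptions carry a `namespace|` prefix (e.g.
  the three GO sub-ontologies), correction is applied within each
  namespace independently. The hypergeometric tail uses `stats::phyper`
  (log-space internally); the test oracle is exact binomial-product
  enumeration, feasible without rational arithmetic because every term
  $\binom{K}{i}\binom{N-K}{n-i} \le \binom{N}{n} \le \binom{40}{20} < 2^{53}$
  on the tested grid.
* **C-T-P-D sizing.** "Node size proportional to degree" fixes only
  proportionality, so the exported `size_score` is degree divided by the
  maximum degree; single compound and disease nodes, since the workflow
  studies one compound and one disorder.
* **Bench formulas.** The sucrose-preference complement identity
  (preference + bottle-swapped preference = 100) holds exactly in real
  arithmetic but only to ~1e-14 in floating point; tests assert it at
  1e-12. `2^-ddCt` is parameterized by arbitrary reference-gene Ct values
  and takes no position on which reference gene is correct.

## The synthetic world

Real interactome snapshots behind published screens are unversioned and
undeposited, so validation runs against a generator whose defaults state
one fixed benchmark world:

* a **500-protein** interactome grown by Barabási–Albert preferential
  attachment with **3 edges per node** — the simplest generator with the
  hub-dominated, right-skewed degree distribution that median-threshold
  hub screening presupposes;
* a **30-node planted core** densified with random within-core edges until
  its induced density reaches **0.8** — the "true" answer the screen
  should find;
* drug and disease seed sets of **40 targets** each, **80%** drawn from
  the core-adjacent pool (core plus direct neighbors), emulating target
  lists that genuinely converge on a shared module;
* **200 annotation terms** with sizes uniform on **10–40** (typical
  curated-pathway sizes relative to a 500-node universe; chosen once, not
  tuned), of which **5** draw **90%** of their members from the core.

All randomness flows from one integer seed. R has no passable generator
object, so each generator uses `withr::with_seed` with a fixed small
offset per sub-generator (interactome +0, seed sets +1, annotation +2);
global RNG state is never touched, and identical configurations produce
bit-identical artifacts.

The generator does **not** model edge confidence scores, direction,
tissue specificity, identifier-vocabulary noise, or literature bias in
term databases. A green end-to-end test therefore establishes that the
*procedure* behaves as specified on data satisfying its own assumptions —
not that any particular biological screen was correct.

## What the screen recovers — and a structural caveat

On the benchmark world the stage-1 filter is essentially perfect: over
twenty seeded replicates the hit-hub network contains the entire planted
core (recall 1.0) at precision ~0.7 (`analysis/04_recovery_benchmark.R`
reproduces the table). The stage-2 five-metric filter then trades nearly
all of that recall for purity: survivors are almost always true core
nodes (precision ~1.0), but mean recall drops to ~0.16.

This is not an implementation artifact but a property of the rule. The
stage-2 medians are computed on the hit-hub network itself; when the
hit-hub population is dominated by the planted module — which strong
convergent seed sets guarantee — the median of each metric falls *inside*
the module, and a strict above-median cut on any single metric can keep at
most half of the nodes, before the other four simultaneous cuts remove
more. Requiring joint strict exceedance of five medians of a homogeneous
population is intrinsically a "top slice" operation, not a module
detector: it presupposes a heterogeneous hit-hub network in which the
module is a minority. Interpreting the final core list as a ranking of
the most central module members (high precision, deliberately low recall)
matches both this analysis and the way such lists are used downstream —
as a shortlist for experimental validation. The interesting related
observation, visible in the deterministic test cases, is that a *lone*
hub can never survive stage 2: neighborhood connectivity structurally
favors nodes attached to hubs over the hub itself, so only mutually
high-degree groups — dense modules — pass all five cuts together.

## Limitations

* One-hop seed expansion is fixed by design; deeper expansions would
  require confidence-weighted pruning to stay tractable, which is out of
  scope along with edge weights and directionality.
* The enrichment module performs generic over-representation analysis
  over any GMT term set: no GO DAG propagation, no term–term clustering.
* Group-level significance testing for the bench tables (ANOVA, post-hoc
  comparisons) is deliberately left to base R's standard routines.
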