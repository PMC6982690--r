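---
title: "Network-pharmacology screening of an herb pair: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-pharmacology screening of an herb pair: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnetscreen)
```

## The screening problem

Traditional Chinese medicine formulas act through many compounds hitting many
protein targets at once, so single-compound, single-target assays cannot
explain why a formula works. Network pharmacology replaces them with a
screening funnel over database-derived tables. `herbnetscreen` implements
that funnel for a two-herb formula (the worked example is the rougui-fuzi
pair, *Cinnamomum cassia* twig plus *Aconitum carmichaelii* root, studied
against cardiocerebral vascular disease):

1. **Inventory.** Per-herb compound tables are merged and deduplicated on the
   stable compound identifier; display names are not trusted as keys because
   the same molecule is often named differently across herbs.
2. **Target attachment.** A compound-target interaction table is joined onto
   the inventory. Upstream target prediction is treated as given data: the
   databases that produce it publish no reproducible model, so the artifact's
   contract starts at the interaction table. Raw protein names are corrected
   to official uppercase gene symbols through a lookup table.
3. **Disease mapping.** Targets are intersected with the *union* of several
   disease gene sets. Targets in the intersection are *potential targets*;
   compounds hitting at least one of them are *active compounds*. Per-disease
   membership is retained because the tripartite network needs it.
4. **Enrichment.** The potential-target list is tested for over-representation
   against pathway and GO-style annotation sets.
5. **Networks and screening.** Three undirected simple graphs are built —
   compound-target-disease (C-T-D), target-pathway (T-P), and a
   score-thresholded protein-protein interaction (PPI) graph — and nodes are
   screened by centrality rules.

## Statistics

**Over-representation.** For a query of $n$ genes drawn from a background of
$N$, against a set with $K$ annotated genes of which $k$ are hit, the p-value
is the exact hypergeometric upper tail

$$P[X \ge k] \;=\; \sum_{i=k}^{\min(K,n)}
  \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

accumulated in log space (log-binomial coefficients combined with
log-sum-exp) so that large backgrounds neither overflow nor lose small tails
to cancellation. P-values are adjusted with the Benjamini-Hochberg step-up
and filtered at a strict `p < alpha` (default `alpha = 0.05` on the adjusted
value; a flag restores raw-p filtering, since screening studies often report
unadjusted "P < 0.05"). `alpha = 1` disables the filter so every
size-eligible set is returned. One numerical caveat worth stating: the BH
step-up is *not* a fixed point under re-application — adjusting
`(0.2, 0.8)` gives `(0.4, 0.8)`, and re-adjusting that gives `(0.8, 0.8)` —
so adjusted values must never be fed back through the adjustment. The test
suite checks the step-up against a hand-computed running-minimum oracle and
its rank-monotonicity instead.

**Background choice.** The study behind the worked example never states its
enrichment universe. The package defaults to the union of all collection
members (the convention of the common ORA tools), extended with the query in
the pipeline so the query-within-background precondition always holds; both
are overridable, because an unstated background is the single largest source
of irreproducibility in ORA.

**Centralities.** All shortest paths are unweighted. For a node $v$ in a
connected component of size $N_c$:

* degree centrality `DC` is the raw incident-edge count;
* betweenness `BC` is $\sum_{s \ne t \ne v} \sigma_{st}(v)/\sigma_{st}$ over
  unordered pairs within the component, normalized by
  $(N_c-1)(N_c-2)/2$ (zero when $N_c < 3$);
* closeness `CC` is the number of reachable nodes divided by the summed
  distance to them (zero for isolates).

Screening studies usually *define* these verbally as raw counts yet report
values in $[0,1]$; the per-component normalizations above are what common
network viewers apply to disconnected graphs and reproduce the reported
magnitudes. `normalized = FALSE` exposes the raw quantities.
Cross-component pairs contribute nothing by construction.

**Screening rules.** All threshold comparisons are strict, reading "higher
than the average" literally: a network whose compounds all tie yields no key
compound, and a regular PPI graph yields no hub. Key compounds must exceed
the compound-role means on all three centralities; hub genes must exceed the
mean degree over *all* PPI nodes; key pathways default to the same
triple-above-average rule over pathway nodes. Result ordering is
deterministic: DC descending, then BC descending, then node id.

The key-pathway screen also accepts an explicit id list. This is deliberate:
in the worked example the literature-informed trio includes arachidonic acid
metabolism, whose degree (5) is *below* the pathway mean (5.1429), so no
centrality rule can reproduce that selection — it exists only as curator
judgment, and the package models it as configuration rather than guessing a
rule. Similarly, the worked-example key-compound table is internally
inconsistent with its own stated averages: two of its 21 rows (closeness
0.3040 against a mean of 0.3464; betweenness 0.0067 against 0.0068) fail the
stated rule, which the desk-check reports as 19 of 21 passing. The package
implements the stated rule and leaves the discrepancy visible rather than
special-casing it.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | strict significance cut for ORA |
| `filter_on` | `"p_adj"` | which p-value `alpha` applies to |
| `min_size`, `max_size` | 3, 500 | eligible background-restricted set sizes (conventional ORA guards against trivially small or uselessly broad sets) |
| `limits` | BP 30, CC 30, MF 25 | per-category caps on reported terms |
| `ppi_threshold` | 0.4 | strict lower bound on the PPI combined score (the STRING medium-confidence convention, dimensionless on [0,1]) |
| `screening_role` | `"compound"` | role over which key-compound averages are taken |
| `key_pathway_rule` | `"centrality"` | or `"explicit"` with an id list |

Duplicate scored edges keep the maximum score (conservative and
deterministic); both STRING score dialects are accepted, with the 0-999
integer scale auto-detected whenever any score exceeds 1 and divided by
1000. Unordered edge pairs are canonicalized lexicographically. Floating
point is rounded only in display layers, never in stored intermediates.

## The synthetic-data generator

All real inputs of such a screen are live database queries, so the package
ships a seeded emulator of their *structure*: overlapping herb inventories
(defaults 65 + 100 compounds with 2 shared), a many-to-many compound-target
map with truncated-geometric per-compound degree (mean 2.5, cap 12, matching
the skewed degree profile screening tables show) over a 500-symbol universe
with rank-skewed target popularity, five disease sets of ~120 genes that
contain a configurable fraction of the compound-hit targets, twenty pathway
sets of 12 genes of which a quarter are enriched for the disease-mapped
targets, and a uniform-scored Erdős–Rényi PPI graph (density 0.15 by
default; uniform scores exercise the 0.4 threshold non-trivially).

One root seed feeds independent named sub-streams, one per table, so adding
a generator stage never perturbs earlier draws and identical configurations
are byte-identical on disk. Ground truth (the planted active compounds,
potential targets, and hub proteins) is recorded by direct set arithmetic at
generation time and re-verified against the emitted tables before the bundle
is returned; an exact-planting mode guarantees stated active/target counts
(used for the 84-active/42-target/5-disease worked-example geometry), and a
planted-hub mode inflates selected nodes' edge probability by a degree
multiplier for recovery studies.

What the generator does *not* emulate: real compound chemistry, correlated
target panels shared by chemically similar compounds, literature-biased
disease annotations, or the heavy clustering of real PPI neighborhoods.
Passing tests therefore demonstrate that the pipeline's set arithmetic,
statistics, and graph rules are correct under controlled structure — not
that any biological conclusion from real databases is right.

## Problem sizes and numerical tolerances

The test suite checks betweenness and closeness against an exhaustive
BFS-and-path-counting oracle to 1e-9 on 200 random graphs of up to 30 nodes,
the hypergeometric tail against full draw enumeration for every instance
with $N \le 12$ (and against the distribution function at larger sizes) to
1e-12, and planted-hub recovery over 20 seeds per multiplier on a sparse
(density 0.05) background, where sensitivity saturates at 1.0 from
multiplier 5 and is monotone from 1 upward. These sizes were chosen so the
whole suite exercises every rule deeply while remaining enumeration-exact
where an exact oracle exists.

## Known limitations

* Annotations are flat gene sets; no GO DAG propagation or pathway topology.
* Symbol correction is a lookup table, not a live identifier service;
  unmapped names pass through uppercased with a warning.
* The upstream compound screening (oral bioavailability, drug-likeness) and
  target prediction are upstream of the contract; compound tables are taken
  as already screened.
* Molecular docking and chromatographic verification stages of a full
  screening study are out of scope.
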