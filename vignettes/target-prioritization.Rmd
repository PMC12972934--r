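---
title: "Methods: network-pharmacology target prioritization with netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-pharmacology target prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

# Scope and model

`netpharm` implements a drug-target prioritization chain for network
pharmacology: target-list intersection, PPI node-topology profiling with
maximal clique centrality (MCC) hub ranking, hypergeometric
over-representation analysis (ORA) with Benjamini–Hochberg (BH) control,
a tree-ensemble priority score on a 0–15 scale, and rank fusion of the
evidence channels. Database retrieval (target prediction services, STRING
queries, GO/KEGG annotation), docking engines and molecular-dynamics
post-processing are out of scope: lists, edge lists, GMT collections and
docking tables are consumed as files, and seeded generators produce
synthetic stand-ins with planted ground truth for all of them.

# Target lists

Symbols are trimmed, uppercased and deduplicated; empty and `#`-comment
lines are skipped. No alias or identifier mapping is attempted — the
normalization is deterministic and reversible, and gene-symbol alias
tables would import a database dependency the rest of the chain avoids.
Disease lists from several sources are unioned before intersection
(`union_targets`); intersecting against each source separately is
available by simply calling `intersect_targets` per source.

# PPI topology

`read_edge_list` accepts the STRING export dialect (`node1`, `node2`,
`combined_score`) with scores on either the 0–999 integer or [0,1]
fractional convention, auto-detected from the maximum observed score and
overridable. The default confidence threshold is 0.4 ("medium"), the
STRING default. Self-loops and reciprocal duplicate rows are dropped.

Conventions for `compute_topology` follow the Cytoscape NetworkAnalyzer
toolchain, so profiles are comparable with what that ecosystem reports:

* closeness, average shortest path length and radiality are computed
  within each node's connected component, with
  radiality(v) = Σ_w (diam_comp + 1 − d(v,w)) / (n_comp − 1);
  isolated nodes get 0 for all three;
* betweenness is normalized by (n−1)(n−2)/2 over the whole graph;
* stress counts shortest paths through an interior node, each unordered
  endpoint pair counted once, and is left unnormalized — the downstream
  feature scaling is min-max, so only relative spread matters;
* the local clustering coefficient is 0 for degree < 2.

MCC(v) sums (|C|−1)! over the maximal cliques C containing v (the
cytoHubba definition; the singleton clique of an isolated node contributes
(1−1)! = 1, so MCC ≥ 1 everywhere). Maximal cliques are enumerated with
igraph; a configurable clique-count budget (default 10^6) aborts on
pathologically dense graphs instead of hanging. The test suite
cross-checks every metric against an independent brute-force oracle
(Floyd–Warshall distances, DP geodesic counts, a plain Bron–Kerbosch
enumerator) on random graphs. Hub ranking sorts by MCC, ties broken by raw
degree then symbol, and keeps the top k (default 10).

# Enrichment

The ORA p-value is the exact hypergeometric upper tail, computed in log
space from binomial coefficients; k = 0 returns exactly 1. BH adjustment
is the step-up rule q_(i) = min_{j≥i}(p_(j)·m/j) capped at 1. Both are
implemented in the package (and cross-checked against `phyper` and
`p.adjust` in tests) because this statistical stage is part of the
re-implemented chain rather than delegated to an annotation framework.
The default universe is every symbol annotated in the collection — the
common convention when no assay background is stated — and is echoed
loudly, because universe choice is the single most consequential ORA
knob. BH is applied within a collection (one namespace), mirroring
per-namespace top-10 reporting; q < 0.05 is the default significance cut.

# Machine-learning prioritization

The feature matrix fixes eight columns in a recorded order (degree
centrality, betweenness, closeness, average shortest path length, raw
degree, stress, radiality, clustering coefficient). MCC is deliberately
excluded: it defines the PPI-hub evidence channel and must remain
independent of the ML channel that is later fused with it.

Choices where the procedure was genuinely open:

* **Labels.** The composite score defaults to the mean of the three
  scaled scatter-plot centralities (degree, betweenness, closeness); its
  70th percentile (linear interpolation between order statistics,
  `quantile` type 7) is the threshold, and positives strictly exceed it.
  A `label_basis` argument accepts any feature subset, including a single
  feature.
* **Circularity.** Labels derive from a subset of the classifier
  features. That is inherent to this design (the published protocol
  derives labels from the same topology table) and is documented rather
  than hidden; `holdout_label_features = TRUE` removes the label-defining
  columns from the classifiers for a non-circular mode.
* **Split.** 7:3 stratified, test size ⌈0.3n⌉ with largest-remainder
  allocation across classes — 126 targets split 88/38 — seeded and
  deterministic.
* **Tuning.** Grid search by mean 5-fold CV F1, then refit on the full
  training set. Default grids are small (≤ 3 values per knob) so the
  search runs in seconds; the random-forest grid includes mtry equal to
  the full feature count (pure bagging), which matters because the label
  boundary is generally a function of several features at once.
* **Audit.** Test accuracy/F1, 10-fold CV F1 mean ± sd on the full
  labeled set, train − test gaps for both metrics, and per-model feature
  importances normalized to sum to 1.
* **Scores.** A random-forest regressor and a gradient-boosted regressor
  are fit to the composite score (the quantity whose percentile defined
  the labels — the natural regression target, recorded as a choice since
  alternatives exist), predictions averaged, then mapped by
  15·(raw − min)/(max − min). A constant raw vector degenerates to all
  zeros with a warning. The whole stage is bit-reproducible for a fixed
  seed.

# Evidence integration

Docking tables (target, binding energy in kcal/mol) are summarized
(min/max/mean, count at or below a bound) and ranked by ascending energy
with competition ("1224") ranking, so tied energies share the better
rank. Fusion is Borda rank-sum by default — the simplest order-based
rule, making no scale assumptions across kcal/mol, clique counts and 0–15
scores — with `mean-rank` as an order-equivalent alternative. Targets
missing from a channel carry that channel's worst-rank penalty (n+1) and
are flagged. Whether the original analyses fused channels numerically at
all is unknowable from narrative alone; the fusion here makes the
qualitative "ranks first/second across channels" reasoning reproducible
without claiming to be the original procedure.

# Assay calculators

The wound-healing rate, 2^−ΔΔCt fold change, MDA content and CAT activity
are literal evaluations of their kit formulas; all are pure functions.
The CAT formula's printed "/0.1 mL/60 s" is treated as unit bookkeeping
folded into the 235.65 constant (the kit constant already carries the
volume/time units); `literal_divisors = TRUE` applies the divisors
numerically instead, since the printed composite is genuinely ambiguous —
both readings are computable, neither asserted as the kit's truth.
Standard curves are linear (least squares) by default with a
four-parameter logistic option (Levenberg–Marquardt via minpack.lm),
both inverted in closed form; calibration responses must be monotone in
concentration, and interpolation outside the calibrated response range is
flagged as extrapolation rather than refused.

# Synthetic data: what it emulates and what it does not

The generators are pure functions of (parameters, seed): re-runs are
byte-identical, and every planted truth is recorded in a JSON manifest
and audited against the written files.

* `gen_target_lists` plants an exact drug/disease overlap (defaults
  181/300 with 126 shared in a 500-symbol universe, the scale of the
  original screen) plus optional duplicate/case noise.
* `gen_ppi_network` draws a preferential-attachment background (each new
  node attaches to `attach_m` existing nodes, degree-proportional) and
  embeds each planted hub — chosen among the highest-degree background
  nodes — in its own clique of fresh recruits that have no background
  edges. Recruits then score exactly (clique size − 1)! under MCC while
  the hub adds its neighborhood on top, which makes hub recovery a sharp
  property. Edge scores are uniform on [0.4, 1.0] so default thresholding
  never severs planted structure; `subthreshold_fraction` adds droppable
  edges for threshold tests.
* `gen_gene_sets` samples decoy terms uniformly and enriched terms with
  query members weighted `odds`-fold (default 8).
* `gen_docking_results` draws one energy per target uniformly in a
  negative window and records the true order.
* `gen_assay_sheets` draws Gaussian replicates around group means.

Synthetic symbols ("G000001"…) avoid implying real gene identities. The
generators do not emulate real STRING score distributions, GO term-size
distributions, annotation redundancy (term nesting), or the heavy-tailed
degree mixing of curated interactomes; passing tests demonstrate that the
algorithms are correct and that planted signal of stated strength is
recovered, not that any particular biological claim holds on real
database exports.

# Validation scale and conditions

The test suite validates at desk scale: oracle equivalence on 100 random
graphs (n ≤ 10 for the BFS metrics at tolerance 1e−9; n ≤ 12 for MCC,
exact), planted-hub recovery on 50 networks of 100 nodes (background
attachment 2, three planted 6-cliques, top-5 criterion), ORA against the
exhaustive pmf sum on an N ≤ 40 grid (tolerance 1e−12) and planted-term
detection over 100 collections (universe 500, query 126, odds 8, 50
decoys). The circular-label ML check runs on 126-node networks with
attachment degree 5 — the node count matching the original feature table
and a mean degree (~10) typical of a medium-confidence STRING export for
a disease target set — with a single-feature label basis
(`degree_centrality`): the point of a circular construction is that the
label rule is a function of the classifier's own inputs, and a
single-feature (axis-aligned) rule is the case where that construction
genuinely bounds the achievable error of axis-aligned tree ensembles.
With the default three-feature composite the boundary is oblique and
trees carry an irreducible few-sample boundary error that reflects the
model class, not a pipeline defect; the three-feature composite remains
the analysis default.

# Limitations

* Symbol normalization is lexical; no ortholog/alias resolution.
* ORA ignores annotation dependence between terms (no DAG propagation);
  BH assumes the usual positive-dependence conditions.
* MCC enumeration is exponential in the worst case; the clique budget
  makes failure explicit rather than preventing it.
* The ML stage's labels are percentile-derived from topology, so its
  scores should be read as a topology-consensus ranking, not an
  independent evidence channel in the strict sense; the fusion stage
  treats it as one channel among three regardless.
* Docking energies are ingested, never computed; their accuracy is the
  upstream engine's affair.
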