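# netpharm

Network-pharmacology target prioritization in R: from drug- and
disease-target gene lists to a fused, multi-evidence ranking of candidate
therapeutic targets.

## The problem

Network pharmacology asks which proteins mediate a compound's effect on a
disease. The standard computational chain starts from two gene lists — the
compound's predicted targets and the disease's associated genes — and
prioritizes their intersection using network and statistical evidence:

1. **Target intersection.** Deduplicate and intersect the lists; the shared
   symbols are the candidate targets.
2. **PPI topology.** Build a protein–protein interaction network over the
   shared targets (STRING-style edge list, confidence-thresholded) and
   profile every node: degree centrality, betweenness, closeness, average
   shortest path length, raw degree, stress, radiality, clustering
   coefficient, and **maximal clique centrality**

   MCC(v) = Σ_{C ∋ v} (|C| − 1)!

   summed over all maximal cliques C containing v (the cytoHubba hub
   statistic). The top-10 MCC nodes are the hub targets.
3. **Enrichment.** Hypergeometric over-representation of the shared set
   against a gene-set collection (GMT), with the upper-tail probability

   p = Σ_{i=k}^{min(K,n)} C(K,i) C(N−K, n−i) / C(N,n)

   and Benjamini–Hochberg adjustment across terms.
4. **Machine-learning prioritization.** The 8 topology features are
   min-max scaled; binary labels are set by the 70th percentile of a
   composite centrality score; random-forest and XGBoost classifiers are
   tuned by grid search with 5-fold cross-validation and audited for
   overfitting (10-fold CV stability, train−test gaps); two regressors on
   the composite are averaged and linearly mapped to a 0–15 priority
   score.
5. **Evidence integration.** Binding-energy tables from molecular docking
   are summarized and rank-fused (Borda rank-sum) with the MCC ranking and
   the ML score ranking into one final ordering.

Every input the chain consumes can be generated synthetically with planted
ground truth (target overlap, clique hubs, enriched terms, energy order),
so the whole pipeline is testable offline. Calculators for the wet-lab
follow-up formulas (wound-healing rate, 2^−ΔΔCt fold change, MDA/CAT kit
formulas, standard-curve interpolation) are included.

## Worked example

The `analysis/` scripts run the chain end to end on simulated inputs
(seeded, reproducible): `Rscript analysis/01_simulate_inputs.R` through
`analysis/06_integrate_evidence.R`. Step 2 prints

```
<target_list> drug: 181 unique symbols (196 raw entries)
<target_list> disease: 300 unique symbols (315 raw entries)
<intersection_result> drug (181) x disease (300): 126 shared targets
```

— 181 deduplicated drug targets, of which 126 are shared with the disease
list and carried forward. Step 5 reports the classifier audit and the 0–15
priority scores:

```
<model_report> train n = 88 , test n = 38
  rf   acc 1.000 / F1 1.000 (test); CV10 F1 0.960 +/- 0.064; gaps 0.000/0.000
  xgb  acc 1.000 / F1 1.000 (test); CV10 F1 0.940 +/- 0.080; gaps 0.000/0.000
```

and step 6 summarizes the recorded ten-hub docking table and fuses the
three evidence channels:

```
Recorded docking table: min -6.7, max -4.3, mean -5.58 kcal/mol; 10/10 at or below -4.3
   target mcc_rank docking_rank ml_rank n_missing aggregate_score final_rank
1 G000014        1            3       1         0               5          1
```

The final line names the target that ranks best across MCC, docking energy
and ML score — here the strongest planted hub, with a Borda score of 5
(channel ranks 1 + 3 + 1).

Equivalent single-call interface: `run_pipeline(default_config(seed = 1))`.

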