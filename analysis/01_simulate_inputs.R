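#!/usr/bin/env Rscript
# Step 1 — simulate the database-derived inputs.
# The study's inputs are database exports (target-prediction hits, disease
# genes, a STRING edge list, GO/KEGG annotation, docking scores). Here we
# generate their synthetic stand-ins with planted ground truth: a drug list
# of 181 targets and a disease list sharing exactly 126 of them, mirroring
# the scale of the original screen.

library(netpharm)
seed <- 1L
dir.create("results/inputs", showWarnings = FALSE, recursive = TRUE)

man <- gen_target_lists(seed = seed, dir = "results/inputs",
                        n_universe = 500, n_drug = 181, n_disease = 300,
                        overlap = 126, dup_noise = 15)
cat("Wrote drug list (", man$n_drug, " targets + noise) and disease list (",
    man$n_disease, " targets); planted overlap: ", man$overlap, "\n", sep = "")
cat("Manifest:", man$manifest_path, "\n")
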