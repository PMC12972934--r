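#!/usr/bin/env Rscript
# Step 2 — ingest the target lists and intersect them.
# The shared symbols between the compound's predicted targets and the
# disease's associated genes are the candidate therapeutic targets carried
# into all downstream analyses.

library(netpharm)

drug <- read_target_list("results/inputs/drug_targets.txt", "drug")
disease <- read_target_list("results/inputs/disease_targets.txt", "disease")
print(drug); print(disease)

venn <- intersect_targets(drug, disease)
print(venn)
write_venn_summary(venn, "results/venn_summary.csv")
cat("Venn summary -> results/venn_summary.csv; shared list -> ",
    "results/venn_summary_shared.txt\n", sep = "")
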