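#!/usr/bin/env Rscript
# Step 3 — PPI network over the shared targets: topology profile + MCC hubs.
# A STRING-style edge list is simulated over the 126 shared targets (three
# planted clique hubs stand in for genuinely central proteins), then every
# node's 8-feature topological profile and maximal clique centrality are
# computed and the top-10 MCC hub ranking extracted.

library(netpharm)
seed <- 1L

shared <- readLines("results/venn_summary_shared.txt")
man <- gen_ppi_network(seed = seed + 1L, dir = "results/inputs",
                       n_nodes = length(shared), attach_m = 2,
                       hub_nodes = 3, hub_clique_size = 6,
                       node_names = shared)
cat("Simulated PPI network:", man$n_edges_total, "edges over",
    length(shared), "targets; planted hubs:",
    paste(man$hubs, collapse = ", "), "\n")

g <- read_edge_list("results/inputs/ppi_edges.tsv", score_threshold = 0.4)
topo <- compute_topology(g)
hubs <- top_hubs(g, k = 10)
export_network(g, topo, "results")
utils::write.csv(hubs, "results/hub_ranking.csv", row.names = FALSE)

cat("Top-10 MCC hubs:\n")
print(hubs)
cat("Planted hubs recovered in top-3:",
    all(man$hubs %in% hubs$node[1:3]), "\n")
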