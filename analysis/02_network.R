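#!/usr/bin/env Rscript
# Stage 2: build the analysis network.
#
# Reads the simulated (or user-substituted) edge list, applies the strict
# high-confidence filter (> 0.7) and reports the resulting topology, both
# for the whole filtered graph and for its largest connected component --
# the two readings of "the PPI network" a Cytoscape-style workflow can mean.

suppressPackageStartupMessages(library(netpharm))

net <- read_edge_list("results/data/network.tsv")
filt <- filter_by_confidence(net, 0.7)
write_edge_list(filt, "results/network_filtered.tsv")

s <- network_summary(filt)
cat(sprintf("filtered network: %d nodes, %d edges, density %.4f, %d component(s)\n",
            s$n_nodes, s$n_edges, s$density, s$n_components))
cat(sprintf("largest connected component: %d nodes\n",
            s$largest_component_size))
jsonlite::write_json(s, "results/network_summary.json",
                     auto_unbox = TRUE, pretty = TRUE)
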