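#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
#
# Generates a disease interactome at the reference regime -- 906 proteins,
# 9,647 high-confidence interactions carrying three planted dense modules of
# 79, 44 and 59 nodes -- together with a 1,155-gene disease list, a 318-gene
# compound-target list sharing exactly 96 genes with it, and 30 annotation
# terms (one oversampled 5x into the pipeline's query universe). Everything
# is written in the plain-text formats the downstream stages read.

suppressPackageStartupMessages(library(netpharm))

seed <- 17
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = seed,
                        n_terms = 30, term_size_range = c(30, 60),
                        query_size = 200,
                        enriched_terms = list(list(term_index = 2,
                                                   oversample_factor = 5)))

sim <- generate_network(cfg)
gl <- generate_gene_lists(sim$network, cfg)
ga <- generate_annotations(sim$network, cfg)

write_edge_list(sim$network, file.path(out, "network.tsv"))
write_gene_list(gl$disease, file.path(out, "disease_genes.txt"))
write_gene_list(gl$targets, file.path(out, "compound_targets.txt"))
write_gmt(ga$annotations, file.path(out, "annotations.gmt"))
write_gene_list(ga$query, file.path(out, "enriched_query.txt"))
jsonlite::write_json(
  list(seed = seed,
       modules = sim$truth$modules,
       module_edge_counts = sim$truth$module_edge_counts,
       shared_truth = gl$truth$shared,
       enriched_terms = ga$truth$enriched_terms),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)

s <- network_summary(sim$network)
cat(sprintf("simulated network: %d nodes, %d edges (target 9647), density %.4f\n",
            s$n_nodes, s$n_edges, s$density))
cat(sprintf("planted module edges: %s\n",
            paste(sim$truth$module_edge_counts, collapse = ", ")))
cat(sprintf("gene lists: %d disease, %d targets, %d planted shared\n",
            length(gl$disease$ids), length(gl$targets$ids),
            length(gl$truth$shared)))
cat("inputs written to", out, "\n")
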