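#!/usr/bin/env Rscript
# Stage 5: three-phase intersection of disease genes and compound targets.
#
# Phase 1: all disease genes vs targets (Venn + coverage of the full list).
# Phase 2: hub candidates and hub genes vs targets.
# Phase 3: MCODE complex members vs targets (per-complex coverage).

suppressPackageStartupMessages(library(netpharm))

disease <- read_gene_list("results/data/disease_genes.txt", "disease")
targets <- read_gene_list("results/data/compound_targets.txt", "targets")
hubs <- jsonlite::read_json("results/hubs.json", simplifyVector = TRUE)
mc <- jsonlite::read_json("results/mcode.json", simplifyVector = TRUE)

v <- intersect_gene_sets(disease, targets)
print(v)
cov_all <- coverage(v$shared, disease)
cat("phase 1: "); print(cov_all)

cov_cand <- coverage(targets, hubs$candidates)
cov_hub <- coverage(targets, hubs$hubs)
cat("phase 2 (candidates): "); print(cov_cand)
cat("phase 2 (hubs): "); print(cov_hub)

clusters <- lapply(seq_len(nrow(mc$clusters)), function(i)
  list(members = mc$clusters$members[[i]], seed = mc$clusters$seed[i],
       n_nodes = mc$clusters$n_nodes[i]))
ccov <- cluster_coverage(clusters, targets)
cat("phase 3 (per-complex target coverage):\n")
print(utils::head(ccov, 5), row.names = FALSE)

write_gene_list(v$shared, "results/shared_genes.txt")
jsonlite::write_json(
  list(region_counts = as.list(v$region_counts),
       coverage_all = unclass(cov_all),
       coverage_candidates = unclass(cov_cand),
       coverage_hubs = unclass(cov_hub),
       cluster_coverage = ccov),
  "results/intersection.json", auto_unbox = TRUE, pretty = TRUE)
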