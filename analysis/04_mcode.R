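#!/usr/bin/env Rscript
# Stage 4: MCODE molecular-complex detection.
#
# Runs MCODE at the reference parameter set (degree cut-off 4, node score
# cut-off 0.2, k-core 2, haircut off, max depth 100) on the filtered
# network and reports each complex with its density-times-size score,
# then checks how well the top complexes recover the planted modules.

suppressPackageStartupMessages(library(netpharm))

net <- read_edge_list("results/network_filtered.tsv")
res <- mcode(net, mcode_params())
write_mcode(res, "results/mcode.json")
print(res)

truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
for (mi in seq_along(truth$modules)) {
  best <- which.max(vapply(res, function(cl)
    jaccard(cl$members, truth$modules[[mi]]), numeric(1)))
  cat(sprintf(
    "planted module %d (%d nodes): best-matching complex rank %d, Jaccard %.2f\n",
    mi, length(truth$modules[[mi]]), best,
    jaccard(res[[best]]$members, truth$modules[[mi]])))
}
cat("note: at moderate planted densities MCODE reports the dense cores of\n")
cat("modules rather than whole blocks; perfect recovery is expected only for\n")
cat("near-clique modules on a sparse background.\n")
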