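#' Pipeline configuration
#'
#' Bundles the settings of a full network-pharmacology run. Defaults follow
#' the conventional high-confidence analysis: confidence filter > 0.7, hub
#' candidates from the top-20% per-centrality filter, hub genes from the
#' intersection of per-centrality top-20 lists, MCODE at
#' `mcode_params()` defaults, Holm-adjusted hypergeometric enrichment.
#' Inputs come either from files (`edge_list`, `disease_list`, `target_list`,
#' optional `id_mapping` and `gmt`) or, when `edge_list` is NULL, from the
#' seeded synthetic generators configured by `synthetic`.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed used for every stochastic stage.
#' @param edge_list,disease_list,target_list,id_mapping,gmt input file paths;
#'   all optional when running on synthetic data.
#' @param confidence_threshold strict confidence cut (default 0.7).
#' @param hub_fraction,hub_k,hub_combine hub-selection settings.
#' @param mcode an [mcode_params()] object.
#' @param min_overlap,adjust_method enrichment settings.
#' @param synthetic a [synthetic_config()]; its seed is overridden by `seed`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            edge_list = NULL, disease_list = NULL,
                            target_list = NULL, id_mapping = NULL, gmt = NULL,
                            confidence_threshold = 0.7,
                            hub_fraction = 0.2, hub_k = 20,
                            hub_combine = "intersection",
                            mcode = mcode_params(),
                            min_overlap = 3, adjust_method = "holm",
                            synthetic = synthetic_config()) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L,
            confidence_threshold >= 0, confidence_threshold <= 1,
            inherits(mcode, "mcode_params"),
            inherits(synthetic, "synthetic_config"))
  for (p in c(edge_list, disease_list, target_list, id_mapping, gmt))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  synthetic$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 edge_list = edge_list, disease_list = disease_list,
                 target_list = target_list, id_mapping = id_mapping,
                 gmt = gmt,
                 confidence_threshold = confidence_threshold,
                 hub_fraction = hub_fraction, hub_k = hub_k,
                 hub_combine = hub_combine, mcode = mcode,
                 min_overlap = min_overlap, adjust_method = adjust_method,
                 synthetic = synthetic),
            class = "pipeline_config")
}

#' Run the full network-pharmacology pipeline
#'
#' Chains the analysis stages in their canonical order -- network
#' construction (read or simulate), confidence filtering, centrality,
#' two-stage hub selection, MCODE module detection, disease/target
#' intersection with coverage statistics, and term enrichment of the shared
#' genes -- writing one artifact per stage plus a run manifest into
#' `config$out_dir`. Given the same configuration and seed, every artifact
#' is byte-identical across runs.
#'
#' Artifacts: `network.tsv`, `network_summary.json`, `centrality.tsv`,
#' `hubs.json`, `mcode.json`, `intersection.json`, `shared_genes.txt`,
#' `enrichment.tsv`, `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages (default TRUE).
#' @return invisibly, a list with the in-memory stage results (`network`,
#'   `filtered`, `summary`, `centrality`, `hubs`, `mcode`, `venn`,
#'   `coverage`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  say <- function(...) if (!quiet) message(...)

  # 1. network
  if (!is.null(config$edge_list)) {
    say("reading network from ", config$edge_list)
    net <- read_edge_list(config$edge_list)
    lists <- NULL
  } else {
    say("simulating network (seed ", config$seed, ")")
    sim <- generate_network(config$synthetic)
    net <- sim$network
    lists <- generate_gene_lists(net, config$synthetic)
  }
  write_edge_list(net, out("network.tsv"))

  # 2. confidence filter + summary
  filtered <- filter_by_confidence(net, config$confidence_threshold)
  summ <- network_summary(filtered)
  jsonlite::write_json(summ, out("network_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say(sprintf("filtered network: %d nodes, %d edges", summ$n_nodes,
              summ$n_edges))

  # 3. centrality
  ctab <- centrality_table(filtered)
  write_centrality_table(ctab, out("centrality.tsv"))

  # 4. hub selection
  hubs <- hub_selection(ctab, fraction = config$hub_fraction,
                        k = config$hub_k, combine = config$hub_combine)
  write_hub_selection(hubs, out("hubs.json"))
  say(sprintf("%d hub candidates, %d hub genes", length(hubs$candidates),
              length(hubs$hubs)))

  # 5. MCODE
  mc <- mcode(filtered, config$mcode)
  write_mcode(mc, out("mcode.json"))

  # 6. gene lists, normalization, intersection, coverage
  mapping <- if (!is.null(config$id_mapping)) read_id_mapping(config$id_mapping)
  if (is.null(lists)) {
    if (is.null(config$disease_list) || is.null(config$target_list))
      stop("disease_list and target_list are required with a file-based network")
    disease <- read_gene_list(config$disease_list, "disease")
    targets <- read_gene_list(config$target_list, "targets")
  } else {
    disease <- lists$disease
    targets <- lists$targets
  }
  disease <- normalize_ids(disease, mapping)$set
  targets <- normalize_ids(targets, mapping)$set
  venn <- intersect_gene_sets(disease, targets)
  shared <- venn$shared
  write_gene_list(shared, out("shared_genes.txt"))
  cov_all <- coverage(shared, disease)
  cov_hubs <- if (length(hubs$hubs) > 0L) coverage(targets, hubs$hubs)
  cov_cand <- if (length(hubs$candidates) > 0L)
    coverage(targets, hubs$candidates)
  ccov <- cluster_coverage(mc, targets)
  jsonlite::write_json(
    list(set_sizes = list(disease = length(disease$ids),
                          targets = length(targets$ids)),
         region_counts = as.list(venn$region_counts),
         n_shared = length(shared$ids),
         coverage_all_disease = unclass(cov_all),
         coverage_hub_candidates = if (!is.null(cov_cand)) unclass(cov_cand),
         coverage_hubs = if (!is.null(cov_hubs)) unclass(cov_hubs),
         cluster_coverage = ccov),
    out("intersection.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say(sprintf("shared genes: %d (%.2f%% of disease list)",
              length(shared$ids), cov_all$percent))

  # 7. enrichment of the shared genes
  enr <- NULL
  ann <- NULL
  if (!is.null(config$gmt)) {
    ann <- read_gmt(config$gmt)
  } else if (is.null(config$edge_list)) {
    ann <- generate_annotations(net, config$synthetic)$annotations
  }
  if (!is.null(ann)) {
    in_bg <- intersect(shared$ids, ann$background)
    if (length(in_bg) > 0L) {
      enr <- hypergeometric_enrich(shared, ann,
                                   min_overlap = config$min_overlap,
                                   method = config$adjust_method)
      write_enrichment(enr, out("enrichment.tsv"))
    }
  }

  # 8. manifest
  artifacts <- c("network.tsv", "network_summary.json", "centrality.tsv",
                 "hubs.json", "mcode.json", "shared_genes.txt",
                 "intersection.json",
                 if (!is.null(enr)) "enrichment.tsv")
  hashes <- as.list(tools::md5sum(vapply(artifacts, out, "")))
  names(hashes) <- artifacts
  manifest <- list(
    tool = "netpharm",
    version = as.character(utils::packageVersion("netpharm")),
    seed = config$seed,
    config = list(confidence_threshold = config$confidence_threshold,
                  hub_fraction = config$hub_fraction, hub_k = config$hub_k,
                  hub_combine = config$hub_combine,
                  mcode = unclass(config$mcode),
                  min_overlap = config$min_overlap,
                  adjust_method = config$adjust_method,
                  inputs = list(edge_list = config$edge_list,
                                disease_list = config$disease_list,
                                target_list = config$target_list,
                                id_mapping = config$id_mapping,
                                gmt = config$gmt),
                  synthetic = if (is.null(config$edge_list))
                    unclass(config$synthetic)),
    artifact_md5 = hashes)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(network = net, filtered = filtered, summary = summ,
                 centrality = ctab, hubs = hubs, mcode = mc, venn = venn,
                 coverage = list(all = cov_all, candidates = cov_cand,
                                 hubs = cov_hubs, clusters = ccov),
                 enrichment = enr, manifest = manifest))
}
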