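#' Configuration for the synthetic-data generators
#'
#' The defaults emulate the regime of a literature-mined disease
#' interactome: a ~900-node, ~9,600-edge high-confidence PPI network carrying
#' three dense modules of 79, 44 and 59 nodes (within-module densities chosen
#' to give 881, 404 and 287 intra-module edges), a disease gene list of 1,155
#' identifiers (the network nodes plus off-network literature genes), a
#' compound target list of 318 identifiers sharing exactly 96 genes with the
#' disease list, and 50 annotation terms of 10-60 genes. Edge confidences
#' emulate a STRING export already restricted to high-confidence
#' interactions, so they are drawn above 0.7 by default.
#'
#' @param seed integer RNG seed; every generator derives its own stream from
#'   it, so outputs are reproducible and independent of call order.
#' @param n_nodes,target_edges network size; the generator hits
#'   `target_edges` exactly when feasible (always within 2%).
#' @param planted_modules list of `list(size, density)` blocks realized as
#'   Erdos-Renyi subgraphs with an exact edge count `round(density * C(size, 2))`.
#' @param confidence_dist,module_confidence_dist `list(dist = "uniform", lo, hi)`
#'   or `list(dist = "beta", a, b)` for background / planted-module edge
#'   confidences. Module confidences default to the upper tail (>= 0.7) so a
#'   high-confidence filter does not destroy planted structure.
#' @param max_degree cap on background-attachment degree (Inf = uncapped);
#'   planted-module edges are exempt.
#' @param disease_list_size,target_list_size,overlap_count gene-list regime;
#'   the generated lists share exactly `overlap_count` identifiers.
#' @param n_terms,term_size_range,query_size,enriched_terms annotation
#'   regime; `enriched_terms` is a list of `list(term_index, oversample_factor)`
#'   marking terms whose members are oversampled into the query.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_nodes = 906,
                             target_edges = 9647,
                             planted_modules = list(
                               list(size = 79, density = 881 / 3081),
                               list(size = 44, density = 404 / 946),
                               list(size = 59, density = 287 / 1711)),
                             confidence_dist = list(dist = "uniform",
                                                    lo = 0.7, hi = 1),
                             module_confidence_dist = list(dist = "uniform",
                                                           lo = 0.7, hi = 1),
                             max_degree = Inf,
                             disease_list_size = 1155,
                             target_list_size = 318,
                             overlap_count = 96,
                             n_terms = 50,
                             term_size_range = c(10, 60),
                             query_size = 100,
                             enriched_terms = list()) {
  stopifnot(n_nodes >= 2, target_edges >= 0,
            disease_list_size >= 1, target_list_size >= 1,
            overlap_count >= 0,
            overlap_count <= min(disease_list_size, target_list_size),
            n_terms >= 1, length(term_size_range) == 2L,
            term_size_range[1] >= 1, term_size_range[2] >= term_size_range[1],
            term_size_range[2] <= n_nodes,
            query_size >= 1, query_size <= n_nodes)
  sizes <- vapply(planted_modules, `[[`, numeric(1), "size")
  dens <- vapply(planted_modules, `[[`, numeric(1), "density")
  if (length(sizes) > 0) {
    if (any(sizes < 2) || any(sizes > n_nodes) || sum(sizes) > n_nodes)
      stop("infeasible planted-module sizes for ", n_nodes, " nodes")
    if (any(dens <= 0) || any(dens > 1))
      stop("planted-module density must lie in (0, 1]")
  }
  module_edges <- sum(round(dens * sizes * (sizes - 1) / 2))
  if (target_edges < module_edges)
    stop("target_edges smaller than the planted-module edge total (",
         module_edges, ")")
  if (target_edges > n_nodes * (n_nodes - 1) / 2)
    stop("target_edges exceeds the simple-graph maximum")
  structure(list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
                 target_edges = as.integer(target_edges),
                 planted_modules = planted_modules,
                 confidence_dist = confidence_dist,
                 module_confidence_dist = module_confidence_dist,
                 max_degree = max_degree,
                 disease_list_size = as.integer(disease_list_size),
                 target_list_size = as.integer(target_list_size),
                 overlap_count = as.integer(overlap_count),
                 n_terms = as.integer(n_terms),
                 term_size_range = as.integer(term_size_range),
                 query_size = as.integer(query_size),
                 enriched_terms = enriched_terms),
            class = "synthetic_config")
}

sample_confidence <- function(dist, n) {
  switch(dist$dist,
         uniform = stats::runif(n, dist$lo, dist$hi),
         beta = stats::rbeta(n, dist$a, dist$b),
         stop("unknown confidence distribution: ", dist$dist))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Generate a synthetic PPI network with planted modules
#'
#' Builds a preferential-attachment (scale-free) background, optionally
#' degree-capped, plants Erdos-Renyi modules of the configured sizes and
#' densities on disjoint node blocks, and tops up or trims background edges
#' to hit the target edge count. Collision policy (deterministic): background
#' edges falling inside a planted module or directly bridging two planted
#' modules are discarded and replaced during top-up, so planted densities
#' are exact and modules stay separable; top-up retries are bounded, so the
#' realized count can fall short of an extreme target but stays within 2%.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `network` (a `ppi_network`) and `truth` (planted module
#'   memberships and edge bookkeeping).
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(derive_seed(cfg$seed, 0L))
  n <- cfg$n_nodes
  nodes <- sprintf("G%04d", seq_len(n))

  # disjoint module blocks on a random node subset
  sizes <- vapply(cfg$planted_modules, `[[`, numeric(1), "size")
  perm <- sample.int(n)
  module_of <- integer(n) # 0 = background
  modules <- list()
  off <- 0L
  for (mi in seq_along(sizes)) {
    idx <- perm[(off + 1L):(off + sizes[mi])]
    module_of[idx] <- mi
    modules[[mi]] <- sort(nodes[idx])
    off <- off + sizes[mi]
  }

  # planted module edges: exact count per module
  ea <- character(0); eb <- character(0); is_module <- logical(0)
  for (mi in seq_along(sizes)) {
    s <- sizes[mi]
    d <- cfg$planted_modules[[mi]]$density
    m_e <- round(d * s * (s - 1) / 2)
    pairs <- utils::combn(modules[[mi]], 2L)
    pick <- sample.int(ncol(pairs), m_e)
    ea <- c(ea, pairs[1L, pick]); eb <- c(eb, pairs[2L, pick])
    is_module <- c(is_module, rep(TRUE, m_e))
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (k in pair_key(ea, eb)) assign(k, TRUE, envir = seen)
  deg <- table(factor(c(ea, eb), levels = nodes))
  deg <- stats::setNames(as.integer(deg), nodes)

  blocked_pair <- function(i, j) {
    mi <- module_of[i]; mj <- module_of[j]
    (mi != 0L && mi == mj) || (mi != 0L && mj != 0L && mi != mj)
  }

  # preferential-attachment background over all n nodes (in index order);
  # module-internal and module-bridging attachments are skipped
  n_bg_target <- cfg$target_edges - length(ea)
  m_pa <- max(1L, floor(n_bg_target / n))
  bdeg <- stats::setNames(integer(n), nodes) # background-only degree, for the cap
  for (v in 2:n) {
    prev <- seq_len(v - 1L)
    elig <- prev[bdeg[prev] < cfg$max_degree & !vapply(prev, blocked_pair,
                                                       logical(1), j = v)]
    if (length(elig) == 0L) next
    m_v <- min(m_pa, length(elig))
    w <- deg[elig] + 1
    targets <- if (length(elig) == 1L) elig else
      sample(elig, m_v, prob = w)
    for (u in targets) {
      k <- pair_key(nodes[u], nodes[v])
      if (!is.null(seen[[k]])) next
      assign(k, TRUE, envir = seen)
      ea <- c(ea, nodes[u]); eb <- c(eb, nodes[v]); is_module <- c(is_module, FALSE)
      deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
      bdeg[u] <- bdeg[u] + 1L; bdeg[v] <- bdeg[v] + 1L
    }
  }

  # top-up / trim to the exact target
  need <- cfg$target_edges - length(ea)
  if (need > 0L) {
    tries <- 0L; budget <- 50L * need
    while (need > 0L && tries < budget) {
      tries <- tries + 1L
      ij <- sample.int(n, 2L)
      i <- min(ij); j <- max(ij)
      if (blocked_pair(i, j)) next
      if (bdeg[i] >= cfg$max_degree || bdeg[j] >= cfg$max_degree) next
      k <- pair_key(nodes[i], nodes[j])
      if (!is.null(seen[[k]])) next
      assign(k, TRUE, envir = seen)
      ea <- c(ea, nodes[i]); eb <- c(eb, nodes[j]); is_module <- c(is_module, FALSE)
      bdeg[i] <- bdeg[i] + 1L; bdeg[j] <- bdeg[j] + 1L
      need <- need - 1L
    }
  } else if (need < 0L) {
    drop <- sample(which(!is_module), -need)
    keep <- setdiff(seq_along(ea), drop)
    ea <- ea[keep]; eb <- eb[keep]; is_module <- is_module[keep]
  }

  conf <- numeric(length(ea))
  conf[is_module] <- sample_confidence(cfg$module_confidence_dist,
                                       sum(is_module))
  conf[!is_module] <- sample_confidence(cfg$confidence_dist, sum(!is_module))

  net <- ppi_network(data.frame(a = ea, b = eb, confidence = conf,
                                stringsAsFactors = FALSE),
                     nodes = nodes,
                     metadata = list(source = "synthetic",
                                     seed = cfg$seed,
                                     target_edges = cfg$target_edges))
  truth <- list(modules = modules,
                module_edge_counts = vapply(seq_along(sizes), function(mi)
                  sum(is_module & (module_of[match(ea, nodes)] == mi)),
                  integer(1)),
                n_edges = length(ea),
                n_background_edges = sum(!is_module))
  list(network = net, truth = truth)
}

#' Generate disease and compound-target gene lists
#'
#' The disease list is a degree-biased sample of network nodes (emulating
#' literature-mined disease genes, which over-represent hubs), padded with
#' off-network identifiers when the requested size exceeds the network. The
#' target list shares exactly `overlap_count` identifiers with the disease
#' list; its remainder is drawn from non-disease network nodes first, then
#' from fresh off-network identifiers.
#'
#' @param net a `ppi_network` (typically from [generate_network()]).
#' @param cfg a [synthetic_config()].
#' @return list with `disease` and `targets` (`gene_set`s) and `truth`
#'   (the intended shared set).
#' @export
generate_gene_lists <- function(net, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  nodes <- network_nodes(net)
  deg <- degree_centrality(net)[nodes]
  n_in <- min(cfg$disease_list_size, length(nodes))
  disease <- sample(nodes, n_in, prob = deg + 1)
  extra <- cfg$disease_list_size - n_in
  if (extra > 0L) disease <- c(disease, sprintf("DZX%04d", seq_len(extra)))

  shared <- if (cfg$overlap_count > 0L)
    sample(disease, cfg$overlap_count) else character(0)
  rest <- cfg$target_list_size - cfg$overlap_count
  pool <- setdiff(nodes, disease)
  take <- min(rest, length(pool))
  targets <- c(shared,
               if (take > 0L) sample(pool, take) else character(0),
               if (rest > take) sprintf("TGX%04d", seq_len(rest - take)))
  list(disease = gene_set(disease, "disease"),
       targets = gene_set(targets, "targets"),
       truth = list(shared = sort(shared)))
}

#' Generate an annotation collection with optional planted enrichment
#'
#' Terms are uniform samples from the network node universe. The query set is
#' sampled without replacement with weight 1 per node, raised to
#' `oversample_factor` for members of each term listed in
#' `cfg$enriched_terms` -- those terms are the planted positives for
#' enrichment-recovery experiments.
#'
#' @param net a `ppi_network`.
#' @param cfg a [synthetic_config()].
#' @return list with `annotations` (an `annotation_collection` whose
#'   background is the node universe), `query` (a `gene_set`), and `truth`
#'   (planted term ids).
#' @export
generate_annotations <- function(net, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(derive_seed(cfg$seed, 2L))
  universe <- network_nodes(net)
  sizes <- sample(seq(cfg$term_size_range[1], cfg$term_size_range[2]),
                  cfg$n_terms, replace = TRUE)
  ids <- sprintf("T%03d", seq_len(cfg$n_terms))
  terms <- stats::setNames(lapply(seq_len(cfg$n_terms), function(i)
    list(name = sprintf("synthetic term %d", i),
         members = sort(sample(universe, sizes[i])))), ids)
  ann <- annotation_collection(terms, background = universe)

  w <- stats::setNames(rep(1, length(universe)), universe)
  planted <- character(0)
  for (et in cfg$enriched_terms) {
    id <- ids[et$term_index]
    planted <- c(planted, id)
    m <- terms[[id]]$members
    w[m] <- pmax(w[m], et$oversample_factor)
  }
  query <- sample(universe, cfg$query_size, prob = w)
  list(annotations = ann,
       query = gene_set(query, "query"),
       truth = list(enriched_terms = planted))
}
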