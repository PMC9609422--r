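#' MCODE parameter set
#'
#' Defaults follow the common Cytoscape-plugin configuration for PPI module
#' detection: degree cut-off 4, node score cut-off 0.2, k-core 2, haircut and
#' fluff off, maximum growth depth 100.
#'
#' @param degree_cutoff integer >= 1; nodes with fewer neighbors get weight 0
#'   and can neither seed nor score.
#' @param node_score_cutoff real in \[0, 1); a neighbor joins a growing
#'   complex when its weight is at least `seed_weight * (1 - node_score_cutoff)`.
#' @param k_core integer >= 2; complexes lacking a k-core of this order are
#'   discarded.
#' @param haircut iteratively remove complex members with fewer than two
#'   intra-complex neighbors (default FALSE).
#' @param fluff add dense neighborhoods around complexes (not implemented;
#'   must be FALSE).
#' @param fluff_density_cutoff retained for interface completeness; unused
#'   while `fluff` is off.
#' @param max_depth integer >= 1; growth explores nodes at most this many
#'   steps from the seed (seed depth 0).
#' @return object of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 4, node_score_cutoff = 0.2,
                         k_core = 2, haircut = FALSE, fluff = FALSE,
                         fluff_density_cutoff = 0.1, max_depth = 100) {
  stopifnot(degree_cutoff >= 1, node_score_cutoff >= 0, node_score_cutoff < 1,
            k_core >= 2, is.logical(haircut), is.logical(fluff),
            max_depth >= 1)
  if (fluff) stop("fluff post-processing is not implemented")
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core),
                 haircut = haircut, fluff = fluff,
                 fluff_density_cutoff = fluff_density_cutoff,
                 max_depth = as.integer(max_depth)),
            class = "mcode_params")
}

#' k-core of a network
#'
#' The maximal subgraph in which every node has degree at least `k` within
#' the subgraph (equivalently, the nodes of core number >= k).
#'
#' @param net a `ppi_network`.
#' @param k integer >= 0.
#' @return the induced `ppi_network` (possibly empty).
#' @export
k_core_subgraph <- function(net, k) {
  stopifnot(k >= 0)
  g <- as_igraph(net)
  keep <- which(igraph::coreness(g) >= k)
  new_ppi_network(igraph::induced_subgraph(g, keep), net$metadata)
}

#' MCODE vertex weighting
#'
#' Weights each node by the density of the densest region of its closed
#' neighborhood: `weight(v) = k_max * density(H)` where `N[v]` is the
#' subgraph induced by `v` and its neighbors, `k_max` is the highest core
#' number present in `N[v]`, and `H` is that highest k-core (loop-free
#' density). Nodes with degree below `degree_cutoff` are given weight 0 so
#' sparse periphery cannot seed complexes.
#'
#' @param net a `ppi_network`.
#' @param degree_cutoff minimum degree for a nonzero weight (default 4).
#' @return named numeric vector over all nodes, names sorted.
#' @export
mcode_vertex_weights <- function(net, degree_cutoff = 4) {
  g <- as_igraph(net)
  nm <- igraph::V(g)$name
  deg <- igraph::degree(g)
  w <- stats::setNames(numeric(length(nm)), nm)
  for (vi in seq_along(nm)) {
    if (deg[vi] < degree_cutoff) next
    nbhd <- c(vi, as.integer(igraph::neighbors(g, vi)))
    sub <- igraph::induced_subgraph(g, nbhd)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0L) next
    hk <- igraph::induced_subgraph(sub, which(core >= kmax))
    w[nm[vi]] <- kmax * simple_density(igraph::vcount(hk), igraph::ecount(hk))
  }
  w[order(names(w), method = "radix")]
}

# grow one complex outward from seed_v (vertex index), breadth-first,
# including unassigned neighbors whose weight reaches the seed-derived
# threshold, up to max_depth steps from the seed
grow_complex <- function(g, w_by_index, seed_v, threshold, max_depth, assigned) {
  members <- seed_v
  visited <- logical(length(w_by_index))
  visited[seed_v] <- TRUE
  frontier <- seed_v
  depth <- 0L
  while (length(frontier) > 0L && depth < max_depth) {
    nxt <- integer()
    for (v in frontier) {
      for (u in as.integer(igraph::neighbors(g, v))) {
        if (visited[u] || assigned[u]) next
        visited[u] <- TRUE
        if (w_by_index[u] >= threshold) {
          members <- c(members, u)
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
    depth <- depth + 1L
  }
  members
}

# haircut: repeatedly shave members with < 2 intra-complex neighbors
haircut_members <- function(g, members) {
  repeat {
    if (length(members) == 0L) return(members)
    sub <- igraph::induced_subgraph(g, members)
    d <- igraph::degree(sub)
    if (all(d >= 2)) return(members)
    members <- members[d >= 2]
  }
}

#' Run the MCODE molecular-complex-detection algorithm
#'
#' Three stages: (1) vertex weighting by the density of the highest k-core of
#' each node's closed neighborhood ([mcode_vertex_weights()]); (2) complex
#' prediction -- starting from the highest-weighted unassigned seed, a
#' complex grows breadth-first over neighbors whose weight is at least
#' `seed_weight * (1 - node_score_cutoff)`, bounded by `max_depth`; nodes
#' belong to at most one complex, so complexes are vertex-disjoint; (3)
#' post-processing -- complexes without a `k_core` are discarded and, when
#' `haircut` is on, singly-connected members are iteratively shaved.
#'
#' Complexes are scored with [score_cluster()] (density times node count) and
#' returned sorted by descending score, ties by descending size then seed id.
#' Equal-weight seeds are taken in lexicographic id order so output is fully
#' deterministic.
#'
#' @param net a `ppi_network`.
#' @param params an [mcode_params()] object.
#' @param weights optional precomputed [mcode_vertex_weights()] vector
#'   (must cover all nodes); computed from `net` when NULL.
#' @return object of class `mcode_result`: list of `mcode_cluster` records
#'   (`members`, `n_nodes`, `n_edges`, `seed`, `score`), with the parameter
#'   set and weights attached as attributes.
#' @export
mcode <- function(net, params = mcode_params(), weights = NULL) {
  stopifnot(inherits(net, "ppi_network"), inherits(params, "mcode_params"))
  g <- as_igraph(net)
  nm <- igraph::V(g)$name
  if (is.null(weights)) {
    weights <- mcode_vertex_weights(net, params$degree_cutoff)
  } else if (!all(nm %in% names(weights))) {
    stop("weights must cover every node of the network")
  }
  w_by_index <- as.numeric(weights[nm])

  # seed order: weight descending, id ascending; weight-0 nodes cannot seed
  seed_order <- order(-w_by_index, nm, method = "radix")
  seed_order <- seed_order[w_by_index[seed_order] > 0]
  assigned <- logical(length(nm))

  clusters <- list()
  for (s in seed_order) {
    if (assigned[s]) next
    threshold <- w_by_index[s] * (1 - params$node_score_cutoff)
    members <- grow_complex(g, w_by_index, s, threshold, params$max_depth,
                            assigned)
    assigned[members] <- TRUE
    # k-core filter: the complex must contain a k_core
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < params$k_core) next
    if (params$haircut) {
      members <- haircut_members(g, members)
      if (length(members) == 0L) next
      sub <- igraph::induced_subgraph(g, members)
    }
    nn <- igraph::vcount(sub)
    ne <- igraph::ecount(sub)
    clusters[[length(clusters) + 1L]] <- structure(
      list(members = sort(nm[members]), n_nodes = nn, n_edges = ne,
           seed = nm[s], score = score_cluster(nn, ne)),
      class = "mcode_cluster")
  }
  ord <- order(-vapply(clusters, `[[`, numeric(1), "score"),
               -vapply(clusters, `[[`, numeric(1), "n_nodes"),
               vapply(clusters, `[[`, character(1), "seed"),
               method = "radix")
  structure(clusters[ord], class = "mcode_result",
            params = params, weights = weights)
}

#' MCODE cluster score
#'
#' `score = density * n_nodes` with loop-free undirected density
#' `2 E / (n (n - 1))`; equivalently `2 E / (n - 1)`. A complex of fewer than
#' two nodes scores 0, and a clique of size `n` scores exactly `n`.
#'
#' @param n_nodes number of cluster nodes.
#' @param n_edges number of edges of the induced subgraph.
#' @return the score, a non-negative real.
#' @export
score_cluster <- function(n_nodes, n_edges) {
  stopifnot(n_nodes >= 0, n_edges >= 0)
  if (n_edges > n_nodes * (n_nodes - 1) / 2)
    stop("edge count exceeds the simple-graph maximum for ", n_nodes, " nodes")
  if (n_nodes < 2L) return(0)
  simple_density(n_nodes, n_edges) * n_nodes
}

#' @export
print.mcode_result <- function(x, ...) {
  cat(sprintf("MCODE: %d complex(es)\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  %d. score %.2f, %d nodes, %d edges, seed %s\n",
                i, x[[i]]$score, x[[i]]$n_nodes, x[[i]]$n_edges, x[[i]]$seed))
  invisible(x)
}

#' Write MCODE results as JSON
#'
#' Ordered cluster records (`rank`, `seed`, `score`, `n_nodes`, `n_edges`,
#' `members`) with the parameter set echoed in a header block.
#'
#' @param x an `mcode_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mcode <- function(x, path) {
  recs <- lapply(seq_along(x), function(i)
    list(rank = i, seed = x[[i]]$seed, score = x[[i]]$score,
         n_nodes = x[[i]]$n_nodes, n_edges = x[[i]]$n_edges,
         members = x[[i]]$members))
  jsonlite::write_json(list(params = unclass(attr(x, "params")),
                            clusters = recs),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
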