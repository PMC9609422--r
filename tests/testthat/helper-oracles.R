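# Independent oracles and fixture builders. Everything here works on plain
# edge-list data frames / adjacency lists and never calls igraph, so the
# oracles share no code path with the implementation they check.

# build a ppi_network from an edge vector c(a1,b1, a2,b2, ...)
net_from_pairs <- function(..., confidence = 1) {
  v <- c(...)
  ppi_network(data.frame(a = v[c(TRUE, FALSE)], b = v[c(FALSE, TRUE)],
                         confidence = confidence))
}

# adjacency list (named list id -> character vector of neighbors)
adj_list <- function(net) {
  ed <- network_edges(net)
  nodes <- network_nodes(net)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(ed))) {
    adj[[ed$a[i]]] <- c(adj[[ed$a[i]]], ed$b[i])
    adj[[ed$b[i]]] <- c(adj[[ed$b[i]]], ed$a[i])
  }
  adj
}

# hand-coded BFS distances from one source; unreachable = Inf
oracle_bfs <- function(adj, src) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[src] <- 0
  queue <- src
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in adj[[v]]) {
      if (is.infinite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  dist
}

# all-pairs betweenness by shortest-path counting: for each ordered source,
# count geodesics sigma by dynamic programming over BFS layers, then sum
# pair dependencies sigma_sv * sigma_vt / sigma_st over interior vertices.
oracle_betweenness <- function(net) {
  adj <- adj_list(net)
  nodes <- names(adj)
  bw <- stats::setNames(rep(0, length(nodes)), nodes)
  dmat <- sapply(nodes, function(s) oracle_bfs(adj, s))  # dmat[v, s]
  sigma <- sapply(nodes, function(s) {                   # sigma[v, s]
    d <- dmat[, s]
    sg <- stats::setNames(rep(0, length(nodes)), nodes)
    sg[s] <- 1
    for (dd in sort(unique(d[is.finite(d) & d > 0]))) {
      for (v in nodes[d == dd]) {
        pred <- adj[[v]][d[adj[[v]]] == dd - 1]
        sg[v] <- sum(sg[pred])
      }
    }
    sg
  })
  for (si in seq_along(nodes)) for (ti in seq_along(nodes)) {
    if (si >= ti) next
    s <- nodes[si]; t <- nodes[ti]
    if (is.infinite(dmat[t, s])) next
    for (v in nodes) {
      if (v == s || v == t) next
      if (dmat[v, s] + dmat[t, v] == dmat[t, s])
        bw[v] <- bw[v] + sigma[v, s] * sigma[t, v] / sigma[t, s]
    }
  }
  bw
}

# naive k-core: repeatedly delete nodes of degree < k until stable
oracle_kcore_nodes <- function(net, k) {
  adj <- adj_list(net)
  repeat {
    deg <- lengths(adj)
    drop <- names(adj)[deg < k]
    if (length(drop) == 0L) return(sort(names(adj)))
    adj <- adj[!names(adj) %in% drop]
    adj <- lapply(adj, function(nb) nb[!nb %in% drop])
  }
}

# exhaustive hypergeometric tail: enumerate every size-n draw from an
# N-element universe containing K marked elements, count draws with >= k marks
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # elements 1..K are the marked ones
  mean(hits >= k)
}

# seeded Erdos-Renyi gnp edge table (plain R, no igraph)
random_gnp_net <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2L)
  on <- stats::runif(ncol(pairs)) < p
  ppi_network(data.frame(a = pairs[1L, on], b = pairs[2L, on],
                         confidence = 1), nodes = nodes)
}

# centrality table with a planted elite that tops all three centralities
planted_elite_table <- function(n_total, elite_ids, seed) {
  set.seed(seed)
  ids <- c(elite_ids, sprintf("bg%04d", seq_len(n_total - length(elite_ids))))
  n_bg <- n_total - length(elite_ids)
  tbl <- data.frame(
    id = ids,
    degree = c(sample(200:400, length(elite_ids)), sample(1:100, n_bg, TRUE)),
    closeness = c(stats::runif(length(elite_ids), 0.8, 1),
                  stats::runif(n_bg, 0.1, 0.5)),
    betweenness = c(stats::runif(length(elite_ids), 0.5, 1),
                    stats::runif(n_bg, 0, 0.2)),
    stringsAsFactors = FALSE)
  class(tbl) <- c("centrality_table", "data.frame")
  tbl
}
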