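#' Degree centrality
#'
#' Raw neighbor counts (not normalized), the convention Cytoscape's
#' NetworkAnalyzer reports for PPI hub ranking.
#'
#' @param net a `ppi_network`.
#' @return named integer vector over all nodes, names sorted.
#' @export
degree_centrality <- function(net) {
  g <- as_igraph(net)
  d <- igraph::degree(g, loops = FALSE)
  d <- d[order(names(d), method = "radix")]
  storage.mode(d) <- "integer"
  d
}

#' Closeness centrality
#'
#' For a node `v` in a connected component of size `m > 1`,
#' `closeness(v) = (m - 1) / sum of shortest-path distances from v within its
#' component` -- the reciprocal of the mean geodesic distance, computed
#' per component (NetworkAnalyzer's convention for disconnected graphs).
#' Isolated nodes score 0. Values lie in \[0, 1\].
#'
#' @param net a `ppi_network`.
#' @return named numeric vector over all nodes, names sorted.
#' @export
closeness_centrality <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  out <- stats::setNames(numeric(n), igraph::V(g)$name)
  if (n == 0L) return(out)
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    m <- length(idx)
    if (m < 2L) next
    sub <- igraph::induced_subgraph(g, idx)
    dmat <- igraph::distances(sub, weights = NA)
    out[igraph::V(sub)$name] <- (m - 1) / rowSums(dmat)
  }
  out[order(names(out), method = "radix")]
}

#' Betweenness centrality
#'
#' Shortest-path betweenness by Brandes' algorithm (endpoints excluded).
#' When `normalized`, values are scaled by `2 / ((m - 1) (m - 2))` where `m`
#' is, per the default `scope = "component"`, the size of the node's connected
#' component (nodes in components smaller than 3 score 0); with
#' `scope = "graph"` the whole-graph node count is used instead.
#'
#' @param net a `ppi_network`.
#' @param normalized scale into \[0, 1\] (default TRUE).
#' @param scope normalization denominator: per `"component"` (default) or
#'   whole `"graph"`.
#' @return named numeric vector over all nodes, names sorted.
#' @export
betweenness_centrality <- function(net, normalized = TRUE,
                                   scope = c("component", "graph")) {
  scope <- match.arg(scope)
  g <- as_igraph(net)
  bw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  if (normalized) {
    n <- igraph::vcount(g)
    if (scope == "graph") {
      bw <- if (n >= 3L) bw * 2 / ((n - 1) * (n - 2)) else bw * 0
    } else {
      comp <- igraph::components(g)
      m <- comp$csize[comp$membership]
      scale <- ifelse(m >= 3L, 2 / ((m - 1) * (m - 2)), 0)
      bw <- bw * scale
    }
  }
  bw[order(names(bw), method = "radix")]
}

#' Per-node centrality table
#'
#' Computes the three centralities hub selection ranks on. Row order is
#' sorted node id, so floating-point accumulation and downstream ranking are
#' reproducible run to run.
#'
#' @param net a `ppi_network`.
#' @inheritParams betweenness_centrality
#' @return data.frame of class `centrality_table` with columns `id`,
#'   `degree`, `closeness`, `betweenness`.
#' @export
centrality_table <- function(net, scope = c("component", "graph")) {
  scope <- match.arg(scope)
  deg <- degree_centrality(net)
  clo <- closeness_centrality(net)
  btw <- betweenness_centrality(net, normalized = TRUE, scope = scope)
  tbl <- data.frame(id = names(deg), degree = as.integer(deg),
                    closeness = as.numeric(clo[names(deg)]),
                    betweenness = as.numeric(btw[names(deg)]),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(tbl) <- c("centrality_table", "data.frame")
  tbl
}

#' Write a centrality table as TSV
#'
#' Four columns (`id`, `degree`, `closeness`, `betweenness`), sorted by
#' descending degree with ties broken by id.
#'
#' @param tbl a `centrality_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_centrality_table <- function(tbl, path) {
  ord <- order(-tbl$degree, tbl$id, method = "radix")
  out <- tbl[ord, , drop = FALSE]
  lines <- c("id\tdegree\tcloseness\tbetweenness",
             sprintf("%s\t%d\t%s\t%s", out$id, out$degree,
                     formatC(out$closeness, format = "g", digits = 15),
                     formatC(out$betweenness, format = "g", digits = 15)))
  writeLines(lines, path)
  invisible(path)
}
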