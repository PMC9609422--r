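#' @importFrom igraph V E graph_from_data_frame vcount ecount degree
#'   components induced_subgraph delete_vertices subgraph_from_edges
#'   as_data_frame coreness distances betweenness neighbors make_empty_graph
#'   vertex_attr edge_attr gorder gsize
NULL

#' Construct a PPI network from an interaction table
#'
#' Builds a simple undirected protein-protein interaction network with a
#' per-edge confidence score in \[0, 1\]. Cleaning removes self-loops and
#' collapses duplicate (unordered) edges keeping the maximum confidence --
#' the conservative choice ahead of a strict ">" confidence filter.
#'
#' @param edges data.frame with columns `a`, `b` (gene symbols, no
#'   whitespace) and optionally `confidence` (defaults to
#'   `default_confidence`).
#' @param default_confidence confidence assigned to rows lacking one.
#' @param nodes optional character vector of node ids; nodes not appearing in
#'   any surviving edge are retained as isolates. By default the node set is
#'   the endpoints of the cleaned edges.
#' @param metadata named list stored on the network (source file, thresholds,
#'   parse report, ...).
#' @return an object of class `ppi_network`.
#' @export
ppi_network <- function(edges, default_confidence = 1, nodes = NULL,
                        metadata = list()) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0L) {
    a <- as.character(edges[[1L]])
    b <- as.character(edges[[2L]])
    conf <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else
      rep(default_confidence, nrow(edges))
    conf[is.na(conf)] <- default_confidence
    if (any(grepl("\\s", c(a, b)))) stop("gene symbols must not contain whitespace")
    if (any(conf < 0 | conf > 1)) stop("confidence values must lie in [0, 1]")
    self <- a == b
    a <- a[!self]; b <- b[!self]; conf <- conf[!self]
    n_dup <- 0L
    if (length(a) > 0L) {
      # canonical unordered orientation, then collapse duplicates keeping max
      lo <- pmin(a, b); hi <- pmax(a, b)
      key <- paste(lo, hi, sep = "\r")
      keep <- !duplicated(key)
      n_dup <- sum(!keep)
      conf_max <- tapply(conf, key, max)
      ed <- data.frame(a = lo[keep], b = hi[keep],
                       confidence = as.numeric(conf_max[key[keep]]),
                       stringsAsFactors = FALSE)
      ord <- order(ed$a, ed$b, method = "radix")
      ed <- ed[ord, , drop = FALSE]
    } else {
      ed <- data.frame(a = character(), b = character(), confidence = numeric())
    }
    metadata$n_self_loops_dropped <- metadata$n_self_loops_dropped %||% sum(self)
    metadata$n_duplicates_collapsed <- metadata$n_duplicates_collapsed %||% n_dup
  } else {
    ed <- data.frame(a = character(), b = character(), confidence = numeric())
  }
  vnames <- sort(unique(c(ed$a, ed$b, as.character(nodes))))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = vnames))
  new_ppi_network(g, metadata)
}

new_ppi_network <- function(graph, metadata = list()) {
  structure(list(graph = graph, metadata = metadata), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("PPI network: %d nodes, %d edges, density %.4f, %d component(s)\n",
              s$n_nodes, s$n_edges, s$density, s$n_components))
  if (!is.null(x$metadata$confidence_threshold))
    cat(sprintf("  confidence filter: > %g\n", x$metadata$confidence_threshold))
  invisible(x)
}

#' Underlying igraph object of a PPI network
#' @param net a `ppi_network`.
#' @return the `igraph` graph (vertex attribute `name`, edge attribute
#'   `confidence`).
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  net$graph
}

#' Node identifiers of a network
#' @param net a `ppi_network`.
#' @return character vector of node ids, sorted.
#' @export
network_nodes <- function(net) sort(igraph::V(as_igraph(net))$name)

#' Edge table of a network
#' @param net a `ppi_network`.
#' @return data.frame `a`, `b`, `confidence` in canonical (a < b) orientation,
#'   sorted by (a, b).
#' @export
network_edges <- function(net) {
  df <- igraph::as_data_frame(as_igraph(net), what = "edges")
  if (nrow(df) == 0L)
    return(data.frame(a = character(), b = character(), confidence = numeric()))
  out <- data.frame(a = pmin(df$from, df$to), b = pmax(df$from, df$to),
                    confidence = df$confidence, stringsAsFactors = FALSE)
  out[order(out$a, out$b, method = "radix"), , drop = FALSE]
}

#' Read an interaction edge list
#'
#' Parses tab-separated edge lists (`nodeA nodeB [confidence]`) or Cytoscape
#' SIF files (`nodeA relation nodeB [nodeC ...]`; the relation is ignored).
#' Lines starting with `#` and blank lines are skipped. For TSV, a header is
#' auto-detected when the first data line has a non-numeric third field.
#' Cleaning (self-loop removal, duplicate collapse keeping the maximum
#' confidence) is applied and summarized in the returned network's metadata.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension, default `tsv`), `"tsv"`, or `"sif"`.
#' @param default_confidence confidence used when the file carries none
#'   (2-column TSV, SIF).
#' @return a `ppi_network` whose metadata holds a parse report
#'   (`rows_read`, `n_self_loops_dropped`, `n_duplicates_collapsed`, `source`).
#' @export
read_edge_list <- function(path, format = c("auto", "tsv", "sif"),
                           default_confidence = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty edge list: ", path)

  if (format == "sif") {
    parts <- strsplit(trimws(lines), "[ \t]+")
    edges <- do.call(rbind, lapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      if (length(p) == 1L)       # isolated node declaration
        return(data.frame(a = character(), b = character()))
      if (length(p) == 2L)
        stop(sprintf("malformed SIF row at line %d: need node, relation, node(s)",
                     lineno[i]))
      data.frame(a = p[1L], b = p[3:length(p)], stringsAsFactors = FALSE)
    }))
    isolates <- unlist(lapply(parts, function(p) if (length(p) == 1L) p else NULL))
    edges$confidence <- rep(default_confidence, nrow(edges))
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    # header: first line whose third field is present and not numeric
    start <- 1L
    p1 <- parts[[1L]]
    if (length(p1) >= 3L && is.na(suppressWarnings(as.numeric(p1[3L]))))
      start <- 2L
    if (start > length(parts)) stop("empty edge list (header only): ", path)
    rows <- lapply(seq(start, length(parts)), function(i) {
      p <- trimws(parts[[i]])
      if (length(p) < 2L || any(p[1:2] == ""))
        stop(sprintf("malformed row at line %d: need at least two columns",
                     lineno[i]))
      conf <- default_confidence
      if (length(p) >= 3L && p[3L] != "") {
        conf <- suppressWarnings(as.numeric(p[3L]))
        if (is.na(conf))
          stop(sprintf("malformed confidence at line %d: '%s'", lineno[i], p[3L]))
        if (conf < 0 || conf > 1)
          stop(sprintf("confidence outside [0, 1] at line %d: %s", lineno[i], p[3L]))
      }
      data.frame(a = p[1L], b = p[2L], confidence = conf, stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rows)
    isolates <- NULL
  }
  ppi_network(edges, default_confidence = default_confidence, nodes = isolates,
              metadata = list(source = path, format = format,
                              rows_read = length(lines)))
}

#' Write a network as a canonical 3-column TSV edge list
#'
#' Edges are written in canonical orientation (a < b), sorted
#' lexicographically by (a, b), so identical networks always serialize to
#' byte-identical files.
#'
#' @param net a `ppi_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  ed <- network_edges(net)
  lines <- sprintf("%s\t%s\t%s", ed$a, ed$b,
                   formatC(ed$confidence, format = "g", digits = 15))
  writeLines(lines, path)
  invisible(path)
}

#' Filter edges by confidence
#'
#' Keeps exactly the edges whose confidence is strictly greater than
#' `threshold` (matching the usual "high confidence > 0.7" STRING cut), and
#' by default drops nodes left without any edge.
#'
#' @param net a `ppi_network`.
#' @param threshold confidence cut in \[0, 1\]; strict inequality.
#' @param keep_isolated keep nodes that lose all their edges (default FALSE,
#'   Cytoscape's default view behavior).
#' @return the filtered `ppi_network`; metadata records the threshold.
#' @export
filter_by_confidence <- function(net, threshold, keep_isolated = FALSE) {
  stopifnot(inherits(net, "ppi_network"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  g <- as_igraph(net)
  keep <- which(igraph::E(g)$confidence > threshold)
  g2 <- igraph::subgraph_from_edges(g, keep, delete.vertices = !keep_isolated)
  md <- net$metadata
  md$confidence_threshold <- threshold
  new_ppi_network(g2, md)
}

#' Summary statistics of a network
#'
#' @param net a `ppi_network`.
#' @return list with `n_nodes`, `n_edges`, `density` (loop-free
#'   `2E / (V (V - 1))`, 0 by convention for fewer than two nodes),
#'   `n_components`, and `largest_component_size`.
#' @export
network_summary <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  comp <- igraph::components(g)
  list(n_nodes = n,
       n_edges = igraph::ecount(g),
       density = simple_density(n, igraph::ecount(g)),
       n_components = if (n == 0L) 0L else comp$no,
       largest_component_size = if (n == 0L) 0L else max(comp$csize))
}
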