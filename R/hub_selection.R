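#' Top-ranked nodes by one centrality
#'
#' Ranks nodes by the named centrality, descending, with deterministic
#' tie-breaking (higher value first, then lexicographic id), and returns the
#' leading slice. `fraction` takes the ceiling of `fraction * n` nodes so a
#' positive fraction never yields an empty list on a small network; `k` takes
#' exactly `k`. With `include_ties` the slice is extended to every node tying
#' the last included value (the size is then data-dependent).
#'
#' @param table a `centrality_table`.
#' @param centrality one of `"degree"`, `"closeness"`, `"betweenness"`.
#' @param fraction fraction of nodes to keep, in (0, 1\]. Exactly one of
#'   `fraction` and `k` must be given.
#' @param k number of nodes to keep, `1 <= k <= n`.
#' @param include_ties extend the cut to all value ties (default FALSE).
#' @return ordered character vector of node ids.
#' @export
top_fraction <- function(table, centrality, fraction = NULL, k = NULL,
                         include_ties = FALSE) {
  stopifnot(inherits(table, "data.frame"))
  if (!centrality %in% c("degree", "closeness", "betweenness"))
    stop("unknown centrality: ", centrality)
  n <- nrow(table)
  if (is.null(k)) {
    stopifnot(is.numeric(fraction), length(fraction) == 1L,
              fraction > 0, fraction <= 1)
    k <- ceiling(fraction * n)
  } else {
    stopifnot(is.null(fraction), is.numeric(k), length(k) == 1L, k >= 1, k <= n)
    k <- as.integer(k)
  }
  val <- table[[centrality]]
  ord <- order(-val, table$id, method = "radix")
  if (include_ties && k < n) {
    cutval <- val[ord[k]]
    k <- max(which(val[ord] >= cutval))
  }
  table$id[ord[seq_len(min(k, n))]]
}

#' Hub candidates: the per-centrality top-fraction filter
#'
#' Applies the same top-`fraction` filter to degree, closeness and
#' betweenness and combines the three lists. The default combination is the
#' intersection -- a node must sit in the leading 20% on all three
#' centralities to be a candidate -- which on a ~900-node disease network
#' typically leaves a few dozen candidates; `combine = "union"` is the
#' permissive alternative.
#'
#' @param table a `centrality_table`.
#' @param fraction per-centrality fraction (default 0.2).
#' @param combine `"intersection"` (default) or `"union"`.
#' @param include_ties passed to [top_fraction()].
#' @return sorted character vector of candidate ids.
#' @export
select_candidates <- function(table, fraction = 0.2,
                              combine = c("intersection", "union"),
                              include_ties = FALSE) {
  combine <- match.arg(combine)
  lists <- lapply(c("degree", "closeness", "betweenness"), function(cn)
    top_fraction(table, cn, fraction = fraction, include_ties = include_ties))
  f <- if (combine == "intersection") intersect else union
  sort(Reduce(f, lists))
}

#' Hub genes: intersection of per-centrality top-k lists
#'
#' A node is a hub when it ranks among the `k` highest on degree, closeness
#' and betweenness simultaneously.
#'
#' @param table a `centrality_table`.
#' @param k per-centrality list length (default 20).
#' @param include_ties passed to [top_fraction()].
#' @return sorted character vector of hub ids.
#' @export
select_hubs <- function(table, k = 20, include_ties = FALSE) {
  lists <- lapply(c("degree", "closeness", "betweenness"), function(cn)
    top_fraction(table, cn, k = k, include_ties = include_ties))
  sort(Reduce(intersect, lists))
}

#' Two-stage hub selection
#'
#' Runs the candidate filter (top `fraction` per centrality, combined) and
#' the hub rule (intersection of top-`k` lists) in one call and records the
#' ranked per-centrality lists used.
#'
#' @inheritParams select_candidates
#' @inheritParams select_hubs
#' @return object of class `hub_selection`: list with `candidates`, `hubs`,
#'   `top_lists` (per-centrality ordered top-k ids), and `parameters`.
#' @export
hub_selection <- function(table, fraction = 0.2, k = 20,
                          combine = c("intersection", "union"),
                          include_ties = FALSE) {
  combine <- match.arg(combine)
  top_lists <- stats::setNames(
    lapply(c("degree", "closeness", "betweenness"), function(cn)
      top_fraction(table, cn, k = k, include_ties = include_ties)),
    c("degree", "closeness", "betweenness"))
  structure(list(
    candidates = select_candidates(table, fraction, combine, include_ties),
    hubs = select_hubs(table, k, include_ties),
    top_lists = top_lists,
    parameters = list(fraction = fraction, k = k, combine = combine,
                      include_ties = include_ties)),
    class = "hub_selection")
}

#' @export
print.hub_selection <- function(x, ...) {
  cat(sprintf("Hub selection (fraction %g [%s], k = %d): %d candidates, %d hubs\n",
              x$parameters$fraction, x$parameters$combine, x$parameters$k,
              length(x$candidates), length(x$hubs)))
  cat("  hubs:", paste(x$hubs, collapse = ", "), "\n")
  invisible(x)
}

#' Write a hub-selection result as JSON
#' @param x a `hub_selection`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hub_selection <- function(x, path) {
  jsonlite::write_json(
    list(parameters = x$parameters, candidates = x$candidates,
         hubs = x$hubs, top_lists = x$top_lists),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
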