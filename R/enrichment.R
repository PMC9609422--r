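#' Build an annotation collection
#'
#' Holds named term sets over a gene universe for over-representation
#' analysis. The background defaults to the union of all term members; a
#' user-supplied background must contain every term member.
#'
#' @param terms named list; each element is either a character vector of
#'   member ids or a list with `name` and `members`. Names are term ids.
#' @param background optional character vector / `gene_set` of universe ids.
#' @return object of class `annotation_collection` with `terms` (each a list
#'   `name`, `members`) and `background` (character).
#' @export
annotation_collection <- function(terms, background = NULL) {
  stopifnot(is.list(terms), length(terms) > 0, !is.null(names(terms)),
            all(names(terms) != ""))
  terms <- lapply(stats::setNames(names(terms), names(terms)), function(id) {
    t <- terms[[id]]
    if (is.character(t)) t <- list(name = id, members = t)
    t$members <- unique(as.character(t$members))
    if (length(t$members) == 0L) stop("empty term: ", id)
    t$name <- t$name %||% id
    t
  })
  members_all <- unique(unlist(lapply(terms, `[[`, "members")))
  if (is.null(background)) {
    background <- sort(members_all)
  } else {
    background <- sort(unique(as_gene_set(background)$ids))
    missing <- setdiff(members_all, background)
    if (length(missing) > 0L)
      stop("term members missing from background: ",
           paste(utils::head(missing, 5L), collapse = ", "))
  }
  structure(list(terms = terms, background = background),
            class = "annotation_collection")
}

#' Read annotation sets in GMT format
#'
#' One term per line: term id, description, then tab-separated member ids.
#'
#' @param path GMT file.
#' @param background optional universe (default: union of all members).
#' @return an `annotation_collection`.
#' @export
read_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L)
    stop("malformed GMT row at line ", bad[1L], ": need id, description, members")
  terms <- stats::setNames(lapply(parts, function(p)
    list(name = p[2L], members = p[-(1:2)][nzchar(p[-(1:2)])])),
    vapply(parts, `[[`, "", 1L))
  annotation_collection(terms, background)
}

#' Write an annotation collection in GMT format
#' @param annotations an `annotation_collection`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  lines <- vapply(names(annotations$terms), function(id) {
    t <- annotations$terms[[id]]
    paste(c(id, t$name, t$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Adjust p-values for multiple testing
#'
#' Holm (Bonferroni step-down, the default family-wise correction ClueGO-style
#' enrichment reports), plain Bonferroni, or Benjamini-Hochberg FDR. Values
#' are clipped at 1 and returned in the input order.
#'
#' @param p numeric vector of raw p-values in (0, 1\].
#' @param method `"holm"`, `"bonferroni"`, or `"bh"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bonferroni", "bh")) {
  method <- match.arg(method)
  stopifnot(is.numeric(p), all(p > 0), all(p <= 1))
  stats::p.adjust(p, method = c(holm = "holm", bonferroni = "bonferroni",
                                bh = "BH")[[method]])
}

#' Associated-genes percentage
#'
#' For an annotation term of size `K` with `k` members in the query set,
#' `100 * k / K` -- the share of the term captured by the query.
#'
#' @param k overlap count, `0 <= k <= K`.
#' @param K term size, `K >= 1`.
#' @return percentage, unrounded.
#' @export
associated_percent <- function(k, K) {
  stopifnot(length(k) == length(K))
  if (any(K == 0)) stop("term size K must be at least 1")
  stopifnot(all(k >= 0), all(k <= K))
  100 * k / K
}

#' Hypergeometric over-representation analysis
#'
#' One-sided over-representation test: for each term with `K` members in a
#' background of `N` genes and a query of `n` genes overlapping the term in
#' `k` genes, `p_raw = P[X >= k]` with `X ~ Hypergeometric(N, K, n)`. Query
#' ids outside the background are dropped (and reported in the
#' `dropped_query_ids` attribute). Terms with `k < min_overlap` are omitted.
#' Adjusted p-values are computed over the retained terms; rows are sorted
#' by ascending adjusted then raw p-value, then term id.
#'
#' @param query `gene_set` or character vector of query genes.
#' @param annotations an `annotation_collection`.
#' @param min_overlap minimum overlap to report a term (default 3).
#' @param method multiple-testing method for [adjust_pvalues()]
#'   (default `"holm"`).
#' @return data.frame of class `enrichment_result` with columns `term_id`,
#'   `term_name`, `k`, `K`, `n`, `N`, `associated_percent`, `p_raw`,
#'   `p_adjusted`.
#' @export
hypergeometric_enrich <- function(query, annotations, min_overlap = 3,
                                  method = c("holm", "bonferroni", "bh")) {
  method <- match.arg(method)
  stopifnot(inherits(annotations, "annotation_collection"), min_overlap >= 1)
  query <- as_gene_set(query)
  bg <- annotations$background
  if (length(bg) == 0L) stop("empty background")
  q <- intersect(query$ids, bg)
  dropped <- setdiff(query$ids, bg)
  if (length(q) == 0L) stop("empty query after restriction to the background")
  N <- length(bg)
  n <- length(q)
  rows <- lapply(names(annotations$terms), function(id) {
    t <- annotations$terms[[id]]
    K <- length(t$members)
    k <- length(intersect(q, t$members))
    if (k < min_overlap) return(NULL)
    data.frame(term_id = id, term_name = t$name, k = k, K = K, n = n, N = N,
               associated_percent = associated_percent(k, K),
               p_raw = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    res <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), associated_percent = numeric(),
                      p_raw = numeric(), p_adjusted = numeric())
  } else {
    res <- do.call(rbind, rows)
    res$p_adjusted <- adjust_pvalues(res$p_raw, method)
    res <- res[order(res$p_adjusted, res$p_raw, res$term_id,
                     method = "radix"), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "dropped_query_ids") <- dropped
  attr(res, "method") <- method
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Write an enrichment table as TSV
#' @param res an `enrichment_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
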