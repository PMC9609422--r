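#' Construct a labeled gene set
#'
#' @param ids character vector of identifiers; duplicates are removed
#'   (first occurrence kept).
#' @param label non-empty set label.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(ids, label = "set") {
  stopifnot(is.character(label), nchar(label) > 0)
  ids <- as.character(ids)
  ids <- ids[!is.na(ids) & ids != ""]
  structure(list(label = label, ids = unique(ids)), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s': %d ids\n", x$label, length(x$ids)))
  invisible(x)
}

as_gene_set <- function(x, label = "set") {
  if (inherits(x, "gene_set")) x else gene_set(x, label)
}

#' Read a gene list (one id per line)
#'
#' Blank lines and `#` comments are skipped.
#'
#' @param path input file.
#' @param label set label (defaults to the file name).
#' @return a `gene_set`.
#' @export
read_gene_list <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  gene_set(lines[!grepl("^(#|$)", lines)], label)
}

#' Write a gene list (one id per line, sorted)
#' @param set a `gene_set` or character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(set, path) {
  writeLines(sort(as_gene_set(set)$ids), path)
  invisible(path)
}

#' Normalize identifiers against a mapping table
#'
#' Replaces each identifier by its canonical accession where the mapping
#' provides one (emulating symbol-to-UniProt conversion that removes spelling
#' and alias variants before set comparison). Unmapped identifiers are kept
#' verbatim by default, so set cardinalities stay conservative, and are
#' listed in the report; `strict` drops them instead. Identifiers that merge
#' onto one accession are deduplicated.
#'
#' @param raw a `gene_set` or character vector.
#' @param mapping two-column data.frame (source, canonical accession); NULL
#'   or empty means identity. Duplicate source keys must agree.
#' @param strict drop unmapped ids (default FALSE).
#' @return list with `set` (normalized `gene_set`), `unmapped` (character),
#'   `n_merged` (ids lost to deduplication).
#' @export
normalize_ids <- function(raw, mapping = NULL, strict = FALSE) {
  raw <- as_gene_set(raw)
  if (is.null(mapping) || nrow(mapping) == 0L) {
    return(list(set = raw, unmapped = raw$ids, n_merged = 0L))
  }
  src <- as.character(mapping[[1L]])
  dst <- as.character(mapping[[2L]])
  dup <- duplicated(src)
  if (any(dup)) {
    conflict <- vapply(unique(src[dup]), function(s)
      length(unique(dst[src == s])) > 1L, logical(1))
    if (any(conflict))
      stop("conflicting mapping for source id(s): ",
           paste(unique(src[dup])[conflict], collapse = ", "))
    src <- src[!dup]; dst <- dst[!dup]
  }
  hit <- match(raw$ids, src)
  mapped <- ifelse(is.na(hit), raw$ids, dst[hit])
  unmapped <- raw$ids[is.na(hit)]
  if (strict) mapped <- mapped[!is.na(hit)]
  out <- unique(mapped)
  list(set = gene_set(out, raw$label),
       unmapped = unmapped,
       n_merged = length(mapped) - length(out))
}

#' Read a two-column identifier mapping table (TSV)
#' @param path TSV with source id and canonical accession; `#` comments
#'   skipped.
#' @return data.frame with columns `source`, `accession`.
#' @export
read_id_mapping <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) stop("malformed mapping row (need two columns)")
  data.frame(source = vapply(parts, `[[`, "", 1L),
             accession = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Intersect two gene sets (pairwise Venn)
#'
#' @param a,b `gene_set`s (or character vectors) in the same identifier
#'   namespace.
#' @return object of class `venn_result` with `set_labels`, `region_counts`
#'   (signatures `"10"`, `"01"`, `"11"`: membership bitmask in input order),
#'   `regions` (the id lists), and `shared` (a `gene_set` of the
#'   intersection).
#' @export
intersect_gene_sets <- function(a, b) {
  a <- as_gene_set(a, "a"); b <- as_gene_set(b, "b")
  venn_regions(list(a, b))
}

#' Venn partition of two or three gene sets
#'
#' Partitions the union of the input sets into disjoint membership regions.
#' Region signatures are bitmasks in input order (e.g. `"110"` = in sets 1
#' and 2, not 3), so counts always sum to the union size.
#'
#' @param sets list of two or three `gene_set`s (or character vectors).
#' @return a `venn_result` (see [intersect_gene_sets()]); `shared` holds the
#'   all-sets intersection.
#' @export
venn_regions <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2L, 3L))
  sets <- lapply(seq_along(sets), function(i)
    as_gene_set(sets[[i]], paste0("set", i)))
  labels <- vapply(sets, `[[`, "", "label")
  uni <- sort(unique(unlist(lapply(sets, `[[`, "ids"))))
  member <- vapply(sets, function(s) uni %in% s$ids, logical(length(uni)))
  if (length(uni) == 1L) member <- matrix(member, nrow = 1L)
  sig <- apply(member, 1L, function(row) paste(as.integer(row), collapse = ""))
  grid <- as.matrix(expand.grid(rep(list(0:1), length(sets))))
  all_sigs <- apply(grid, 1L, paste, collapse = "")
  all_sigs <- sort(setdiff(all_sigs, strrep("0", length(sets))),
                   decreasing = TRUE)
  regions <- lapply(stats::setNames(all_sigs, all_sigs),
                    function(s) uni[sig == s])
  shared_ids <- regions[[paste(rep("1", length(sets)), collapse = "")]]
  structure(list(set_labels = labels,
                 region_counts = lengths(regions),
                 regions = regions,
                 shared = gene_set(shared_ids,
                                   paste(labels, collapse = " ∩ "))),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("Venn of {%s}: union %d, shared %d\n",
              paste(x$set_labels, collapse = ", "),
              sum(x$region_counts), length(x$shared$ids)))
  for (s in names(x$region_counts))
    cat(sprintf("  [%s] %d\n", s, x$region_counts[[s]]))
  invisible(x)
}

#' Coverage of a reference set
#'
#' `100 * |shared intersect reference| / |reference|`, rounded half-up to two
#' decimal places -- the share of a disease gene set that a compound's
#' targets reach.
#'
#' @param shared a `gene_set` or character vector (e.g. the drug-disease
#'   intersection).
#' @param reference non-empty reference `gene_set` or character vector.
#' @return object of class `coverage_stat`: list with `numerator`,
#'   `denominator`, `percent`.
#' @export
coverage <- function(shared, reference) {
  shared <- as_gene_set(shared); reference <- as_gene_set(reference)
  if (length(reference$ids) == 0L) stop("reference set is empty")
  num <- length(intersect(shared$ids, reference$ids))
  den <- length(reference$ids)
  structure(list(numerator = num, denominator = den,
                 percent = round_half_up(100 * num / den, 2)),
            class = "coverage_stat")
}

#' @export
print.coverage_stat <- function(x, ...) {
  cat(sprintf("coverage: %d / %d = %.2f%%\n",
              x$numerator, x$denominator, x$percent))
  invisible(x)
}

#' Per-cluster target coverage
#'
#' For each detected complex, how many of its members a target set reaches,
#' and the percentage of the complex covered.
#'
#' @param clusters an `mcode_result` or list of `mcode_cluster`s.
#' @param targets a `gene_set` or character vector.
#' @return data.frame with `rank`, `seed`, `n_nodes`, `n_overlap`,
#'   `percent_covered`.
#' @export
cluster_coverage <- function(clusters, targets) {
  targets <- as_gene_set(targets)
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    ov <- length(intersect(cl$members, targets$ids))
    data.frame(rank = i, seed = cl$seed, n_nodes = cl$n_nodes,
               n_overlap = ov,
               percent_covered = round_half_up(100 * ov / cl$n_nodes, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
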