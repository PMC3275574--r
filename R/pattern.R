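#' Connectivity patterns
#'
#' A connectivity pattern is the bipartite TF-to-gene zero pattern that
#' constrains the bilinear decomposition: a control strength may be nonzero
#' only where an edge exists.  Edges carry an evidence label
#' (`"experimental"` or `"motif"`), mirroring curated regulatory databases
#' in which interactions are supported either by direct experiments or by
#' motif scanning.
#'
#' @param edges A data frame with columns `gene`, `tf` and optionally
#'   `evidence` (defaults to `"experimental"`).  Duplicate gene-TF pairs are
#'   collapsed to a single edge.
#' @param tf_ids,gene_ids Optional character vectors fixing the identity and
#'   order of TFs and genes.  Defaults to the order of first appearance in
#'   `edges`.  Ids referenced by `edges` must be present.
#'
#' @return An object of class `connectivity_pattern`: a list with elements
#'   `edges` (tibble), `tf_ids` and `gene_ids`.
#' @export
#' @examples
#' pat <- connectivity_pattern(
#'   data.frame(gene = c("g1", "g2", "g2"), tf = c("tfA", "tfA", "tfB"))
#' )
#' pat
connectivity_pattern <- function(edges, tf_ids = NULL, gene_ids = NULL) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("gene", "tf") %in% names(edges))) {
    abort("`edges` must have columns `gene` and `tf`.")
  }
  if (!"evidence" %in% names(edges)) edges$evidence <- "experimental"
  bad <- setdiff(unique(edges$evidence), c("experimental", "motif"))
  if (length(bad) > 0) {
    abort(paste0("Unknown evidence label(s): ", paste(bad, collapse = ", ")))
  }
  edges <- dplyr::distinct(edges, .data$gene, .data$tf, .keep_all = TRUE)
  edges <- dplyr::mutate(edges,
    gene = as.character(.data$gene), tf = as.character(.data$tf)
  )
  if (is.null(tf_ids)) tf_ids <- unique(edges$tf)
  if (is.null(gene_ids)) gene_ids <- unique(edges$gene)
  if (!all(edges$tf %in% tf_ids)) abort("`edges` references unknown TF ids.")
  if (!all(edges$gene %in% gene_ids)) abort("`edges` references unknown gene ids.")
  structure(
    list(
      edges = edges[c("gene", "tf", "evidence")],
      tf_ids = as.character(tf_ids),
      gene_ids = as.character(gene_ids)
    ),
    class = "connectivity_pattern"
  )
}

#' @export
print.connectivity_pattern <- function(x, ...) {
  cat(
    "<connectivity_pattern> ", length(x$tf_ids), " TFs, ",
    length(x$gene_ids), " genes, ", nrow(x$edges), " edges\n",
    sep = ""
  )
  invisible(x)
}

#' @export
#' @rdname connectivity_pattern
#' @param x A `connectivity_pattern`.
#' @param ... Unused.
#' @method tidy connectivity_pattern
tidy.connectivity_pattern <- function(x, ...) x$edges

#' Logical incidence matrix of a connectivity pattern
#'
#' @param pattern A [connectivity_pattern()].
#' @return A logical genes-by-TFs matrix with dimnames, `TRUE` where an edge
#'   exists.
#' @export
pattern_matrix <- function(pattern) {
  stopifnot(inherits(pattern, "connectivity_pattern"))
  M <- matrix(
    FALSE, length(pattern$gene_ids), length(pattern$tf_ids),
    dimnames = list(pattern$gene_ids, pattern$tf_ids)
  )
  M[cbind(pattern$edges$gene, pattern$edges$tf)] <- TRUE
  M
}

#' Read / write connectivity tables
#'
#' Connectivity files are 3-column tab-separated tables with header
#' `tf`, `gene`, `evidence`.  On read, edges can be restricted to an
#' evidence class; curated interactions flagged as experimentally validated
#' are commonly preferred over motif-search predictions to limit false
#' positive connections.  TFs that lose all their edges under the filter are
#' dropped with a warning.
#'
#' @param path File path.
#' @param evidence_filter Character vector of evidence labels to retain
#'   (subset of `"experimental"`, `"motif"`).
#' @return `read_connectivity()` returns a [connectivity_pattern()];
#'   `write_connectivity()` returns `path` invisibly.
#' @export
read_connectivity <- function(path, evidence_filter = c("experimental", "motif")) {
  evidence_filter <- match.arg(evidence_filter, several.ok = TRUE)
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("tf", "gene", "evidence") %in% names(tbl))) {
    abort("Connectivity file must have columns `tf`, `gene`, `evidence`.")
  }
  if (anyNA(tbl$tf) || anyNA(tbl$gene) || anyNA(tbl$evidence)) {
    abort("Malformed connectivity rows: missing tf, gene or evidence values.")
  }
  bad <- setdiff(unique(tbl$evidence), c("experimental", "motif"))
  if (length(bad) > 0) {
    abort(paste0("Unknown evidence label(s): ", paste(bad, collapse = ", ")))
  }
  kept <- tbl[tbl$evidence %in% evidence_filter, , drop = FALSE]
  lost <- setdiff(unique(tbl$tf), unique(kept$tf))
  if (length(lost) > 0) {
    warn(paste0(
      "Dropping TF(s) with no edges after evidence filtering: ",
      paste(lost, collapse = ", ")
    ))
  }
  if (nrow(kept) == 0) abort("No edges remain after evidence filtering.")
  connectivity_pattern(kept[c("gene", "tf", "evidence")])
}

#' @rdname read_connectivity
#' @param pattern A [connectivity_pattern()].
#' @export
write_connectivity <- function(pattern, path) {
  stopifnot(inherits(pattern, "connectivity_pattern"))
  readr::write_tsv(pattern$edges[c("tf", "gene", "evidence")], path)
  invisible(path)
}

## Internal: drop listed genes/TFs, keeping edge set consistent.
subset_pattern <- function(pattern, genes = pattern$gene_ids, tfs = pattern$tf_ids) {
  edges <- pattern$edges[pattern$edges$gene %in% genes & pattern$edges$tf %in% tfs, ]
  connectivity_pattern(
    edges,
    tf_ids = intersect(tfs, unique(edges$tf)),
    gene_ids = intersect(genes, unique(edges$gene))
  )
}
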