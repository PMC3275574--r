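#' Log-ratio expression matrices
#'
#' Container for the matrix `E` consumed by the decomposition: one row per
#' gene, one column per non-reference condition, entries are log2 expression
#' ratios of each condition group mean to the reference group mean.
#'
#' @param values Numeric matrix with gene ids as rownames and condition ids
#'   as colnames.  All entries must be finite.
#' @param reference_label Condition id or pooled-reference tag the ratios
#'   are relative to.
#' @return An object of class `expression_ratios`.
#' @export
expression_ratios <- function(values, reference_label = "reference") {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values))) {
    abort("`values` must be a finite numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene rownames and condition colnames.")
  }
  structure(
    list(
      values = values,
      gene_ids = rownames(values),
      condition_ids = colnames(values),
      reference_label = reference_label
    ),
    class = "expression_ratios"
  )
}

#' @export
print.expression_ratios <- function(x, ...) {
  cat(
    "<expression_ratios> ", length(x$gene_ids), " genes x ",
    length(x$condition_ids), " conditions (reference: ",
    x$reference_label, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
#' @rdname expression_ratios
#' @param x An `expression_ratios` object.
#' @param ... Unused.
#' @method tidy expression_ratios
tidy.expression_ratios <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "condition", values_to = "log2_ratio")
}

#' Read / write log-ratio matrices
#'
#' TSV matrix format: first column `gene`, remaining columns one per
#' condition.  The reference label travels in a `# reference:` comment line.
#'
#' @param path File path.
#' @export
read_expression_ratios <- function(path) {
  first <- readLines(path, n = 1)
  ref <- if (startsWith(first, "# reference:")) {
    trimws(sub("^# reference:", "", first))
  } else {
    "reference"
  }
  tbl <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ))
  values <- as.matrix(tbl[-1])
  rownames(values) <- tbl$gene
  expression_ratios(values, reference_label = ref)
}

#' @rdname read_expression_ratios
#' @param ratios An [expression_ratios()] object.
#' @export
write_expression_ratios <- function(ratios, path) {
  stopifnot(inherits(ratios, "expression_ratios"))
  writeLines(paste0("# reference: ", ratios$reference_label), path)
  readr::write_tsv(
    tibble::as_tibble(ratios$values, rownames = "gene"), path,
    append = TRUE, col_names = TRUE
  )
  invisible(path)
}

#' Collapse probe-level expression to gene level
#'
#' Expression platforms often interrogate a gene with several probesets;
#' a gene's expression is then taken as the arithmetic mean of its probes'
#' rows.  A probe mapping to more than one gene is an error rather than
#' being silently averaged into both.
#'
#' @param expr A data frame whose first column is the probe id and whose
#'   remaining columns are numeric sample values.
#' @param probe_map A data frame with columns `probe`, `gene`.
#' @return A tibble: first column `gene`, remaining columns the per-gene
#'   mean of the mapped probe rows.
#' @export
#' @examples
#' expr <- data.frame(probe = c("p1", "p2"), s1 = c(1, 3), s2 = c(2, 6))
#' map <- data.frame(probe = c("p1", "p2"), gene = c("g", "g"))
#' average_probesets(expr, map)
average_probesets <- function(expr, probe_map) {
  expr <- tibble::as_tibble(expr)
  probe_map <- tibble::as_tibble(probe_map)
  if (!all(c("probe", "gene") %in% names(probe_map))) {
    abort("`probe_map` must have columns `probe` and `gene`.")
  }
  multi <- probe_map |>
    dplyr::distinct(.data$probe, .data$gene) |>
    dplyr::count(.data$probe) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(paste0(
      "Probe(s) mapped to multiple genes: ",
      paste(multi$probe, collapse = ", ")
    ))
  }
  names(expr)[1] <- "probe"
  expr |>
    dplyr::inner_join(dplyr::distinct(probe_map), by = "probe") |>
    dplyr::select(-"probe") |>
    dplyr::summarise(
      dplyr::across(dplyr::where(is.numeric), mean),
      .by = "gene"
    )
}

#' Condition-averaged log2 ratios from single-channel expression
#'
#' Biological replicate arrays are averaged first, on the linear scale,
#' before ratios are formed; averaging before taking logs damps extreme
#' individual log-ratios.  Each non-reference condition group contributes
#' one column: `E[g, c] = log2(mean_c(g) / mean_ref(g))`.
#'
#' @param expr A data frame: first column gene id, remaining columns one
#'   per sample, strictly positive linear-scale values (set
#'   `values_are_log2 = TRUE` for log2 input, which is unlogged before
#'   averaging).
#' @param design A data frame with columns `sample`, `group` mapping sample
#'   columns to condition groups.
#' @param reference Name of the reference group (must be non-empty in
#'   `design`).
#' @param values_are_log2 Whether `expr` values are on the log2 scale.
#' @return An [expression_ratios()] with one column per non-reference group.
#' @export
#' @examples
#' expr <- data.frame(gene = "g1", a1 = 2, a2 = 4, r1 = 1, r2 = 1)
#' design <- data.frame(
#'   sample = c("a1", "a2", "r1", "r2"),
#'   group = c("trt", "trt", "ctl", "ctl")
#' )
#' to_log_ratios(expr, design, reference = "ctl")$values
to_log_ratios <- function(expr, design, reference, values_are_log2 = FALSE) {
  expr <- tibble::as_tibble(expr)
  design <- tibble::as_tibble(design)
  if (!all(c("sample", "group") %in% names(design))) {
    abort("`design` must have columns `sample` and `group`.")
  }
  if (!reference %in% design$group) abort("Empty reference group.")
  groups <- split(design$sample, design$group)
  if (any(lengths(groups) == 0)) abort("Empty replicate group in `design`.")
  missing <- setdiff(design$sample, names(expr))
  if (length(missing) > 0) {
    abort(paste0("Samples absent from `expr`: ", paste(missing, collapse = ", ")))
  }
  genes <- as.character(expr[[1]])
  vals <- as.matrix(expr[design$sample])
  if (values_are_log2) vals <- 2^vals
  if (any(vals <= 0)) abort("Linear-scale expression values must be strictly positive.")
  means <- vapply(
    groups, function(s) rowMeans(vals[, s, drop = FALSE]), numeric(length(genes))
  )
  if (length(genes) == 1) means <- matrix(means, nrow = 1, dimnames = list(NULL, names(groups)))
  E <- log2(means[, setdiff(names(groups), reference), drop = FALSE] /
    means[, reference])
  rownames(E) <- genes
  expression_ratios(E, reference_label = reference)
}

#' Fold-change gene filter
#'
#' Flags genes whose expression changes by at least `threshold_fold` (on the
#' linear scale) in any condition, and partitions them into up- and
#' down-regulated by the sign of the largest-magnitude change.
#'
#' @param ratios An [expression_ratios()] or a numeric log2-ratio matrix
#'   with gene rownames.
#' @param threshold_fold Linear fold-change threshold (> 1); genes pass when
#'   `|log2 ratio| >= log2(threshold_fold)` in at least one column.
#' @return A list with `genes` (tibble: gene, direction, max_abs_log2),
#'   `n_up`, `n_down`, and `summary` (tibble with counts and percentages of
#'   the passing set, percentages rounded to one decimal).
#' @export
fold_change_filter <- function(ratios, threshold_fold = 2) {
  if (threshold_fold <= 1) abort("`threshold_fold` must be greater than 1.")
  E <- if (inherits(ratios, "expression_ratios")) ratios$values else as.matrix(ratios)
  cut <- log2(threshold_fold)
  amax <- apply(E, 1, function(r) r[which.max(abs(r))])
  pass <- abs(amax) >= cut & amax != 0
  genes <- tibble::tibble(
    gene = rownames(E)[pass],
    direction = ifelse(amax[pass] > 0, "up", "down"),
    max_abs_log2 = abs(amax[pass])
  )
  genes <- dplyr::arrange(genes, dplyr::desc(.data$max_abs_log2))
  n_up <- sum(genes$direction == "up")
  n_down <- sum(genes$direction == "down")
  total <- n_up + n_down
  list(
    genes = genes, n_up = n_up, n_down = n_down,
    summary = tibble::tibble(
      direction = c("up", "down"),
      n = c(n_up, n_down),
      percent = if (total > 0) round(100 * c(n_up, n_down) / total, 1) else c(NA_real_, NA_real_)
    )
  )
}
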