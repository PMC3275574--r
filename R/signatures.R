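#' Hierarchical clustering of samples by TFA signature
#'
#' Samples are compared with the uncentered-correlation (cosine) metric,
#' `d(x, y) = 1 - sum(x * y) / (||x|| * ||y||)`, which ignores per-sample
#' positive rescaling but is sensitive to the sign pattern of the
#' activities, and merged by complete linkage.  Cutting the tree at `k`
#' yields the sample groups used for status association.
#'
#' @param tfa Numeric TFs-by-samples matrix (e.g. `fit$P` with cohort
#'   samples as conditions), or its tidy three-column equivalent
#'   (`tf`, `sample`/`condition`, value).
#' @param k Number of groups to cut into (tumor cohorts commonly separate
#'   into three).
#' @return An object of class `tfa_clusters`: list with `hclust` (the
#'   linkage record), `groups` (named integer vector, groups numbered by
#'   order of first appearance in the dendrogram so that group 1 is the
#'   leftmost cluster), `k` and `metric`.
#' @export
cluster_samples <- function(tfa, k = 3) {
  tfa <- as_tfa_matrix(tfa)
  n <- ncol(tfa)
  if (k > n) abort("`k` cannot exceed the number of samples.")
  nrm <- sqrt(colSums(tfa^2))
  if (any(nrm == 0)) {
    abort(paste0(
      "All-zero sample vector(s): ",
      paste(colnames(tfa)[nrm == 0], collapse = ", ")
    ))
  }
  cosine <- crossprod(sweep(tfa, 2, nrm, "/"))
  d <- as.dist(1 - cosine)
  hc <- hclust(d, method = "complete")
  raw <- cutree(hc, k = k)
  ## renumber groups in dendrogram (leaf) order for a stable convention
  ord <- unique(raw[hc$order])
  groups <- setNames(match(raw, ord), names(raw))
  structure(
    list(hclust = hc, groups = groups, k = k, metric = "uncentered_correlation"),
    class = "tfa_clusters"
  )
}

as_tfa_matrix <- function(tfa) {
  if (is.data.frame(tfa)) {
    stopifnot(ncol(tfa) == 3)
    wide <- tidyr::pivot_wider(
      tfa,
      names_from = dplyr::all_of(names(tfa)[2]),
      values_from = dplyr::all_of(names(tfa)[3])
    )
    m <- as.matrix(wide[-1])
    rownames(m) <- wide[[1]]
    return(m)
  }
  as.matrix(tfa)
}

#' @export
print.tfa_clusters <- function(x, ...) {
  cat(
    "<tfa_clusters> ", length(x$groups), " samples in ", x$k,
    " groups (", x$metric, ", complete linkage)\n",
    sep = ""
  )
  print(table(group = x$groups))
  invisible(x)
}

#' @export
#' @rdname cluster_samples
#' @param x A `tfa_clusters` object.
#' @param ... Unused.
#' @method tidy tfa_clusters
tidy.tfa_clusters <- function(x, ...) {
  tibble::tibble(sample = names(x$groups), group = unname(x$groups))
}

#' Chi-squared association of cluster groups with a binary status
#'
#' Tests whether membership in group 1 versus the pooled remaining groups
#' is associated with a binary status label (e.g. a pathway functional versus
#' deficient) using the Pearson chi-squared test on the 2x2 table, one
#' degree of freedom, without continuity correction.
#'
#' @param groups Group labels per sample (integer or factor), e.g.
#'   `tfa_clusters$groups`; samples with `NA` status are excluded.
#' @param status Binary status labels aligned with `groups`.
#' @param group1 The group compared against the pooled rest (default the
#'   first group level, i.e. group 1).
#' @return A tibble with `chi2`, `df`, `p`, `log10p` and the 2x2 table as
#'   attribute `"table"`.
#' @export
#' @examples
#' associate_status(rep(1:2, each = 10), rep(c("neg", "pos"), each = 10))
associate_status <- function(groups, status, group1 = NULL) {
  keep <- !is.na(groups) & !is.na(status)
  groups <- groups[keep]
  status <- status[keep]
  if (length(unique(groups)) < 2) abort("Need at least 2 groups.")
  if (length(unique(status)) != 2) abort("`status` must have exactly two observed levels.")
  if (is.null(group1)) group1 <- sort(unique(groups))[1]
  side <- factor(
    ifelse(groups == group1, "group1", "rest"),
    levels = c("group1", "rest")
  )
  tab <- table(side, status = factor(status))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Undefined test: a zero marginal in the 2x2 table.")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  out <- tibble::tibble(
    chi2 = unname(ct$statistic), df = unname(ct$parameter),
    p = ct$p.value, log10p = log10(ct$p.value)
  )
  attr(out, "table") <- tab
  out
}

#' Per-TF two-sample t-tests between status groups
#'
#' Compares each TF's activities between two sample groups with a
#' two-sample t-test (pooled-variance Student test by default, Welch with
#' `var_equal = FALSE`), and marks significance at the conventional
#' 0.05 / 0.001 / 1e-4 levels.
#'
#' @param tfa TFs-by-samples matrix (or tidy equivalent, see
#'   [cluster_samples()]).
#' @param samples_a,samples_b Column names (or logical/integer indices) of
#'   the two groups; each needs at least 2 samples.
#' @param var_equal Pooled-variance test if `TRUE` (default), Welch
#'   otherwise.
#' @return A tibble with columns `tf`, `mean_a`, `mean_b`, `t`, `p`,
#'   `mark` (`""`, `"*"` p<0.05, `"**"` p<0.001, `"***"` p<1e-4) and
#'   `degenerate` (both groups constant: `t`/`p` are `NA` and flagged).
#' @export
tfa_ttest <- function(tfa, samples_a, samples_b, var_equal = TRUE) {
  tfa <- as_tfa_matrix(tfa)
  a <- tfa[, samples_a, drop = FALSE]
  b <- tfa[, samples_b, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) abort("Need at least 2 samples per group.")
  res <- purrr::map(rownames(tfa), function(t) {
    x <- a[t, ]
    y <- b[t, ]
    if (var(x) == 0 && var(y) == 0) {
      return(tibble::tibble(
        tf = t, mean_a = mean(x), mean_b = mean(y),
        t = NA_real_, p = NA_real_, degenerate = TRUE
      ))
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    tibble::tibble(
      tf = t, mean_a = mean(x), mean_b = mean(y),
      t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE
    )
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(
      mark = dplyr::case_when(
        is.na(.data$p) ~ NA_character_,
        .data$p < 1e-4 ~ "***",
        .data$p < 0.001 ~ "**",
        .data$p < 0.05 ~ "*",
        TRUE ~ ""
      ),
      .before = "degenerate"
    )
}

#' Derive a status signature of differentially active TFs
#'
#' TFs whose activities differ between the two status groups at
#' `p < alpha`; the default cutoff 1e-4 selects a compact signature
#' suitable for cross-cohort prediction.
#'
#' @inheritParams tfa_ttest
#' @param status Binary status labels per sample (vector aligned with the
#'   columns of `tfa`, or named); samples with `NA` status are excluded.
#' @param alpha Selection cutoff (default `1e-4`).
#' @return A tibble of selected TFs (`tf`, `t`, `p`), sorted by `p`.
#' @export
derive_status_signature <- function(tfa, status, alpha = 1e-4, var_equal = TRUE) {
  tfa <- as_tfa_matrix(tfa)
  if (!is.null(names(status))) status <- status[colnames(tfa)]
  keep <- !is.na(status)
  lev <- unique(status[keep])
  if (length(lev) != 2) abort("`status` must have exactly two observed levels.")
  tt <- tfa_ttest(
    tfa[, keep, drop = FALSE],
    which(status[keep] == lev[1]), which(status[keep] == lev[2]),
    var_equal = var_equal
  )
  tt |>
    dplyr::filter(!is.na(.data$p), .data$p < alpha) |>
    dplyr::arrange(.data$p) |>
    dplyr::select("tf", "t", "p")
}

#' Pairwise TFA co-activity structure
#'
#' Absolute Pearson correlation between every pair of TF activity profiles
#' across samples, with rows and columns reordered by hierarchical
#' clustering of the correlation matrix so that co-active TF groups sit
#' together.
#'
#' @param tfa TFs-by-samples matrix (or tidy equivalent); needs >= 3
#'   samples.
#' @return An object of class `tfa_correlation`: list with `abs_r`
#'   (symmetric matrix, unit diagonal, ordered), `order` (TF ordering) and
#'   `constant_tfs` (TFs with zero variance, excluded and flagged).
#' @export
tfa_correlation <- function(tfa) {
  tfa <- as_tfa_matrix(tfa)
  if (ncol(tfa) < 3) abort("Need at least 3 samples.")
  v <- apply(tfa, 1, var)
  constant <- rownames(tfa)[v == 0]
  if (length(constant) > 0) {
    warn(paste0(
      "Constant TFA row(s) excluded (correlation undefined): ",
      paste(constant, collapse = ", ")
    ))
    tfa <- tfa[v > 0, , drop = FALSE]
  }
  r <- abs(cor(t(tfa)))
  ord <- if (nrow(r) > 2) {
    hclust(as.dist(1 - r), method = "complete")$order
  } else {
    seq_len(nrow(r))
  }
  structure(
    list(
      abs_r = r[ord, ord, drop = FALSE],
      order = rownames(r)[ord],
      constant_tfs = constant
    ),
    class = "tfa_correlation"
  )
}

#' @export
print.tfa_correlation <- function(x, ...) {
  cat(
    "<tfa_correlation> ", nrow(x$abs_r), " TFs; mean off-diagonal |r| = ",
    round(mean(x$abs_r[upper.tri(x$abs_r)]), 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
#' @rdname tfa_correlation
#' @param object A `tfa_correlation`.
#' @param ... Unused.
#' @method autoplot tfa_correlation
autoplot.tfa_correlation <- function(object, ...) {
  tibble::as_tibble(object$abs_r, rownames = "tf1") |>
    tidyr::pivot_longer(-"tf1", names_to = "tf2", values_to = "abs_r") |>
    dplyr::mutate(
      tf1 = factor(.data$tf1, levels = object$order),
      tf2 = factor(.data$tf2, levels = object$order)
    ) |>
    ggplot2::ggplot(ggplot2::aes(.data$tf1, .data$tf2, fill = .data$abs_r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "red", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "|r|") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Center activities on a reference sample set
#'
#' Subtracts, per TF, the mean activity over reference samples (e.g. normal
#' tissue), so that heatmap values show the direction of variation relative
#' to the reference average.
#'
#' @param tfa TFs-by-samples matrix (or tidy equivalent).
#' @param reference_samples Column names or indices of the reference
#'   samples (non-empty).
#' @return The centered matrix.
#' @export
normalize_to_reference <- function(tfa, reference_samples) {
  tfa <- as_tfa_matrix(tfa)
  ref <- tfa[, reference_samples, drop = FALSE]
  if (ncol(ref) == 0) abort("Empty reference sample set.")
  sweep(tfa, 1, rowMeans(ref), "-")
}
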