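#' Null TFA distributions from random-gene networks
#'
#' Calibrates the magnitude of deduced TF activities against what the same
#' network structure yields on unrelated genes: for each of `n_networks`
#' random networks, every pattern gene's expression row is replaced by a
#' row sampled (without replacement within a draw, with replacement across
#' draws) from a background gene pool, and the decomposition is refitted
#' with identical options.  The collected activities form, per TF and
#' condition, the null distribution against which observed TFAs are
#' standardized by [modified_zscore()].
#'
#' @inheritParams trim_network
#' @param n_networks Number of random networks (default 200).
#' @param seed Integer seed.
#' @param tol,max_iter,n_restarts,ridge Fit options; for the null to be
#'   comparable these must equal the options used for the observed fit
#'   (the defaults match [nca_decompose()]).
#' @return An object of class `tfa_null`: list with `values` (array TFs x
#'   conditions x networks), `n_networks`, `seed`.
#' @export
build_null <- function(pool, pattern, n_networks = 200, seed = 1,
                       tol = 1e-6, max_iter = 1000, n_restarts = 3,
                       ridge = 0) {
  stopifnot(inherits(pattern, "connectivity_pattern"))
  pool <- as.matrix(pool)
  M <- pattern_matrix(pattern)
  if (nrow(pool) < nrow(M)) {
    abort("Background pool must have at least as many genes as the pattern.")
  }
  idrep <- check_identifiability(pattern, n_conditions = ncol(pool))
  if (!idrep$identifiable) {
    abort(paste0(
      "Pattern is not identifiable; null TFAs would not be comparable (TFs: ",
      paste(idrep$failing_tfs, collapse = ", "), ")."
    ))
  }
  withr::local_seed(seed)
  vals <- array(
    NA_real_, c(ncol(M), ncol(pool), n_networks),
    dimnames = list(colnames(M), colnames(pool), NULL)
  )
  for (b in seq_len(n_networks)) {
    En <- pool[sample(nrow(pool), nrow(M)), , drop = FALSE]
    rownames(En) <- rownames(M)
    f <- nca_decompose(
      En, pattern,
      tol = tol, max_iter = max_iter,
      n_restarts = n_restarts, ridge = ridge, check = FALSE
    )
    vals[, , b] <- f$P
  }
  structure(
    list(values = vals, n_networks = n_networks, seed = seed),
    class = "tfa_null"
  )
}

#' @export
print.tfa_null <- function(x, ...) {
  cat(
    "<tfa_null> ", dim(x$values)[1], " TFs x ", dim(x$values)[2],
    " conditions, ", x$n_networks, " random networks (seed ", x$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Robust modified z-score against a null sample
#'
#' Standardizes an observation against the median and the median absolute
#' deviation (MAD) of a null sample rather than its mean and standard
#' deviation, to resist outliers:
#' `z = 0.6745 * (x - median(null)) / MAD(null)`, where 0.6745 is the
#' standard consistency constant making `z` comparable to a normal z-score.
#' The two-tailed p-value is `2 * (1 - pnorm(|z|))`.
#'
#' @param x Observed value(s); vectorized.
#' @param null_values Numeric null sample (at least 10 values).
#' @param empirical Use the empirical two-sided tail fraction of the null
#'   instead of the normal tail (with the +1 correction that bounds p away
#'   from zero).
#' @return A tibble with columns `z`, `p`, `degenerate`.  A null sample
#'   with `MAD = 0` is degenerate: `z` is infinite and `p` is reported as 0
#'   with `degenerate = TRUE` rather than silently.
#' @export
#' @examples
#' modified_zscore(2, c(-1, -0.5, 0, 0.5, 1, -0.2, 0.2, 0.7, -0.7, 0.1))
modified_zscore <- function(x, null_values, empirical = FALSE) {
  null_values <- null_values[is.finite(null_values)]
  if (length(null_values) < 10) abort("Need at least 10 null values.")
  m <- median(null_values)
  mad0 <- median(abs(null_values - m))
  if (mad0 == 0) {
    warn("Degenerate null sample (MAD = 0).")
    return(tibble::tibble(
      z = ifelse(x == m, 0, Inf * sign(x - m)),
      p = ifelse(x == m, 1, 0),
      degenerate = TRUE
    ))
  }
  z <- 0.6745 * (x - m) / mad0
  p <- if (empirical) {
    vapply(x, function(xi) {
      (1 + sum(abs(null_values - m) >= abs(xi - m))) / (1 + length(null_values))
    }, numeric(1))
  } else {
    2 * pnorm(-abs(z))
  }
  tibble::tibble(z = z, p = p, degenerate = FALSE)
}

#' Significance of observed TFAs against the random-network null
#'
#' @param fit An `nca_fit`.
#' @param null A `tfa_null` built with [build_null()] on the same pattern
#'   and fit options.
#' @param empirical Passed to [modified_zscore()].
#' @return A tibble of class `tfa_significance` with columns `tf`,
#'   `condition`, `tfa`, `z`, `p`, `degenerate`.
#' @export
tfa_significance <- function(fit, null, empirical = FALSE) {
  stopifnot(inherits(fit, "nca_fit"), inherits(null, "tfa_null"))
  tfs <- rownames(fit$P)
  conds <- colnames(fit$P)
  if (!identical(dim(fit$P), dim(null$values)[1:2])) {
    abort("Fit and null dimensions disagree.")
  }
  out <- tidyr::expand_grid(tf = tfs, condition = conds)
  res <- purrr::pmap(out, function(tf, condition) {
    dplyr::bind_cols(
      tibble::tibble(tfa = fit$P[tf, condition]),
      modified_zscore(
        fit$P[tf, condition], null$values[tf, condition, ],
        empirical = empirical
      )
    )
  })
  out <- dplyr::bind_cols(out, dplyr::bind_rows(res))
  attr(out, "n_networks") <- null$n_networks
  attr(out, "consistency_constant") <- 0.6745
  attr(out, "tail") <- if (empirical) "empirical" else "normal"
  class(out) <- c("tfa_significance", class(out))
  out
}

#' Select perturbed TFs
#'
#' A TF is called perturbed when its activity is significant (`p < alpha`)
#' in at least one condition; selected TFs are ordered by their minimum
#' p-value.  No multiple-testing correction is applied by default; set
#' `adjust = "BH"` for a Benjamini-Hochberg-adjusted selection.
#'
#' @param sig A `tfa_significance` table.
#' @param alpha Two-tailed significance cutoff in (0, 1); default 0.05.
#' @param adjust `"none"` (default) or a method accepted by
#'   [stats::p.adjust()], applied across all TF-condition cells.
#' @return A tibble with columns `tf`, `min_p`, sorted by `min_p`.
#' @export
select_perturbed_tfs <- function(sig, alpha = 0.05, adjust = "none") {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  p <- if (adjust == "none") sig$p else stats::p.adjust(sig$p, method = adjust)
  sig |>
    dplyr::mutate(.p = p) |>
    dplyr::summarise(min_p = min(.data$.p), .by = "tf") |>
    dplyr::filter(.data$min_p < alpha) |>
    dplyr::arrange(.data$min_p)
}

#' @export
#' @rdname tfa_significance
#' @param object A `tfa_significance` table.
#' @param alpha Cutoff drawn as a reference line.
#' @param ... Unused.
#' @method autoplot tfa_significance
autoplot.tfa_significance <- function(object, alpha = 0.05, ...) {
  object |>
    dplyr::mutate(log10p = -log10(pmax(.data$p, 1e-300))) |>
    ggplot2::ggplot(ggplot2::aes(.data$tf, .data$log10p, fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Persist a null distribution to TSV for audit
#'
#' @param null A `tfa_null`.
#' @param path Output TSV path (columns `tf`, `condition`, `network`,
#'   `tfa`).
#' @export
write_null <- function(null, path) {
  stopifnot(inherits(null, "tfa_null"))
  d <- dim(null$values)
  tbl <- tidyr::expand_grid(
    network = seq_len(d[3]),
    condition = dimnames(null$values)[[2]],
    tf = dimnames(null$values)[[1]]
  )
  tbl$tfa <- null$values[cbind(
    match(tbl$tf, dimnames(null$values)[[1]]),
    match(tbl$condition, dimnames(null$values)[[2]]),
    tbl$network
  )]
  readr::write_tsv(tbl[c("tf", "condition", "network", "tfa")], path)
  invisible(path)
}
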