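#' Network component analysis by alternating least squares
#'
#' Fits the log-linear model `E = A %*% P` in which a gene's log expression
#' ratio is proportional to the log activity ratios of its regulators: `A`
#' (genes x TFs) holds control strengths, constrained to zero off the
#' connectivity pattern, and `P` (TFs x conditions) holds the deduced TF
#' activities (TFAs).  Estimation alternates an unconstrained least-squares
#' activity step with per-gene least-squares strength steps restricted to
#' each gene's regulator set, which makes the Frobenius residual
#' non-increasing.  Because the model is bilinear and non-convex, the fit
#' is repeated from an SVD-based ridge projection plus `n_restarts - 1`
#' random on-pattern initializations, keeping the best residual.
#'
#' Scale and sign per TF are inherently indeterminate (any sign-respecting
#' diagonal rescaling of `A` and its inverse on `P` reproduces `E`), so on
#' exit each column of `A` is normalized to unit Euclidean norm with its
#' largest-magnitude entry positive; the scale and sign are absorbed into
#' `P`.
#'
#' @param E An [expression_ratios()] or a numeric matrix with gene rownames.
#' @param pattern A [connectivity_pattern()].  Genes present in `E` but
#'   absent from the pattern are ignored (a count is reported); TFs with no
#'   surviving targets are dropped.  Non-identifiable patterns produce a
#'   warning and a best-effort fit.
#' @param tol Convergence tolerance on the change in Frobenius residual
#'   relative to `||E||_F`.
#' @param max_iter Maximum alternating iterations per restart.
#' @param n_restarts Number of initializations (>= 1).
#' @param ridge Relative Tikhonov regularization strength (>= 0, default 0
#'   = exact alternating least squares).  The absolute penalty added to the
#'   squared loss is `ridge * mean(E^2) * (||A||_F^2 + ||P||_F^2)`.  A small
#'   positive value (e.g. 0.1-1) suppresses a degeneracy of the
#'   unregularized fit on weakly informative data: two TFs sharing target
#'   genes can drift into near-parallel strength columns with huge
#'   cancelling activities that improve the residual negligibly.  Null
#'   calibration ([build_null()]) must use the same value as the observed
#'   fit.
#' @param seed Optional integer seed for the random restarts.
#' @param check Set `FALSE` to skip the identifiability check (used
#'   internally for repeated null fits on a pattern already verified).
#' @return An object of class `nca_fit`: list with `A`, `P`,
#'   `residual_fro`, `n_iter`, `converged`, `pattern` (the pattern actually
#'   used) and `options`.
#' @export
#' @examples
#' sim <- simulate_nca_dataset(
#'   n_tfs = 4, n_genes = 24, targets_per_tf = 4,
#'   n_conditions = 8, n_perturbed = 0, noise_sd = 0, seed = 1
#' )
#' fit <- nca_decompose(sim$expr, sim$pattern, seed = 1)
#' glance(fit)
nca_decompose <- function(E, pattern, tol = 1e-6, max_iter = 1000,
                          n_restarts = 3, ridge = 0, seed = NULL,
                          check = TRUE) {
  if (ridge < 0) abort("`ridge` must be non-negative.")
  stopifnot(inherits(pattern, "connectivity_pattern"))
  Em <- if (inherits(E, "expression_ratios")) E$values else as.matrix(E)
  if (!all(is.finite(Em))) abort("Non-finite values in expression input.")
  if (is.null(rownames(Em))) abort("Expression matrix must have gene rownames.")

  common <- intersect(rownames(Em), pattern$gene_ids)
  if (length(common) == 0) {
    abort("No overlap between expression genes and pattern genes.")
  }
  n_ignored <- nrow(Em) - length(common)
  if (n_ignored > 0) {
    inform(paste0(n_ignored, " expression gene(s) absent from the pattern ignored."))
  }
  pat <- subset_pattern(pattern, genes = common)
  if (length(pat$tf_ids) < length(pattern$tf_ids)) {
    inform(paste0(
      "Dropped TF(s) with no surviving targets: ",
      paste(setdiff(pattern$tf_ids, pat$tf_ids), collapse = ", ")
    ))
  }
  Em <- Em[pat$gene_ids, , drop = FALSE]
  M <- pattern_matrix(pat)

  if (check) {
    idrep <- check_identifiability(pat, n_conditions = ncol(Em))
    if (!idrep$identifiable) {
      warn(paste0(
        "Pattern is not structurally identifiable (TFs: ",
        paste(idrep$failing_tfs, collapse = ", "),
        "); returning a best-effort fit."
      ))
    }
  }

  opts <- list(
    tol = tol, max_iter = max_iter, n_restarts = n_restarts, ridge = ridge,
    seed = seed
  )
  if (all(Em == 0)) {
    A <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
    P <- matrix(0, ncol(M), ncol(Em), dimnames = list(colnames(M), colnames(Em)))
    return(new_nca_fit(A, P, 0, 0L, TRUE, pat, opts))
  }

  if (!is.null(seed)) withr::local_seed(seed)
  mask <- matrix(as.integer(M), nrow(M))
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    A0 <- if (r == 1) init_svd_ridge(Em, M) else init_random(M)
    f <- als_engine(Em, mask, A0, tol, max_iter, ridge * mean(Em^2))
    if (is.null(best) || f$residual < best$residual) best <- f
  }

  A <- best$A
  P <- best$P
  dimnames(A) <- dimnames(M)
  dimnames(P) <- list(colnames(M), colnames(Em))
  norms <- sqrt(colSums(A^2))
  sgn <- apply(A, 2, function(a) {
    s <- sign(a[which.max(abs(a))])
    if (s == 0) 1 else s
  })
  sc <- ifelse(norms > 0, norms, 1) * sgn
  A <- sweep(A, 2, sc, "/")
  P <- sweep(P, 1, sc, "*")
  A[!M] <- 0 # exact zeros off-pattern

  new_nca_fit(A, P, best$residual, best$n_iter, best$converged, pat, opts)
}

new_nca_fit <- function(A, P, residual, n_iter, converged, pattern, options) {
  structure(
    list(
      A = A, P = P, residual_fro = residual, n_iter = as.integer(n_iter),
      converged = converged, pattern = pattern, options = options
    ),
    class = "nca_fit"
  )
}

## SVD-based initialization: P0 from the leading singular triplets (padded
## with small noise when there are fewer conditions than TFs), then a
## ridge-regularized per-gene projection of E onto the pattern support.
init_svd_ridge <- function(E, M) {
  n_tfs <- ncol(M)
  k <- min(n_tfs, nrow(E), ncol(E))
  sv <- svd(E, nu = k, nv = k)
  P0 <- diag(sv$d[seq_len(k)], k) %*% t(sv$v)
  if (k < n_tfs) {
    P0 <- rbind(P0, matrix(rnorm((n_tfs - k) * ncol(E), 0, 0.01), n_tfs - k))
  }
  lam <- 1e-6 * sum(P0^2) / nrow(P0)
  A0 <- matrix(0, nrow(E), n_tfs)
  for (g in seq_len(nrow(E))) {
    idx <- which(M[g, ])
    Ps <- P0[idx, , drop = FALSE]
    A0[g, idx] <- solve(
      tcrossprod(Ps) + lam * diag(length(idx)),
      Ps %*% E[g, ]
    )
  }
  A0
}

init_random <- function(M) {
  A0 <- matrix(0, nrow(M), ncol(M))
  A0[M] <- rnorm(sum(M))
  A0
}

#' @export
print.nca_fit <- function(x, ...) {
  cat(
    "<nca_fit> ", ncol(x$A), " TFs, ", nrow(x$A), " genes, ", ncol(x$P),
    " conditions\n  residual (Frobenius): ", format(x$residual_fro),
    ", iterations: ", x$n_iter, ", converged: ", x$converged, "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a fitted decomposition
#'
#' @param x An `nca_fit`.
#' @param matrix `"activities"` for the TFA matrix `P` (one row per TF and
#'   condition) or `"strengths"` for the on-pattern control strengths of
#'   `A`.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method tidy nca_fit
tidy.nca_fit <- function(x, matrix = c("activities", "strengths"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "activities") {
    tibble::as_tibble(x$P, rownames = "tf") |>
      tidyr::pivot_longer(-"tf", names_to = "condition", values_to = "tfa")
  } else {
    M <- pattern_matrix(x$pattern)
    idx <- which(M, arr.ind = TRUE)
    tibble::tibble(
      gene = rownames(M)[idx[, 1]],
      tf = colnames(M)[idx[, 2]],
      strength = x$A[idx]
    )
  }
}

#' @export
#' @rdname tidy.nca_fit
#' @method glance nca_fit
glance.nca_fit <- function(x, ...) {
  tibble::tibble(
    residual_fro = x$residual_fro, n_iter = x$n_iter,
    converged = x$converged,
    n_tfs = ncol(x$A), n_genes = nrow(x$A), n_conditions = ncol(x$P)
  )
}

#' @export
#' @rdname tidy.nca_fit
#' @param object An `nca_fit`.
#' @method autoplot nca_fit
autoplot.nca_fit <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$condition, .data$tf, fill = .data$tfa)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "TFA") +
    ggplot2::theme_minimal()
}

#' Compare recovered activities to a simulated ground truth
#'
#' Because the decomposition is determined only up to a per-TF scale and
#' sign, recovery is quantified by the absolute Pearson correlation between
#' each recovered activity row and the corresponding true row.
#'
#' @param fit An `nca_fit`.
#' @param sim An `nca_simulation` (or a matrix of true activities with TF
#'   rownames).
#' @return A tibble with columns `tf`, `abs_r`.
#' @export
tfa_recovery <- function(fit, sim) {
  P_true <- if (inherits(sim, "nca_simulation")) sim$P_true else as.matrix(sim)
  tfs <- intersect(rownames(fit$P), rownames(P_true))
  tibble::tibble(
    tf = tfs,
    abs_r = vapply(
      tfs, function(t) abs(cor(fit$P[t, ], P_true[t, ])), numeric(1)
    )
  )
}

#' Export a fitted decomposition to TSV/JSON files
#'
#' Writes the on-pattern control strengths (`gene`, `tf`, `strength`), the
#' activity matrix (`tf`, `condition`, `tfa`) and a JSON fit summary.
#'
#' @param fit An `nca_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_nca_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "nca_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tidy(fit, "strengths"), file.path(dir, "strengths.tsv"))
  readr::write_tsv(tidy(fit, "activities"), file.path(dir, "activities.tsv"))
  jsonlite::write_json(
    c(glance(fit), fit$options[c("tol", "max_iter", "n_restarts", "seed")]),
    file.path(dir, "fit.json"),
    auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(dir)
}
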