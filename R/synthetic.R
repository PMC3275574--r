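#' Simulate an identifiable connectivity pattern
#'
#' Builds a sparse TF-to-gene pattern that is identifiable by construction:
#' each TF receives one *exclusive* target gene (a gene regulated by that TF
#' alone), which guarantees the structural rank conditions checked by
#' [check_identifiability()], and the remaining targets are drawn at random
#' from a shared gene pool.  Genes left without a regulator are attached to
#' a random TF, so every gene has at least one regulator.
#'
#' @param n_tfs,n_genes Number of TFs and genes.  `n_genes` must be at least
#'   `2 * n_tfs` so that exclusive targets leave a usable shared pool.
#' @param targets_per_tf Targets drawn per TF (>= 2); must not exceed
#'   `n_genes - n_tfs + 1`.
#' @param seed Integer seed; the same seed reproduces the pattern exactly.
#' @return A [connectivity_pattern()].
#' @export
#' @examples
#' simulate_pattern(5, 40, 4, seed = 1)
simulate_pattern <- function(n_tfs, n_genes, targets_per_tf, seed) {
  if (n_genes < 2 * n_tfs) {
    abort("Infeasible size: `n_genes` must be at least 2 * `n_tfs`.")
  }
  if (targets_per_tf < 2) abort("`targets_per_tf` must be at least 2.")
  if (targets_per_tf - 1 > n_genes - n_tfs) {
    abort("Infeasible size: not enough shared genes for `targets_per_tf`.")
  }
  withr::local_seed(seed)
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  shared <- (n_tfs + 1):n_genes
  edges <- vector("list", n_tfs)
  for (t in seq_len(n_tfs)) {
    tgt <- c(t, sample(shared, targets_per_tf - 1))
    edges[[t]] <- tibble::tibble(gene = gene_ids[tgt], tf = tf_ids[t])
  }
  edges <- dplyr::bind_rows(edges)
  orphan <- setdiff(gene_ids, edges$gene)
  if (length(orphan) > 0) {
    edges <- dplyr::bind_rows(
      edges,
      tibble::tibble(gene = orphan, tf = sample(tf_ids, length(orphan), replace = TRUE))
    )
  }
  edges$evidence <- "experimental"
  connectivity_pattern(edges, tf_ids = tf_ids, gene_ids = gene_ids)
}

#' Simulate a ground-truth regulatory dataset
#'
#' Generates control strengths, TF activities, log-ratio expression and a
#' background gene pool under the log-linear model `E = A %*% P + noise`.
#' Control strengths are uniform on +/- \[0.5, 1.5\] (random sign) so that no
#' true edge is numerically negligible; activities of unperturbed TFs are
#' standard normal across conditions, while perturbed TFs additionally shift
#' by `effect_size` (with a random sign, constant per TF) in the second
#' condition group, emulating a two-group tumor-versus-normal contrast.
#' A fraction of pattern edges can be *spurious*: present in the
#' connectivity used for fitting but carrying a true strength of exactly
#' zero, emulating false positive interactions from high-throughput binding
#' data.  The background pool contains `pool_factor` times `n_genes`
#' unrelated noise genes (standard normal log-ratios, a variance comparable
#' to the network genes) for null-network sampling.
#'
#' @inheritParams simulate_pattern
#' @param n_conditions Number of expression columns (log-ratio contrasts).
#' @param n_perturbed Number of TFs with a planted activity shift.
#' @param effect_size Mean activity shift `delta` (>= 0) of perturbed TFs
#'   between the two condition groups, in log-ratio units.
#' @param noise_sd Standard deviation `sigma` (>= 0) of additive Gaussian
#'   measurement noise on `E`.
#' @param activity_sd Standard deviation of the baseline (unperturbed)
#'   activity variation across conditions.  The default 1 gives every TF
#'   genuine condition-to-condition activity, appropriate for recovery and
#'   clustering studies.  Set to 0 for significance studies emulating an
#'   inducible-contrast design, where TFs not targeted by the perturbation
#'   show no systematic activity change and network genes behave like
#'   background genes.
#' @param fraction_spurious Fraction of true edge count added as
#'   zero-strength pattern edges.
#' @param pool_factor Background pool size as a multiple of `n_genes`.
#' @return A list of class `nca_simulation` with elements
#'   \describe{
#'     \item{pattern}{[connectivity_pattern()] including spurious edges.}
#'     \item{A_true}{genes x TFs control strengths (zero off-pattern and on
#'       spurious edges).}
#'     \item{P_true}{TFs x conditions activity matrix.}
#'     \item{expr}{[expression_ratios()] with `E = A_true %*% P_true + noise`.}
#'     \item{pool}{background pool matrix (pool genes x conditions).}
#'     \item{perturbed_tfs, spurious_edges, group_labels, status_labels,
#'       noise_sd, seed}{ground-truth annotations.}
#'   }
#' @export
simulate_nca_dataset <- function(n_tfs = 20, n_genes = 200, targets_per_tf = 10,
                                 n_conditions = 12, n_perturbed = 4,
                                 effect_size = 2, noise_sd = 0.1,
                                 activity_sd = 1,
                                 fraction_spurious = 0, pool_factor = 10,
                                 seed = 1) {
  if (effect_size < 0) abort("`effect_size` must be non-negative.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (activity_sd < 0) abort("`activity_sd` must be non-negative.")
  if (fraction_spurious < 0 || fraction_spurious >= 1) {
    abort("`fraction_spurious` must be in [0, 1).")
  }
  if (n_perturbed > n_tfs) abort("`n_perturbed` cannot exceed `n_tfs`.")
  pattern <- simulate_pattern(n_tfs, n_genes, targets_per_tf, seed)
  withr::local_seed(seed + 1L)

  true_edges <- pattern$edges
  n_spur <- round(fraction_spurious * nrow(true_edges))
  spurious <- tibble::tibble(gene = character(0), tf = character(0))
  if (n_spur > 0) {
    M <- pattern_matrix(pattern)
    shared_genes <- pattern$gene_ids[-seq_len(n_tfs)] # keep exclusive targets clean
    cand <- expand.grid(
      gene = shared_genes, tf = pattern$tf_ids,
      stringsAsFactors = FALSE
    )
    cand <- cand[!M[cbind(cand$gene, cand$tf)], , drop = FALSE]
    pick <- cand[sample(nrow(cand), n_spur), , drop = FALSE]
    spurious <- tibble::as_tibble(pick)
    pattern <- connectivity_pattern(
      dplyr::bind_rows(true_edges, dplyr::mutate(spurious, evidence = "experimental")),
      tf_ids = pattern$tf_ids, gene_ids = pattern$gene_ids
    )
  }

  M_true <- matrix(
    FALSE, n_genes, n_tfs,
    dimnames = list(pattern$gene_ids, pattern$tf_ids)
  )
  M_true[cbind(true_edges$gene, true_edges$tf)] <- TRUE
  A <- matrix(
    0, n_genes, n_tfs,
    dimnames = list(pattern$gene_ids, pattern$tf_ids)
  )
  n_e <- sum(M_true)
  A[M_true] <- runif(n_e, 0.5, 1.5) * sample(c(-1, 1), n_e, replace = TRUE)

  cond_ids <- sprintf("cond%02d", seq_len(n_conditions))
  group_labels <- setNames(
    rep(c("A", "B"), c(ceiling(n_conditions / 2), floor(n_conditions / 2))),
    cond_ids
  )
  P <- matrix(
    rnorm(n_tfs * n_conditions, 0, activity_sd), n_tfs, n_conditions,
    dimnames = list(pattern$tf_ids, cond_ids)
  )
  perturbed <- if (n_perturbed > 0) sample(pattern$tf_ids, n_perturbed) else character(0)
  for (t in perturbed) {
    P[t, group_labels == "B"] <- P[t, group_labels == "B"] +
      effect_size * sample(c(-1, 1), 1)
  }

  E <- A %*% P + matrix(rnorm(n_genes * n_conditions, 0, noise_sd), n_genes)
  pool <- matrix(
    rnorm(pool_factor * n_genes * n_conditions), pool_factor * n_genes,
    dimnames = list(sprintf("bg%05d", seq_len(pool_factor * n_genes)), cond_ids)
  )

  structure(
    list(
      pattern = pattern, A_true = A, P_true = P,
      expr = expression_ratios(E, reference_label = "reference"),
      pool = pool,
      perturbed_tfs = perturbed, spurious_edges = spurious,
      group_labels = group_labels,
      status_labels = setNames(
        ifelse(group_labels == "B", "altered", "baseline"), cond_ids
      ),
      noise_sd = noise_sd, activity_sd = activity_sd,
      effect_size = effect_size, seed = seed
    ),
    class = "nca_simulation"
  )
}

#' @export
print.nca_simulation <- function(x, ...) {
  cat(
    "<nca_simulation> ", ncol(x$A_true), " TFs, ", nrow(x$A_true), " genes, ",
    ncol(x$P_true), " conditions; ", length(x$perturbed_tfs),
    " perturbed TF(s), ", nrow(x$spurious_edges), " spurious edge(s), sigma = ",
    x$noise_sd, "\n",
    sep = ""
  )
  invisible(x)
}

#' True activities as a tidy table
#'
#' Sidecar table (TF, condition, activity) used by recovery tests.
#'
#' @param x An `nca_simulation`.
#' @param ... Unused.
#' @export
#' @method tidy nca_simulation
tidy.nca_simulation <- function(x, ...) {
  tibble::as_tibble(x$P_true, rownames = "tf") |>
    tidyr::pivot_longer(-"tf", names_to = "condition", values_to = "activity")
}

#' Simulate a TFA cohort with planted sample blocks
#'
#' Builds a TFs-by-samples activity matrix with two sample blocks that
#' differ in which half of the TFs is elevated, plus a binary functional
#' status aligned with the blocks.  This emulates the downstream situation
#' where tumor subgroups carry distinct TF-activity signatures.
#'
#' @param n_tfs,n_samples Matrix dimensions.
#' @param shift Mean activity elevation of the block-specific TFs.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Integer seed.
#' @return A list with `tfa` (matrix), `block` (integer vector 1/2) and
#'   `status` (character, `"deficient"` for block 1, `"functional"` for
#'   block 2).
#' @export
simulate_tfa_cohort <- function(n_tfs = 16, n_samples = 40, shift = 3,
                                noise_sd = 0.2, seed = 1) {
  if (shift < 0 || noise_sd < 0) abort("`shift` and `noise_sd` must be non-negative.")
  withr::local_seed(seed)
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  block <- rep(1:2, c(ceiling(n_samples / 2), floor(n_samples / 2)))
  half <- seq_len(ceiling(n_tfs / 2))
  mu <- matrix(0, n_tfs, n_samples, dimnames = list(tf_ids, sample_ids))
  mu[half, block == 1] <- shift
  mu[-half, block == 2] <- shift
  tfa <- mu + matrix(rnorm(n_tfs * n_samples, 0, noise_sd), n_tfs)
  list(
    tfa = tfa, block = setNames(block, sample_ids),
    status = setNames(
      ifelse(block == 1, "deficient", "functional"), sample_ids
    )
  )
}

#' Write a simulated dataset to TSV files
#'
#' Writes the connectivity table, the log-ratio expression matrix, the
#' background pool, the sample annotations and a ground-truth activity
#' sidecar into `dir`, in the same formats the preprocessing readers
#' consume.
#'
#' @param sim An `nca_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "nca_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_connectivity(sim$pattern, file.path(dir, "connectivity.tsv"))
  write_expression_ratios(sim$expr, file.path(dir, "ratios.tsv"))
  readr::write_tsv(
    tibble::as_tibble(sim$pool, rownames = "gene"),
    file.path(dir, "pool.tsv")
  )
  readr::write_tsv(tidy(sim), file.path(dir, "truth.tsv"))
  readr::write_tsv(
    tibble::tibble(
      sample = names(sim$group_labels),
      group = unname(sim$group_labels),
      status = unname(sim$status_labels)
    ),
    file.path(dir, "annotations.tsv")
  )
  invisible(dir)
}
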