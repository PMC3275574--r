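#' Trim spurious edges from a connectivity pattern
#'
#' High-throughput binding data contribute false positive TF-gene
#' interactions whose fitted control strength is indistinguishable from
#' what a random, unrelated gene would produce.  Trimming removes such
#' edges iteratively: the network is fitted, and for every edge a null
#' distribution of the control-strength magnitude is built by replacing the
#' target gene's expression row with rows drawn from a background gene pool
#' and re-estimating that gene's strengths against the fitted activities
#' (`n_null` draws).  Edges whose observed `|CS|` falls below the null by
#' modified z-score (`z < z_cut`; see [modified_zscore()]) are removed, the
#' network is refitted, and the procedure repeats until no edge is removed
#' or `max_rounds` is reached.  An edge that is a TF's last connection is
#' never removed (it is reported instead); a gene whose edges are all
#' removed drops out of the pattern.
#'
#' @inheritParams nca_decompose
#' @param pool Background pool matrix (pool genes x conditions) with at
#'   least as many rows as the pattern has genes, e.g. the `pool` element
#'   of [simulate_nca_dataset()] or expression of genome genes outside the
#'   network.
#' @param n_null Null draws per round.
#' @param z_cut Removal threshold on the modified z-score of `|CS|`.
#' @param max_rounds Maximum fit-and-trim rounds; `0` returns the input
#'   pattern unchanged (with its fit).
#' @param seed Integer seed for the null draws.
#' @return A list of class `trim_result`: `pattern` (trimmed), `fit`
#'   (`nca_fit` on the trimmed pattern), `removed` (tibble of removed edges
#'   with round and z), `protected` (edges kept as a TF's last connection)
#'   and `n_rounds`.
#' @export
trim_network <- function(E, pattern, pool, n_null = 100, z_cut = 1,
                         max_rounds = 5, seed = 1, tol = 1e-6,
                         max_iter = 1000, n_restarts = 3, ridge = 0) {
  if (missing(pool) || is.null(pool)) abort("A background `pool` matrix is required.")
  pool <- as.matrix(pool)
  withr::local_seed(seed)

  cur <- pattern
  removed <- list()
  protected <- list()
  fit <- NULL
  rnd <- 0L
  repeat {
    fit <- nca_decompose(
      E, cur,
      tol = tol, max_iter = max_iter,
      n_restarts = n_restarts, ridge = ridge, check = rnd == 0L
    )
    if (rnd >= max_rounds) break
    rnd <- rnd + 1L

    cur <- fit$pattern
    M <- pattern_matrix(cur)
    mask <- matrix(as.integer(M), nrow(M))
    if (nrow(pool) < nrow(M)) abort("Background pool has fewer rows than the pattern has genes.")

    ## Null |CS| per edge: re-estimate per-gene strengths against the
    ## fitted activities with every gene row replaced by a random pool row.
    null_abs <- array(NA_real_, c(nrow(M), ncol(M), n_null))
    for (b in seq_len(n_null)) {
      En <- pool[sample(nrow(pool), nrow(M)), , drop = FALSE]
      null_abs[, , b] <- abs(gene_strengths(En, mask, fit$P))
    }

    idx <- which(M, arr.ind = TRUE)
    z <- vapply(seq_len(nrow(idx)), function(i) {
      modified_zscore(
        abs(fit$A[idx[i, 1], idx[i, 2]]),
        null_abs[idx[i, 1], idx[i, 2], ]
      )$z
    }, numeric(1))

    drop_i <- which(z < z_cut)
    if (length(drop_i) == 0) break

    edges <- tibble::tibble(
      gene = rownames(M)[idx[, 1]],
      tf = colnames(M)[idx[, 2]],
      z = z
    )
    to_drop <- edges[drop_i, ]
    ## never sever a TF's last connection
    keep_last <- character(0)
    tf_left <- table(edges$tf)
    tf_dropped <- table(to_drop$tf)
    for (t in names(tf_dropped)) {
      if (tf_dropped[[t]] >= tf_left[[t]]) {
        worst <- to_drop[to_drop$tf == t, ]
        spare <- worst$gene[which.max(worst$z)]
        keep_last <- c(keep_last, paste(spare, t, sep = "|"))
      }
    }
    if (length(keep_last) > 0) {
      key <- paste(to_drop$gene, to_drop$tf, sep = "|")
      protected[[rnd]] <- to_drop[key %in% keep_last, ]
      inform(paste0(
        nrow(protected[[rnd]]),
        " edge(s) kept as a TF's last connection despite z < z_cut."
      ))
      to_drop <- to_drop[!key %in% keep_last, ]
    }
    if (nrow(to_drop) == 0) break
    removed[[rnd]] <- dplyr::mutate(to_drop, round = rnd)

    key_drop <- paste(to_drop$gene, to_drop$tf, sep = "|")
    kept <- cur$edges[
      !paste(cur$edges$gene, cur$edges$tf, sep = "|") %in% key_drop,
    ]
    cur <- connectivity_pattern(
      kept,
      tf_ids = intersect(cur$tf_ids, unique(kept$tf)),
      gene_ids = intersect(cur$gene_ids, unique(kept$gene))
    )
  }

  structure(
    list(
      pattern = fit$pattern, fit = fit,
      removed = if (length(removed)) dplyr::bind_rows(removed) else
        tibble::tibble(gene = character(0), tf = character(0), z = numeric(0), round = integer(0)),
      protected = if (length(protected)) dplyr::bind_rows(protected) else
        tibble::tibble(gene = character(0), tf = character(0), z = numeric(0)),
      n_rounds = rnd
    ),
    class = "trim_result"
  )
}

#' @export
print.trim_result <- function(x, ...) {
  cat(
    "<trim_result> ", nrow(x$removed), " edge(s) removed over ", x$n_rounds,
    " round(s); ", nrow(x$pattern$edges), " edge(s) retained\n",
    sep = ""
  )
  invisible(x)
}
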