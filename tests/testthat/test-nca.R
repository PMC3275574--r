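test_that("the decomposition honors the zero pattern and normalization exactly", {
  sim <- small_sim(seed = 1, noise_sd = 0.05)
  fit <- nca_decompose(sim$expr, sim$pattern, seed = 1)
  M <- pattern_matrix(fit$pattern)
  ## invariant: A is exactly zero off-pattern
  expect_true(all(fit$A[!M] == 0))
  ## unit-norm columns, largest-magnitude entry positive
  expect_equal(unname(sqrt(colSums(fit$A^2))), rep(1, ncol(fit$A)))
  for (j in seq_len(ncol(fit$A))) {
    a <- fit$A[, j]
    expect_gt(a[which.max(abs(a))], 0)
  }
  expect_true(fit$converged)
  expect_gte(fit$residual_fro, 0)
})

test_that("noiseless activities are recovered up to scale and sign", {
  sim <- small_sim(seed = 2)
  fit <- nca_decompose(sim$expr, sim$pattern, tol = 1e-12, max_iter = 2000, seed = 1)
  rec <- tfa_recovery(fit, sim)
  expect_true(all(rec$abs_r > 1 - 1e-6))
  ## A %*% P reproduces E regardless of the per-TF scale/sign indeterminacy
  expect_lt(
    norm(sim$expr$values - fit$A %*% fit$P, "F") / norm(sim$expr$values, "F"),
    1e-6
  )
})

test_that("more iterations never worsen the residual", {
  sim <- small_sim(seed = 3, noise_sd = 0.3)
  r_by_iter <- vapply(c(1, 3, 10, 50), function(mi) {
    nca_decompose(
      sim$expr, sim$pattern,
      tol = 0, max_iter = mi, n_restarts = 1, seed = 1
    )$residual_fro
  }, numeric(1))
  expect_true(all(diff(r_by_iter) <= 1e-10))
})

test_that("an all-zero expression matrix yields the trivial exact fit", {
  sim <- small_sim(seed = 4)
  E0 <- sim$expr$values * 0
  fit <- nca_decompose(E0, sim$pattern)
  expect_equal(fit$residual_fro, 0)
  expect_true(all(fit$P == 0))
  expect_true(fit$converged)
})

test_that("genes absent from the pattern are ignored with a message", {
  sim <- small_sim(seed = 5)
  E <- rbind(sim$expr$values, stranger = rnorm(ncol(sim$expr$values)))
  expect_message(fit <- nca_decompose(E, sim$pattern, seed = 1), "1 expression gene")
  expect_equal(nrow(fit$A), nrow(sim$expr$values))
  expect_error(
    nca_decompose(E["stranger", , drop = FALSE], sim$pattern),
    "No overlap"
  )
})

test_that("non-identifiable patterns warn but still return a fit", {
  pat <- connectivity_pattern(data.frame(
    gene = c("g1", "g2", "g1", "g2"),
    tf = c("tfA", "tfA", "tfB", "tfB")
  ))
  E <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
  expect_warning(fit <- nca_decompose(E, pat, seed = 1), "identifiable")
  expect_s3_class(fit, "nca_fit")
})

test_that("ridge regularization bounds activity magnitudes on pure noise", {
  sim <- simulate_nca_dataset(
    n_tfs = 10, n_genes = 100, targets_per_tf = 5, n_conditions = 12,
    n_perturbed = 0, noise_sd = 1, activity_sd = 0, seed = 101
  )
  plain <- nca_decompose(
    sim$expr, sim$pattern,
    max_iter = 300, n_restarts = 1, seed = 1
  )
  reg <- nca_decompose(
    sim$expr, sim$pattern,
    max_iter = 300, n_restarts = 1, ridge = 1, seed = 1
  )
  ## this seed exhibits the shared-target degeneracy of exact ALS (two
  ## near-parallel strength columns with huge cancelling activities);
  ## the penalty must suppress it
  expect_gt(sd(plain$P), 5)
  expect_lt(sd(reg$P), 3)
  expect_error(nca_decompose(sim$expr, sim$pattern, ridge = -1), "ridge")
})

test_that("tidy, glance and autoplot expose the fit in standard shapes", {
  sim <- small_sim(seed = 6, noise_sd = 0.1)
  fit <- nca_decompose(sim$expr, sim$pattern, seed = 1)
  act <- tidy(fit)
  expect_s3_class(act, "tbl_df")
  expect_named(act, c("tf", "condition", "tfa"))
  expect_equal(nrow(act), ncol(fit$A) * ncol(fit$P))
  cs <- tidy(fit, matrix = "strengths")
  expect_named(cs, c("gene", "tf", "strength"))
  expect_equal(nrow(cs), nrow(fit$pattern$edges))
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_true(all(c("residual_fro", "converged", "n_tfs") %in% names(g)))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("fits are exported to readable TSV/JSON artifacts", {
  sim <- small_sim(seed = 7, noise_sd = 0.1)
  fit <- nca_decompose(sim$expr, sim$pattern, seed = 1)
  dir <- withr::local_tempdir()
  write_nca_fit(fit, dir)
  act <- readr::read_tsv(file.path(dir, "activities.tsv"), show_col_types = FALSE)
  expect_equal(nrow(act), ncol(fit$A) * ncol(fit$P))
  meta <- jsonlite::read_json(file.path(dir, "fit.json"))
  expect_equal(meta$n_tfs, ncol(fit$A))
})
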