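test_that("modified_zscore matches the closed-form median/MAD formula", {
  null <- c(-1, -0.5, 0, 0.5, 1, -0.2, 0.2, 0.7, -0.7, 0.1)
  x <- 2
  out <- modified_zscore(x, null)
  m <- median(null)
  mad0 <- median(abs(null - m))
  expect_equal(out$z, 0.6745 * (x - m) / mad0)
  expect_equal(out$p, 2 * (1 - pnorm(abs(out$z))))
  expect_false(out$degenerate)
  ## vectorized, and monotone: a larger |x - median| never has larger p
  xs <- seq(-3, 3, by = 0.5)
  res <- modified_zscore(xs, null)
  ord <- order(abs(xs - m))
  expect_true(all(diff(res$p[ord]) <= 1e-12))
})

test_that("a degenerate null (MAD = 0) is flagged, not silently scored", {
  expect_warning(out <- modified_zscore(3, rep(1, 20)), "Degenerate")
  expect_true(out$degenerate)
  expect_equal(out$p, 0)
  expect_warning(out0 <- modified_zscore(1, rep(1, 20)), "Degenerate")
  expect_equal(out0$z, 0)
  expect_equal(out0$p, 1)
  expect_error(modified_zscore(1, 1:5), "at least 10")
})

test_that("the empirical tail is bounded away from zero", {
  null <- rnorm(99)
  out <- modified_zscore(1e6, null, empirical = TRUE)
  expect_equal(out$p, 1 / 100)
  mid <- modified_zscore(median(null), null, empirical = TRUE)
  expect_equal(mid$p, 1)
})

test_that("build_null reproduces with the same seed and respects structure", {
  sim <- small_sim(seed = 8, noise_sd = 0.5, n_conditions = 6)
  a <- build_null(sim$pool, sim$pattern, n_networks = 25, seed = 5,
                  max_iter = 200, n_restarts = 1)
  b <- build_null(sim$pool, sim$pattern, n_networks = 25, seed = 5,
                  max_iter = 200, n_restarts = 1)
  expect_identical(a$values, b$values)
  expect_equal(dim(a$values), c(4, 6, 25))
  expect_equal(dimnames(a$values)[[1]], sim$pattern$tf_ids)
  c2 <- build_null(sim$pool, sim$pattern, n_networks = 25, seed = 6,
                   max_iter = 200, n_restarts = 1)
  expect_false(identical(a$values, c2$values))
  ## pool smaller than the network is rejected
  expect_error(
    build_null(sim$pool[1:10, ], sim$pattern, n_networks = 2),
    "pool"
  )
})

test_that("tfa_significance scores every TF-condition cell against its null", {
  sim <- small_sim(seed = 9, noise_sd = 0.5, n_conditions = 6)
  fit <- nca_decompose(sim$expr, sim$pattern, max_iter = 200,
                       n_restarts = 1, seed = 1)
  null <- build_null(sim$pool, sim$pattern, n_networks = 30, seed = 2,
                     max_iter = 200, n_restarts = 1)
  sig <- tfa_significance(fit, null)
  expect_equal(nrow(sig), 4 * 6)
  expect_true(all(sig$p >= 0 & sig$p <= 1))
  expect_true(all(c("tf", "condition", "tfa", "z", "p") %in% names(sig)))
  ## manual recomputation of one cell
  cell <- sig[sig$tf == "TF01" & sig$condition == "cond01", ]
  manual <- modified_zscore(fit$P["TF01", "cond01"], null$values["TF01", "cond01", ])
  expect_equal(cell$z, manual$z)
  expect_equal(cell$p, manual$p)
  expect_s3_class(ggplot2::autoplot(sig), "ggplot")
})

test_that("select_perturbed_tfs uses the any-condition rule ordered by min p", {
  sig <- tibble::tibble(
    tf = rep(c("a", "b", "c"), each = 2),
    condition = rep(c("c1", "c2"), 3),
    tfa = 0,
    z = 0,
    p = c(0.01, 0.9, 0.2, 0.3, 0.04, 0.001),
    degenerate = FALSE
  )
  class(sig) <- c("tfa_significance", class(sig))
  sel <- select_perturbed_tfs(sig, alpha = 0.05)
  expect_equal(sel$tf, c("c", "a"))
  expect_equal(sel$min_p, c(0.001, 0.01))
  expect_equal(nrow(select_perturbed_tfs(sig, alpha = 0.0005)), 0)
  expect_error(select_perturbed_tfs(sig, alpha = 0), "alpha")
  ## BH adjustment can only shrink the selection
  sel_bh <- select_perturbed_tfs(sig, alpha = 0.05, adjust = "BH")
  expect_true(all(sel_bh$tf %in% sel$tf))
})

test_that("detection power grows with effect size", {
  min_p_at <- function(delta) {
    sim <- simulate_nca_dataset(
      n_tfs = 6, n_genes = 60, targets_per_tf = 5, n_conditions = 8,
      n_perturbed = 1, effect_size = delta, noise_sd = 0.1,
      activity_sd = 0, seed = 21
    )
    fit <- nca_decompose(sim$expr, sim$pattern, max_iter = 200,
                         n_restarts = 1, ridge = 1, seed = 1)
    null <- build_null(sim$pool, sim$pattern, n_networks = 50, seed = 3,
                       max_iter = 200, n_restarts = 1, ridge = 1)
    sig <- tfa_significance(fit, null)
    min(sig$p[sig$tf == sim$perturbed_tfs])
  }
  p0 <- min_p_at(0)
  p2 <- min_p_at(2)
  p5 <- min_p_at(5)
  expect_lt(p2, p0)
  expect_lt(p5, p2)
  expect_lt(p5, 0.05)
})

test_that("null distributions export to a tidy TSV", {
  sim <- small_sim(seed = 10, noise_sd = 0.5, n_conditions = 4)
  null <- build_null(sim$pool, sim$pattern, n_networks = 12, seed = 4,
                     max_iter = 100, n_restarts = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_null(null, path)
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(tbl), 4 * 4 * 12)
  one <- tbl[tbl$tf == "TF02" & tbl$condition == "cond03" & tbl$network == 7, ]
  expect_equal(one$tfa, null$values["TF02", "cond03", 7])
})
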