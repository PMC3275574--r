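test_that("cosine clustering separates planted blocks and is scale-invariant", {
  co <- simulate_tfa_cohort(n_tfs = 8, n_samples = 20, shift = 3,
                            noise_sd = 0.2, seed = 3)
  cl <- cluster_samples(co$tfa, k = 2)
  ## groups coincide with the planted blocks (up to label switching)
  tab <- table(cl$groups, co$block)
  expect_equal(sum(tab > 0), 2)
  ## positive per-sample rescaling does not change the cosine metric
  scaled <- sweep(co$tfa, 2, runif(20, 0.5, 5), "*")
  cl2 <- cluster_samples(scaled, k = 2)
  expect_equal(unname(cl2$groups), unname(cl$groups))
  ## tidy output and input validation
  td <- tidy(cl)
  expect_named(td, c("sample", "group"))
  expect_error(cluster_samples(co$tfa, k = 21), "samples")
  bad <- co$tfa
  bad[, 1] <- 0
  expect_error(cluster_samples(bad, k = 2), "zero")
})

test_that("cluster groups are numbered by dendrogram leaf order", {
  co <- simulate_tfa_cohort(n_tfs = 8, n_samples = 12, shift = 4,
                            noise_sd = 0.1, seed = 5)
  cl <- cluster_samples(co$tfa, k = 2)
  first_leaf <- names(cl$groups)[cl$hclust$order[1]]
  expect_equal(unname(cl$groups[first_leaf]), 1L)
})

test_that("associate_status reproduces the Pearson chi-squared without correction", {
  groups <- rep(c(1, 2, 3), c(13, 35, 64))
  status <- c(
    rep(c("altered", "normal"), c(9, 4)),
    rep(c("altered", "normal"), c(11, 24)),
    rep(c("altered", "normal"), c(3, 61))
  )
  out <- associate_status(groups, status)
  oracle <- suppressWarnings(
    chisq.test(table(groups == 1, status), correct = FALSE)
  )
  expect_equal(out$chi2, unname(oracle$statistic))
  expect_equal(out$p, oracle$p.value)
  expect_equal(out$df, 1)
  ## swapping the status labels leaves the statistic unchanged
  flipped <- associate_status(
    groups, ifelse(status == "altered", "normal", "altered")
  )
  expect_equal(flipped$chi2, out$chi2)
})

test_that("associate_status validates degenerate tables", {
  expect_error(associate_status(rep(1, 10), rep(c("a", "b"), 5)), "2 groups")
  expect_error(associate_status(rep(1:2, 5), rep("a", 10)), "two observed levels")
  out <- associate_status(
    c(1, 1, 2, 2, NA), c("a", "b", "a", "b", "a")
  )
  expect_equal(out$chi2, 0)
})

test_that("tfa_ttest matches stats::t.test and marks significance levels", {
  withr::local_seed(9)
  tfa <- matrix(rnorm(5 * 12), 5, 12,
    dimnames = list(paste0("TF", 1:5), paste0("s", 1:12))
  )
  tfa["TF1", 7:12] <- tfa["TF1", 7:12] + 10
  out <- tfa_ttest(tfa, 1:6, 7:12)
  oracle <- t.test(tfa["TF2", 1:6], tfa["TF2", 7:12], var.equal = TRUE)
  row2 <- out[out$tf == "TF2", ]
  expect_equal(row2$t, unname(oracle$statistic))
  expect_equal(row2$p, oracle$p.value)
  expect_equal(out$mark[out$tf == "TF1"], "***")
  ## Welch option
  outw <- tfa_ttest(tfa, 1:6, 7:12, var_equal = FALSE)
  oraclew <- t.test(tfa["TF2", 1:6], tfa["TF2", 7:12])
  expect_equal(outw$p[outw$tf == "TF2"], oraclew$p.value)
  ## degenerate constant rows are flagged, not scored
  tfa["TF3", ] <- 2
  outd <- tfa_ttest(tfa, 1:6, 7:12)
  expect_true(outd$degenerate[outd$tf == "TF3"])
  expect_true(is.na(outd$p[outd$tf == "TF3"]))
  expect_error(tfa_ttest(tfa, 1, 2:12), "at least 2")
})

test_that("derive_status_signature selects the truly shifted TFs", {
  co <- simulate_tfa_cohort(n_tfs = 10, n_samples = 30, shift = 4,
                            noise_sd = 0.3, seed = 12)
  sig <- derive_status_signature(co$tfa, co$status, alpha = 1e-4)
  ## every TF is block-specific in this design, so all are differential
  expect_equal(sort(sig$tf), sort(rownames(co$tfa)))
  expect_true(all(sig$p < 1e-4))
  expect_true(!is.unsorted(sig$p))
  ## with shuffled labels nothing survives the stringent cutoff
  withr::local_seed(1)
  shuffled <- setNames(sample(co$status), names(co$status))
  expect_equal(nrow(derive_status_signature(co$tfa, shuffled, alpha = 1e-6)), 0)
})

test_that("tfa_correlation yields a unit-diagonal |r| matrix and flags constants", {
  co <- simulate_tfa_cohort(n_tfs = 6, n_samples = 15, shift = 3,
                            noise_sd = 0.2, seed = 14)
  cc <- tfa_correlation(co$tfa)
  expect_equal(unname(diag(cc$abs_r)), rep(1, 6))
  expect_true(all(cc$abs_r >= 0 & cc$abs_r <= 1))
  expect_equal(cc$abs_r, t(cc$abs_r))
  expect_s3_class(ggplot2::autoplot(cc), "ggplot")
  flat <- co$tfa
  flat["TF01", ] <- 5
  expect_warning(cc2 <- tfa_correlation(flat), "TF01")
  expect_false("TF01" %in% rownames(cc2$abs_r))
})

test_that("normalize_to_reference centers on the reference mean per TF", {
  tfa <- matrix(1:12, 3, 4,
    dimnames = list(paste0("TF", 1:3), paste0("s", 1:4))
  )
  out <- normalize_to_reference(tfa, c("s1", "s2"))
  expect_equal(unname(rowMeans(out[, c("s1", "s2")])), rep(0, 3))
  expect_equal(out, sweep(tfa, 1, rowMeans(tfa[, 1:2])))
  expect_error(normalize_to_reference(tfa, character(0)), "reference")
})
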