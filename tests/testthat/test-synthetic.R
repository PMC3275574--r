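test_that("simulated patterns are identifiable by construction", {
  for (seed in 1:5) {
    pat <- simulate_pattern(6, 40, 4, seed = seed)
    rep <- check_identifiability(pat)
    expect_true(rep$identifiable)
  }
})

test_that("simulated datasets carry a consistent ground truth", {
  sim <- small_sim(seed = 3, noise_sd = 0.1, n_perturbed = 2, effect_size = 2)
  expect_s3_class(sim, "nca_simulation")
  expect_equal(dim(sim$A_true), c(24, 4))
  expect_equal(dim(sim$P_true), c(4, 8))
  expect_equal(dim(sim$expr$values), c(24, 8))
  expect_length(sim$perturbed_tfs, 2)
  expect_true(all(sim$perturbed_tfs %in% sim$pattern$tf_ids))
  ## strengths are only nonzero on the pattern, and never negligible on
  ## non-spurious edges
  M <- pattern_matrix(sim$pattern)
  expect_true(all(sim$A_true[!M] == 0))
  expect_true(all(abs(sim$A_true[M]) >= 0.5))
  ## group labels partition the conditions
  expect_setequal(unique(sim$group_labels), c("A", "B"))
})

test_that("noiseless expression reproduces A %*% P exactly", {
  sim <- small_sim(seed = 2)
  expect_equal(sim$expr$values, sim$A_true %*% sim$P_true)
})

test_that("the same seed reproduces the dataset, different seeds differ", {
  a <- small_sim(seed = 11, noise_sd = 0.2)
  b <- small_sim(seed = 11, noise_sd = 0.2)
  c <- small_sim(seed = 12, noise_sd = 0.2)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$pattern$edges, b$pattern$edges)
  expect_false(identical(a$expr$values, c$expr$values))
})

test_that("spurious edges are present in the pattern but carry zero strength", {
  sim <- simulate_nca_dataset(
    n_tfs = 6, n_genes = 60, targets_per_tf = 5, n_conditions = 10,
    n_perturbed = 0, noise_sd = 0, fraction_spurious = 0.2, seed = 4
  )
  expect_gt(nrow(sim$spurious_edges), 0)
  keys <- edge_keys(sim$spurious_edges)
  expect_true(all(keys %in% edge_keys(sim$pattern$edges)))
  for (i in seq_len(nrow(sim$spurious_edges))) {
    expect_identical(
      sim$A_true[sim$spurious_edges$gene[i], sim$spurious_edges$tf[i]], 0
    )
  }
})

test_that("activity_sd = 0 zeroes baseline activities but keeps planted shifts", {
  sim <- simulate_nca_dataset(
    n_tfs = 6, n_genes = 60, targets_per_tf = 5, n_conditions = 10,
    n_perturbed = 2, effect_size = 2, noise_sd = 0, activity_sd = 0, seed = 5
  )
  quiet <- setdiff(rownames(sim$P_true), sim$perturbed_tfs)
  expect_true(all(sim$P_true[quiet, ] == 0))
  shifted <- sim$P_true[sim$perturbed_tfs, sim$group_labels == "B", drop = FALSE]
  expect_true(all(abs(shifted) == 2))
  expect_error(small_sim(activity_sd = -1), "activity_sd")
})

test_that("perturbation shifts activities by effect_size between groups", {
  sim <- small_sim(seed = 6, n_perturbed = 1, effect_size = 3, activity_sd = 1)
  tf <- sim$perturbed_tfs
  d <- mean(sim$P_true[tf, sim$group_labels == "B"]) -
    mean(sim$P_true[tf, sim$group_labels == "A"])
  ## the shift is +/- effect_size on top of N(0, 1) baseline noise
  expect_gt(abs(d), 1)
})

test_that("infeasible generator sizes error early", {
  expect_error(simulate_pattern(10, 15, 3, seed = 1), "n_genes")
  expect_error(small_sim(targets_per_tf = 50), "targets_per_tf")
  expect_error(small_sim(n_perturbed = 10), "n_perturbed")
})

test_that("cohort simulation plants two separable blocks with status labels", {
  co <- simulate_tfa_cohort(
    n_tfs = 8, n_samples = 20, shift = 3, noise_sd = 0.2, seed = 2
  )
  expect_equal(dim(co$tfa), c(8, 20))
  expect_setequal(unique(co$block), 1:2)
  expect_setequal(unique(co$status), c("deficient", "functional"))
  expect_named(co$block)
  expect_identical(names(co$block), colnames(co$tfa))
})

test_that("tidy() and write_simulation() expose the ground truth", {
  sim <- small_sim(seed = 7)
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("tf", "condition", "activity") %in% names(td)))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("connectivity.tsv", "ratios.tsv", "pool.tsv", "truth.tsv",
           "annotations.tsv")
  ))))
})
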