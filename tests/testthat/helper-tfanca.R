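## Small, fast simulated dataset shared by unit tests.
small_sim <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(
      n_tfs = 4, n_genes = 24, targets_per_tf = 4, n_conditions = 8,
      n_perturbed = 0, noise_sd = 0, seed = seed
    ),
    list(...)
  )
  do.call(simulate_nca_dataset, args)
}

edge_keys <- function(edges) paste(edges$gene, edges$tf)
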