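#' Read and validate a pipeline run configuration
#'
#' The pipeline stages are driven by a plain-text YAML configuration with
#' explicit seeds (no hidden global randomness).  Top-level keys:
#' `output_dir`, `seed`, and one optional block per stage (`simulate`,
#' `preprocess`, `fit`, `trim`, `significance`, `cluster`, `associate`)
#' overriding that stage's defaults.  Paths referenced by a stage are
#' checked when the stage runs.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$output_dir)) abort("Config must set `output_dir`.")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

stage_opts <- function(config, stage, defaults) {
  utils::modifyList(defaults, config[[stage]] %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    abort(paste0(
      "Missing upstream artifact `", path, "`; run the `", producer,
      "` stage first."
    ))
  }
  path
}

write_manifest <- function(dir, stage, inputs, options, outputs) {
  manifest <- list(
    stage = stage,
    inputs = as.list(inputs),
    options = options,
    outputs = lapply(
      setNames(outputs, basename(outputs)),
      function(f) list(path = f, md5 = unname(tools::md5sum(f)))
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(
    manifest, file.path(dir, paste0(stage, ".manifest.json")),
    auto_unbox = TRUE, null = "null", digits = NA
  )
}

#' Run one pipeline stage
#'
#' Orchestrates the analysis end to end through named stages, each reading
#' the previous stage's TSV artifacts from the configured output directory
#' and writing its own, together with a machine-readable manifest (inputs,
#' options, seeds, output hashes) sufficient to reproduce the artifact.
#'
#' Stages: `simulate` (synthetic ground-truth dataset), `preprocess`
#' (expression table + design to log ratios), `fit` (the decomposition),
#' `trim` (edge trimming, writes a trimmed connectivity), `significance`
#' (random-network null and TF selection), `cluster` (sample groups from
#' activities), `associate` (chi-squared status association and per-TF
#' t-tests), `report` (collects stage summaries).
#'
#' @param stage Stage name.
#' @param config A `run_config` (or path to one).
#' @return Invisibly, a list of the stage's main results.
#' @export
run_pipeline_stage <- function(stage = c(
                                 "simulate", "preprocess", "fit", "trim",
                                 "significance", "cluster", "associate", "report"
                               ),
                               config) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  t0 <- Sys.time()
  res <- switch(stage,
    simulate = stage_simulate(config, out_dir, seed),
    preprocess = stage_preprocess(config, out_dir),
    fit = stage_fit(config, out_dir, seed),
    trim = stage_trim(config, out_dir, seed),
    significance = stage_significance(config, out_dir, seed),
    cluster = stage_cluster(config, out_dir),
    associate = stage_associate(config, out_dir),
    report = stage_report(config, out_dir)
  )
  message(sprintf(
    "[%s] completed in %.1fs", stage,
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ))
  invisible(res)
}

stage_simulate <- function(config, out_dir, seed) {
  opts <- stage_opts(config, "simulate", list(
    n_tfs = 20, n_genes = 200, targets_per_tf = 10, n_conditions = 12,
    n_perturbed = 4, effect_size = 2, noise_sd = 0.1, activity_sd = 1,
    fraction_spurious = 0, pool_factor = 10
  ))
  sim <- do.call(simulate_nca_dataset, c(opts, list(seed = seed)))
  write_simulation(sim, out_dir)
  outs <- file.path(out_dir, c(
    "connectivity.tsv", "ratios.tsv", "pool.tsv", "truth.tsv", "annotations.tsv"
  ))
  write_manifest(out_dir, "simulate", character(0), c(opts, seed = seed), outs)
  list(sim = sim)
}

stage_preprocess <- function(config, out_dir) {
  opts <- stage_opts(config, "preprocess", list(
    expression = NULL, design = NULL, reference = NULL,
    connectivity = NULL, evidence = c("experimental"),
    values_are_log2 = FALSE
  ))
  for (key in c("expression", "design", "reference", "connectivity")) {
    if (is.null(opts[[key]])) abort(paste0("`preprocess` config needs `", key, "`."))
  }
  pat <- read_connectivity(
    require_artifact(opts$connectivity, "simulate"),
    evidence_filter = opts$evidence
  )
  expr <- readr::read_tsv(
    require_artifact(opts$expression, "simulate"),
    show_col_types = FALSE
  )
  design <- readr::read_tsv(opts$design, show_col_types = FALSE)
  ratios <- to_log_ratios(
    expr, design, opts$reference,
    values_are_log2 = opts$values_are_log2
  )
  write_expression_ratios(ratios, file.path(out_dir, "ratios.tsv"))
  write_connectivity(pat, file.path(out_dir, "connectivity.tsv"))
  write_manifest(
    out_dir, "preprocess",
    c(opts$expression, opts$design, opts$connectivity), opts,
    file.path(out_dir, c("ratios.tsv", "connectivity.tsv"))
  )
  list(ratios = ratios, pattern = pat)
}

read_stage_inputs <- function(out_dir) {
  list(
    pattern = read_connectivity(
      require_artifact(file.path(out_dir, "connectivity.tsv"), "simulate or preprocess")
    ),
    ratios = read_expression_ratios(
      require_artifact(file.path(out_dir, "ratios.tsv"), "simulate or preprocess")
    )
  )
}

fit_options <- function(config) {
  stage_opts(config, "fit", list(
    tol = 1e-6, max_iter = 1000, n_restarts = 3, ridge = 0
  ))
}

stage_fit <- function(config, out_dir, seed) {
  opts <- fit_options(config)
  inp <- read_stage_inputs(out_dir)
  fit <- nca_decompose(
    inp$ratios, inp$pattern,
    tol = opts$tol, max_iter = opts$max_iter,
    n_restarts = opts$n_restarts, ridge = opts$ridge, seed = seed
  )
  write_nca_fit(fit, out_dir)
  write_manifest(
    out_dir, "fit",
    file.path(out_dir, c("connectivity.tsv", "ratios.tsv")),
    c(opts, seed = seed),
    file.path(out_dir, c("strengths.tsv", "activities.tsv", "fit.json"))
  )
  list(fit = fit)
}

read_pool <- function(out_dir) {
  tbl <- readr::read_tsv(
    require_artifact(file.path(out_dir, "pool.tsv"), "simulate"),
    show_col_types = FALSE
  )
  m <- as.matrix(tbl[-1])
  rownames(m) <- tbl[[1]]
  m
}

stage_trim <- function(config, out_dir, seed) {
  opts <- stage_opts(config, "trim", list(n_null = 100, z_cut = 1, max_rounds = 5))
  fopts <- fit_options(config)
  inp <- read_stage_inputs(out_dir)
  pool <- read_pool(out_dir)
  tr <- trim_network(
    inp$ratios, inp$pattern, pool,
    n_null = opts$n_null, z_cut = opts$z_cut, max_rounds = opts$max_rounds,
    seed = seed, tol = fopts$tol, max_iter = fopts$max_iter,
    n_restarts = fopts$n_restarts, ridge = fopts$ridge
  )
  write_connectivity(tr$pattern, file.path(out_dir, "connectivity.tsv"))
  readr::write_tsv(tr$removed, file.path(out_dir, "removed_edges.tsv"))
  write_nca_fit(tr$fit, out_dir)
  write_manifest(
    out_dir, "trim",
    file.path(out_dir, c("ratios.tsv", "pool.tsv")),
    c(opts, seed = seed),
    file.path(out_dir, c("connectivity.tsv", "removed_edges.tsv", "activities.tsv"))
  )
  list(trim = tr)
}

stage_significance <- function(config, out_dir, seed) {
  opts <- stage_opts(config, "significance", list(
    n_networks = 200, alpha = 0.05, empirical = FALSE
  ))
  fopts <- fit_options(config)
  inp <- read_stage_inputs(out_dir)
  pool <- read_pool(out_dir)
  fit <- nca_decompose(
    inp$ratios, inp$pattern,
    tol = fopts$tol, max_iter = fopts$max_iter,
    n_restarts = fopts$n_restarts, ridge = fopts$ridge, seed = seed
  )
  ## the null must be refit with the exact options used for the observed fit
  null <- build_null(
    pool, fit$pattern,
    n_networks = opts$n_networks, seed = seed,
    tol = fopts$tol, max_iter = fopts$max_iter,
    n_restarts = fopts$n_restarts, ridge = fopts$ridge
  )
  sig <- tfa_significance(fit, null, empirical = opts$empirical)
  sel <- select_perturbed_tfs(sig, alpha = opts$alpha)
  sig$selected <- sig$tf %in% sel$tf
  readr::write_tsv(sig, file.path(out_dir, "significance.tsv"))
  readr::write_tsv(sel, file.path(out_dir, "selected_tfs.tsv"))
  write_manifest(
    out_dir, "significance",
    file.path(out_dir, c("connectivity.tsv", "ratios.tsv", "pool.tsv")),
    c(opts, seed = seed),
    file.path(out_dir, c("significance.tsv", "selected_tfs.tsv"))
  )
  list(significance = sig, selected = sel)
}

read_tfa_matrix <- function(out_dir) {
  tbl <- readr::read_tsv(
    require_artifact(file.path(out_dir, "activities.tsv"), "fit"),
    show_col_types = FALSE
  )
  as_tfa_matrix(tbl)
}

stage_cluster <- function(config, out_dir) {
  opts <- stage_opts(config, "cluster", list(k = 3))
  tfa <- read_tfa_matrix(out_dir)
  cl <- cluster_samples(tfa, k = opts$k)
  readr::write_tsv(tidy(cl), file.path(out_dir, "groups.tsv"))
  write_manifest(
    out_dir, "cluster", file.path(out_dir, "activities.tsv"), opts,
    file.path(out_dir, "groups.tsv")
  )
  list(clusters = cl)
}

stage_associate <- function(config, out_dir) {
  opts <- stage_opts(config, "associate", list(
    annotations = file.path(out_dir, "annotations.tsv"),
    status_column = "status", alpha = 1e-4
  ))
  groups <- readr::read_tsv(
    require_artifact(file.path(out_dir, "groups.tsv"), "cluster"),
    show_col_types = FALSE
  )
  ann <- readr::read_tsv(
    require_artifact(opts$annotations, "simulate"),
    show_col_types = FALSE
  )
  ## the annotations may carry their own `group` column (condition design);
  ## the cluster group from groups.tsv wins the name
  merged <- dplyr::inner_join(
    groups, ann,
    by = "sample", suffix = c("", ".annotation")
  )
  status <- merged[[opts$status_column]]
  assoc <- associate_status(merged$group, status)
  tfa <- read_tfa_matrix(out_dir)[, merged$sample, drop = FALSE]
  lev <- sort(unique(status))
  tt <- tfa_ttest(tfa, which(status == lev[1]), which(status == lev[2]))
  sig <- derive_status_signature(tfa, setNames(status, merged$sample), alpha = opts$alpha)
  readr::write_tsv(tt, file.path(out_dir, "ttests.tsv"))
  readr::write_tsv(sig, file.path(out_dir, "signature.tsv"))
  jsonlite::write_json(
    list(
      chi2 = assoc$chi2, df = assoc$df, p = assoc$p, log10p = assoc$log10p,
      table = as.list(as.data.frame(attr(assoc, "table"))),
      continuity_correction = FALSE, test = "pearson_chi2_group1_vs_rest"
    ),
    file.path(out_dir, "association.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_manifest(
    out_dir, "associate",
    c(file.path(out_dir, "groups.tsv"), opts$annotations), opts,
    file.path(out_dir, c("ttests.tsv", "signature.tsv", "association.json"))
  )
  list(association = assoc, ttests = tt, signature = sig)
}

stage_report <- function(config, out_dir) {
  manifests <- list.files(out_dir, pattern = "\\.manifest\\.json$", full.names = TRUE)
  report <- lapply(manifests, jsonlite::read_json)
  names(report) <- sub("\\.manifest\\.json$", "", basename(manifests))
  jsonlite::write_json(
    report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  list(report = report)
}
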