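#' Run the train / cross-validate / replicate workflow from a config
#'
#' Executes the end-to-end training workflow described by a structured
#' configuration: read paired blood and target-tissue matrices, cross-validate
#' per-gene imputation models for each requested component count, train a
#' full-data bundle per K, optionally evaluate external replication against an
#' independent paired dataset, and write all outputs plus a run manifest
#' (package version, parameters, seed and input checksums) into `out_dir`.
#' Reruns with an identical config and seed reproduce the outputs exactly.
#'
#' @param config A named list, or the path to a YAML file, with fields:
#'   `blood`, `lung` (paths, required), `seed` (required), and optional
#'   `pcs` (vector, default 20), `folds` (default 5), `unit` (default
#'   `"normalized"`), `r2_min`, `q_max`, `rep_blood`, `rep_lung`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the per-K cross-validation results, the
#'   sweep summary tibble, and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Reading YAML configs requires the 'yaml' package.")
    }
    config <- yaml::read_yaml(config)
  }
  config <- validate_pipeline_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  blood <- read_expression_matrix(config$blood, unit = config$unit)
  lung <- read_expression_matrix(config$lung, unit = config$unit)
  rep_blood <- rep_lung <- NULL
  if (!is.null(config$rep_blood)) {
    rep_blood <- read_expression_matrix(config$rep_blood, unit = config$unit)
    rep_lung <- read_expression_matrix(config$rep_lung, unit = config$unit)
  }
  cvs <- list()
  summary_rows <- list()
  for (K in config$pcs) {
    cv <- cross_validate(blood, lung, K = K, k = config$folds,
                         seed = config$seed, r2_min = config$r2_min,
                         q_max = config$q_max)
    cvs[[as.character(K)]] <- cv
    readr::write_tsv(tibble::as_tibble(cv),
                     file.path(out_dir, sprintf("cv_K%d.tsv", K)),
                     progress = FALSE)
    bundle <- train_bundle(blood, lung, K = K)
    save_bundle(bundle, file.path(out_dir, sprintf("bundle_K%d", K)))
    sel <- select_genes(cv, r2_min = config$r2_min, q_max = config$q_max)
    row <- tibble::tibble(n_pcs = K, n_selected = nrow(sel),
                          mean_cv_accuracy = mean(sel$mean_fold_r))
    if (!is.null(rep_blood)) {
      rep <- evaluate_replication(cv, bundle, rep_blood, rep_lung)
      readr::write_tsv(tibble::as_tibble(rep),
                       file.path(out_dir, sprintf("replication_K%d.tsv", K)),
                       progress = FALSE)
      g <- glance(rep)
      row$n_imputed_rep <- g$n_evaluated
      row$mean_validation_accuracy <- g$mean_validation_accuracy
      row$n_replicated <- g$n_replicated
      row$pct_replicated <- g$pct_replicated
    }
    summary_rows[[as.character(K)]] <- row
  }
  summary <- dplyr::bind_rows(summary_rows)
  readr::write_tsv(summary, file.path(out_dir, "sweep_summary.tsv"),
                   progress = FALSE)
  inputs <- unlist(config[intersect(c("blood", "lung", "rep_blood", "rep_lung"),
                                    names(config))])
  manifest <- list(
    package = "crosstx",
    version = as.character(utils::packageVersion("crosstx")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = config,
    input_md5 = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cv = cvs, summary = summary, manifest = manifest))
}

validate_pipeline_config <- function(config) {
  if (!is.list(config)) abort("config must be a named list or a YAML file path.")
  defaults <- list(pcs = 20, folds = 5, unit = "normalized",
                   r2_min = 0.01, q_max = 0.05)
  config <- modifyList(defaults, config)
  for (field in c("blood", "lung", "seed")) {
    if (is.null(config[[field]])) {
      abort(sprintf("config field '%s' is required.", field))
    }
  }
  for (field in c("blood", "lung", "rep_blood", "rep_lung")) {
    path <- config[[field]]
    if (!is.null(path) && !file.exists(path)) {
      abort(sprintf("config field '%s': file '%s' does not exist.", field, path))
    }
  }
  if (xor(is.null(config$rep_blood), is.null(config$rep_lung))) {
    abort("config fields 'rep_blood' and 'rep_lung' must be given together.")
  }
  if (!is.numeric(config$pcs) || any(config$pcs < 1)) {
    abort("config field 'pcs' must be a vector of positive integers.")
  }
  if (!config$unit %in% expr_units()) {
    abort(sprintf("config field 'unit' must be one of: %s.",
                  paste(expr_units(), collapse = ", ")))
  }
  config$seed <- as.integer(config$seed)
  config
}
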