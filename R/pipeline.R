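# End-to-end workflow: data (loaded or generated) -> QC exclusion ->
# replicate split -> optional biomarker selection -> per-target ensembles
# -> consensus predictions on the testing replicates -> SMAPE summary ->
# train/test divergence screen -> random-walk significance benchmark.
# Everything is driven by one config list and one global seed; identical
# configs produce byte-identical outputs.

#' Assemble a pipeline run configuration
#'
#' @param data_path tidy concentration CSV to load, or `NULL` to generate
#'   synthetic data from `synth`.
#' @param biomarkers biomarker ids in the loaded data (required with
#'   `data_path`).
#' @param synth a [synth_spec()] used when `data_path` is `NULL`.
#' @param excluded_days sampling days to drop before analysis (QC).
#' @param oe an [oe_spec()]; default static FIR on the biomarker panel.
#' @param candidates,k when non-`NULL`, run exhaustive biomarker selection
#'   over `candidates` choose `k` and use the chosen panel downstream;
#'   otherwise the designated biomarkers are used as-is.
#' @param n_walks random walks per metabolite in the benchmark (default
#'   10000).
#' @param alpha,mean_diff_threshold divergence-screen settings, see
#'   [compare_train_test()].
#' @param seed global seed; the replicate split, generator and benchmark
#'   draw from streams derived from it.
#' @return a list of class `run_config`.
#' @export
run_config <- function(data_path = NULL, biomarkers = NULL,
                       synth = synth_spec(), excluded_days = numeric(0),
                       oe = NULL, candidates = NULL, k = NULL,
                       n_walks = 10000, alpha = 0.05,
                       mean_diff_threshold = 0.20, seed = 1) {
  structure(list(data_path = data_path, biomarkers = biomarkers,
                 synth = synth, excluded_days = excluded_days, oe = oe,
                 candidates = candidates, k = k, n_walks = n_walks,
                 alpha = alpha, mean_diff_threshold = mean_diff_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror [run_config()]: `data.path`, `data.biomarkers`,
#' `data.excluded_days`, `split.seed` (alias for the global seed), `seed`,
#' `n_walks`, `candidates`, `k`, `synth.*` fields.
#'
#' @param path YAML config file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth_args <- y$synth %||% list()
  cfg <- run_config(
    data_path = y$data$path,
    biomarkers = y$data$biomarkers,
    synth = do.call(synth_spec, synth_args),
    excluded_days = as.numeric(y$data$excluded_days %||% numeric(0)),
    candidates = y$candidates, k = y$k,
    n_walks = y$n_walks %||% 10000,
    seed = y$seed %||% y$split$seed %||% 1)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full forecasting workflow
#'
#' Executes every stage in order and writes each stage's table to
#' `out_dir`, plus a machine-readable `summary.json`.  Identical configs
#' give identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage messages.
#' @return invisibly, the summary list (also written as JSON): metabolite /
#'   target counts, chosen biomarkers, global median and sd of SMAPE,
#'   number and fraction significant, divergence fraction.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  if (!is.null(config$data_path)) {
    say("stage data: loading %s", config$data_path)
    ds <- read_dataset(config$data_path, config$biomarkers)
  } else {
    sy <- config$synth
    sy$seed <- derive_seed(config$seed, "synth")
    say("stage data: generating synthetic dataset (seed %d)", sy$seed)
    gen <- generate_dataset(sy)
    ds <- gen$dataset
    write_ground_truth(gen$ground_truth,
                       file.path(out_dir, "ground_truth_coefficients.csv"),
                       file.path(out_dir, "ground_truth_bag_factors.csv"))
  }

  if (length(config$excluded_days) > 0) {
    say("stage qc: excluding day(s) %s",
        paste(config$excluded_days, collapse = ", "))
    ds <- exclude_timepoints(ds, config$excluded_days)
  }

  split <- split_replicates(ds, config$seed)
  say("stage split: %d training / %d testing replicates",
      length(split$training_replicates), length(split$testing_replicates))

  biomarkers <- ds$biomarker_ids
  selection <- NULL
  if (!is.null(config$candidates) && !is.null(config$k)) {
    say("stage select: %d choose %d candidate panels",
        length(config$candidates), config$k)
    selection <- select_biomarkers(ds, split$training_replicates,
                                   config$candidates, config$k)
    biomarkers <- selection$chosen
    write_table(selection$table, file.path(out_dir, "selection.csv"))
  }

  spec <- config$oe %||% oe_spec(length(biomarkers))
  targets <- setdiff(ds$metabolites$metabolite_id,
                     union(biomarkers, config$candidates))
  say("stage train: %d ensembles of %d members", length(targets),
      length(split$training_replicates))
  predictions <- list()
  for (tgt in targets) {
    em <- train_ensemble(ds, split, tgt, spec, biomarker_ids = biomarkers)
    predictions[[tgt]] <- predict_targets(em, ds, split$testing_replicates)
  }

  pred_rows <- do.call(rbind, lapply(targets, function(tgt) {
    pr <- predictions[[tgt]]
    do.call(rbind, lapply(names(pr$replicates), function(r) {
      z <- pr$replicates[[r]]
      data.frame(target_id = tgt, replicate_id = r, time_days = ds$time_days,
                 consensus = z$consensus, measured = z$measured,
                 smape_of_replicate = z$smape, stringsAsFactors = FALSE)
    }))
  }))
  write_table(pred_rows, file.path(out_dir, "predictions.csv"))

  say("stage evaluate: summarizing %d metabolites", length(targets))
  summary_eval <- summarize_predictions(predictions)
  write_table(summary_eval$per_metabolite, file.path(out_dir, "smape_summary.csv"))

  say("stage divergence: train/test screen")
  div <- compare_train_test(ds, split, config$alpha, config$mean_diff_threshold)
  write_table(div$table, file.path(out_dir, "divergence.csv"))

  say("stage benchmark: %d walks per metabolite", config$n_walks)
  bench <- benchmark_dataset(ds, split, predictions,
                             n_walks = config$n_walks,
                             seed = derive_seed(config$seed, "benchmark"))
  write_table(bench, file.path(out_dir, "benchmark.csv"))

  summary <- list(
    n_metabolites = nrow(ds$metabolites),
    n_biomarkers = length(biomarkers),
    biomarkers = biomarkers,
    n_targets = length(targets),
    n_ensembles = length(targets),
    members_per_ensemble = length(split$training_replicates),
    n_timepoints = length(ds$time_days),
    global_median_smape = summary_eval$global_median,
    global_sd_smape = summary_eval$global_sd,
    n_significant = sum(bench$significant),
    fraction_significant = mean(bench$significant),
    divergence_flagged_fraction = div$flagged_fraction,
    n_walks = config$n_walks,
    seed = config$seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

pipeline_stage_files <- c(benchmark = "benchmark.csv",
                          evaluate = "smape_summary.csv",
                          predictions = "predictions.csv",
                          divergence = "divergence.csv",
                          summary = "summary.json")

#' Print the headline numbers of a completed run
#'
#' Reads `summary.json` (no recomputation) and prints the fractions a
#' reader cares about: significant targets, global median SMAPE, panel.
#'
#' @param out_dir a directory written by [run_pipeline()].
#' @return invisibly, the summary list.
#' @export
report_run <- function(out_dir) {
  for (stage in names(pipeline_stage_files)) {
    if (!file.exists(file.path(out_dir, pipeline_stage_files[[stage]])))
      rbf_stop(paste0("incomplete run: missing output of stage '", stage, "'"),
               "usage_error")
  }
  s <- jsonlite::read_json(file.path(out_dir, "summary.json"), simplifyVector = TRUE)
  cat(sprintf("run summary (%s)\n", out_dir))
  cat(sprintf("  metabolites: %d (%d biomarkers: %s)\n", s$n_metabolites,
              s$n_biomarkers, paste(s$biomarkers, collapse = ", ")))
  cat(sprintf("  ensembles: %d x %d members over %d time points\n",
              s$n_ensembles, s$members_per_ensemble, s$n_timepoints))
  cat(sprintf("  significant vs random walk: %d/%d (%.0f%%) at %d walks\n",
              s$n_significant, s$n_targets, 100 * s$fraction_significant,
              s$n_walks))
  cat(sprintf("  global SMAPE: median %.4f +/- %.4f (sd)\n",
              s$global_median_smape, s$global_sd_smape))
  cat(sprintf("  train/test divergence: %.1f%% of cells flagged\n",
              100 * s$divergence_flagged_fraction))
  invisible(s)
}
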