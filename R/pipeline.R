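## End-to-end pipeline: load or simulate -> standardize -> blocks -> waves ->
## hierarchical regression -> two-stage clustering -> engagement ordering ->
## salience profile, with seeded determinism and a machine-readable bundle of
## reports. Per-stage seeds are derived from the master seed and the stage
## name, so changing one stage's configuration never perturbs another's
## random stream. All numeric tables are emitted both as TSV and JSON, and
## every JSON output is byte-reproducible under a fixed master seed (timing
## information goes to the log only).

#' Pipeline run configuration
#'
#' Exactly one of `input` (a CSV path) or `sim_config` must be given.
#'
#' @param input path to a participant CSV in the documented schema.
#' @param sim_config a [simulation_config()] to generate data instead.
#' @param network a [network_config()].
#' @param cluster a [cluster_config()].
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param catalog behavior catalog.
#' @param reverse_cognitions see [standardize()].
#' @param holdout_estimates see [run_prediction_waves()].
#' @param salience_threshold |d| threshold for the salience profile.
#' @param verbose print one structured line per stage.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input = NULL, sim_config = NULL,
                       network = network_config(), cluster = cluster_config(),
                       out_dir = tempfile("milieu_run_"), seed = 1L,
                       catalog = default_catalog(),
                       reverse_cognitions = FALSE,
                       holdout_estimates = FALSE,
                       salience_threshold = 0.50,
                       verbose = TRUE) {
  if (is.null(input) == is.null(sim_config)) {
    stop("provide exactly one of `input` (CSV path) or `sim_config`",
         call. = FALSE)
  }
  structure(list(input = input, sim_config = sim_config, network = network,
                 cluster = cluster, out_dir = out_dir, seed = as.integer(seed),
                 catalog = catalog,
                 reverse_cognitions = isTRUE(reverse_cognitions),
                 holdout_estimates = isTRUE(holdout_estimates),
                 salience_threshold = salience_threshold,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

stage_log <- function(cfg, stage, ...) {
  if (cfg$verbose) {
    message(sprintf("[milieu] %-12s %s", stage, paste0(...)))
  }
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  path
}

write_tsv_out <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage and writes a reproducible artifact bundle to
#' `config$out_dir`: the analyzed data (`data.csv` when simulated, plus
#' `ground_truth.json`), the wave summary (`waves.json`) and serialized
#' saturated network (`network_saturated.json`), the incremental-validity
#' table (`regression.tsv`/`.json`), the salience report with sub-threshold
#' cells blanked (`salience.tsv`) and the full d matrix
#' (`salience_full.tsv`/`salience.json`), cluster assignments
#' (`clusters.json`), and a `manifest.json` echoing seeds and configuration.
#' Any stage failure aborts with the stage name.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with all intermediate objects: `raw`, `truth`,
#'   `std`, `blocks`, `waves`, `regression`, `solution`, `salience`, and
#'   `files` (the bundle paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  if (!is.null(config$sim_config)) {
    gen <- run_stage("simulate",
                     generate_dataset(config$sim_config,
                                      seed = derive_seed(config$seed, "simulate")))
    raw <- gen$raw
    truth <- gen$truth
    files["data"] <- write_raw(raw, file.path(config$out_dir, "data.csv"))
    files["truth"] <- write_json_out(
      list(group_labels = truth$group_labels,
           group_names = truth$group_names,
           latent_propensity = truth$latent_propensity,
           planted_increments = truth$planted_increments),
      file.path(config$out_dir, "ground_truth.json"))
    stage_log(config, "simulate", "n=", n_participants(raw))
  } else {
    raw <- run_stage("load", load_raw(config$input, config$catalog))
    stage_log(config, "load", "n=", n_participants(raw), " from ", config$input)
  }

  std <- run_stage("standardize",
                   standardize(raw, reverse_cognitions = config$reverse_cognitions))
  blocks <- run_stage("blocks", assemble_blocks(std))
  stage_log(config, "blocks",
            paste(names(block_widths(blocks)), block_widths(blocks),
                  sep = "=", collapse = ", "))

  net_cfg <- config$network
  net_cfg$seed <- derive_seed(config$seed, "network")
  waves <- run_stage("waves",
                     run_prediction_waves(blocks, std$health_index, net_cfg,
                                          holdout_estimates = config$holdout_estimates))
  stage_log(config, "waves",
            paste(sprintf("%s r=%.2f", names(waves),
                          vapply(waves, `[[`, numeric(1), "r_with_target")),
                  collapse = ", "))
  files["network"] <- write_network(waves$saturated$model,
                                    file.path(config$out_dir,
                                              "network_saturated.json"))
  files["waves"] <- write_json_out(
    lapply(unclass(waves), function(w)
      list(wave = w$wave_name, r = w$r_with_target,
           epochs = w$model$epochs, restart = w$model$restart,
           estimates = w$estimates)),
    file.path(config$out_dir, "waves.json"))

  hr <- run_stage("regression", hierarchical_regression(waves, std$health_index))
  tab2 <- regression_table(hr)
  stage_log(config, "regression",
            sprintf("final adj R2 = %.3f", hr$final$adj_r2))
  files["regression_tsv"] <- write_tsv_out(tab2, file.path(config$out_dir,
                                                           "regression.tsv"))
  files["regression_json"] <- write_json_out(
    list(table = tab2, final = hr$final,
         steps = lapply(hr$steps, function(s)
           s[c("step_index", "predictors", "r2", "adj_r2", "delta_r2",
               "delta_adj_r2", "f_change", "df", "p_value")])),
    file.path(config$out_dir, "regression.json"))

  clu_cfg <- config$cluster
  clu_cfg$seed <- derive_seed(config$seed, "cluster")
  feat <- run_stage("cluster",
                    build_cluster_matrix(blocks, waves$saturated, clu_cfg))
  solution <- run_stage("cluster", two_stage_cluster(feat, clu_cfg))
  solution <- run_stage("ordering",
                        engagement_ordering(solution, std$health_index))
  stage_log(config, "cluster", "k=", solution$k, ", sizes ",
            paste(solution$sizes, collapse = "/"))
  files["clusters"] <- write_json_out(
    list(k = solution$k, sizes = solution$sizes, labels = solution$labels,
         engagement_mean = solution$engagement_mean,
         engagement_d = solution$engagement_d,
         assignments = solution$assignments),
    file.path(config$out_dir, "clusters.json"))

  sal <- run_stage("salience",
                   salience_profile(solution, std, blocks,
                                    threshold = config$salience_threshold))
  files["salience_tsv"] <- write_tsv_out(salience_table(sal),
                                         file.path(config$out_dir,
                                                   "salience.tsv"))
  files["salience_full_tsv"] <- write_tsv_out(
    salience_table(sal, full = TRUE, digits = 4),
    file.path(config$out_dir, "salience_full.tsv"))
  files["salience_json"] <- write_json_out(
    list(threshold = sal$threshold, groups = sal$labels, sizes = sal$sizes,
         d = as.data.frame(sal$d_matrix),
         variables = rownames(sal$d_matrix),
         salient = as.data.frame(sal$salient_mask)),
    file.path(config$out_dir, "salience.json"))
  stage_log(config, "salience", sum(sal$salient_mask, na.rm = TRUE),
            " salient cells")

  manifest <- list(
    package_version = as.character(utils::packageVersion("milieu")),
    seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, "simulate"),
                       network = derive_seed(config$seed, "network"),
                       cluster = derive_seed(config$seed, "cluster")),
    input = config$input,
    simulated = !is.null(config$sim_config),
    n_participants = n_participants(raw),
    network = unclass(config$network),
    cluster = unclass(config$cluster)[c("feature_mode", "k_min", "k_max",
                                        "refine_with_kmeans",
                                        "min_cluster_size")],
    salience_threshold = config$salience_threshold,
    files = as.list(vapply(files, basename, character(1))))
  files["manifest"] <- write_json_out(manifest,
                                      file.path(config$out_dir, "manifest.json"))
  stage_log(config, "done",
            sprintf("%.1fs -> %s", proc.time()[["elapsed"]] - t0,
                    config$out_dir))

  invisible(list(raw = raw, truth = truth, std = std, blocks = blocks,
                 waves = waves, regression = hr, solution = solution,
                 salience = sal, files = files, manifest = manifest))
}
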