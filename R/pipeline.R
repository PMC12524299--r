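#' Run the full simulate / build / evaluate pipeline
#'
#' Convenience driver gluing the stages together: simulate a synthetic
#' panel session, build per-panelist and panel-mean curves, bootstrap each
#' condition, evaluate the requested architectures by leave-one-pairing-out
#' cross-validation and rank them. Each stage logs its size and timing.
#'
#' @param config Run configuration from [read_run_config()] /
#'   [default_run_config()].
#' @param out_dir Optional directory; when given, the event log, curve CSV,
#'   results JSON, report CSV and a config snapshot are written there.
#' @param quiet Suppress progress messages.
#' @return A list with `trials`, `panel` (per-panelist curves),
#'   `panel_means`, `dataset` (bootstrap replicates), `results` and
#'   `report`.
#' @export
run_tl_pipeline <- function(config = default_run_config(), out_dir = NULL,
                            quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stamp <- function(expr, what) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    say("%s [%.1f s]", what, proc.time()[["elapsed"]] - t0)
    res
  }
  design <- study_design(n_panelists = config$n_panelists,
                         n_repetitions = config$n_repetitions)
  grid <- time_grid(config$grid_points)

  trials <- stamp(simulate_panel(design, seed = config$seed),
                  sprintf("simulated %d trials (seed %d)",
                          design$n_panelists * nrow(design$conditions) *
                            2 * design$n_repetitions, config$seed))
  panel <- stamp(build_panel_curves(trials, grid),
                 "built per-panelist curve pairs")
  panel_means <- lapply(panel, build_panel_mean)
  dataset <- stamp(
    bootstrap_panel(panel, n_replicates = config$n_replicates,
                    seed = config$seed),
    sprintf("bootstrapped %d replicates per condition",
            config$n_replicates))
  results <- stamp(
    sweep_architectures(dataset, neurons = config$neurons,
                        aux_configs = config$aux_configs,
                        seed = config$seed,
                        spectral_radius = config$spectral_radius,
                        leak_rate = config$leak_rate,
                        input_scaling = config$input_scaling,
                        recurrent_density = config$recurrent_density,
                        input_density = config$input_density,
                        ridge = config$ridge, washout = config$washout,
                        clip = config$clip, pooling = config$pooling),
    sprintf("evaluated %d architecture(s)",
            length(config$neurons) * length(config$aux_configs)))
  report <- rank_architectures(results)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_event_log(trials, file.path(out_dir, "event_log.csv"))
    write_curves(c(panel,
                   list(panel_mean = unname(panel_means)),
                   stats::setNames(dataset,
                                   paste0(names(dataset), "_boot"))),
                 file.path(out_dir, "curves.csv"))
    write_eval_results(results, file.path(out_dir, "results.json"))
    write_report(report, file.path(out_dir, "report.csv"))
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    say("outputs written to %s", out_dir)
  }
  list(trials = trials, panel = panel, panel_means = panel_means,
       dataset = dataset, results = results, report = report)
}
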