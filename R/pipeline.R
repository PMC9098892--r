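# End-to-end driver: simulate all three data modalities under one global
# seed, run every analysis stage, and write deterministic result CSVs plus
# a JSON run report. Child seeds are derived from the global seed with
# child_seed() so the three simulators consume independent streams.

#' Run the full simulation-and-analysis pipeline
#'
#' Simulates spine-tracking, calcium-trace and tracing-count data under the
#' configured sizes, runs the complete analysis layer (transition
#' classification, turnover rates, density, persistence, morphology
#' fractions; filtering, compensation, transient detection, activity
#' fractions with bootstrap CIs; starter interpolation and connectivity
#' tables) and writes all inputs and results under `out_dir`. Identical
#' config and seed give byte-identical outputs (no timestamps are written).
#'
#' @param config configuration list, see [default_run_config()].
#' @param out_dir output directory; created if needed. Outputs are staged in
#'   a temporary sibling directory and moved into place only on success, so
#'   a failing run leaves no partial `out_dir`.
#' @return invisibly, a list with the in-memory results (`spines`,
#'   `calcium`, `tracing`, `report`).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  config <- validate_run_config(utils::modifyList(default_run_config(), config))
  abort_if(missing(out_dir) || !is.character(out_dir),
           "out_dir must be a directory path")
  stage <- paste0(out_dir, ".staging")
  unlink(stage, recursive = TRUE)
  dir.create(stage, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage, recursive = TRUE))

  seed <- config$seed
  # --- spines ---------------------------------------------------------------
  sp <- config$spine_sim
  spine_params <- spine_sim_params(
    n_dendrites = sp$n_dendrites,
    spines_per_dendrite_mean = sp$spines_per_dendrite_mean,
    dendrite_length_um = sp$dendrite_length_um,
    session_times = config$session_order,
    elimination_prob = sp$elimination_prob,
    formation_rate = sp$formation_rate,
    seed = child_seed(seed, 1))
  spine_sim <- simulate_spine_tracks(spine_params)
  write_spine_tracks(spine_sim$tracks, file.path(stage, "spine_tracks.csv"))

  trans <- classify_transitions(spine_sim$tracks, config$session_order)
  rates <- turnover_rates(trans)
  rate_summary <- do.call(rbind, lapply(
    c("elimination_rate_pct", "formation_rate_pct", "stable_fraction_pct"),
    function(v) cbind(metric = v,
                      aggregate_series(rates, v, c("session_from", "session_to")))))
  density_final <- spine_density(spine_sim$tracks,
                                 config$session_order[length(config$session_order)])
  persistence <- persistence_index(spine_sim$tracks, config$session_order,
                                   config$baseline_sessions,
                                   config$persistence_denominator)
  morph <- morphology_fractions(spine_sim$tracks, config$session_order[1L])
  utils::write.csv(rates, file.path(stage, "turnover_per_dendrite.csv"),
                   row.names = FALSE)
  utils::write.csv(rate_summary, file.path(stage, "turnover_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(density_final, file.path(stage, "spine_density.csv"),
                   row.names = FALSE)
  utils::write.csv(persistence, file.path(stage, "persistence.csv"),
                   row.names = FALSE)
  utils::write.csv(morph, file.path(stage, "morphology_fractions.csv"),
                   row.names = FALSE)

  # --- calcium --------------------------------------------------------------
  ca <- config$calcium_sim
  det <- config$detection
  calcium_params <- calcium_sim_params(
    n_neurons = ca$n_neurons, n_frames = ca$n_frames,
    frame_rate_hz = ca$frame_rate_hz,
    event_rate_per_min = ca$event_rate_per_min,
    neuropil_coefficient = det$alpha,
    seed = child_seed(seed, 2))
  calcium_sim <- simulate_calcium_recording(calcium_params)
  write_traces(calcium_sim$traces, file.path(stage, "calcium_traces.csv"))
  activity <- analyze_traces(calcium_sim$traces, ca$frame_rate_hz,
                             alpha = det$alpha, cutoff_hz = det$cutoff_hz,
                             min_duration_frames = det$min_duration_frames,
                             k_sigma = det$k_sigma)
  boot <- bootstrap_fraction_ci(activity$active,
                                n_iterations = config$bootstrap$n_iterations,
                                level = config$bootstrap$level,
                                seed = child_seed(seed, 3),
                                resample_unit = config$bootstrap$unit)
  utils::write.csv(activity, file.path(stage, "calcium_activity.csv"),
                   row.names = FALSE)

  # --- tracing --------------------------------------------------------------
  tr <- config$tracing_sim
  tracing_params <- tracing_sim_params(
    n_brains = tr$n_brains, n_starters_true = tr$n_starters_true,
    sections_imaged = tr$sections_imaged, sections_total = tr$sections_total,
    seed = child_seed(seed, 4))
  tracing_sim <- simulate_tracing_experiment(tracing_params)
  utils::write.csv(tracing_sim$counts, file.path(stage, "tracing_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(tracing_sim$starters, file.path(stage, "tracing_starters.csv"),
                   row.names = FALSE)
  conn <- build_connectivity_table(tracing_sim$counts, tracing_sim$starters)
  utils::write.csv(conn$table, file.path(stage, "connectivity_table.csv"),
                   row.names = FALSE)

  # --- report ---------------------------------------------------------------
  report <- run_report(
    config = config,
    summaries = list(
      spine = list(
        n_dendrites = length(unique(spine_sim$tracks$dendrite_id)),
        n_spines = length(unique(spine_sim$tracks$spine_id)),
        mean_elimination_rate_pct =
          mean(rates$elimination_rate_pct, na.rm = TRUE),
        mean_formation_rate_pct =
          mean(rates$formation_rate_pct, na.rm = TRUE),
        undefined_rate_pairs = sum(is.na(rates$elimination_rate_pct)),
        persistence_undefined = sum(is.na(persistence$persistence_index))),
      calcium = list(
        n_neurons = nrow(activity),
        fraction_active = boot$estimate,
        fraction_active_ci = c(boot$ci_low, boot$ci_high),
        bootstrap_iterations = boot$n_iterations),
      tracing = list(
        n_brains = tr$n_brains,
        excluded_brains = conn$excluded_brains)))
  jsonlite::write_json(report, file.path(stage, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report_markdown(report), file.path(stage, "run_report.md"))

  unlink(out_dir, recursive = TRUE)
  ok <- file.rename(stage, out_dir)
  abort_if(!ok, "could not move staged results into %s", out_dir)
  invisible(list(
    spines = list(sim = spine_sim, transitions = trans, rates = rates,
                  summary = rate_summary, density = density_final,
                  persistence = persistence, morphology = morph),
    calcium = list(sim = calcium_sim, activity = activity, bootstrap = boot),
    tracing = list(sim = tracing_sim, connectivity = conn),
    report = report))
}

#' Assemble a machine-readable run report
#'
#' Collects package version, configuration hash, seeds and per-module
#' summary tables (including undefined-value exclusion counts) into one
#' list; serialised as JSON and Markdown by [run_pipeline()]. Contains no
#' timestamps, so regenerating with identical inputs yields identical
#' content.
#'
#' @param config the resolved configuration.
#' @param summaries named list of per-module summaries.
#' @return report list.
#' @export
run_report <- function(config, summaries) {
  abort_if(length(summaries) < 1L, "at least one module summary is required")
  list(package = "contraplast",
       version = as.character(utils::packageVersion("contraplast")),
       config_hash = config_hash(config),
       seed = config$seed,
       child_seeds = list(spines = child_seed(config$seed, 1),
                          calcium = child_seed(config$seed, 2),
                          bootstrap = child_seed(config$seed, 3),
                          tracing = child_seed(config$seed, 4)),
       config = config,
       summaries = summaries)
}

report_markdown <- function(report) {
  s <- report$summaries
  c(sprintf("# %s run report", report$package),
    "",
    sprintf("- version: %s", report$version),
    sprintf("- seed: %s (config hash %s)", report$seed, report$config_hash),
    "",
    "## Spine dynamics",
    sprintf("- %d dendrites, %d spines tracked", s$spine$n_dendrites,
            s$spine$n_spines),
    sprintf("- mean elimination rate %.2f%%, mean formation rate %.2f%%",
            s$spine$mean_elimination_rate_pct, s$spine$mean_formation_rate_pct),
    sprintf("- undefined rate pairs excluded: %d; undefined persistence: %d",
            s$spine$undefined_rate_pairs, s$spine$persistence_undefined),
    "",
    "## Calcium activity",
    sprintf("- %d neurons, fraction active %.3f (95%% CI %.3f-%.3f, %d bootstrap iterations)",
            s$calcium$n_neurons, s$calcium$fraction_active,
            s$calcium$fraction_active_ci[1L], s$calcium$fraction_active_ci[2L],
            s$calcium$bootstrap_iterations),
    "",
    "## Connectivity",
    sprintf("- %d brains; excluded for zero starters: %s", s$tracing$n_brains,
            if (length(s$tracing$excluded_brains) == 0) "none"
            else paste(s$tracing$excluded_brains, collapse = ", ")))
}
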