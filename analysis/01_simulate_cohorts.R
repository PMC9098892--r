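#!/usr/bin/env Rscript
# Generate the three synthetic cohorts every downstream analysis consumes:
# a longitudinal spine-tracking cohort with an injury-phase hazard profile,
# tri-session calcium recordings for two neuron populations, and
# tracing-count tables for four experimental groups.
# Outputs: results/data/*.csv (+ JSON ground-truth sidecars).

suppressPackageStartupMessages(library(contraplast))

seed <- 20260901L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sessions <- c("B1", "B2", "3d", "6d", "9d", "12d", "15d", "18d", "21d")
post <- sessions[-1]
# hazard profile: quiet baselines, an acute surge in elimination after the
# lesion, then gradual recovery with a formation overshoot
elim <- setNames(c(0.05, 0.22, 0.16, 0.12, 0.09, 0.07, 0.06, 0.05), post)
form <- setNames(c(0.05, 0.08, 0.12, 0.11, 0.09, 0.07, 0.06, 0.05), post)
sp <- spine_sim_params(n_dendrites = 81, spines_per_dendrite_mean = 126,
                       session_times = sessions,
                       elimination_prob = elim, formation_rate = form,
                       seed = child_seed(seed, 1))
spines <- simulate_spine_tracks(sp)
write_spine_tracks(spines$tracks, file.path(out, "spine_tracks.csv"))
jsonlite::write_json(spines$truth, file.path(out, "spine_truth.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("spines: %d dendrites, %d spines, %d sessions",
                length(unique(spines$tracks$dendrite_id)),
                length(unique(spines$tracks$spine_id)), length(sessions)))

# calcium: callosal (139 neurons) and non-callosal (663) populations at
# baseline / 10d / 42d, with depressed mid-session event rates
rates <- c(baseline = 1.2, d10 = 0.3, d42 = 0.8)
pops <- list(callosal = 139, non_callosal = 663)
k <- 0L
for (pop in names(pops)) {
  for (sess in names(rates)) {
    k <- k + 1L
    sim <- simulate_calcium_recording(calcium_sim_params(
      n_neurons = pops[[pop]], n_frames = 6000,
      event_rate_per_min = rates[[sess]], seed = child_seed(seed, 10 + k)))
    write_traces(sim$traces,
                 file.path(out, sprintf("calcium_%s_%s.csv", pop, sess)))
  }
}
message(sprintf("calcium: %d trace files (%s x %s)", k,
                paste(names(pops), collapse = "/"),
                paste(names(rates), collapse = "/")))

# tracing: four groups; TBI 7d with depressed contralesional input
mk_means <- function(scale) c(somatosensory = 800 * scale, motor = 300 * scale,
                              auditory = 150 * scale,
                              retrosplenial = 120 * scale,
                              thalamus = 200 * scale)
groups <- list(control_7d = 1, tbi_7d = 0.45, control_42d = 1, tbi_42d = 0.9)
counts <- NULL; starters <- NULL
for (g in names(groups)) {
  sim <- simulate_tracing_experiment(tracing_sim_params(
    mean_presyn_per_region = mk_means(groups[[g]]),
    n_brains = 7, group = g, seed = child_seed(seed, 30 + match(g, names(groups)))))
  counts <- rbind(counts, sim$counts)
  starters <- rbind(starters, sim$starters)
}
write.csv(counts, file.path(out, "tracing_counts.csv"), row.names = FALSE)
write.csv(starters, file.path(out, "tracing_starters.csv"), row.names = FALSE)
message(sprintf("tracing: %d brains across %d groups",
                nrow(starters), length(groups)))
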