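#!/usr/bin/env Rscript
# Longitudinal spine dynamics of the simulated cohort: per-dendrite
# transition counts, elimination/formation rates, density time course,
# morphology fractions and persistence indices by spine class.
# Reads results/data/spine_tracks.csv; writes results/spines/*.csv.

suppressPackageStartupMessages(library(contraplast))

tracks <- read_spine_tracks("results/data/spine_tracks.csv")
truth <- jsonlite::read_json("results/data/spine_truth.json",
                             simplifyVector = TRUE)
sessions <- truth$session_times
out <- "results/spines"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rates <- turnover_rates(classify_transitions(tracks, sessions))
write.csv(rates, file.path(out, "turnover_per_dendrite.csv"), row.names = FALSE)
summary_tab <- do.call(rbind, lapply(
  c("elimination_rate_pct", "formation_rate_pct", "stable_fraction_pct"),
  function(v) cbind(metric = v,
                    aggregate_series(rates, v, c("session_from", "session_to")))))
write.csv(summary_tab, file.path(out, "turnover_summary.csv"), row.names = FALSE)

# truth hazards are ordered over the post-first transitions (JSON sidecars
# carry no names on numeric vectors)
acute_i <- 2L   # transition B2 -> first post-injury session
acute <- summary_tab[summary_tab$session_to == sessions[acute_i + 1L], ]
message(sprintf(
  "acute transition %s->%s: elimination %.1f%% (true %.0f%%), formation %.1f%% (true %.0f%%)",
  sessions[acute_i], sessions[acute_i + 1L],
  acute$mean[acute$metric == "elimination_rate_pct"],
  100 * truth$elimination_prob[[acute_i]],
  acute$mean[acute$metric == "formation_rate_pct"],
  100 * truth$formation_rate[[acute_i]]))

dens <- do.call(rbind, lapply(sessions, function(s) {
  cbind(session = s, aggregate_series(spine_density(tracks, s),
                                      "density_per_um", "dendrite_length_um"))
}))
write.csv(dens, file.path(out, "density_timecourse.csv"), row.names = FALSE)
message(sprintf("density: %.2f spines/um at %s -> %.2f at %s",
                dens$mean[1], sessions[1],
                dens$mean[nrow(dens)], sessions[length(sessions)]))

morph <- do.call(rbind, lapply(c(sessions[1], sessions[length(sessions)]),
  function(s) cbind(session = s, morphology_fractions(tracks, s))))
write.csv(morph, file.path(out, "morphology_fractions.csv"), row.names = FALSE)

pers <- persistence_index(tracks, sessions, c("B1", "B2"))
write.csv(pers, file.path(out, "persistence.csv"), row.names = FALSE)
for (cls in c("pre_existing", "newly_formed")) {
  v <- pers$persistence_index[pers$class == cls]
  message(sprintf("persistence (%s): n=%d, median %.3f [IQR %.3f-%.3f]",
                  cls, sum(!is.na(v)), median(v, na.rm = TRUE),
                  quantile(v, 0.25, na.rm = TRUE),
                  quantile(v, 0.75, na.rm = TRUE)))
}
mw <- standard_test("mann_whitney", list(
  x = pers$persistence_index[pers$class == "pre_existing"],
  y = pers$persistence_index[pers$class == "newly_formed"]))
message(sprintf("pre-existing vs newly formed persistence: %s p = %.3g",
                mw$method, mw$p_value))
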