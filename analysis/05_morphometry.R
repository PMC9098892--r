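#!/usr/bin/env Rscript
# Histomorphometry of the fixture measurements: lesion volume (Cavalieri),
# cortical thickness, cell density and synaptic-pair densities.
# Writes results/morphometry/summary.csv.

suppressPackageStartupMessages(library(contraplast))

out <- "results/morphometry"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fix <- read.csv(system.file("extdata", "morphometry_fixtures.csv",
                            package = "contraplast"))
lesion_areas <- fix$value[fix$measure == "lesion_area_mm2"]
vol <- lesion_volume(lesion_areas, section_spacing_mm = 0.05)
thick <- cortical_thickness(fix$value[fix$measure == "cortical_thickness_mm"])

# illustrative cell-count and synaptic-pair measurements
dens <- cell_density(n_cells = 250, area_mm2 = 0.5)
pairs <- synaptic_pair_density(excitatory_pairs = 12, inhibitory_pairs = 4,
                               perimeter_length_um = 40)

summary <- data.frame(
  quantity = c("lesion_volume_mm3", "cortical_thickness_mm",
               "cell_density_per_mm2", "excitatory_pairs_per_um",
               "inhibitory_pairs_per_um"),
  value = c(vol, thick, dens, pairs$excitatory_per_um, pairs$inhibitory_per_um))
write.csv(summary, file.path(out, "summary.csv"), row.names = FALSE)

message(sprintf("lesion volume: %.3f mm^3 over %d sections at 50 um spacing",
                vol, length(lesion_areas)))
message(sprintf("cortical thickness: %.2f mm (mean of 3 medio-lateral points)",
                thick))
message(sprintf("cell density: %.0f cells/mm^2; synaptic pairs: %.2f exc, %.2f inh per um",
                dens, pairs$excitatory_per_um, pairs$inhibitory_per_um))
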