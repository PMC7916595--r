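#!/usr/bin/env Rscript
# Step 3: apparent-mass calibration and migration-shift detection.
#
# Fits the slice-to-mass calibration from the wild-type marker complexes
# plus the gel endpoints, then calls peaks on every normalised profile and
# classifies them as matched, gained or lost between conditions.  The
# knock-out hallmarks to look for: MT-CO1's residual ~130 kDa species and
# the ~750 kDa complex I precomplex gained by non-N-module subunits.

library(comprof)

scenario <- read_scenario_config("results/scenario.yaml")
evidence <- read_evidence("results/evidence.tsv", scenario$gel$n_slices)
annotation <- read_complex_annotation("results/annotation.tsv")
mapped <- map_channels_to_conditions(evidence, scenario_swap_map(scenario))
profiles <- build_profiles(mapped, scenario$gel$n_slices, scenario$conditions)
ratios <- protein_ratios(mapped, scenario$conditions, scenario$mixing_ratio)

calibration <- self_calibration(profiles, scenario$gel, "wt")
print(calibration)
write_marker_table(attr(calibration, "markers"), "results/markers.tsv")

report <- comparison_report(profiles, ratios, annotation, calibration,
                            scenario$conditions)
write.table(report$shifts, "results/shifts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pk <- detect_peaks(profile_get(profiles, "MT-CO1", "KO"),
                   calibration = calibration)
dom <- pk[which.max(pk$rel_height), ]
cat(sprintf("\nMT-CO1 dominant KO peak: slice %.1f, %.0f kDa\n",
            dom$slice, dom$mass_kda))

gained <- report$shifts[report$shifts$direction == "gained", ]
ci <- oxphos_rosters()$cI
ci_gained <- gained[gained$protein_id %in% ci, ]
near750 <- ci_gained[abs(ci_gained$mass_kda - 750) / 750 <= 0.15, ]
cat(sprintf("complex I subunits gaining a ~750 kDa KO peak: %d of %d\n",
            length(unique(near750$protein_id)), length(ci)))
n_mod <- oxphos_rosters()$cI_N_module
cat(sprintf("  of which N-module subunits: %d (expected 0 of %d)\n",
            length(intersect(unique(near750$protein_id), n_mod)),
            length(n_mod)))
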