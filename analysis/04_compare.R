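#!/usr/bin/env Rscript
# Step 4: comparative summaries.
#
# Complex-level fold changes, the mitoribosome depletion, co-migration of
# the residual complex IV assembly factors with MT-CO1, and the label-free
# style log2 fold-change table.  Everything downstream of the evidence is
# deterministic, so this reproduces the step-2/3 quantities it needs.

library(comprof)

scenario <- read_scenario_config("results/scenario.yaml")
evidence <- read_evidence("results/evidence.tsv", scenario$gel$n_slices)
annotation <- read_complex_annotation("results/annotation.tsv")
mapped <- map_channels_to_conditions(evidence, scenario_swap_map(scenario))
profiles <- build_profiles(mapped, scenario$gel$n_slices, scenario$conditions)
ratios <- protein_ratios(mapped, scenario$conditions, scenario$mixing_ratio)
calibration <- self_calibration(profiles, scenario$gel, "wt")

report <- comparison_report(
  profiles, ratios, annotation, calibration, scenario$conditions,
  comigration_proteins = c("MT-CO1", "COA3", "HIGD1A", "HIGD2A",
                           "COX5B", "NDUFA4"))
write.table(report$proteins, "results/report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(report$complexes, "results/complexes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(report$comigration, "results/comigration.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

fc <- function(cx) complex_fold_change(ratios, annotation, cx)
cat(sprintf("complex I depletion (median wt/KO):   %.2f-fold\n",
            fc("cI")$median_ratio))
cat(sprintf("complex II (unchanged control):       %.2f\n",
            fc("cII")$median_ratio))
cat(sprintf("complex III (shifted, mildly lower):  %.2f\n",
            fc("cIII")$median_ratio))
civ <- fc("cIV")
cat(sprintf("complex IV: %d of %d subunits absent in KO; residual median %.1f\n",
            civ$n_absent_perturbed,
            civ$n_absent_perturbed + civ$n_finite, civ$median_ratio))
mito <- c(oxphos_rosters()$mtLSU, oxphos_rosters()$mtSSU)
cat(sprintf("mitoribosome (mtLSU+mtSSU) median:    %.2f-fold\n",
            median(ratios$ratio[ratios$protein_id %in% mito], na.rm = TRUE)))
af <- ratios$ratio[ratios$protein_id %in% c("DDX28", "ERAL1")]
cat(sprintf("DDX28/ERAL1 geometric mean:           %.2f-fold\n",
            exp(mean(log(af)))))

cm <- comigration_score(profile_get(profiles, "MT-CO1", "KO"),
                        profile_get(profiles, "COA3", "KO"))
cat(sprintf("MT-CO1 ~ COA3 co-migration (KO):      r = %.3f\n", cm$r))

ab <- protein_abundances(mapped)
lfc <- lfq_log2fc_summary(ab, annotation, "wt")
write.csv(lfc, "results/log2fc.csv", row.names = FALSE)
mlfc <- median(lfc$log2fc[lfc$complex_id %in% c("mtLSU", "mtSSU")],
               na.rm = TRUE)
cat(sprintf("mitoribosome median log2 fold change: %.2f\n", mlfc))
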