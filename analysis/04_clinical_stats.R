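#!/usr/bin/env Rscript
# Stage 4: region volumes and downstream clinical statistics.
#
# Integrates per-subject GM volume inside the TIS mask (on the unsmoothed
# cohort, so volumes are physical), derives the change table across all
# outcome analogues, the between-arm comparisons, the per-arm Pearson
# correlation matrices of change scores with average-linkage heat-map
# ordering, and the annualized whole-GM loss per arm.

library(vbmsparing)

raw <- read_cohort("results/cohort")
tis_mask_vol <- read_volume("results/maps/tis_mask.nii.gz")
tis_mask <- region_mask(round(tis_mask_vol$data), "TIS",
                        tis_mask_vol$affine, tis_mask_vol$voxel_size_mm)

vols <- region_volume_series(raw, tis_mask)
cat(sprintf("TIS GM volume percent-change difference (treated - placebo): %.2f +/- %.2f %%\n",
            vols$group_diff$estimate_pct, vols$group_diff$se_pct))

whole <- region_volume_series(raw, raw$brain_mask)
arm <- tapply(-whole$subjects$annualized_pct, whole$subjects$group, mean)
cat(sprintf("annualized whole-GM loss: treated %.2f %%, placebo %.2f %%\n",
            arm[["treated"]], arm[["placebo"]]))

outcomes <- outcome_table(raw, vols)
changes <- change_table(outcomes)
print(changes, digits = 2)

cors <- pearson_matrix(outcomes, by_group = TRUE)
treated <- outcomes[outcomes$group == "treated", ]
cat(sprintf("treated arm: corr(TIS change, PASAT2 change) = %.2f; corr(TIS change, CSF change) = %.2f\n",
            cor(treated$tis_ml_change, treated$pasat2_change),
            cor(treated$tis_ml_change, treated$csf_ml_change)))

dir.create("results/stats", showWarnings = FALSE, recursive = TRUE)
write.csv(vols$subjects, "results/stats/tis_volumes.csv", row.names = FALSE)
write.csv(outcomes, "results/stats/outcomes.csv", row.names = FALSE)
write.csv(changes, "results/stats/change_table.csv", row.names = FALSE)
for (g in names(cors)) {
  write.csv(cors[[g]]$r, sprintf("results/stats/correlations_%s.csv", g))
  correlation_heatmap(cors[[g]], sprintf("results/stats/heatmap_%s.png", g),
                      paste("correlation of changes,", g, "arm"))
}
cat("written: results/stats/\n")
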