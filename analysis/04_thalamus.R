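#!/usr/bin/env Rscript
# Stage 4 — per-nucleus thalamic compartment bias.
#
# Renormalizes and trims each thalamic probability pair, counts
# suprathreshold voxels per nucleus (share >= 0.55), applies the
# four-voxel nucleus volume filter and the 10 % / zero-compartment
# subject-hemisphere QC, and writes the per-record matrix fractions.
# Finding: pooled per-nucleus fractions recover the planted bias table to
# about +/- 0.02.

suppressPackageStartupMessages(library(striothal))

seed <- 20260924L
params <- cohort_params(n_subjects = 20, spacing = 1.5, seed = seed)
config <- default_config(params)
cohort <- generate_cohort(params, components = "thalamic")

thal <- stage_thalamus(cohort, config)
write.csv(thal$records, "results/nucleus_records.csv", row.names = FALSE)
write.csv(thal$qc$exclusions, "results/qc_exclusions.csv",
          row.names = FALSE)
write.csv(thal$volume_filter, "results/nucleus_volume_filter.csv",
          row.names = FALSE)

pooled <- tapply(thal$records$matrix_fraction, thal$records$nucleus, mean)
n_left <- tapply(thal$records$hemisphere == "left", thal$records$nucleus,
                 mean)
planted <- params$nucleus_bias + params$asymmetry_delta *
  n_left[names(params$nucleus_bias)]
cmp <- data.frame(nucleus = names(params$nucleus_bias),
                  planted = round(planted, 3),
                  recovered = round(pooled[names(params$nucleus_bias)], 3))
print(cmp, row.names = FALSE)
cat(sprintf("Max |recovered - planted|: %.3f over %d nuclei; %d records, %d excluded hemispheres\n",
            max(abs(cmp$recovered - cmp$planted)), nrow(cmp),
            nrow(thal$records), nrow(thal$qc$exclusions)))
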