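#!/usr/bin/env Rscript
# Stage 1 — simulate the default synthetic cohort.
#
# Generates a 20-subject phantom cohort at 1.5 mm isotropic resolution with
# the default nucleus-bias table, left-hemisphere matrix asymmetry
# delta = 0.05, and probability noise sd = 0.1, and writes the ground-truth
# table.  All later stages regenerate the cohort deterministically from the
# same seed, so nothing volumetric needs to be cached on disk.

suppressPackageStartupMessages(library(striothal))

seed <- 20260924L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

params <- cohort_params(n_subjects = 20, spacing = 1.5, seed = seed)
cohort <- generate_cohort(params, components = "thalamic")

write.csv(cohort$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)

# export one subject's volumes as NIfTI-1 + sidecars for inspection
ph <- cohort$subjects[[1]]
vol_dir <- file.path(out_dir, "example_subject")
dir.create(vol_dir, showWarnings = FALSE)
write_volume(ph$nucleus_labels$left, file.path(vol_dir, "nuclei_left.nii.gz"))
write_volume(ph$thalamic_ctt$left$p_mat,
             file.path(vol_dir, "p_matrix_left.nii.gz"))
write_volume(ph$masks$left$gpi, file.path(vol_dir, "gpi_left.nii.gz"))

cat("Simulated", params$n_subjects, "subjects at", params$spacing,
    "mm; truth table in", file.path(out_dir, "truth.csv"), "\n")
cat("Planted matrix-fraction range:",
    paste(range(params$nucleus_bias), collapse = " - "),
    "; left-hemisphere asymmetry:", params$asymmetry_delta, "\n")
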