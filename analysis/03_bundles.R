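#!/usr/bin/env Rscript
# Stage 3 — compartment-specific streamline bundle metrics.
#
# Normalizes each subject's bundle densities to the GPi maximum, localizes
# intra-pallidal peaks, aligns hemispheres, and writes peak separation,
# per-plane coefficients of variation, Dice overlap of the group-mean cores
# at 25/50/90 % stringency (inside and outside the GPi), and per-seed
# streamline rates.  Findings: distinct peaks separated by roughly the
# planted offset, overlap growing with stringency, and a matrix:striosome
# per-seed fold ratio near the planted 5.7.

suppressPackageStartupMessages(library(striothal))

seed <- 20260924L
# bundle stage runs at 2.0 mm for a compact grid; the physical geometry is
# resolution-independent by construction
params <- cohort_params(n_subjects = 20, spacing = 2.0, seed = seed)
config <- default_config(params)
cohort <- generate_cohort(params, components = c("striatal", "bundles"))

bundles <- stage_bundles(cohort, config)
write.csv(bundles$peaks, "results/bundle_peaks.csv", row.names = FALSE)
write.csv(bundles$dice, "results/bundle_dice.csv", row.names = FALSE)
write.csv(bundles$rates, "results/bundle_rates.csv", row.names = FALSE)
write.csv(bundles$cv, "results/bundle_cv.csv", row.names = FALSE)

cat(sprintf("Peak RMS separation: %.2f mm (planted %.2f mm)\n",
            bundles$peak_rms,
            sqrt(sum((params$peak_offset_matrix -
                        params$peak_offset_striosome)^2))))
cat(sprintf("Per-seed fold ratio (matrix:striosome): %.2f (planted %.1f)\n",
            bundles$fold, params$fold_factor))
print(bundles$dice, row.names = FALSE)
cat(sprintf("Subjects whose 50%% core overlaps the group core: %.0f%%\n",
            100 * mean(bundles$colocalization$overlaps)))
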