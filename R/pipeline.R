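# ---------------------------------------------------------------------------
# End-to-end orchestration over a synthetic cohort: simulate -> parcellate ->
# bundles -> thalamus -> stats -> report.  Every stage is a pure function of
# its inputs; run_pipeline() chains them and (optionally) writes each
# stage's tables as CSV so a report can be regenerated from disk.
# ---------------------------------------------------------------------------

#' Default pipeline configuration
#'
#' All analysis constants in one place: selection thresholds (1.5 sd; 83
#' voxels at 2.0 mm / 180 at 1.5 mm), edge trim at 0.5, suprathreshold share
#' 0.55, seed-region suprathreshold 0.87, 10 % volume QC, stringency set
#' {0.25, 0.5, 0.9}, and alpha 0.05.
#'
#' @param params a [cohort_params()] describing the cohort to simulate.
#' @param seed global seed override (defaults to `params$seed`).
#' @return list of class `run_config`.
#' @export
default_config <- function(params = cohort_params(), seed = NULL) {
  structure(list(
    params = params,
    sd_k = 1.5,
    fixed_n = fixed_n_default(params$spacing),
    trim = 0.5,
    supra = 0.55,
    seed_region_supra = 0.87,
    qc_fraction = 0.10,
    stringencies = c(0.25, 0.5, 0.9),
    alpha = 0.05,
    jitter_max_shift = 3L,
    seed = if (is.null(seed)) params$seed else as.integer(seed)),
    class = "run_config")
}

#' Parcellation stage
#'
#' Per subject and hemisphere: bias map from the striatal probability pair,
#' equal-volume compartment masks, and voxel locations relative to the
#' caudate/putamen centroids.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config a [default_config()].
#' @return list: `masks` (nested subject -> hemisphere ->
#'   [make_equal_volume_masks()]), `locations` (data.frame).
#' @export
stage_parcellate <- function(cohort, config) {
  masks <- list()
  locs <- list()
  for (ph in cohort$subjects) {
    for (h in c("left", "right")) {
      bias <- compute_bias_map(ph$striatal_ctt[[h]]$P_str,
                               ph$striatal_ctt[[h]]$P_mat,
                               ph$striatum[[h]])
      cm <- make_equal_volume_masks(bias, N = config$fixed_n)
      masks[[ph$id]][[h]] <- cm
      locs[[paste(ph$id, h)]] <- relative_locations(
        cm, ph$masks[[h]]$caudate, ph$masks[[h]]$putamen,
        subject = ph$id, hemisphere = h)
    }
  }
  list(masks = masks, locations = do.call(rbind, locs))
}

#' Bundle metrics stage
#'
#' Normalizes each density to its GPi maximum, localizes peaks, aligns
#' hemispheres, and reports peak separation (RMS), per-plane coefficients
#' of variation, Dice overlap of group-mean cores at each stringency (inside
#' and outside the GPi), per-seed rates and the fold ratio, and per-subject
#' core colocalization with the group-mean core.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config a [default_config()].
#' @return list of tables: `peaks`, `peak_rms`, `cv`, `dice`, `rates`,
#'   `colocalization`.
#' @export
stage_bundles <- function(cohort, config) {
  peaks <- list(); rates <- list()
  norm_dens <- list()
  for (ph in cohort$subjects) {
    for (h in c("left", "right")) {
      gpi <- ph$masks[[h]]$gpi
      for (comp in c("striosome", "matrix")) {
        dm <- normalize_to_waypoint_max(ph$bundles[[h]][[comp]], gpi)
        norm_dens[[comp]][[h]][[ph$id]] <- dm$volume$values
        pk <- peak_location(dm, gpi)
        al <- align_hemispheres(pk$mm, side = h,
                                gpi_left = ph$masks$left$gpi,
                                gpi_right = ph$masks$right$gpi)
        peaks[[paste(ph$id, h, comp)]] <- data.frame(
          subject = ph$id, hemisphere = h, compartment = comp,
          x = pk$mm[1], y = pk$mm[2], z = pk$mm[3],
          ax = al[1], ay = al[2], az = al[3], amplitude = pk$amplitude)
        rates[[paste(ph$id, h, comp)]] <- data.frame(
          subject = ph$id, hemisphere = h, compartment = comp,
          n_seed = dm$n_seed_voxels, total = dm$total_streamlines,
          per_seed = per_seed_count(dm$total_streamlines, dm$n_seed_voxels))
      }
    }
  }
  peaks <- do.call(rbind, peaks); rownames(peaks) <- NULL
  rates <- do.call(rbind, rates); rownames(rates) <- NULL

  pk_str <- peaks[peaks$compartment == "striosome", ]
  pk_mat <- peaks[peaks$compartment == "matrix", ]
  key <- function(d) paste(d$subject, d$hemisphere)
  pk_mat <- pk_mat[match(key(pk_str), key(pk_mat)), ]
  peak_rms <- rms_difference(as.matrix(pk_str[, c("ax", "ay", "az")]),
                             as.matrix(pk_mat[, c("ax", "ay", "az")]))

  cv <- do.call(rbind, lapply(c("striosome", "matrix"), function(comp) {
    pc <- peaks[peaks$compartment == comp, ]
    data.frame(compartment = comp,
               cv_x = coefficient_of_variation(pc$ax),
               cv_y = coefficient_of_variation(pc$ay),
               cv_z = coefficient_of_variation(pc$az))
  }))

  # group-mean (left-hemisphere frame) densities per compartment
  grid <- cohort$subjects[[1]]$grid
  mean_density <- function(comp, h) {
    arrs <- norm_dens[[comp]][[h]]
    scalar_volume(grid, Reduce(`+`, arrs) / length(arrs))
  }
  gpi <- list(left = cohort$subjects[[1]]$masks$left$gpi,
              right = cohort$subjects[[1]]$masks$right$gpi)
  dice_rows <- list()
  for (h in c("left", "right")) {
    ms <- mean_density("striosome", h); mm <- mean_density("matrix", h)
    subcort <- cohort$subjects[[1]]$masks[[h]]$subcortical
    inv_gpi <- binary_mask(grid, subcort$membership & !gpi[[h]]$membership)
    for (q in config$stringencies) {
      dice_rows[[paste(h, q)]] <- data.frame(
        hemisphere = h, stringency = q,
        dsc_inside = dice(core_mask(ms, q, within = gpi[[h]]),
                          core_mask(mm, q, within = gpi[[h]])),
        dsc_outside = dice(core_mask(ms, q, within = inv_gpi),
                           core_mask(mm, q, within = inv_gpi)))
    }
  }
  dice_tab <- do.call(rbind, dice_rows); rownames(dice_tab) <- NULL

  coloc <- list()
  for (comp in c("striosome", "matrix")) for (h in c("left", "right")) {
    gcore <- core_mask(mean_density(comp, h), 0.5, within = gpi[[h]])
    for (ph in cohort$subjects) {
      score <- core_mask(scalar_volume(grid, norm_dens[[comp]][[h]][[ph$id]]),
                         0.5, within = gpi[[h]])
      cc <- subject_core_colocalization(score, gcore)
      coloc[[paste(comp, h, ph$id)]] <- data.frame(
        subject = ph$id, hemisphere = h, compartment = comp,
        overlaps = cc$overlaps, fraction = cc$fraction)
    }
  }
  coloc <- do.call(rbind, coloc); rownames(coloc) <- NULL

  rate_str <- mean(rates$per_seed[rates$compartment == "striosome"])
  rate_mat <- mean(rates$per_seed[rates$compartment == "matrix"])
  list(peaks = peaks, peak_rms = peak_rms, cv = cv, dice = dice_tab,
       rates = rates,
       fold = fold_ratio(rate_mat, rate_str),
       colocalization = coloc)
}

#' Thalamic bias stage
#'
#' Renormalizes and trims each hemisphere's thalamic probability pair,
#' counts suprathreshold voxels per nucleus, applies the minimum-volume
#' nucleus filter and subject-hemisphere QC, and emits per-record matrix
#' fractions.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config a [default_config()].
#' @return list: `records` (QC-passed per subject/hemisphere/nucleus),
#'   `qc` (a [hemisphere_qc()] report), `volume_filter`, `counts` (raw).
#' @export
stage_thalamus <- function(cohort, config) {
  counts <- list(); totals <- list()
  vox_vol <- prod(cohort$subjects[[1]]$grid$spacing)
  for (ph in cohort$subjects) {
    for (h in c("left", "right")) {
      labs <- ph$nucleus_labels[[h]]
      thal <- binary_mask(labs$grid, labs$labels > 0L)
      pair <- renormalize_and_trim(ph$thalamic_ctt[[h]]$p_str,
                                   ph$thalamic_ctt[[h]]$p_mat,
                                   thal, trim = config$trim)
      ct <- count_suprathreshold(pair, labs, supra = config$supra)
      ct$subject <- ph$id; ct$hemisphere <- h
      counts[[paste(ph$id, h)]] <- ct
      totals[[paste(ph$id, h)]] <- data.frame(
        subject = ph$id, hemisphere = h,
        n_str = sum(ct$n_str), n_mat = sum(ct$n_mat),
        voxel_volume_mm3 = vox_vol)
    }
  }
  counts <- do.call(rbind, counts); rownames(counts) <- NULL
  totals <- do.call(rbind, totals); rownames(totals) <- NULL

  # nucleus volume filter from the first subject's segmentation (shared
  # geometry up to jitter); volumes in mm^3 per nucleus
  labs1 <- cohort$subjects[[1]]$nucleus_labels$left
  nuc_vol <- vapply(names(labs1$label_table), function(nu) {
    sum(labs1$labels == labs1$label_table[[nu]]) * vox_vol
  }, numeric(1))
  vf <- nucleus_volume_filter(nuc_vol, cohort$subjects[[1]]$grid$spacing[1])

  qc <- hemisphere_qc(totals, qc_fraction = config$qc_fraction)
  kept_key <- paste(qc$kept$subject, qc$kept$hemisphere)
  keep_nuclei <- vf$nucleus[vf$retained]
  rec <- counts[paste(counts$subject, counts$hemisphere) %in% kept_key &
                  counts$nucleus %in% keep_nuclei, ]
  rec$matrix_fraction <- matrix_fraction(rec$n_str, rec$n_mat)
  rec <- rec[!is.na(rec$matrix_fraction), ]
  rownames(rec) <- NULL
  list(records = rec, qc = qc, volume_filter = vf, counts = counts)
}

#' Statistics and report stage
#'
#' Location ANOVAs per axis (compartment x nucleus with subject blocks),
#' hemispheric comparison and nucleus classification of the thalamic
#' records, and the laterality sign-consistency statistic.
#'
#' @param parcel a [stage_parcellate()] result.
#' @param thal a [stage_thalamus()] result.
#' @param config a [default_config()].
#' @return list of tables: `location_anova`, `location_means`,
#'   `hemispheric`, `classification`, `laterality`.
#' @export
stage_stats <- function(parcel, thal, config) {
  loc <- parcel$locations
  # medial-positive x so the compartment effect does not cancel across
  # hemispheres; y (rostral) and z (dorsal) share sign in both hemispheres
  loc$dx_medial <- ifelse(loc$hemisphere == "left", loc$dx, -loc$dx)
  anovas <- lapply(c(dx = "dx_medial", dy = "dy", dz = "dz"), function(ax) {
    two_factor_anova(loc, ax, "compartment", "nucleus", subject = "subject")
  })
  loc_means <- stats::aggregate(loc[, c("dx", "dy", "dz")],
                                by = list(compartment = loc$compartment),
                                FUN = mean)

  hemi <- hemispheric_comparison(thal$records, alpha = config$alpha)
  split_nuclei <- hemi$nucleus[hemi$split]
  combined <- setdiff(hemi$nucleus, split_nuclei)
  cls <- classify_nucleus(thal$records, nuclei = combined,
                          alpha = config$alpha,
                          family_m = length(combined))
  cls$hemispheres <- "combined"
  if (length(split_nuclei)) {
    per_side <- lapply(c("left", "right"), function(h) {
      sub <- thal$records[thal$records$hemisphere == h &
                            thal$records$nucleus %in% split_nuclei, ]
      out <- classify_nucleus(sub, nuclei = split_nuclei,
                              alpha = config$alpha,
                              family_m = length(split_nuclei))
      if (!is.null(out)) out$hemispheres <- paste0(h, "-only")
      out
    })
    cls <- rbind(cls, do.call(rbind, per_side))
  }

  lat <- laterality_consistency(
    stats::setNames(hemi$mean_left, hemi$nucleus),
    stats::setNames(hemi$mean_right, hemi$nucleus))

  list(location_anova = anovas, location_means = loc_means,
       hemispheric = hemi, classification = cls, laterality = lat)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Chains simulate, parcellate, bundles, thalamus, and stats; optionally
#' writes each stage's tables as CSV under `out_dir`.
#'
#' @param config a [default_config()].
#' @param out_dir optional output directory for CSV tables.
#' @return list: `cohort`, `parcel`, `bundles`, `thalamus`, `stats`,
#'   `report` (see [pipeline_report()]).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  params <- config$params
  params$seed <- config$seed
  cohort <- generate_cohort(params)
  parcel <- stage_parcellate(cohort, config)
  bundles <- stage_bundles(cohort, config)
  thal <- stage_thalamus(cohort, config)
  sts <- stage_stats(parcel, thal, config)
  rep <- pipeline_report(bundles, thal, sts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE)
    wr(cohort$truth, "truth.csv")
    wr(parcel$locations, "voxel_locations.csv")
    wr(bundles$peaks, "bundle_peaks.csv")
    wr(bundles$dice, "bundle_dice.csv")
    wr(bundles$rates, "bundle_rates.csv")
    wr(thal$records, "nucleus_records.csv")
    wr(thal$qc$exclusions, "qc_exclusions.csv")
    wr(sts$hemispheric, "hemispheric_comparison.csv")
    wr(sts$classification, "nucleus_classification.csv")
    wr(rep$summary, "report_summary.csv")
  }
  list(cohort = cohort, parcel = parcel, bundles = bundles,
       thalamus = thal, stats = sts, report = rep)
}

#' Assemble the summary report
#'
#' Per-nucleus classification table (mean matrix fraction, SEM, p, verdict),
#' the laterality line (k of n, 1 in N), and the bundle-metric headline
#' numbers (peak RMS, Dice by stringency, fold ratio).
#'
#' @param bundles a [stage_bundles()] result.
#' @param thal a [stage_thalamus()] result.
#' @param sts a [stage_stats()] result.
#' @return list: `nucleus_table`, `laterality`, `bundle_table`, `summary`
#'   (one-row data.frame of headline scalars), `qc`.
#' @export
pipeline_report <- function(bundles, thal, sts) {
  lat <- sts$laterality
  summary <- data.frame(
    peak_rms_mm = bundles$peak_rms,
    fold_ratio = bundles$fold,
    laterality_k = lat$k, laterality_n = lat$n,
    laterality_one_in = lat$one_in,
    n_excluded_hemispheres = nrow(thal$qc$exclusions),
    n_matrix_biased = sum(sts$classification$verdict == "matrix-biased"),
    n_striosome_biased = sum(sts$classification$verdict ==
                               "striosome-biased"),
    n_neutral = sum(sts$classification$verdict == "neutral"))
  list(nucleus_table = sts$classification,
       laterality = lat,
       bundle_table = bundles$dice,
       summary = summary,
       qc = thal$qc$exclusions)
}
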