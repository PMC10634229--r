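# ---------------------------------------------------------------------------
# Per-nucleus compartment bias: renormalization and edge trimming,
# suprathreshold counting with the 0.45-0.55 indeterminate band, minimum
# nucleus volume filtering, subject-hemisphere QC, hemispheric comparison,
# nucleus classification, and the laterality sign-consistency statistic.
# ---------------------------------------------------------------------------

#' Renormalize a thalamic probability pair and trim edge voxels
#'
#' Voxels whose pair sum falls below `trim` (default 0.5) are removed from
#' the retained mask (partial-volume edge trimming); the remaining voxels
#' are rescaled so the pair sums to exactly 1.
#'
#' @param p_str,p_mat non-negative [scalar_volume()]s.
#' @param thalamus support [binary_mask()].
#' @param trim minimum admissible pair sum (default 0.5).
#' @return list: `p_str`, `p_mat` (renormalized), `retained`
#'   ([binary_mask()]), `n_trimmed`.
#' @export
renormalize_and_trim <- function(p_str, p_mat, thalamus, trim = 0.5) {
  stop_if_grid_mismatch(p_str, p_mat)
  grid <- p_str$grid
  idx <- which(thalamus$membership)
  ps <- p_str$values[idx]; pm <- p_mat$values[idx]
  if (any(ps < 0) || any(pm < 0))
    stop("probability values must be non-negative")
  tot <- ps + pm
  keep <- tot >= trim
  vs <- array(0, grid$shape); vm <- array(0, grid$shape)
  vs[idx[keep]] <- ps[keep] / tot[keep]
  vm[idx[keep]] <- pm[keep] / tot[keep]
  memb <- array(FALSE, grid$shape); memb[idx[keep]] <- TRUE
  list(p_str = scalar_volume(grid, vs), p_mat = scalar_volume(grid, vm),
       retained = binary_mask(grid, memb), n_trimmed = sum(!keep))
}

#' Count suprathreshold voxels per nucleus
#'
#' A retained voxel is striosome-favoring if its renormalized striosome
#' share is `>= supra` (default 0.55), matrix-favoring if the matrix share
#' is `>= supra`; shares in the 0.45-0.55 indeterminate band are counted for
#' neither.  Counts are accumulated per thalamic nucleus label.
#'
#' @param pair a [renormalize_and_trim()] result.
#' @param nucleus_labels a [label_volume()].
#' @param supra suprathreshold share (default 0.55).
#' @return data.frame: nucleus, n_str, n_mat, n_retained.
#' @export
count_suprathreshold <- function(pair, nucleus_labels, supra = 0.55) {
  idx <- which(pair$retained$membership & nucleus_labels$labels > 0L)
  lab <- nucleus_labels$labels[idx]
  ss <- pair$p_str$values[idx]
  sm <- pair$p_mat$values[idx]
  name_of <- stats::setNames(names(nucleus_labels$label_table),
                             nucleus_labels$label_table)
  nuclei <- names(nucleus_labels$label_table)
  agg <- function(flag) {
    t0 <- table(factor(name_of[as.character(lab[flag])], levels = nuclei))
    as.integer(t0)
  }
  data.frame(nucleus = nuclei,
             n_str = agg(ss >= supra),
             n_mat = agg(sm >= supra),
             n_retained = agg(rep(TRUE, length(lab))))
}

#' Matrix fraction from suprathreshold counts
#'
#' `n_mat / (n_str + n_mat)`; its complement is the striosome fraction.
#' Undefined (NA) when both counts are zero — such records are removed by
#' QC, not silently kept.
#'
#' @param n_str,n_mat suprathreshold voxel counts.
#' @return fraction in \[0, 1\], or NA when both counts are zero.
#' @export
matrix_fraction <- function(n_str, n_mat) {
  out <- n_mat / (n_str + n_mat)
  out[(n_str + n_mat) == 0] <- NA_real_
  out
}

#' Minimum-volume nucleus filter
#'
#' Retains a nucleus iff its volume is at least four diffusion-space voxels
#' (inclusive): 13.5 mm^3 at 1.5 mm spacing, 32 mm^3 at 2.0 mm.
#'
#' @param nucleus_volumes_mm3 named numeric vector of per-nucleus volumes.
#' @param diffusion_spacing_mm isotropic diffusion voxel size in mm.
#' @return data.frame: nucleus, volume_mm3, min_volume_mm3, retained.
#' @export
nucleus_volume_filter <- function(nucleus_volumes_mm3, diffusion_spacing_mm) {
  min_vol <- 4 * diffusion_spacing_mm^3
  data.frame(nucleus = names(nucleus_volumes_mm3),
             volume_mm3 = unname(nucleus_volumes_mm3),
             min_volume_mm3 = min_vol,
             retained = unname(nucleus_volumes_mm3) >= min_vol)
}

#' Subject-hemisphere quality control
#'
#' Two single-pass exclusion rules, applied in order: (1) a
#' subject-hemisphere is excluded when its whole-thalamus suprathreshold
#' volume falls below `qc_fraction` (default 10 %) of the mean suprathreshold
#' volume for that side, the mean computed once over all subjects; (2) a
#' subject-hemisphere is excluded when one compartment has no suprathreshold
#' voxels at all (`n_str == 0` or `n_mat == 0`), which would binarize the
#' bias estimate.
#'
#' @param totals data.frame with columns subject, hemisphere, n_str, n_mat
#'   (whole-thalamus suprathreshold counts) and voxel_volume_mm3.
#' @param qc_fraction volume cutoff as a fraction of the per-side mean.
#' @return list: `exclusions` (data.frame subject, hemisphere, reason),
#'   `mean_volume` (per side), `kept` (data.frame of retained rows).
#' @export
hemisphere_qc <- function(totals, qc_fraction = 0.10) {
  totals$supra_volume <- (totals$n_str + totals$n_mat) *
    totals$voxel_volume_mm3
  mean_volume <- tapply(totals$supra_volume, totals$hemisphere, mean)
  cutoff <- qc_fraction * mean_volume[totals$hemisphere]
  low <- totals$supra_volume < cutoff
  zero <- !low & (totals$n_str == 0L | totals$n_mat == 0L)
  exclusions <- rbind(
    data.frame(subject = totals$subject[low],
               hemisphere = totals$hemisphere[low],
               reason = rep("low_volume", sum(low))),
    data.frame(subject = totals$subject[zero],
               hemisphere = totals$hemisphere[zero],
               reason = rep("zero_compartment", sum(zero))))
  list(exclusions = exclusions,
       mean_volume = mean_volume,
       kept = totals[!low & !zero, , drop = FALSE])
}

#' Per-nucleus hemispheric comparison
#'
#' Pooled-variance two-sample t-test of the matrix fraction, left vs right,
#' per nucleus, with a Bonferroni family threshold `alpha / n_nuclei`.  A
#' nucleus is flagged for split (per-hemisphere) reporting when the
#' hemispheric difference is significant AND exactly one hemisphere is
#' itself significantly biased away from 0.5 while the other is neutral;
#' nuclei that differ but share a significant bias direction stay combined.
#'
#' @param records data.frame with columns subject, hemisphere, nucleus,
#'   matrix_fraction (QC-passed, defined fractions only).
#' @param nuclei nuclei to test (default: all in `records`).
#' @param alpha family-wise alpha (default 0.05).
#' @return data.frame per nucleus: mean_left, mean_right, n_left, n_right,
#'   t, p, threshold, significant, split.
#' @export
hemispheric_comparison <- function(records, nuclei = NULL, alpha = 0.05) {
  if (is.null(nuclei)) nuclei <- sort(unique(records$nucleus))
  m <- length(nuclei)
  thr <- bonferroni(alpha, m)
  out <- lapply(nuclei, function(nu) {
    l <- records$matrix_fraction[records$nucleus == nu &
                                   records$hemisphere == "left"]
    r <- records$matrix_fraction[records$nucleus == nu &
                                   records$hemisphere == "right"]
    if (length(l) < 2L || length(r) < 2L) {
      warning("nucleus ", nu, " skipped: fewer than 2 records per side")
      return(NULL)
    }
    tt <- pooled_two_sample_t(l, r, alpha = alpha, family_m = m)
    side_bias <- function(x) {
      bt <- classify_sample(x, alpha_threshold = thr)
      bt$verdict
    }
    vl <- side_bias(l); vr <- side_bias(r)
    split <- tt$significant &&
      xor(vl == "neutral", vr == "neutral")
    data.frame(nucleus = nu, mean_left = mean(l), mean_right = mean(r),
               n_left = length(l), n_right = length(r),
               t = tt$statistic, p = tt$p, threshold = thr,
               significant = tt$significant, split = split,
               verdict_left = vl, verdict_right = vr)
  })
  do.call(rbind, out)
}

# two-sample test of a fraction sample against its complement; verdict on
# the bias direction at the given threshold
classify_sample <- function(fr, alpha_threshold) {
  tt <- pooled_two_sample_t(fr, 1 - fr)
  verdict <- if (tt$p < alpha_threshold) {
    if (mean(fr) > 0.5) "matrix-biased" else "striosome-biased"
  } else "neutral"
  list(verdict = verdict, t = tt$statistic, p = tt$p, mean = mean(fr),
       sem = stats::sd(fr) / sqrt(length(fr)))
}

#' Classify a nucleus as striosome-biased, matrix-biased, or neutral
#'
#' Pooled-variance two-sided two-sample t-test comparing the matrix-fraction
#' sample against the complementary striosome-fraction sample.  The verdict
#' is matrix-biased if the mean exceeds 0.5 with `p` below the family
#' threshold, striosome-biased if below 0.5 with `p` below threshold, else
#' neutral.  A statistically equivalent one-sample test against 0.5 is
#' available via `method = "one_sample"`.
#'
#' @param records data.frame with columns nucleus, matrix_fraction
#'   (QC-passed; NA fractions are an error).
#' @param nuclei nuclei to classify (default: all).
#' @param alpha family-wise alpha.
#' @param family_m Bonferroni family size (default: number of nuclei
#'   classified).
#' @param method `"two_sample"` (default) or `"one_sample"`.
#' @return data.frame per nucleus: mean, sem, t, p, threshold, verdict.
#' @export
classify_nucleus <- function(records, nuclei = NULL, alpha = 0.05,
                             family_m = NULL,
                             method = c("two_sample", "one_sample")) {
  method <- match.arg(method)
  if (anyNA(records$matrix_fraction))
    stop("records contain undefined matrix fractions; run QC first")
  if (is.null(nuclei)) nuclei <- sort(unique(records$nucleus))
  if (is.null(family_m)) family_m <- length(nuclei)
  thr <- bonferroni(alpha, family_m)
  out <- lapply(nuclei, function(nu) {
    fr <- records$matrix_fraction[records$nucleus == nu]
    if (length(fr) < 2L) {
      warning("nucleus ", nu, " skipped: fewer than 2 records")
      return(NULL)
    }
    tt <- if (method == "two_sample") pooled_two_sample_t(fr, 1 - fr)
          else one_sample_t(fr, mu = 0.5)
    verdict <- if (tt$p < thr) {
      if (mean(fr) > 0.5) "matrix-biased" else "striosome-biased"
    } else "neutral"
    data.frame(nucleus = nu, mean = mean(fr),
               sem = stats::sd(fr) / sqrt(length(fr)),
               n = length(fr), t = tt$statistic, df = tt$df, p = tt$p,
               threshold = thr, verdict = verdict)
  })
  do.call(rbind, out)
}

#' Laterality sign-consistency statistic
#'
#' Counts the nuclei whose left-hemisphere mean matrix fraction exceeds the
#' right (`k` of `n`; exact ties count for neither side and reduce `n`),
#' and reports the fair-coin probability of that count,
#' `C(n, k) / 2^n`, rendered as "1 in N".  Eighteen of twenty gives
#' 1 in 5,519.
#'
#' @param mean_left,mean_right named numeric vectors of per-nucleus means
#'   (matched order or matching names).
#' @return list: `k`, `n`, `probability`, `one_in`, `direction` per nucleus.
#' @export
laterality_consistency <- function(mean_left, mean_right) {
  if (!is.null(names(mean_left)) && !is.null(names(mean_right)))
    mean_right <- mean_right[names(mean_left)]
  if (length(mean_left) != length(mean_right))
    stop("mean vectors must pair up")
  ok <- is.finite(mean_left) & is.finite(mean_right)
  d <- mean_left[ok] - mean_right[ok]
  ties <- d == 0
  d <- d[!ties]
  n <- length(d)
  if (n == 0L) stop("laterality_consistency: no comparable nuclei")
  k <- sum(d > 0)
  bm <- binomial_exact_mass(n, k)
  list(k = k, n = n, probability = bm$probability, one_in = bm$one_in,
       direction = stats::setNames(ifelse(d > 0, "left", "right"),
                                   names(d)))
}
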