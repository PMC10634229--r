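# ---------------------------------------------------------------------------
# Striatal parcellation: paired connectivity probability maps -> equal-volume
# striosome-like / matrix-like voxel masks, plus the precision controls
# (jittered masks, leave-one-out seed-region profiling) and voxel-location
# summaries.
# ---------------------------------------------------------------------------

#' Voxelwise compartment bias map
#'
#' The striosome fraction `f(v) = P_str(v) / (P_str(v) + P_mat(v))` on the
#' striatal support.  Voxels where both probabilities are zero carry no
#' information and are dropped from the support (their count is recorded).
#' The map is invariant to rescaling both inputs by the same positive
#' constant.
#'
#' @param P_str,P_mat non-negative [scalar_volume()] probability maps.
#' @param striatal_mask support [binary_mask()].
#' @return list of class `bias_map`: `grid`, `f` (values array, NA off
#'   support), `support` ([binary_mask()]), `n_dropped`.
#' @export
compute_bias_map <- function(P_str, P_mat, striatal_mask) {
  stop_if_grid_mismatch(P_str, P_mat)
  stop_if_grid_mismatch(P_str, striatal_mask)
  grid <- P_str$grid
  idx <- which(striatal_mask$membership)
  ps <- P_str$values[idx]; pm <- P_mat$values[idx]
  if (any(ps < 0) || any(pm < 0))
    stop("probability maps must be non-negative on the striatal mask")
  tot <- ps + pm
  keep <- tot > 0
  f <- array(NA_real_, grid$shape)
  f[idx[keep]] <- ps[keep] / tot[keep]
  support <- array(FALSE, grid$shape)
  support[idx[keep]] <- TRUE
  structure(list(grid = grid, f = f,
                 support = binary_mask(grid, support),
                 n_dropped = sum(!keep)),
            class = "bias_map")
}

bias_scores <- function(bias, compartment) {
  idx <- which(bias$support$membership)
  s <- bias$f[idx]
  if (compartment == "matrix") s <- 1 - s
  list(idx = idx, s = s)
}

#' Select the most compartment-biased voxels
#'
#' Scores each support voxel by its striosome fraction (striosome) or its
#' complement (matrix) and selects either all voxels strictly above
#' `mean + k sd` of the score (`sd` mode, default k = 1.5) or the `N`
#' highest-scoring voxels (`fixed_n` mode; defaults 83 voxels at 2.0 mm,
#' 180 at 1.5 mm spacing).  `fixed_n` ties at the cut are broken by
#' ascending linear voxel index for cross-platform determinism.
#'
#' @param bias a [compute_bias_map()] result.
#' @param compartment `"striosome"` or `"matrix"`.
#' @param mode `"sd"` or `"fixed_n"`.
#' @param param `k` for `sd` mode (default 1.5); `N` for `fixed_n` mode
#'   (default from [fixed_n_default()] at the grid spacing).
#' @return a [binary_mask()].
#' @export
select_top_voxels <- function(bias, compartment = c("striosome", "matrix"),
                              mode = c("sd", "fixed_n"), param = NULL) {
  compartment <- match.arg(compartment)
  mode <- match.arg(mode)
  sc <- bias_scores(bias, compartment)
  sel <- if (mode == "sd") {
    k <- if (is.null(param)) 1.5 else param
    cut <- mean(sc$s) + k * stats::sd(sc$s)
    if (is.na(cut)) cut <- Inf  # single-voxel support: sd undefined
    sc$idx[sc$s > cut]
  } else {
    N <- if (is.null(param)) fixed_n_default(bias$grid$spacing[1])
         else as.integer(param)
    if (N > length(sc$s))
      stop("fixed_n selection: N = ", N, " exceeds support size ",
           length(sc$s))
    # order by descending score, ties by ascending linear index
    ord <- order(-sc$s, sc$idx)
    sc$idx[ord[seq_len(N)]]
  }
  memb <- array(FALSE, bias$grid$shape)
  memb[sel] <- TRUE
  binary_mask(bias$grid, memb)
}

#' Equal-volume compartment mask pair
#'
#' Fixed-N selection of the N most striosome-like and the N most matrix-like
#' voxels.  The two masks are guaranteed disjoint: on a pathological flat
#' map where a voxel would qualify for both, it is assigned to the
#' compartment where its rank is better (ties to striosome) and the other
#' compartment takes its next-ranked voxel.
#'
#' @param bias a [compute_bias_map()] result.
#' @param N voxels per compartment; `2N` must not exceed the support size.
#' @return list of class `compartment_masks`: `striosome_like`,
#'   `matrix_like` ([binary_mask()]), `n_selected`, `mode`.
#' @export
make_equal_volume_masks <- function(bias, N = NULL) {
  if (is.null(N)) N <- fixed_n_default(bias$grid$spacing[1])
  N <- as.integer(N)
  sc <- bias_scores(bias, "striosome")
  if (2L * N > length(sc$s))
    stop("equal-volume selection: 2N = ", 2L * N,
         " exceeds support size ", length(sc$s))
  ord_str <- order(-sc$s, sc$idx)          # best striosome first
  ord_mat <- order(sc$s, sc$idx)           # best matrix first
  rank_str <- rank_mat <- integer(length(sc$s))
  rank_str[ord_str] <- seq_along(ord_str)
  rank_mat[ord_mat] <- seq_along(ord_mat)
  take_str <- logical(length(sc$s)); take_mat <- logical(length(sc$s))
  i_str <- 1L; i_mat <- 1L
  n_str <- 0L; n_mat <- 0L
  while (n_str < N || n_mat < N) {
    if (n_str < N) {
      cand <- ord_str[i_str]
      if (!take_mat[cand] || rank_str[cand] <= rank_mat[cand]) {
        if (take_mat[cand]) {  # reclaim from matrix (better striosome rank)
          take_mat[cand] <- FALSE; n_mat <- n_mat - 1L
        }
        take_str[cand] <- TRUE; n_str <- n_str + 1L
      }
      i_str <- i_str + 1L
    }
    if (n_mat < N) {
      cand <- ord_mat[i_mat]
      if (!take_str[cand] || rank_mat[cand] < rank_str[cand]) {
        if (take_str[cand]) {
          take_str[cand] <- FALSE; n_str <- n_str - 1L
        }
        take_mat[cand] <- TRUE; n_mat <- n_mat + 1L
      }
      i_mat <- i_mat + 1L
    }
  }
  ms <- array(FALSE, bias$grid$shape); mm <- array(FALSE, bias$grid$shape)
  ms[sc$idx[take_str]] <- TRUE; mm[sc$idx[take_mat]] <- TRUE
  if (any(ms & mm)) stop("internal error: compartment masks overlap")
  structure(list(striosome_like = binary_mask(bias$grid, ms),
                 matrix_like = binary_mask(bias$grid, mm),
                 n_selected = N, mode = "fixed_n"),
            class = "compartment_masks")
}

#' Randomly displace mask voxels (imprecise control mask)
#'
#' Shifts each member voxel independently by integer offsets drawn uniformly
#' from `{-max_shift, ..., +max_shift}` per axis.  Offsets that would land
#' outside `bounds` are redrawn (up to `retry_cap` attempts, then the voxel
#' keeps offset 0).  Destinations are deduplicated, so the jittered mask may
#' be smaller than the input; the mean per-voxel Euclidean displacement (in
#' voxel units, before deduplication) is reported.
#'
#' @param mask member [binary_mask()] (must lie inside `bounds`).
#' @param bounds admissible region [binary_mask()].
#' @param max_shift maximum per-axis shift in voxels (default 3).
#' @param seed integer seed.
#' @param retry_cap redraw attempts per voxel.
#' @return list: `mask` (jittered [binary_mask()]),
#'   `mean_displacement_voxels`, `n_fallback` (voxels left unshifted).
#' @export
jitter_mask <- function(mask, bounds, max_shift = 3L, seed = 1L,
                        retry_cap = 100L) {
  stop_if_grid_mismatch(mask, bounds)
  if (any(mask$membership & !bounds$membership))
    stop("mask must be contained in bounds")
  idx <- mask_indices(mask)
  n <- nrow(idx)
  set.seed(seed)
  if (max_shift == 0L) {
    return(list(mask = mask, mean_displacement_voxels = 0, n_fallback = 0L))
  }
  shp <- mask$grid$shape
  dest <- idx
  disp <- numeric(n)
  n_fallback <- 0L
  for (v in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(retry_cap)) {
      off <- sample.int(2L * max_shift + 1L, 3L, replace = TRUE) -
        (max_shift + 1L)
      cand <- idx[v, ] + off
      if (all(cand >= 1L) && all(cand <= shp) &&
          bounds$membership[matrix(cand, 1)]) {
        dest[v, ] <- cand
        disp[v] <- sqrt(sum(off^2))
        ok <- TRUE
        break
      }
    }
    if (!ok) n_fallback <- n_fallback + 1L  # falls back to offset 0
  }
  memb <- array(FALSE, shp)
  memb[dest] <- TRUE
  list(mask = binary_mask(mask$grid, memb),
       mean_displacement_voxels = mean(disp),
       n_fallback = n_fallback)
}

#' Seed-region compartment bias profile
#'
#' Renormalizes the region's probability pair voxelwise and counts the
#' voxels whose striosome (resp. matrix) share meets the suprathreshold
#' probability (default 0.87, the substantial-bias criterion).  Fractions
#' are over all region voxels with a positive pair sum; mean connection
#' probabilities are reported per compartment.
#'
#' @param P_to_str,P_to_mat [scalar_volume()] connection probability maps.
#' @param region seed region [binary_mask()] (non-empty).
#' @param supra suprathreshold share (default 0.87).
#' @return list: `frac_striosome_favoring`, `frac_matrix_favoring`,
#'   `mean_p_striosome`, `mean_p_matrix`, `n_voxels`.
#' @export
seed_region_bias <- function(P_to_str, P_to_mat, region, supra = 0.87) {
  stop_if_grid_mismatch(P_to_str, P_to_mat)
  idx <- which(region$membership)
  if (length(idx) == 0L) stop("seed_region_bias: empty region")
  ps <- P_to_str$values[idx]; pm <- P_to_mat$values[idx]
  tot <- ps + pm
  keep <- tot > 0
  share_str <- ps[keep] / tot[keep]
  share_mat <- pm[keep] / tot[keep]
  list(frac_striosome_favoring = mean(share_str >= supra),
       frac_matrix_favoring = mean(share_mat >= supra),
       mean_p_striosome = mean(share_str),
       mean_p_matrix = mean(share_mat),
       n_voxels = sum(keep))
}

#' Voxel locations relative to nucleus centroids
#'
#' One row per selected compartment voxel with its mm offset from the
#' centroid of the striatal nucleus (caudate or putamen) containing it.
#'
#' @param masks a [make_equal_volume_masks()] result.
#' @param caudate,putamen nucleus [binary_mask()]s.
#' @param subject,hemisphere identifiers copied into the table.
#' @return data.frame: subject, hemisphere, nucleus, compartment, dx, dy, dz.
#' @export
relative_locations <- function(masks, caudate, putamen,
                               subject = "S001", hemisphere = "left") {
  cen <- list(caudate = centroid_mm(caudate), putamen = centroid_mm(putamen))
  rows <- list()
  for (comp in c("striosome", "matrix")) {
    m <- if (comp == "striosome") masks$striosome_like else masks$matrix_like
    idx <- mask_indices(m)
    in_cau <- caudate$membership[idx]
    in_put <- putamen$membership[idx]
    if (any(in_cau & in_put))
      stop("voxel inside both caudate and putamen masks")
    orphan <- which(!in_cau & !in_put)
    if (length(orphan))
      stop("selected voxels outside both nuclei at linear indices: ",
           paste(utils::head(which(m$membership)[orphan], 5), collapse = ", "))
    mm <- index_to_mm(m$grid, idx)
    nuc <- ifelse(in_cau, "caudate", "putamen")
    off <- mm - t(vapply(nuc, function(k) cen[[k]], numeric(3)))
    rows[[comp]] <- data.frame(subject = subject, hemisphere = hemisphere,
                               nucleus = nuc, compartment = comp,
                               dx = off[, 1], dy = off[, 2], dz = off[, 3])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
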