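# ---------------------------------------------------------------------------
# Compartment-specific streamline bundle metrics: waypoint normalization,
# peak localization, hemisphere alignment, RMS peak separation, stringency
# cores, Dice overlap, per-seed streamline rates.
# ---------------------------------------------------------------------------

#' Streamline density map
#'
#' A non-negative streamline visit-count volume for one subject, hemisphere,
#' and seed compartment, with the seed-voxel count and total streamlines
#' that met the anatomical criteria.
#'
#' @param volume a non-negative [scalar_volume()].
#' @param compartment `"striosome"` or `"matrix"`.
#' @param hemisphere `"left"` or `"right"`.
#' @param n_seed_voxels seed voxel count (>= 1).
#' @param total_streamlines total streamlines reaching the target.
#' @return list of class `density_map`.
#' @export
density_map <- function(volume, compartment, hemisphere,
                        n_seed_voxels, total_streamlines = NA_real_) {
  stopifnot(inherits(volume, "scalar_volume"), n_seed_voxels >= 1)
  if (any(volume$values < 0)) stop("density values must be non-negative")
  structure(list(volume = volume, compartment = compartment,
                 hemisphere = hemisphere,
                 n_seed_voxels = as.integer(n_seed_voxels),
                 total_streamlines = total_streamlines),
            class = "density_map")
}

density_values <- function(density) {
  if (inherits(density, "density_map")) density$volume else density
}

#' Normalize a density map to its waypoint maximum
#'
#' Divides all values by the maximum value inside the waypoint mask (the
#' GPi), so the post-normalization waypoint maximum is 1.  A non-positive
#' waypoint maximum means the bundle never reached the waypoint; this raises
#' a condition of class `striothal_waypoint_exclusion` so QC can drop the
#' subject-hemisphere-compartment.
#'
#' @param density a [density_map()] or [scalar_volume()].
#' @param waypoint non-empty [binary_mask()].
#' @return Same type as `density`, rescaled.
#' @export
normalize_to_waypoint_max <- function(density, waypoint) {
  vol <- density_values(density)
  stop_if_grid_mismatch(vol, waypoint)
  if (n_voxels(waypoint) == 0L) stop("waypoint mask is empty")
  mx <- max(vol$values[waypoint$membership])
  if (mx <= 0)
    stop(structure(list(message = "zero streamline density inside waypoint",
                        call = sys.call()),
                   class = c("striothal_waypoint_exclusion", "error",
                             "condition")))
  scaled <- scalar_volume(vol$grid, vol$values / mx)
  if (inherits(density, "density_map")) {
    density$volume <- scaled
    density
  } else scaled
}

#' Peak location within a mask
#'
#' Argmax of the density over member voxels; ties are broken by the smallest
#' linear voxel index.  If every member value equals zero the first member
#' voxel is returned with a `degenerate-peak` warning.
#'
#' @param density a [density_map()] or [scalar_volume()].
#' @param within non-empty [binary_mask()].
#' @return list: `mm` (voxel-center coordinate), `index` (1-based triple),
#'   `amplitude`.
#' @export
peak_location <- function(density, within) {
  vol <- density_values(density)
  stop_if_grid_mismatch(vol, within)
  idx <- which(within$membership)
  if (length(idx) == 0L) stop("peak_location: empty mask")
  v <- vol$values[idx]
  if (all(v == 0)) warning("degenerate peak: all values zero in mask")
  lin <- idx[which.max(v)]  # which.max returns first maximum = lowest index
  ind <- arrayInd(lin, vol$grid$shape)
  list(mm = as.vector(index_to_mm(vol$grid, ind)),
       index = as.integer(ind), amplitude = vol$values[lin])
}

gpi_centroids <- function(gpi_left, gpi_right) {
  list(left = centroid_mm(gpi_left), right = centroid_mm(gpi_right))
}

#' Align peak coordinates across hemispheres
#'
#' Maps point sets from both hemispheres into a common frame: right-side x
#' is reflected about `plane_x_mm` and both sides are translated so that
#' each GPi centroid lands on the two-hemisphere mean location (x mean of
#' left and reflected-right centroid x; y and z means of the two centroids).
#'
#' @param points matrix (n x 3) of mm coordinates, or length-3 vector.
#' @param side `"left"` or `"right"`: which hemisphere the points belong to.
#' @param gpi_left,gpi_right non-empty GPi [binary_mask()]s.
#' @param plane_x_mm mirror plane (default: mid-grid plane of the left GPi
#'   grid).
#' @return matrix (n x 3) of aligned mm coordinates.
#' @export
align_hemispheres <- function(points, side = c("right", "left"),
                              gpi_left, gpi_right, plane_x_mm = NULL) {
  side <- match.arg(side)
  if (n_voxels(gpi_left) == 0L || n_voxels(gpi_right) == 0L)
    stop("align_hemispheres: empty GPi mask")
  grid <- gpi_left$grid
  if (is.null(plane_x_mm))
    plane_x_mm <- grid$origin[1] + grid$shape[1] * grid$spacing[1] / 2
  vec <- is.null(dim(points))
  pts <- rbind_index(points)
  cl <- centroid_mm(gpi_left)
  cr <- centroid_mm(gpi_right)
  cr_ref <- c(2 * plane_x_mm - cr[1], cr[2], cr[3])
  target <- c(mean(c(cl[1], cr_ref[1])),
              mean(c(cl[2], cr[2])),
              mean(c(cl[3], cr[3])))
  if (side == "right") {
    pts[, 1] <- 2 * plane_x_mm - pts[, 1]
    shift <- target - cr_ref
  } else {
    shift <- target - cl
  }
  out <- sweep(pts, 2, shift, `+`)
  if (vec) as.vector(out) else out
}

#' RMS separation of paired point sets
#'
#' Square root of the mean squared Euclidean distance over subject-paired
#' points — the peak-separation statistic for striosome vs matrix bundles.
#'
#' @param points_a,points_b matrices (n x 3) of mm coordinates, paired by
#'   row (subject).
#' @return mm scalar.
#' @export
rms_difference <- function(points_a, points_b) {
  a <- rbind_index(points_a); b <- rbind_index(points_b)
  if (nrow(a) != nrow(b)) stop("rms_difference: point lists must pair up")
  if (nrow(a) < 1L) stop("rms_difference: need at least one pair")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Coefficient of variation (percent)
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation; undefined
#' for zero-mean samples.
#'
#' @param values numeric vector.
#' @return percent scalar.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Stringency core of a density map
#'
#' Among voxels with positive amplitude, the `ceil(q * count)` highest; ties
#' at the cut are broken by ascending linear index.  The zero background is
#' excluded so the percentile does not depend on bounding-box size.
#'
#' @param density a [density_map()] or [scalar_volume()].
#' @param q fraction in (0, 1\]; 0.25 is the high-stringency core.
#' @param within optional [binary_mask()] restricting the candidate voxels
#'   (e.g. the GPi, or an analysis mask excluding it).
#' @return a [binary_mask()].
#' @export
core_mask <- function(density, q, within = NULL) {
  stopifnot(q > 0, q <= 1)
  vol <- density_values(density)
  cand <- if (is.null(within)) seq_along(vol$values) else which(within$membership)
  v <- vol$values[cand]
  pos <- v > 0
  if (!any(pos)) stop("core_mask: no positive-amplitude voxels")
  cand <- cand[pos]; v <- v[pos]
  ntake <- ceiling(q * length(v))
  ord <- order(-v, cand)
  memb <- array(FALSE, vol$grid$shape)
  memb[cand[ord[seq_len(ntake)]]] <- TRUE
  binary_mask(vol$grid, memb)
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 0 when both masks are
#' empty.
#'
#' @param a,b [binary_mask()]s on the same grid.
#' @return fraction in \[0, 1\].
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a, b)
  na <- n_voxels(a); nb <- n_voxels(b)
  if (na + nb == 0L) return(0)
  2 * sum(a$membership & b$membership) / (na + nb)
}

#' Streamlines per seed voxel
#'
#' @param total_reaching total streamlines reaching the target.
#' @param n_seed_voxels seed voxel count (>= 1).
#' @return streamlines per seed voxel.
#' @export
per_seed_count <- function(total_reaching, n_seed_voxels) {
  if (n_seed_voxels < 1) stop("per_seed_count: need at least one seed voxel")
  total_reaching / n_seed_voxels
}

#' Matrix:striosome per-seed rate ratio
#'
#' @param matrix_rate,striosome_rate per-seed streamline rates;
#'   `striosome_rate` must be positive.
#' @return unitless fold ratio.
#' @export
fold_ratio <- function(matrix_rate, striosome_rate) {
  if (striosome_rate <= 0) stop("fold_ratio: striosome rate must be positive")
  matrix_rate / striosome_rate
}

#' Subject-core colocalization with the group-mean core
#'
#' @param subject_core non-empty subject core [binary_mask()].
#' @param group_mean_core group-average core [binary_mask()].
#' @return list: `overlaps` (logical), `fraction`
#'   (`|intersection| / |subject_core|`).
#' @export
subject_core_colocalization <- function(subject_core, group_mean_core) {
  stop_if_grid_mismatch(subject_core, group_mean_core)
  ns <- n_voxels(subject_core)
  if (ns == 0L) stop("subject core is empty")
  inter <- sum(subject_core$membership & group_mean_core$membership)
  list(overlaps = inter > 0L, fraction = inter / ns)
}
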