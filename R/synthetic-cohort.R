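# ---------------------------------------------------------------------------
# Synthetic volumetric cohorts with known ground truth.
#
# Each subject phantom carries: ellipsoidal caudate / putamen / GPi /
# thalamus per hemisphere; a labelled partition of the thalamus into 20
# nuclei; a striosome-character field g on the striatum with a planted
# medial/rostral/ventral gradient; paired classification-targets probability
# maps on the striatum and on the thalamus; and compartment-specific
# streamline density fields with planted intra-pallidal peak locations and a
# matrix:striosome amplitude fold factor.
# ---------------------------------------------------------------------------

#' Default per-nucleus matrix-fraction bias table
#'
#' Ground-truth matrix fractions for the 20 thalamic nuclei used as the
#' default recovery experiment: 16 nuclei at their combined-hemisphere group
#' means, plus the four hemisphere-split nuclei (CeM, MDl, Reu, VAmc) at the
#' midpoint of their left/right means.
#'
#' @return named numeric vector, values in \[0, 1\].
#' @export
default_nucleus_bias <- function() {
  c(AV = 0.29, CL = 0.09, CM = 0.76, LD = 0.08, LP = 0.42, MDm = 0.41,
    MGN = 0.38, Pf = 0.70, PuA = 0.62, PuI = 0.51, PuL = 0.65, PuM = 0.49,
    VA = 0.48, VLa = 0.61, VLp = 0.69, VPL = 0.71,
    CeM = 0.455, MDl = 0.46, Reu = 0.29, VAmc = 0.58)
}

#' Cohort generation parameters
#'
#' @param n_subjects number of phantoms (>= 1).
#' @param spacing isotropic voxel size in mm (1.5 or 2.0 typical).
#' @param gradient_weights length-3 weights (medial, rostral, ventral) of the
#'   striosome-character logistic gradient.
#' @param noise_sd zero-mean Gaussian noise sd on the probability scale,
#'   applied to every synthetic probability draw.
#' @param nucleus_bias named vector of ground-truth matrix fractions per
#'   thalamic nucleus, each in \[0, 1\].
#' @param asymmetry_delta additive left-hemisphere matrix-fraction offset.
#' @param share_dispersion half-width of the uniform voxel-to-voxel
#'   heterogeneity of thalamic matrix shares.  The default 0.55 makes the
#'   suprathreshold-count matrix fraction an unbiased estimate of the planted
#'   nucleus bias under the 0.45/0.55 counting band (see the methods
#'   vignette for the derivation).
#' @param fold_factor matrix:striosome streamline amplitude ratio.
#' @param peak_offset_striosome,peak_offset_matrix planted intra-pallidal
#'   peak offsets (mm, hemisphere-local frame: +x medial, +y rostral,
#'   +z dorsal) of the two bundles relative to the GPi centroid.
#' @param per_seed_rate_striosome,per_seed_rate_matrix expected streamlines
#'   per seed voxel reaching the thalamus for each compartment.
#' @param edge_attenuation_depth voxels over which thalamic probability pairs
#'   are linearly attenuated toward the boundary (exercises edge trimming).
#' @param seed integer master seed.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 20L,
                          spacing = 2.0,
                          gradient_weights = c(2, 2, 2),
                          noise_sd = 0.1,
                          nucleus_bias = default_nucleus_bias(),
                          asymmetry_delta = 0.05,
                          share_dispersion = 0.55,
                          fold_factor = 5.7,
                          peak_offset_striosome = c(-0.8, 1.6, -1.6),
                          peak_offset_matrix = c(0.8, -1.6, 1.6),
                          per_seed_rate_striosome = 401,
                          per_seed_rate_matrix = 2291,
                          edge_attenuation_depth = 1L,
                          seed = 1L) {
  stopifnot(n_subjects >= 1, noise_sd >= 0, fold_factor > 0,
            share_dispersion >= 0, edge_attenuation_depth >= 0)
  if (any(nucleus_bias < 0 | nucleus_bias > 1))
    stop("nucleus_bias values must lie in [0, 1]")
  if (is.null(names(nucleus_bias)) || any(!nzchar(names(nucleus_bias))))
    stop("nucleus_bias must be a named vector")
  structure(list(
    n_subjects = as.integer(n_subjects), spacing = spacing,
    gradient_weights = gradient_weights, noise_sd = noise_sd,
    nucleus_bias = nucleus_bias, asymmetry_delta = asymmetry_delta,
    share_dispersion = share_dispersion, fold_factor = fold_factor,
    peak_offset_striosome = peak_offset_striosome,
    peak_offset_matrix = peak_offset_matrix,
    per_seed_rate_striosome = per_seed_rate_striosome,
    per_seed_rate_matrix = per_seed_rate_matrix,
    edge_attenuation_depth = as.integer(edge_attenuation_depth),
    seed = as.integer(seed)), class = "cohort_params")
}

#' Default grid for a given voxel spacing
#'
#' A fixed ~96 x 114 x 84 mm field of view so that 1.5 mm and 2.0 mm cohorts
#' share physical geometry; the mid-sagittal plane falls on a grid plane at
#' both spacings.
#'
#' @param spacing isotropic voxel size in mm.
#' @return a [grid_spec()].
#' @export
default_grid <- function(spacing = 2.0) {
  fov <- c(96, 114, 84)
  shape <- round(fov / spacing)
  grid_spec(shape, spacing, origin = c(0, 0, 0))
}

# mm coordinates of all voxel centers, n x 3
all_centers <- function(grid) {
  ax <- lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$shape[a]) - 0.5) * grid$spacing[a])
  cbind(rep(ax[[1]], times = grid$shape[2] * grid$shape[3]),
        rep(rep(ax[[2]], each = grid$shape[1]), times = grid$shape[3]),
        rep(ax[[3]], each = grid$shape[1] * grid$shape[2]))
}

ellipsoid_mask <- function(grid, center, semi, centers = NULL) {
  # evaluate only inside the ellipsoid bounding box
  ax <- lapply(1:3, function(a) {
    x <- grid$origin[a] + (seq_len(grid$shape[a]) - 0.5) * grid$spacing[a]
    u <- (x - center[a]) / semi[a]
    list(range = which(abs(u) <= 1), u2 = u^2)
  })
  memb <- array(FALSE, grid$shape)
  i <- ax[[1]]$range; j <- ax[[2]]$range; k <- ax[[3]]$range
  if (length(i) && length(j) && length(k)) {
    box <- outer(outer(ax[[1]]$u2[i], ax[[2]]$u2[j], `+`), ax[[3]]$u2[k], `+`)
    memb[i, j, k] <- box <= 1
  }
  binary_mask(grid, memb)
}

# canonical structure geometry (left hemisphere, mm); +x medial direction is
# toward the mid-sagittal plane at x = 48
structure_geometry <- function(jitter = rep(1, 4)) {
  list(
    caudate  = list(center = c(34, 70, 50), semi = c(6, 16, 8) * jitter[1]),
    putamen  = list(center = c(22, 62, 46), semi = c(7.2, 14, 9.2) * jitter[2]),
    gpi      = list(center = c(30, 54, 42), semi = c(5, 7, 6) * jitter[3]),
    thalamus = list(center = c(36, 44, 46), semi = c(10, 14, 10) * jitter[4]))
}

mirror_point <- function(p, plane_x = 48) c(2 * plane_x - p[1], p[2], p[3])

# deterministic 20 nucleus seed sites spanning anterior/medial/lateral/
# posterior sectors of the thalamus ellipsoid (unit-ball coordinates)
nucleus_seed_sites <- function(n) {
  set.seed(20L)  # fixed: parcel layout is anatomy, not a random variate
  pts <- matrix(stats::runif(3 * 200, -1, 1), ncol = 3)
  pts <- pts[rowSums(pts^2) < 0.85, , drop = FALSE]
  # greedy max-min thinning for an even spread
  keep <- 1L
  while (length(keep) < n) {
    d <- sapply(seq_len(nrow(pts)), function(i)
      min(colSums((t(pts[keep, , drop = FALSE]) - pts[i, ])^2)))
    keep <- c(keep, which.max(d))
  }
  pts[keep, , drop = FALSE]
}

#' Generate per-hemisphere structure masks and thalamic nucleus labels
#'
#' Builds mirror-symmetric ellipsoidal caudate, putamen, GPi, and thalamus in
#' each hemisphere, with the thalamus partitioned into contiguous labelled
#' parcels (nearest-site assignment in ellipsoid-normalized coordinates).
#' Ellipsoid semi-axes receive a small seeded per-subject size jitter
#' (+/- 3 %).
#'
#' @param grid a [grid_spec()]; must be large enough to contain all
#'   structures (the [default_grid()] field of view).
#' @param seed integer seed for the size jitter.
#' @param nuclei character vector of nucleus names (>= 16 parcels).
#' @param subcortical whether to also build the dilated subcortical bounding
#'   mask (needed only for bundle analyses).
#' @return list with `masks` (nested: hemisphere -> structure ->
#'   [binary_mask()], plus `subcortical` when requested) and
#'   `nucleus_labels` (hemisphere -> [label_volume()]).
#' @export
make_striatal_geometry <- function(grid, seed = 1L,
                                   nuclei = names(default_nucleus_bias()),
                                   subcortical = TRUE) {
  fov <- grid$shape * grid$spacing
  if (any(fov < c(90, 100, 70)))
    stop("grid too small for the structure geometry (need >= 90x100x70 mm)")
  set.seed(seed)
  jit <- 1 + stats::runif(4, -0.03, 0.03)
  geo <- structure_geometry(jit)
  plane_x <- grid$origin[1] + grid$shape[1] * grid$spacing[1] / 2

  masks <- list()
  for (h in c("left", "right")) {
    taken <- NULL
    hm <- list()
    for (s in names(geo)) {
      ctr <- geo[[s]]$center
      if (h == "right") ctr <- mirror_point(ctr, plane_x)
      m <- ellipsoid_mask(grid, ctr, geo[[s]]$semi)
      if (!is.null(taken)) m$membership <- m$membership & !taken
      taken <- if (is.null(taken)) m$membership else taken | m$membership
      hm[[s]] <- m
    }
    if (subcortical) {
      # subcortical bounding mask: union of structures dilated by 2 voxels
      dil <- taken
      for (it in 1:2) {
        grown <- dil
        for (ax in 1:3) for (sgn in c(-1L, 1L))
          grown <- grown | shift_array(dil, ax, sgn, fill = FALSE)
        dil <- grown
      }
      hm$subcortical <- binary_mask(grid, dil)
    }
    masks[[h]] <- hm
  }

  sites <- nucleus_seed_sites(length(nuclei))
  tab <- stats::setNames(seq_along(nuclei), nuclei)
  nucleus_labels <- list()
  for (h in c("left", "right")) {
    ctr <- geo$thalamus$center
    if (h == "right") ctr <- mirror_point(ctr, plane_x)
    semi <- geo$thalamus$semi
    th <- masks[[h]]$thalamus
    idx <- mask_indices(th)
    mm <- index_to_mm(grid, idx)
    u <- sweep(sweep(mm, 2, ctr, `-`), 2, semi, `/`)
    if (h == "right") u[, 1] <- -u[, 1]  # keep parcels mirror-consistent
    # capacity-balanced power-diagram parcels (Lloyd moves + weight
    # adjustment), so every nucleus estimate has comparable voxel support
    st <- sites
    w <- rep(0, nrow(st))
    target <- nrow(u) / nrow(st)
    for (it in 1:80) {
      d2 <- outer(rowSums(u^2), rowSums(st^2), `+`) - 2 * (u %*% t(st))
      assign <- max.col(-sweep(d2, 2, w, `-`), ties.method = "first")
      sz <- tabulate(assign, nrow(st))
      w <- w - 0.01 * (sz - target) / target
      st <- t(vapply(seq_len(nrow(st)), function(kk) {
        sel <- assign == kk
        if (any(sel)) colMeans(u[sel, , drop = FALSE]) else st[kk, ]
      }, numeric(3)))
    }
    lab <- array(0L, grid$shape)
    lab[idx] <- assign
    nucleus_labels[[h]] <- label_volume(grid, lab, tab)
  }
  list(masks = masks, nucleus_labels = nucleus_labels)
}

logistic <- function(x) 1 / (1 + exp(-x))

# signed normalized coordinates (medial, rostral, ventral all positive)
# relative to the hemisphere striatal bounding box
normalized_coords <- function(grid, striatal_mask, hemisphere) {
  idx <- mask_indices(striatal_mask)
  mm <- index_to_mm(grid, idx)
  rng <- apply(mm, 2, range)
  mid <- colMeans(rng)
  half <- pmax((rng[2, ] - rng[1, ]) / 2, .Machine$double.eps)
  u <- sweep(sweep(mm, 2, mid, `-`), 2, half, `/`)
  medial <- if (hemisphere == "left") u[, 1] else -u[, 1]
  cbind(medial = medial, rostral = u[, 2], ventral = -u[, 3])
}

#' Planted striosome-character field
#'
#' Generates `g(v) = logistic(w_m m + w_r r + w_v d + eps)` on the striatum,
#' where (m, r, d) are signed bounding-box-normalized coordinates (medial,
#' rostral, ventral positive) and eps is zero-mean Gaussian noise.  Positive
#' weights enrich striosome character medially, rostrally, and ventrally.
#'
#' @param grid a [grid_spec()].
#' @param striatal_mask hemisphere striatum (caudate + putamen) mask.
#' @param hemisphere `"left"` or `"right"` (decides the medial direction).
#' @param gradient_weights length-3 numeric weights.
#' @param noise_sd Gaussian noise sd (logit scale).
#' @param seed integer seed.
#' @return a [scalar_volume()] with values in \[0, 1\] on the mask, 0 elsewhere.
#' @export
make_compartment_field <- function(grid, striatal_mask, hemisphere,
                                   gradient_weights = c(2, 2, 2),
                                   noise_sd = 0.1, seed = 1L) {
  stopifnot(all(is.finite(gradient_weights)))
  idx <- mask_indices(striatal_mask)
  u <- normalized_coords(grid, striatal_mask, hemisphere)
  set.seed(seed)
  eps <- stats::rnorm(nrow(idx), 0, noise_sd)
  g <- logistic(as.vector(u %*% gradient_weights) + eps)
  vals <- array(0, grid$shape)
  vals[idx] <- g
  scalar_volume(grid, vals)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Paired striatal classification-targets probability maps
#'
#' Emulates the two superimposable striatal connectivity maps: the
#' striosome-targets probability is the character field plus noise, the
#' matrix-targets probability its complement plus independent noise, both
#' clipped to \[0, 1\].  At least one of the pair is positive at every
#' striatal voxel.
#'
#' @param g striosome-character [scalar_volume()] (values in \[0, 1\]).
#' @param striatal_mask support mask.
#' @param noise_sd Gaussian noise sd on the probability scale.
#' @param seed integer seed.
#' @return list `(P_str, P_mat)` of [scalar_volume()].
#' @export
make_striatal_ctt_pair <- function(g, striatal_mask, noise_sd = 0.1,
                                   seed = 1L) {
  idx <- mask_indices(striatal_mask)
  gv <- g$values[idx]
  set.seed(seed)
  p_str <- clip01(gv + stats::rnorm(length(gv), 0, noise_sd))
  p_mat <- clip01(1 - gv + stats::rnorm(length(gv), 0, noise_sd))
  both0 <- p_str == 0 & p_mat == 0
  if (any(both0)) {  # keep the pair informative at every striatal voxel
    p_str[both0] <- ifelse(gv[both0] >= 0.5, 1e-6, 0)
    p_mat[both0] <- ifelse(gv[both0] < 0.5, 1e-6, 0)
  }
  vs <- array(0, g$grid$shape); vm <- array(0, g$grid$shape)
  vs[idx] <- p_str; vm[idx] <- p_mat
  list(P_str = scalar_volume(g$grid, vs), P_mat = scalar_volume(g$grid, vm))
}

# distance (voxels, 6-neighborhood erosion) to the outside of a mask,
# capped at `depth` + 1; computed on the mask bounding box for speed
boundary_depth <- function(mask, depth) {
  full <- mask$membership
  idx <- which(full, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(array(0L, dim(full)))
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dim(full))
  m <- full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (depth == 0L) {
    out <- array(0L, dim(full))
    out[full] <- 1L
    return(out)
  }
  d <- array(0L, dim(m))
  cur <- m
  for (k in seq_len(depth + 1L)) {
    d[cur] <- k - 1L
    nxt <- cur
    # erode by one voxel (6+20-neighborhood via axis shifts; chebyshev)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      sh <- shift_array(cur, ax, s, fill = FALSE)
      nxt <- nxt & sh
    }
    if (!any(nxt)) { d[cur] <- k - 1L; break }
    cur <- nxt
  }
  d[cur] <- depth + 1L
  d[!m] <- 0L
  out <- array(0L, dim(full))
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- d
  out
}

shift_array <- function(a, axis, by, fill = FALSE) {
  out <- array(fill, dim(a))
  n <- dim(a)[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  ix <- function(which) switch(axis,
    list(which, TRUE, TRUE), list(TRUE, which, TRUE), list(TRUE, TRUE, which))
  do.call(`[<-`, c(list(out), ix(dst),
                   list(do.call(`[`, c(list(a), ix(src), list(drop = FALSE))))))
}

#' Paired thalamic classification-targets probability maps
#'
#' For each thalamic voxel in nucleus `n` and hemisphere `h`, the matrix
#' share is drawn as `clip(beta_n + delta[h == left] + U + Z, 0, 1)` with
#' `U ~ Uniform(-share_dispersion, share_dispersion)` (voxel-to-voxel
#' heterogeneity) and `Z ~ N(0, noise_sd)`.  The pair `(p_str, p_mat)` sums
#' to 1 in the thalamic interior and is linearly attenuated toward the
#' boundary within `edge_attenuation_depth` voxels (boundary voxels sum to
#' 0.2, so downstream trimming at 0.5 removes them).
#'
#' @param nucleus_labels per-hemisphere [label_volume()] of thalamic nuclei.
#' @param hemisphere `"left"` or `"right"`.
#' @param nucleus_bias named ground-truth matrix fractions.
#' @param asymmetry_delta additive left-hemisphere offset.
#' @param noise_sd Gaussian component sd.
#' @param share_dispersion uniform component half-width.
#' @param edge_attenuation_depth ramp depth in voxels.
#' @param seed integer seed.
#' @return list `(p_str, p_mat)` of [scalar_volume()].
#' @export
make_thalamic_ctt_pair <- function(nucleus_labels, hemisphere, nucleus_bias,
                                   asymmetry_delta = 0, noise_sd = 0.1,
                                   share_dispersion = 0.55,
                                   edge_attenuation_depth = 1L, seed = 1L) {
  lab <- nucleus_labels$labels
  grid <- nucleus_labels$grid
  present <- setdiff(unique(as.vector(lab)), 0L)
  name_of <- stats::setNames(names(nucleus_labels$label_table),
                             nucleus_labels$label_table)
  missing <- setdiff(name_of[as.character(present)], names(nucleus_bias))
  if (length(missing))
    stop("nucleus_bias missing entries for: ", paste(missing, collapse = ", "))
  idx <- which(lab > 0L)
  beta <- nucleus_bias[name_of[as.character(lab[idx])]]
  delta <- if (hemisphere == "left") asymmetry_delta else 0
  set.seed(seed)
  u <- if (share_dispersion > 0)
    stats::runif(length(idx), -share_dispersion, share_dispersion) else 0
  z <- if (noise_sd > 0) stats::rnorm(length(idx), 0, noise_sd) else 0
  mshare <- clip01(beta + delta + u + z)
  thal <- binary_mask(grid, lab > 0L)
  dpt <- boundary_depth(thal, edge_attenuation_depth)[idx]
  atten <- pmin(0.2 + 0.8 * dpt / (edge_attenuation_depth + 1L), 1)
  vm <- array(0, grid$shape); vs <- array(0, grid$shape)
  vm[idx] <- mshare * atten
  vs[idx] <- (1 - mshare) * atten
  list(p_str = scalar_volume(grid, vs), p_mat = scalar_volume(grid, vm))
}

#' Synthetic streamline density field
#'
#' A smooth non-negative corridor along seed -> GPi peak -> thalamus whose
#' within-GPi maximum sits at `gpi_centroid + peak_offset_mm`; the whole
#' field scales linearly with `amplitude`.
#'
#' @param grid a [grid_spec()].
#' @param seed_mask,gpi_mask,thalamus_mask structure masks.
#' @param peak_offset_mm length-3 mm offset of the planted peak from the GPi
#'   centroid; the peak must stay inside the GPi.
#' @param amplitude linear amplitude scale.
#' @param sigma_peak,sigma_corridor Gaussian widths (mm) of the peak kernel
#'   and the corridor profile.
#' @param corridor_offset_scale how far (in multiples of `peak_offset_mm`)
#'   the corridor endpoints are displaced from the seed/thalamus centroids,
#'   so bundles with distinct planted peaks also transit distinct corridors.
#' @param noise_frac sd of multiplicative log-normal voxel noise (preserves
#'   linearity in `amplitude`; 0 disables).
#' @param seed integer seed for the noise.
#' @return a [scalar_volume()].
#' @export
make_bundle_density <- function(grid, seed_mask, gpi_mask, thalamus_mask,
                                peak_offset_mm = c(0, 0, 0), amplitude = 1,
                                sigma_peak = 3, sigma_corridor = 4,
                                corridor_offset_scale = 2,
                                noise_frac = 0, seed = 1L) {
  gc_ <- centroid_mm(gpi_mask)
  peak <- gc_ + peak_offset_mm
  if (!gpi_mask$membership[matrix(mm_to_index(grid, peak), 1)])
    stop("planted peak (GPi centroid + offset) falls outside the GPi")
  sc <- centroid_mm(seed_mask) + corridor_offset_scale * peak_offset_mm
  tc <- centroid_mm(thalamus_mask) + corridor_offset_scale * peak_offset_mm
  centers <- all_centers(grid)
  d_line <- pmin(point_segment_dist(centers, sc, peak),
                 point_segment_dist(centers, peak, tc))
  d_peak2 <- rowSums(sweep(centers, 2, peak, `-`)^2)
  vals <- amplitude * (exp(-d_peak2 / (2 * sigma_peak^2)) +
                       0.4 * exp(-d_line^2 / (2 * sigma_corridor^2)))
  if (noise_frac > 0) {
    set.seed(seed)
    vals <- vals * exp(stats::rnorm(length(vals), 0, noise_frac))
  }
  scalar_volume(grid, array(vals, grid$shape))
}

point_segment_dist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(rowSums(sweep(pts, 2, a, `-`)^2)))
  t <- pmin(pmax(sweep(pts, 2, a, `-`) %*% ab / len2, 0), 1)
  proj <- sweep(t %*% t(ab), 2, a, `+`)
  sqrt(rowSums((pts - proj)^2))
}

derive_seed <- function(master, i, stage) {
  # deterministic sub-seed, kept < 2^31 (exact in double arithmetic)
  as.integer((as.numeric(master) * 7919 + i * 104729 + stage * 7) %%
               2147483629)
}

#' Generate one subject phantom
#'
#' @param params a [cohort_params()].
#' @param subject_id integer subject index.
#' @param components which volume families to generate: any of
#'   `"striatal"`, `"bundles"`, `"thalamic"`.  Restricting components speeds
#'   up replicate experiments that only exercise one stage.
#' @return list of class `subject_phantom` with masks, labels, fields, truth.
#' @export
generate_subject <- function(params, subject_id = 1L,
                             components = c("striatal", "bundles", "thalamic")) {
  grid <- default_grid(params$spacing)
  sid <- as.integer(subject_id)
  geo <- make_striatal_geometry(grid, seed = derive_seed(params$seed, sid, 0L),
                                subcortical = "bundles" %in% components)
  ph <- list(id = sprintf("S%03d", sid), grid = grid,
             masks = geo$masks, nucleus_labels = geo$nucleus_labels,
             truth = params, seed = derive_seed(params$seed, sid, 0L))
  for (h in c("left", "right")) {
    hi <- if (h == "left") 1L else 2L
    striatum <- binary_mask(grid, geo$masks[[h]]$caudate$membership |
                                   geo$masks[[h]]$putamen$membership)
    ph$striatum[[h]] <- striatum
    if ("striatal" %in% components) {
      g <- make_compartment_field(grid, striatum, h,
                                  params$gradient_weights, params$noise_sd,
                                  seed = derive_seed(params$seed, sid, hi))
      ph$g[[h]] <- g
      ph$striatal_ctt[[h]] <- make_striatal_ctt_pair(
        g, striatum, params$noise_sd,
        seed = derive_seed(params$seed, sid, hi + 2L))
    }
    if ("thalamic" %in% components) {
      ph$thalamic_ctt[[h]] <- make_thalamic_ctt_pair(
        geo$nucleus_labels[[h]], h, params$nucleus_bias,
        params$asymmetry_delta, params$noise_sd, params$share_dispersion,
        params$edge_attenuation_depth,
        seed = derive_seed(params$seed, sid, hi + 4L))
    }
    if ("bundles" %in% components) {
      ref <- if (h == "left") 1 else -1  # +x medial flips across hemispheres
      for (comp in c("striosome", "matrix")) {
        off <- if (comp == "striosome") params$peak_offset_striosome
               else params$peak_offset_matrix
        off <- c(off[1] * ref, off[2], off[3])
        amp <- if (comp == "matrix") params$fold_factor else 1
        dens <- make_bundle_density(grid, striatum, geo$masks[[h]]$gpi,
                                    geo$masks[[h]]$thalamus,
                                    peak_offset_mm = off, amplitude = amp,
                                    noise_frac = 0.02,
                                    seed = derive_seed(params$seed, sid,
                                                       hi + 10L +
                                                         (comp == "matrix") * 2L))
        rate <- if (comp == "matrix") params$per_seed_rate_matrix
                else params$per_seed_rate_striosome
        nseed <- fixed_n_default(params$spacing)
        set.seed(derive_seed(params$seed, sid, hi + 6L +
                               (comp == "matrix") * 2L))
        total <- stats::rpois(1, rate * nseed)
        ph$bundles[[h]][[comp]] <- density_map(dens, comp, h, nseed, total)
      }
    }
  }
  class(ph) <- "subject_phantom"
  ph
}

#' Default equal-volume mask size for a voxel spacing
#'
#' 83 voxels at 2.0 mm, 180 voxels at 1.5 mm — the fixed mask sizes matching
#' a 1.5 sd selection at each resolution.
#'
#' @param spacing isotropic voxel size in mm.
#' @return integer voxel count.
#' @export
fixed_n_default <- function(spacing) {
  if (isTRUE(all.equal(spacing, 1.5))) 180L
  else if (isTRUE(all.equal(spacing, 2.0))) 83L
  else as.integer(round(83 * (2.0 / spacing)^3))
}

#' Generate a cohort of subject phantoms
#'
#' Draws `n_subjects` phantoms with deterministic per-subject sub-seeds and
#' returns them with a ground-truth table recording every planted parameter.
#'
#' @param params a [cohort_params()].
#' @param components passed to [generate_subject()].
#' @return list with `subjects` (list of phantoms) and `truth` (data.frame).
#' @export
generate_cohort <- function(params,
                            components = c("striatal", "bundles", "thalamic")) {
  stopifnot(inherits(params, "cohort_params"))
  subjects <- lapply(seq_len(params$n_subjects), function(i)
    generate_subject(params, i, components))
  truth <- data.frame(
    nucleus = names(params$nucleus_bias),
    beta = unname(params$nucleus_bias),
    asymmetry_delta = params$asymmetry_delta,
    noise_sd = params$noise_sd,
    share_dispersion = params$share_dispersion,
    fold_factor = params$fold_factor,
    spacing = params$spacing,
    seed = params$seed)
  list(subjects = subjects, truth = truth)
}

#' Emulated leave-one-out seed-region profiling pair
#'
#' Emulates classification-targets profiling of a withheld seed region
#' against compartment masks: each region voxel's unnormalized connection
#' weights are `w_str = s * mean(g over the striosome-like mask)` and
#' `w_mat = (1 - s) * mean(1 - g over the matrix-like mask)`, where `s` is
#' the voxel's own striosome affinity (`region_bias` plus noise).  Imprecise
#' (jittered) masks dilute the mask-mean character and so weaken the favored
#' compartment's share.
#'
#' @param region_mask seed region [binary_mask()].
#' @param striosome_mask,matrix_mask compartment target masks.
#' @param g ground-truth striosome-character [scalar_volume()].
#' @param region_bias mean striosome affinity of the region (default 0.95,
#'   a strongly striosome-favoring region).
#' @param noise_sd Gaussian noise sd on the affinity.
#' @param seed integer seed.
#' @return list `(P_to_str, P_to_mat)` of [scalar_volume()].
#' @export
make_seed_region_ctt <- function(region_mask, striosome_mask, matrix_mask, g,
                                 region_bias = 0.95, noise_sd = 0.05,
                                 seed = 1L) {
  idx <- mask_indices(region_mask)
  a_str <- mean(g$values[striosome_mask$membership])
  a_mat <- mean(1 - g$values[matrix_mask$membership])
  set.seed(seed)
  s <- clip01(region_bias + stats::rnorm(nrow(idx), 0, noise_sd))
  w_str <- s * a_str
  w_mat <- (1 - s) * a_mat
  vs <- array(0, g$grid$shape); vm <- array(0, g$grid$shape)
  vs[idx] <- w_str; vm[idx] <- w_mat
  list(P_to_str = scalar_volume(g$grid, vs),
       P_to_mat = scalar_volume(g$grid, vm))
}
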