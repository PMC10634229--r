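# ---------------------------------------------------------------------------
# Grid geometry and volumetric containers.
#
# All geometry lives in one internal mm frame with a voxel-center convention:
# voxel (i, j, k) (1-based in R) has its center at
#   origin + (index - 1 + 0.5) * spacing
# where `origin` is the mm coordinate of the *corner* of the first voxel.
# ---------------------------------------------------------------------------

#' Voxel grid geometry
#'
#' Defines the sampling lattice shared by all volumes in an analysis: the
#' number of voxels per axis, the isotropic-or-not voxel spacing in mm, and
#' the mm coordinate of the corner of the first voxel.  Typical diffusion
#' resolutions are 1.5 or 2.0 mm isotropic.
#'
#' @param shape integer length-3, voxels per axis (all >= 1).
#' @param spacing numeric length-1 or length-3, mm per voxel (> 0).
#' @param origin numeric length-3, mm coordinate of the corner of voxel
#'   (1,1,1).  Defaults to (0,0,0).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be three integers >= 1")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive and finite")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite mm coordinates")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("<grid %dx%dx%d, spacing %s mm>",
          x$shape[1], x$shape[2], x$shape[3],
          paste(signif(x$spacing, 4), collapse = "x"))
}

#' @export
print.grid_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(grid_of(a), grid_of(b)))
    stop("volumes are defined on different grids")
  invisible(NULL)
}

#' Scalar volume
#'
#' One finite real value per voxel on a [grid_spec()]; the substrate for
#' connectivity probability maps and streamline density fields.
#'
#' @param grid a [grid_spec()].
#' @param values numeric array with `dim == grid$shape` (a vector of the
#'   right length is reshaped).  Non-finite entries are rejected.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(grid, values) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(dim(values))) {
    if (length(values) == 1L) values <- rep(values, prod(grid$shape))
    dim(values) <- grid$shape
  }
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("value array shape does not match grid shape")
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("scalar_volume values must all be finite")
  structure(list(grid = grid, values = values), class = "scalar_volume")
}

#' Binary mask
#'
#' Boolean membership per voxel on a [grid_spec()]; used for seed, waypoint,
#' target, and structure masks.
#'
#' @param grid a [grid_spec()].
#' @param membership logical array with `dim == grid$shape` (or vector of the
#'   right length).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, membership) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(dim(membership))) dim(membership) <- grid$shape
  if (!identical(as.integer(dim(membership)), grid$shape))
    stop("membership array shape does not match grid shape")
  membership <- array(as.logical(membership), dim = grid$shape)
  if (any(is.na(membership))) stop("mask membership must not contain NA")
  structure(list(grid = grid, membership = membership), class = "binary_mask")
}

#' Integer label volume
#'
#' Non-negative integer labels per voxel (0 = background) with a label table
#' mapping label id to name (e.g. thalamic nuclei "CM", "Pf").  Every nonzero
#' label present in the volume must be named in the table.
#'
#' @param grid a [grid_spec()].
#' @param labels integer array with `dim == grid$shape`.
#' @param label_table named integer vector: `names` are label names, values
#'   are label ids.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, labels, label_table) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(dim(labels))) dim(labels) <- grid$shape
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop("label array shape does not match grid shape")
  labels <- array(as.integer(labels), dim = grid$shape)
  if (any(is.na(labels)) || any(labels < 0L))
    stop("labels must be non-negative integers")
  label_table <- stats::setNames(as.integer(label_table), names(label_table))
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, label_table)
  if (length(missing))
    stop("labels present in volume but absent from label_table: ",
         paste(missing, collapse = ", "))
  structure(list(grid = grid, labels = labels, label_table = label_table),
            class = "label_volume")
}

grid_of <- function(x) {
  if (inherits(x, "grid_spec")) x else x$grid
}

#' Number of member voxels in a mask
#' @param mask a [binary_mask()].
#' @return integer count.
#' @export
n_voxels <- function(mask) sum(mask$membership)

# 1-based (i,j,k) indices of member voxels, one row each
mask_indices <- function(mask) {
  which(mask$membership, arr.ind = TRUE)
}

#' Voxel index to mm coordinate
#'
#' Returns the voxel-center coordinate `origin + (index - 0.5) * spacing`
#' (1-based indices, so the first voxel center is origin + spacing/2).
#'
#' @param grid a [grid_spec()].
#' @param index integer matrix (n x 3) or length-3 vector of 1-based voxel
#'   indices.
#' @return numeric matrix (n x 3) of mm coordinates (a vector input returns
#'   a length-3 vector).
#' @export
index_to_mm <- function(grid, index) {
  vec <- is.null(dim(index))
  index <- rbind_index(index)
  if (any(index < 1L) || any(sweep(index, 2, grid$shape, `>`)))
    stop("voxel index out of grid bounds")
  mm <- sweep(sweep(index - 0.5, 2, grid$spacing, `*`), 2, grid$origin, `+`)
  if (vec) as.vector(mm) else mm
}

#' mm coordinate to voxel index
#'
#' Inverse of [index_to_mm()]: the voxel whose cell contains the given mm
#' point (nearest voxel center).
#'
#' @param grid a [grid_spec()].
#' @param mm numeric matrix (n x 3) or length-3 vector of mm coordinates.
#' @return integer matrix (n x 3) of 1-based voxel indices (vector in,
#'   vector out).
#' @export
mm_to_index <- function(grid, mm) {
  vec <- is.null(dim(mm))
  mm <- rbind_index(mm)
  idx <- sweep(sweep(mm, 2, grid$origin, `-`), 2, grid$spacing, `/`) + 0.5
  idx <- round(idx)
  idx[] <- as.integer(idx)
  if (any(idx < 1L) || any(sweep(idx, 2, grid$shape, `>`)))
    stop("mm coordinate outside grid bounds")
  if (vec) as.integer(idx) else idx
}

rbind_index <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
}

#' Centroid of a mask in mm
#'
#' Arithmetic mean of the member voxel-center coordinates.
#'
#' @param mask a non-empty [binary_mask()].
#' @return length-3 mm coordinate.
#' @export
centroid_mm <- function(mask) {
  idx <- mask_indices(mask)
  if (nrow(idx) == 0L) stop("centroid_mm: mask is empty")
  unname(colMeans(index_to_mm(mask$grid, idx)))
}

#' Mask volume in mm^3
#'
#' Member voxel count times the voxel volume.  Four voxels at 1.5 mm
#' isotropic give 13.5 mm^3; at 2.0 mm, 32 mm^3 — the minimum admissible
#' nucleus volumes used by [nucleus_volume_filter()].
#'
#' @param mask a [binary_mask()].
#' @return numeric mm^3.
#' @export
volume_mm3 <- function(mask) {
  n_voxels(mask) * prod(mask$grid$spacing)
}

#' Reflect a volume or mask about a sagittal plane
#'
#' Reflects x about `plane_x_mm`, leaving y and z unchanged.  The plane must
#' be aligned to the grid so that mirrored voxel centers land on voxel
#' centers; otherwise the operation resamples to the nearest voxel.  Mirroring
#' is an involution and preserves mask volume.
#'
#' @param x a [scalar_volume()], [binary_mask()], or [label_volume()].
#' @param plane_x_mm mm x-coordinate of the mirror plane.  Default: the
#'   mid-grid plane.
#' @return Same type as `x`.
#' @export
mirror_x <- function(x, plane_x_mm = NULL) {
  grid <- grid_of(x)
  if (is.null(plane_x_mm))
    plane_x_mm <- grid$origin[1] + grid$shape[1] * grid$spacing[1] / 2
  nx <- grid$shape[1]
  # center of voxel i is origin + (i - 0.5) s; reflection maps it to index
  # j = (2*(plane - origin)/s + 1) - i, rounded to nearest voxel
  src <- seq_len(nx)
  j <- round(2 * (plane_x_mm - grid$origin[1]) / grid$spacing[1] + 1 - src)
  j <- pmin(pmax(as.integer(j), 1L), nx)
  take <- function(arr) arr[j, , , drop = FALSE]
  if (inherits(x, "scalar_volume")) {
    scalar_volume(grid, take(x$values))
  } else if (inherits(x, "binary_mask")) {
    binary_mask(grid, take(x$membership))
  } else if (inherits(x, "label_volume")) {
    label_volume(grid, take(x$labels), x$label_table)
  } else stop("mirror_x: unsupported type")
}

# ---------------------------------------------------------------------------
# NIfTI-1 I/O.  Grid spacing goes in pixdim; the affine encodes
# diag(spacing) with offset = origin + spacing/2 (NIfTI origins are
# voxel-center).  Label tables travel in a JSON sidecar
# (<file>.labels.json) because NIfTI-1 has no standard label-name field.
# ---------------------------------------------------------------------------

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".labels.json", path)
}

#' Write a volume to NIfTI-1
#'
#' Scalar volumes are stored as 32-bit float, masks as uint8, label volumes
#' as int16 with their label table in a `.labels.json` sidecar.
#'
#' @param vol a [scalar_volume()], [binary_mask()], or [label_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  grid <- grid_of(vol)
  if (inherits(vol, "scalar_volume")) {
    arr <- vol$values; dtype <- "float"
  } else if (inherits(vol, "binary_mask")) {
    arr <- array(as.integer(vol$membership), grid$shape); dtype <- "uint8"
  } else if (inherits(vol, "label_volume")) {
    arr <- vol$labels; dtype <- "int16"
  } else stop("write_volume: unsupported type")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$spacing
  aff <- diag(c(grid$spacing, 1))
  aff[1:3, 4] <- grid$origin + grid$spacing / 2
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = dtype)
  if (inherits(vol, "label_volume")) {
    jsonlite::write_json(as.list(vol$label_table), sidecar_path(path),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' @param path `.nii` / `.nii.gz` path.
#' @param as one of `"scalar"`, `"mask"`, `"labels"`, or `"auto"`.  In
#'   `"auto"` mode a `.labels.json` sidecar selects `"labels"`, otherwise
#'   the volume is read as scalar.
#' @return A [scalar_volume()], [binary_mask()], or [label_volume()].
#' @export
read_volume <- function(path, as = c("auto", "scalar", "mask", "labels")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop("malformed NIfTI file '", path, "': ", conditionMessage(e)))
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4] - sp / 2
  arr <- array(as.vector(img), dim = dim(img)[1:3])
  grid <- grid_spec(dim(arr), sp, origin)
  sc <- sidecar_path(path)
  if (as == "auto") as <- if (file.exists(sc)) "labels" else "scalar"
  switch(as,
    scalar = scalar_volume(grid, arr),
    mask = binary_mask(grid, arr > 0.5),
    labels = {
      if (!file.exists(sc))
        stop("label sidecar not found: ", sc)
      tab <- unlist(jsonlite::read_json(sc))
      label_volume(grid, round(arr), stats::setNames(as.integer(tab), names(tab)))
    })
}
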