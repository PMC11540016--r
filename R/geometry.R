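#' Voxel grid geometry
#'
#' Describes the regular voxel grid shared by all volumes in an analysis:
#' world coordinates are right-handed (x left-right, y anterior-posterior,
#' z superior-inferior), in millimetres, with `origin` at the centre of
#' voxel (0,0,0). Voxel indices are 0-based in all world/index conversions.
#'
#' @param origin numeric length 3; world coordinates (mm) of the centre of
#'   voxel (0,0,0).
#' @param spacing numeric length 3; per-axis voxel size in mm, strictly
#'   positive.
#' @param dims integer length 3; voxel counts per axis.
#' @return An object of class `volume_geometry`.
#' @examples
#' g <- volume_geometry(c(-47.5, -47.5, -47.5), c(1, 1, 1), c(96, 96, 96))
#' voxel_volume_mm3(g)
#' @export
volume_geometry <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  if (length(origin) != 3L || length(spacing) != 3L || length(dims) != 3L)
    stop("origin, spacing and dims must each have length 3")
  if (any(!is.finite(origin)) || any(!is.finite(spacing)))
    stop("origin and spacing must be finite")
  if (any(spacing <= 0)) stop("spacing must be strictly positive on all axes")
  if (any(is.na(dims)) || any(dims < 1L)) stop("dims must be positive integers")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf("<volume_geometry> dims %s, spacing %s mm, origin %s mm\n",
              paste(x$dims, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Test geometry compatibility
#'
#' Two geometries are compatible iff origin, spacing and dims agree within
#' `tol` mm on every axis. All voxelwise operations require compatibility.
#'
#' @param a,b `volume_geometry` objects.
#' @param tol tolerance in mm (default `1e-6`).
#' @return logical scalar.
#' @export
geometry_compatible <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "volume_geometry"), inherits(b, "volume_geometry"))
  all(a$dims == b$dims) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol)
}

stop_if_incompatible <- function(a, b, what = "volumes") {
  if (!geometry_compatible(a, b))
    stop(sprintf("geometry mismatch: %s are not on the same voxel grid", what))
  invisible(TRUE)
}

#' @rdname volume_geometry
#' @param geometry a `volume_geometry`.
#' @export
voxel_volume_mm3 <- function(geometry) prod(geometry$spacing)

#' Convert between world coordinates and voxel indices
#'
#' `world_to_index()` maps world points (mm) to continuous 0-based voxel
#' indices; `index_to_world()` maps 0-based indices to the world coordinates
#' of voxel centres. A world point belongs to the voxel whose centre is
#' nearest, i.e. `round(world_to_index(p))`.
#'
#' @param geometry a `volume_geometry`.
#' @param points numeric matrix (n x 3) or length-3 vector.
#' @return numeric matrix (n x 3).
#' @export
world_to_index <- function(geometry, points) {
  p <- as_point_matrix(points)
  sweep(sweep(p, 2, geometry$origin, "-"), 2, geometry$spacing, "/")
}

#' @rdname world_to_index
#' @param index numeric matrix (n x 3) of 0-based voxel indices.
#' @export
index_to_world <- function(geometry, index) {
  p <- as_point_matrix(index)
  sweep(sweep(p, 2, geometry$spacing, "*"), 2, geometry$origin, "+")
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 3)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3 (x, y, z in mm)")
  storage.mode(points) <- "double"
  points
}

#' Grid of voxel-centre coordinates along one axis
#' @param geometry a `volume_geometry`.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of world coordinates (mm) of voxel centres.
#' @export
axis_coords <- function(geometry, axis) {
  geometry$origin[axis] + (seq_len(geometry$dims[axis]) - 1) * geometry$spacing[axis]
}

#' 3D scalar field on a voxel grid
#'
#' Container for a dose volume (Gy), a CBCT-number volume, or a CBCT-number
#' difference volume, on a shared [volume_geometry()]. Values must be finite;
#' dose values must be non-negative.
#'
#' @param values 3D numeric array with dim equal to `geometry$dims`.
#' @param geometry a `volume_geometry`.
#' @param quantity one of `"dose_Gy"`, `"cbct_number"`, `"delta_cbct"`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, geometry,
                          quantity = c("dose_Gy", "cbct_number", "delta_cbct")) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(geometry, "volume_geometry"))
  values <- check_array3(values, geometry, "values")
  if (any(!is.finite(values))) stop("values must all be finite")
  if (quantity == "dose_Gy" && any(values < 0))
    stop("dose_Gy values must be >= 0")
  structure(list(values = values, geometry = geometry, quantity = quantity),
            class = "scalar_volume")
}

check_array3 <- function(values, geometry, what) {
  if (length(dim(values)) != 3L)
    stop(sprintf("%s must be a 3D array", what))
  if (!all(dim(values) == geometry$dims))
    stop(sprintf("%s shape (%s) does not match geometry dims (%s)",
                 what, paste(dim(values), collapse = "x"),
                 paste(geometry$dims, collapse = "x")))
  storage.mode(values) <- "double"
  values
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s, dims %s, range [%g, %g]\n",
              x$quantity, paste(x$geometry$dims, collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binary structure mask on a voxel grid
#'
#' @param values 3D logical (or 0/1 numeric) array matching `geometry$dims`.
#' @param geometry a `volume_geometry`.
#' @param name label for the structure (e.g. `"GTV"`).
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(values, geometry, name = "structure") {
  stopifnot(inherits(geometry, "volume_geometry"))
  if (length(dim(values)) != 3L) stop("mask values must be a 3D array")
  if (!all(dim(values) == geometry$dims))
    stop("mask shape does not match geometry dims")
  v <- array(as.logical(values), dim = geometry$dims)
  if (any(is.na(v))) stop("mask values must be TRUE/FALSE (or 0/1)")
  structure(list(values = v, geometry = geometry, name = as.character(name)),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s', dims %s, %d voxels, %.1f cm^3\n",
              x$name, paste(x$geometry$dims, collapse = "x"),
              sum(x$values), mask_volume_cm3(x)))
  invisible(x)
}

#' Mask volume in cubic centimetres
#' @param mask a `structure_mask`.
#' @return numeric scalar: true-voxel count times voxel volume, in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$values) * voxel_volume_mm3(mask$geometry) / 1000
}

#' Centroid of a mask in world coordinates
#' @param mask a `structure_mask`.
#' @return numeric length 3 (mm); error if the mask is empty.
#' @export
mask_centroid <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  idx <- which(mask$values, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot compute centroid of an empty mask")
  colMeans(index_to_world(mask$geometry, idx - 1))
}

#' Axis-aligned bounding box of a geometry's voxel-centre extent
#' @param geometry a `volume_geometry`.
#' @return list with `lo` and `hi`, world coordinates (mm) of the first and
#'   last voxel centres per axis.
#' @export
geometry_bbox <- function(geometry) {
  list(lo = geometry$origin,
       hi = geometry$origin + (geometry$dims - 1) * geometry$spacing)
}
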