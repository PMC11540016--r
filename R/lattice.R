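#' Lattice specification for sphere-vertex placement
#'
#' Parameters of a lattice of high-dose sphere vertices: pattern (hexagonal
#' close-packed or rectangular), sphere diameter, centre-to-centre spacing,
#' and optional in-plane shifts that translate the whole lattice. The spacing
#' must be at least the sphere diameter so that vertices never overlap.
#'
#' @param pattern `"hexagonal"` or `"rectangular"`.
#' @param sphere_diameter sphere diameter in mm (> 0).
#' @param spacing centre-to-centre distance in mm (>= `sphere_diameter`).
#' @param shift_x,shift_y in-plane lattice shift in mm (no z shift).
#' @return An object of class `lattice_spec`.
#' @examples
#' lattice_spec("hexagonal", sphere_diameter = 15, spacing = 30)
#' @export
lattice_spec <- function(pattern = c("hexagonal", "rectangular"),
                         sphere_diameter, spacing,
                         shift_x = 0, shift_y = 0) {
  pattern <- match.arg(pattern)
  if (!is.numeric(sphere_diameter) || sphere_diameter <= 0)
    stop("sphere_diameter must be > 0")
  if (!is.numeric(spacing) || spacing < sphere_diameter)
    stop("spacing must be >= sphere_diameter (overlapping vertices are not allowed)")
  structure(list(pattern = pattern,
                 sphere_diameter = as.numeric(sphere_diameter),
                 spacing = as.numeric(spacing),
                 shift_x = as.numeric(shift_x),
                 shift_y = as.numeric(shift_y)),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %s, d = %g mm, s = %g mm, shift (%g, %g) mm\n",
              x$pattern, x$sphere_diameter, x$spacing, x$shift_x, x$shift_y))
  invisible(x)
}

#' Set of placed lattice vertices
#'
#' @param centers n x 3 matrix of world points (mm).
#' @param diameter sphere diameter in mm.
#' @param anchor world point of the lattice origin vertex, or `NULL`.
#' @return An object of class `vertex_set`.
#' @export
vertex_set <- function(centers, diameter, anchor = NULL) {
  centers <- if (is.null(centers) || length(centers) == 0L)
    matrix(numeric(0), ncol = 3) else as_point_matrix(centers)
  colnames(centers) <- c("x", "y", "z")
  structure(list(centers = centers, diameter = as.numeric(diameter),
                 anchor = if (is.null(anchor)) NULL else as.numeric(anchor)),
            class = "vertex_set")
}

#' @export
print.vertex_set <- function(x, ...) {
  cat(sprintf("<vertex_set> %d vertices, sphere diameter %g mm\n",
              nrow(x$centers), x$diameter))
  invisible(x)
}

#' Generate hexagonal close-packed candidate sites
#'
#' Constructs all sites of an HCP lattice that fall inside an axis-aligned
#' bounding box. A-layers are triangular lattices with basis
#' `a1 = (s, 0, 0)`, `a2 = (s/2, s*sqrt(3)/2, 0)`; layer k sits at
#' `z = k * s * sqrt(2/3)`, and odd (B) layers are offset in-plane by
#' `(s/2, s/(2*sqrt(3)))`. The anchor is itself a site on layer 0 and the
#' in-plane shift `(shift_x, shift_y)` is added to every site. The nearest
#' neighbour distance of the infinite lattice is exactly `s`, with
#' coordination number 12.
#'
#' @param spec a [lattice_spec()] with `pattern = "hexagonal"`.
#' @param anchor world point (mm): a lattice site on layer 0.
#' @param bbox list with `lo` and `hi` world points (as from
#'   [geometry_bbox()]).
#' @return n x 3 matrix of candidate world points (possibly 0 rows).
#' @export
generate_hcp_candidates <- function(spec, anchor, bbox) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (spec$pattern != "hexagonal")
    stop("generate_hcp_candidates requires pattern = 'hexagonal'")
  s <- spec$spacing
  anchor <- as.numeric(anchor)
  dz <- s * sqrt(2 / 3)
  row_h <- s * sqrt(3) / 2
  tol <- 1e-9
  lo <- as.numeric(bbox$lo); hi <- as.numeric(bbox$hi)
  if (any(hi < lo)) return(vertex_matrix(NULL))

  ax <- anchor[1] + spec$shift_x
  ay <- anchor[2] + spec$shift_y
  az <- anchor[3]

  kr <- range_steps(lo[3], hi[3], az, dz, tol)
  pts <- list()
  for (k in kr) {
    z <- az + k * dz
    off <- if (k %% 2 == 0) c(0, 0) else c(s / 2, s / (2 * sqrt(3)))
    jr <- range_steps(lo[2], hi[2], ay + off[2], row_h, tol)
    for (j in jr) {
      y <- ay + off[2] + j * row_h
      x0 <- ax + off[1] + j * s / 2
      ir <- range_steps(lo[1], hi[1], x0, s, tol)
      if (length(ir))
        pts[[length(pts) + 1L]] <- cbind(x0 + ir * s, y, z)
    }
  }
  vertex_matrix(pts)
}

#' Generate rectangular (cubic) candidate sites
#'
#' Cubic grid with period `spacing` on all three axes, with a site at the
#' anchor, translated in-plane by `(shift_x, shift_y)`; interior sites have
#' 6 nearest neighbours at distance `spacing`.
#'
#' @inheritParams generate_hcp_candidates
#' @return n x 3 matrix of candidate world points.
#' @export
generate_rect_candidates <- function(spec, anchor, bbox) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (spec$pattern != "rectangular")
    stop("generate_rect_candidates requires pattern = 'rectangular'")
  s <- spec$spacing
  anchor <- as.numeric(anchor)
  tol <- 1e-9
  lo <- as.numeric(bbox$lo); hi <- as.numeric(bbox$hi)
  if (any(hi < lo)) return(vertex_matrix(NULL))
  ax <- anchor[1] + spec$shift_x
  ay <- anchor[2] + spec$shift_y
  az <- anchor[3]
  xi <- ax + range_steps(lo[1], hi[1], ax, s, tol) * s
  yi <- ay + range_steps(lo[2], hi[2], ay, s, tol) * s
  zi <- az + range_steps(lo[3], hi[3], az, s, tol) * s
  if (!length(xi) || !length(yi) || !length(zi)) return(vertex_matrix(NULL))
  g <- expand.grid(x = xi, y = yi, z = zi)
  vertex_matrix(list(as.matrix(g)))
}

range_steps <- function(lo, hi, base, step, tol) {
  i0 <- ceiling((lo - base) / step - tol)
  i1 <- floor((hi - base) / step + tol)
  if (i1 < i0) integer(0) else seq(i0, i1)
}

vertex_matrix <- function(pts) {
  if (is.null(pts) || length(pts) == 0L) {
    m <- matrix(numeric(0), ncol = 3)
  } else {
    m <- do.call(rbind, pts)
  }
  colnames(m) <- c("x", "y", "z")
  m
}

#' Euclidean distance transform of a structure mask
#'
#' Distance (mm) from each interior voxel centre to the nearest outside voxel
#' centre, computed exactly with a separable parabolic-envelope transform;
#' 0 on outside voxels. Used to test full sphere containment.
#'
#' @param mask a [structure_mask()].
#' @return 3D numeric array of distances in mm.
#' @export
mask_distance_transform <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  d <- .edt3d_cpp(as.vector(mask$values), mask$geometry$dims,
                  mask$geometry$spacing)
  array(d, dim = mask$geometry$dims)
}

#' Keep candidates whose sphere is fully contained in the target
#'
#' A candidate is kept iff the Euclidean distance transform of the target
#' mask, at the voxel containing the candidate (nearest voxel centre), is at
#' least `radius`. An empty target yields an empty vertex set.
#'
#' @param candidates n x 3 matrix of world points (mm).
#' @param target a [structure_mask()].
#' @param radius sphere radius in mm (> 0).
#' @param anchor optional anchor point carried into the result.
#' @return A [vertex_set()] with `diameter = 2 * radius`.
#' @export
filter_contained <- function(candidates, target, radius, anchor = NULL) {
  stopifnot(inherits(target, "structure_mask"))
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  candidates <- if (length(candidates) == 0L)
    matrix(numeric(0), ncol = 3) else as_point_matrix(candidates)
  if (nrow(candidates) == 0L || !any(target$values))
    return(vertex_set(NULL, diameter = 2 * radius, anchor = anchor))
  dt <- mask_distance_transform(target)
  g <- target$geometry
  idx <- round(world_to_index(g, candidates)) + 1  # 1-based array index
  keep <- rep(FALSE, nrow(candidates))
  inside <- idx[, 1] >= 1 & idx[, 1] <= g$dims[1] &
            idx[, 2] >= 1 & idx[, 2] <= g$dims[2] &
            idx[, 3] >= 1 & idx[, 3] <= g$dims[3]
  if (any(inside)) {
    lin <- (idx[inside, 3] - 1) * g$dims[1] * g$dims[2] +
           (idx[inside, 2] - 1) * g$dims[1] + idx[inside, 1]
    keep[inside] <- dt[lin] >= radius
  }
  vertex_set(candidates[keep, , drop = FALSE], diameter = 2 * radius,
             anchor = anchor)
}

#' Place lattice vertices inside a target structure
#'
#' End-to-end placement: generates candidate sites over the target's bounding
#' box (expanded by one lattice period) and keeps those whose sphere of
#' `sphere_diameter / 2` is fully contained in the target. With the default
#' centroid anchor and a hexagonal pattern, layer 0 (an A-layer) passes
#' through the target centroid with a vertex built around the centre.
#'
#' @param target a [structure_mask()] (e.g. the GTV).
#' @param spec a [lattice_spec()].
#' @param anchor `"centroid"` (default) or a world point (mm).
#' @return A [vertex_set()].
#' @examples
#' g <- volume_geometry(c(-47.5, -47.5, -47.5), c(1, 1, 1), c(96, 96, 96))
#' gtv <- make_cylinder_mask(phantom_spec(radius = 45, height = 90.5, grid = g))
#' vs <- place_vertices(gtv, lattice_spec("hexagonal", 15, 30))
#' nrow(vs$centers)  # 19
#' @export
place_vertices <- function(target, spec, anchor = "centroid") {
  stopifnot(inherits(target, "structure_mask"), inherits(spec, "lattice_spec"))
  if (identical(anchor, "centroid")) anchor <- mask_centroid(target)
  anchor <- as.numeric(anchor)
  bb <- geometry_bbox(target$geometry)
  bb$lo <- bb$lo - spec$spacing
  bb$hi <- bb$hi + spec$spacing
  cand <- switch(spec$pattern,
                 hexagonal = generate_hcp_candidates(spec, anchor, bb),
                 rectangular = generate_rect_candidates(spec, anchor, bb))
  filter_contained(cand, target, spec$sphere_diameter / 2, anchor = anchor)
}

#' Rasterize vertices to a (labelled) mask
#'
#' Sets every voxel whose centre lies within `diameter / 2` of any vertex
#' centre. In labelled mode, voxels get the integer index of their sphere
#' (unambiguous because spacing >= diameter).
#'
#' @param vset a [vertex_set()].
#' @param geometry target [volume_geometry()].
#' @param labeled if `TRUE`, return a [scalar_volume()]-like integer array of
#'   sphere labels wrapped in a list; otherwise a [structure_mask()].
#' @return A [structure_mask()] (default) or, with `labeled = TRUE`, a list
#'   with `labels` (3D integer array) and `geometry`.
#' @export
vertices_to_mask <- function(vset, geometry, labeled = FALSE) {
  stopifnot(inherits(vset, "vertex_set"), inherits(geometry, "volume_geometry"))
  bb <- geometry_bbox(geometry)
  centers <- vset$centers
  if (nrow(centers) > 0L) {
    out <- which(centers[, 1] < bb$lo[1] - 1e-9 | centers[, 1] > bb$hi[1] + 1e-9 |
                 centers[, 2] < bb$lo[2] - 1e-9 | centers[, 2] > bb$hi[2] + 1e-9 |
                 centers[, 3] < bb$lo[3] - 1e-9 | centers[, 3] > bb$hi[3] + 1e-9)
    if (length(out))
      stop(sprintf("vertex centre(s) outside the grid extent: %s",
                   paste(out, collapse = ", ")))
  }
  labels <- array(0L, dim = geometry$dims)
  r <- vset$diameter / 2
  xs <- axis_coords(geometry, 1)
  ys <- axis_coords(geometry, 2)
  zs <- axis_coords(geometry, 3)
  for (v in seq_len(nrow(centers))) {
    c3 <- centers[v, ]
    ix <- which(abs(xs - c3[1]) <= r)
    iy <- which(abs(ys - c3[2]) <= r)
    iz <- which(abs(zs - c3[3]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xs[ix] - c3[1])^2
    dy2 <- (ys[iy] - c3[2])^2
    dz2 <- (zs[iz] - c3[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    sub <- labels[ix, iy, iz, drop = FALSE]
    sub[d2 <= r^2] <- v
    labels[ix, iy, iz] <- sub
  }
  if (labeled) return(list(labels = labels, geometry = geometry))
  structure_mask(labels > 0L, geometry, name = "lattice_spheres")
}

#' Export vertex centres
#'
#' `write_vertices_csv()` writes `x_mm, y_mm, z_mm, label`;
#' `write_vertices_json()` writes the spec, anchor and centres;
#' `read_vertices_json()` restores a [vertex_set()].
#'
#' @param vset a [vertex_set()].
#' @param path output path.
#' @param spec optional [lattice_spec()] echoed into the JSON.
#' @return `path` (writers) or a [vertex_set()] (reader), invisibly for
#'   writers.
#' @export
write_vertices_csv <- function(vset, path) {
  df <- data.frame(x_mm = vset$centers[, 1], y_mm = vset$centers[, 2],
                   z_mm = vset$centers[, 3], label = seq_len(nrow(vset$centers)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vertices_csv
#' @export
write_vertices_json <- function(vset, path, spec = NULL) {
  obj <- list(diameter_mm = vset$diameter,
              anchor_mm = vset$anchor,
              centers_mm = unname(apply(vset$centers, 1, as.numeric,
                                        simplify = FALSE)))
  if (!is.null(spec)) obj$spec <- unclass(spec)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_vertices_csv
#' @export
read_vertices_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- obj$centers_mm
  if (is.list(centers)) centers <- do.call(rbind, centers)
  vertex_set(centers, diameter = obj$diameter_mm, anchor = obj$anchor_mm)
}
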