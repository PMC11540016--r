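#' Cylindrical phantom specification
#'
#' Canonical surrogate for a ~2 L cylindrical gel phantom: the default
#' radius 45 mm and height 90.5 mm give an analytic volume of
#' pi * 4.5^2 * 9.05 = 575.7 cm^3, the contracted body-contour GTV volume
#' the lattice is designed for.
#'
#' @param radius cylinder radius in mm (> 0).
#' @param height cylinder height in mm (> 0).
#' @param grid [volume_geometry()] the phantom is rasterized on; the
#'   cylinder is centred in the grid and must fit inside it.
#' @param shape only `"cylinder"`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(radius = 45, height = 90.5, grid,
                         shape = "cylinder") {
  if (!identical(shape, "cylinder")) stop("only cylindrical phantoms are supported")
  if (radius <= 0 || height <= 0) stop("radius and height must be > 0")
  stopifnot(inherits(grid, "volume_geometry"))
  ext <- (grid$dims - 1) * grid$spacing  # voxel-centre extent
  if (2 * radius > ext[1] + grid$spacing[1] ||
      2 * radius > ext[2] + grid$spacing[2] ||
      height > ext[3] + grid$spacing[3])
    stop("cylinder exceeds the grid extent")
  structure(list(shape = shape, radius = as.numeric(radius),
                 height = as.numeric(height), grid = grid),
            class = "phantom_spec")
}

#' Rasterize the cylindrical phantom mask
#'
#' Voxel centres with `x^2 + y^2 <= r^2` and `|z| <= h/2` (relative to the
#' grid centre) are set.
#'
#' @param spec a [phantom_spec()].
#' @return A [structure_mask()].
#' @examples
#' g <- volume_geometry(c(-47.5, -47.5, -47.5), c(1, 1, 1), c(96, 96, 96))
#' m <- make_cylinder_mask(phantom_spec(45, 90.5, g))
#' mask_volume_cm3(m)  # ~575.7 cm^3
#' @export
make_cylinder_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  ctr <- g$origin + (g$dims - 1) / 2 * g$spacing
  xs <- axis_coords(g, 1) - ctr[1]
  ys <- axis_coords(g, 2) - ctr[2]
  zs <- axis_coords(g, 3) - ctr[3]
  inplane <- outer(xs^2, ys^2, "+") <= spec$radius^2
  inz <- abs(zs) <= spec$height / 2
  vals <- array(FALSE, dim = g$dims)
  for (k in which(inz)) vals[, , k] <- inplane
  structure_mask(vals, g, name = "phantom")
}

#' Analytic multi-sphere lattice dose distribution
#'
#' Emulates the dose morphology of a lattice plan: a valley floor plus, for
#' each vertex, a radial logistic peak. The dose at world point `p` is
#' `D(p) = f * P * sigma((R_env - dmin) / w_env) +
#' (1 - f) * P * max_c sigma((r0 - |p - c|) / w)` with `sigma` the logistic
#' function, `P = peak`, `f = valley_floor_frac`, `dmin` the distance to the
#' nearest vertex, and `r0` chosen in closed form so that `D = rx` exactly
#' at radius `eq_diameter / 2` from each isolated vertex — giving analytic
#' isodose radii for oracle tests. The envelope term makes the valley floor
#' decay away from the lattice, as delivered plans do toward the phantom
#' periphery, so an axial slice spans the full dose range from near zero to
#' the peak; `envelope_radius = Inf` gives a uniform floor.
#'
#' @param vset a [vertex_set()] of sphere centres.
#' @param rx prescription dose in Gy (default 20).
#' @param peak peak dose in Gy at the vertex centres (default 24.9;
#'   must be >= `rx`).
#' @param sphere_radius nominal vertex sphere radius in mm (default 7.5).
#' @param penumbra_w logistic penumbra width parameter in mm (default 1.8).
#' @param valley_floor_frac valley floor as a fraction of `peak`
#'   (default 0.3; must satisfy `0 <= f` and `f * peak < rx`).
#' @param grid [volume_geometry()] to rasterize on.
#' @param eq_diameter diameter (mm) of the rx-level isodose sphere around an
#'   isolated vertex; defaults to `2 * sphere_radius`.
#' @param envelope_radius distance from the nearest vertex (mm) at which the
#'   valley floor has decayed to half (default 30, one lattice period);
#'   `Inf` disables the decay.
#' @param envelope_w logistic width of the floor decay in mm (default 4).
#' @return A [scalar_volume()] with quantity `"dose_Gy"`.
#' @export
make_plan_dose <- function(vset, rx = 20, peak = 24.9, sphere_radius = 7.5,
                           penumbra_w = 1.8, valley_floor_frac = 0.3,
                           grid, eq_diameter = NULL,
                           envelope_radius = 30, envelope_w = 4) {
  stopifnot(inherits(vset, "vertex_set"), inherits(grid, "volume_geometry"))
  if (peak < rx) stop("peak must be >= rx")
  if (valley_floor_frac < 0 || valley_floor_frac >= 1)
    stop("valley_floor_frac must be in [0, 1)")
  if (valley_floor_frac * peak >= rx)
    stop("valley floor must lie below the prescription dose")
  if (is.null(eq_diameter)) eq_diameter <- 2 * sphere_radius
  centers <- vset$centers
  bb <- geometry_bbox(grid)
  if (nrow(centers) > 0L &&
      any(centers[, 1] < bb$lo[1] | centers[, 1] > bb$hi[1] |
          centers[, 2] < bb$lo[2] | centers[, 2] > bb$hi[2] |
          centers[, 3] < bb$lo[3] | centers[, 3] > bb$hi[3]))
    stop("vertex centres outside the grid extent")
  # r0 from the closed-form logistic level crossing at eq_diameter / 2
  q <- (rx - valley_floor_frac * peak) / ((1 - valley_floor_frac) * peak)
  r0 <- eq_diameter / 2 + penumbra_w * log(q / (1 - q))
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  dmin <- array(Inf, dim = grid$dims)
  dz2_all <- lapply(seq_len(nrow(centers)), function(v) (zs - centers[v, 3])^2)
  for (v in seq_len(nrow(centers))) {
    dxy2 <- outer((xs - centers[v, 1])^2, (ys - centers[v, 2])^2, "+")
    for (k in seq_along(zs)) {
      dist <- sqrt(dxy2 + dz2_all[[v]][k])
      dmin[, , k] <- pmin(dmin[, , k], dist)
    }
  }
  if (nrow(centers) > 0L) {
    sig <- stats::plogis((r0 - dmin) / penumbra_w)
    env <- if (is.finite(envelope_radius))
      stats::plogis((envelope_radius - dmin) / envelope_w) else 1
  } else {
    sig <- array(0, grid$dims)
    env <- 1
  }
  d <- valley_floor_frac * peak * env + (1 - valley_floor_frac) * peak * sig
  scalar_volume(d, grid, quantity = "dose_Gy")
}

#' Gel simulation configuration
#'
#' @param curve ground-truth [calibration_curve()] of the simulated gel
#'   batch. The default (alpha 40, beta 60, gamma 0.08 / Gy, phi 0.3)
#'   saturates softly above ~25 Gy, matching a gel read over a 0-25 Gy
#'   lattice dose range.
#' @param noise_sd Gaussian CBCT-number noise SD per scan (default 1% of
#'   `beta`).
#' @param n_scans scans per condition (default 6, mirroring a 6 pre- +
#'   6 post-irradiation protocol).
#' @param ring_amplitude amplitude (CBCT numbers) of an optional radial ring
#'   artefact added to the post-irradiation scans (default 0 = off).
#' @param ring_period radial period of the ring artefact in mm.
#' @param base_number constant CBCT number of the unirradiated gel.
#' @param seed integer RNG seed; the whole simulation is reproducible from
#'   it.
#' @return An object of class `gel_sim_config`.
#' @export
gel_sim_config <- function(curve = calibration_curve(40, 60, 0.08, 0.3),
                           noise_sd = 0.6, n_scans = 6L, ring_amplitude = 0,
                           ring_period = 10, base_number = 1000, seed = 1L) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_scans < 1) stop("n_scans must be >= 1")
  structure(list(curve = curve, noise_sd = as.numeric(noise_sd),
                 n_scans = as.integer(n_scans),
                 ring_amplitude = as.numeric(ring_amplitude),
                 ring_period = as.numeric(ring_period),
                 base_number = as.numeric(base_number),
                 seed = as.integer(seed)),
            class = "gel_sim_config")
}

#' Simulate pre-/post-irradiation CBCT scan sets of a gel phantom
#'
#' The unirradiated gel has a constant CBCT number inside the phantom; each
#' post-irradiation scan adds the forward dose response
#' (`alpha + beta * tanh(gamma * D - phi)`) inside the phantom, an optional
#' azimuthally symmetric ring artefact (a remnant that survives background
#' subtraction), and i.i.d. Gaussian noise; pre-irradiation scans add noise
#' only. A single RNG seeded from `cfg$seed` drives all scans sequentially,
#' so runs are bit-reproducible.
#'
#' @param dose true dose [scalar_volume()].
#' @param phantom gel container [structure_mask()] on the same grid.
#' @param cfg a [gel_sim_config()].
#' @return list with `pre_scans`, `post_scans` (lists of
#'   [scalar_volume()]s, quantity `"cbct_number"`) and `truth`: the
#'   noiseless response field (`response`), the true `dose`, the `curve`,
#'   and the phantom mask.
#' @export
simulate_cbct_pair <- function(dose, phantom, cfg) {
  stopifnot(inherits(dose, "scalar_volume"), inherits(phantom, "structure_mask"),
            inherits(cfg, "gel_sim_config"))
  stop_if_incompatible(dose$geometry, phantom$geometry, "dose and phantom")
  g <- dose$geometry
  inside <- phantom$values
  base <- array(0, g$dims)
  base[inside] <- cfg$base_number
  response <- array(0, g$dims)
  response[inside] <- cal_forward(cfg$curve, dose$values[inside])
  ring <- array(0, g$dims)
  if (cfg$ring_amplitude != 0) {
    ctr <- g$origin + (g$dims - 1) / 2 * g$spacing
    xs <- axis_coords(g, 1) - ctr[1]
    ys <- axis_coords(g, 2) - ctr[2]
    ringsl <- cfg$ring_amplitude *
      sin(2 * pi * sqrt(outer(xs^2, ys^2, "+")) / cfg$ring_period)
    for (k in seq_len(g$dims[3])) ring[, , k] <- ringsl * inside[, , k]
  }
  set.seed(cfg$seed)
  noise_scan <- function(field) {
    vals <- field
    if (cfg$noise_sd > 0)
      vals <- vals + array(stats::rnorm(length(field), sd = cfg$noise_sd),
                           dim = g$dims)
    scalar_volume(vals, g, quantity = "cbct_number")
  }
  pre_scans <- lapply(seq_len(cfg$n_scans), function(i) noise_scan(base))
  post_scans <- lapply(seq_len(cfg$n_scans),
                       function(i) noise_scan(base + response + ring))
  list(pre_scans = pre_scans, post_scans = post_scans,
       truth = list(response = response, dose = dose, curve = cfg$curve,
                    phantom = phantom, ring = ring))
}
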