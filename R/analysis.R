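#' Trilinear interpolation of a scalar volume at world points
#'
#' Exact on fields linear in the coordinates. Points outside the
#' voxel-centre extent yield `NA`.
#'
#' @param vol a [scalar_volume()].
#' @param points n x 3 matrix of world points (mm).
#' @return numeric vector of interpolated values (`NA` outside the grid).
#' @export
trilinear_sample <- function(vol, points) {
  stopifnot(inherits(vol, "scalar_volume"))
  g <- vol$geometry
  idx <- world_to_index(g, points)  # continuous 0-based
  n <- nrow(idx)
  out <- rep(NA_real_, n)
  ok <- idx[, 1] >= 0 & idx[, 1] <= g$dims[1] - 1 &
        idx[, 2] >= 0 & idx[, 2] <= g$dims[2] - 1 &
        idx[, 3] >= 0 & idx[, 3] <= g$dims[3] - 1
  if (!any(ok)) return(out)
  p <- idx[ok, , drop = FALSE]
  i0 <- pmin(floor(p), rep(pmax(g$dims - 2, 0), each = nrow(p)))
  i0 <- pmax(i0, 0)
  f <- p - i0
  v <- vol$values
  d1 <- g$dims[1]; d12 <- g$dims[1] * g$dims[2]
  base <- i0[, 1] + i0[, 2] * d1 + i0[, 3] * d12 + 1
  s1 <- if (g$dims[1] > 1) 1 else 0
  s2 <- if (g$dims[2] > 1) d1 else 0
  s3 <- if (g$dims[3] > 1) d12 else 0
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- v[base] * (1 - fx) + v[base + s1] * fx
  c10 <- v[base + s2] * (1 - fx) + v[base + s2 + s1] * fx
  c01 <- v[base + s3] * (1 - fx) + v[base + s3 + s1] * fx
  c11 <- v[base + s3 + s2] * (1 - fx) + v[base + s3 + s2 + s1] * fx
  out[ok] <- (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
             (c01 * (1 - fy) + c11 * fy) * fz
  out
}

#' Sample a 1D dose profile through two volumes
#'
#' Trilinearly interpolates the reference and evaluated volumes at uniformly
#' spaced arc-length samples along the segment from `start` to `end`.
#'
#' @param ref,eval reference and evaluated [scalar_volume()]s on compatible
#'   geometries.
#' @param start,end world points (mm).
#' @param step sample spacing along the segment in mm.
#' @return An object of class `dose_profile` with `positions` (arc length,
#'   mm), `ref_values` and `eval_values` (Gy), and the segment endpoints.
#' @export
line_profile <- function(ref, eval, start, end, step = 1) {
  stopifnot(inherits(ref, "scalar_volume"), inherits(eval, "scalar_volume"))
  stop_if_incompatible(ref$geometry, eval$geometry, "profile volumes")
  start <- as.numeric(start); end <- as.numeric(end)
  len <- sqrt(sum((end - start)^2))
  if (len <= 0) stop("start and end must differ")
  positions <- seq(0, len, by = step)
  dirv <- (end - start) / len
  pts <- cbind(start[1] + positions * dirv[1],
               start[2] + positions * dirv[2],
               start[3] + positions * dirv[3])
  rv <- trilinear_sample(ref, pts)
  ev <- trilinear_sample(eval, pts)
  bad <- which(is.na(rv) | is.na(ev))
  if (length(bad))
    stop(sprintf("profile leaves the grid at arc length %.3f mm (sample %d)",
                 positions[bad[1]], bad[1]))
  structure(list(start = start, end = end, step = step, positions = positions,
                 ref_values = rv, eval_values = ev),
            class = "dose_profile")
}

find_peaks <- function(y, positions, min_height, min_sep) {
  n <- length(y)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  cand <- cand[y[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(y[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(positions[i] - positions[kept]) >= min_sep))
      kept <- c(kept, i)
  }
  sort(kept)
}

peak_width_at <- function(positions, y, ipeak, level) {
  # full width of the peak at `level`, linear interpolation of crossings
  if (y[ipeak] < level) return(NA_real_)
  left <- ipeak
  while (left > 1 && y[left - 1] >= level) left <- left - 1
  xl <- if (left == 1) positions[1] else {
    stats::approx(y[c(left - 1, left)], positions[c(left - 1, left)],
                  xout = level)$y
  }
  right <- ipeak
  n <- length(y)
  while (right < n && y[right + 1] >= level) right <- right + 1
  xr <- if (right == n) positions[n] else {
    stats::approx(y[c(right, right + 1)], positions[c(right, right + 1)],
                  xout = level)$y
  }
  xr - xl
}

#' Peak and valley metrics of a dose profile
#'
#' Detects profile peaks (local maxima above 50% of the trace maximum,
#' separated by at least `min_separation`), reports the minimum (valley)
#' between each adjacent pair as a percent of the chosen normalization dose,
#' and the full width of each peak at the prescription dose level.
#'
#' @param profile a `dose_profile` from [line_profile()].
#' @param normalization `"volume_max"` (default; pass `norm_dose` = the
#'   volume maximum), `"profile_max"`, or `"prescription"`.
#' @param norm_dose normalization dose in Gy (required for `"volume_max"`
#'   and `"prescription"`).
#' @param rx_gy optional prescription dose (Gy) at which peak widths are
#'   measured.
#' @param which `"eval"` or `"ref"`: which trace to analyse.
#' @param min_separation minimum peak separation in mm (default 10).
#' @return list with `peaks` (position, height), `valleys` (position,
#'   dose_gy, percent), `norm_dose`, and `widths_mm` when `rx_gy` is given.
#' @export
valley_metrics <- function(profile,
                           normalization = c("volume_max", "profile_max",
                                             "prescription"),
                           norm_dose = NULL, rx_gy = NULL,
                           which = c("eval", "ref"), min_separation = 10) {
  stopifnot(inherits(profile, "dose_profile"))
  normalization <- match.arg(normalization)
  which <- match.arg(which)
  y <- if (which == "eval") profile$eval_values else profile$ref_values
  pos <- profile$positions
  if (normalization == "profile_max") norm_dose <- max(y)
  if (is.null(norm_dose))
    stop("norm_dose is required for this normalization")
  pk <- find_peaks(y, pos, min_height = 0.5 * max(y), min_sep = min_separation)
  if (length(pk) < 2L)
    stop("fewer than two peaks above 50% of the profile maximum: no valley defined")
  valleys <- data.frame(position_mm = numeric(0), dose_gy = numeric(0),
                        percent = numeric(0))
  for (i in seq_len(length(pk) - 1L)) {
    seg <- seq(pk[i], pk[i + 1L])
    j <- seg[which.min(y[seg])]
    valleys <- rbind(valleys,
                     data.frame(position_mm = pos[j], dose_gy = y[j],
                                percent = 100 * y[j] / norm_dose))
  }
  out <- list(peaks = data.frame(position_mm = pos[pk], dose_gy = y[pk]),
              valleys = valleys, norm_dose = norm_dose, trace = which)
  if (!is.null(rx_gy))
    out$widths_mm <- vapply(pk, function(i) peak_width_at(pos, y, i, rx_gy),
                            numeric(1))
  out
}

#' Isodose mask at a dose level
#'
#' @param dose a [scalar_volume()] of dose.
#' @param level dose level in Gy (> 0); voxels with dose >= `level` are set.
#' @return A [structure_mask()].
#' @export
isodose_mask <- function(dose, level) {
  stopifnot(inherits(dose, "scalar_volume"))
  if (!is.numeric(level) || level <= 0) stop("level must be > 0")
  structure_mask(dose$values >= level, dose$geometry,
                 name = sprintf("isodose_%g_Gy", level))
}

#' Label the connected components of a mask (26-connectivity)
#' @param mask a [structure_mask()].
#' @return 3D integer array of component labels (0 = background).
#' @export
label_components <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  array(.label3d_cpp(as.vector(mask$values), mask$geometry$dims),
        dim = mask$geometry$dims)
}

#' Equivalent diameters of per-vertex isodose volumes
#'
#' Labels the connected components (26-connectivity) of the isodose mask at
#' `level`, matches each component to the nearest planned vertex centre
#' (within `max_match_mm`), and reports the equivalent spherical diameter
#' `d = (6 V / pi)^(1/3)` of each matched component, with a mean +/- SD
#' summary.
#'
#' @param dose a [scalar_volume()] of dose.
#' @param level isodose level in Gy.
#' @param vset a [vertex_set()] of planned vertices.
#' @param max_match_mm maximum centroid-to-centre matching distance
#'   (default: half the typical lattice spacing, taken as the vertex
#'   diameter).
#' @return list with `table` (per-vertex data.frame: label, planned centre,
#'   measured centroid, volume, equivalent diameter) and `summary`
#'   (mean, sd, n).
#' @export
equivalent_diameters <- function(dose, level, vset, max_match_mm = NULL) {
  stopifnot(inherits(dose, "scalar_volume"), inherits(vset, "vertex_set"))
  if (nrow(vset$centers) == 0L) stop("vertex set is empty")
  if (is.null(max_match_mm)) max_match_mm <- vset$diameter
  lab <- label_components(isodose_mask(dose, level))
  vv <- voxel_volume_mm3(dose$geometry)
  ncomp <- max(lab)
  comp_centroid <- matrix(NA_real_, ncomp, 3)
  comp_vol <- numeric(ncomp)
  if (ncomp > 0) {
    idx <- which(lab > 0, arr.ind = TRUE)
    labs <- lab[lab > 0]
    w <- index_to_world(dose$geometry, idx - 1)
    for (a in 1:3) comp_centroid[, a] <- tapply(w[, a], labs, mean)
    comp_vol <- as.numeric(tapply(labs, labs, length)) * vv
  }
  centers <- vset$centers
  nv <- nrow(centers)
  # component -> nearest vertex; error if one component claims two vertices
  match_vertex <- rep(NA_integer_, ncomp)
  for (cmp in seq_len(ncomp)) {
    d2 <- colSums((t(centers) - comp_centroid[cmp, ])^2)
    near <- which(sqrt(d2) <= max_match_mm)
    if (length(near) > 1L)
      stop(sprintf("isodose component %d matches %d vertices (merged isodose region?)",
                   cmp, length(near)))
    if (length(near) == 1L) match_vertex[cmp] <- near
  }
  tab <- data.frame(label = seq_len(nv),
                    x_mm = centers[, 1], y_mm = centers[, 2], z_mm = centers[, 3],
                    centroid_x_mm = NA_real_, centroid_y_mm = NA_real_,
                    centroid_z_mm = NA_real_,
                    volume_mm3 = NA_real_, equivalent_diameter_mm = NA_real_)
  for (cmp in which(!is.na(match_vertex))) {
    v <- match_vertex[cmp]
    if (!is.na(tab$volume_mm3[v]))
      stop(sprintf("vertex %d matched by multiple isodose components", v))
    tab$centroid_x_mm[v] <- comp_centroid[cmp, 1]
    tab$centroid_y_mm[v] <- comp_centroid[cmp, 2]
    tab$centroid_z_mm[v] <- comp_centroid[cmp, 3]
    tab$volume_mm3[v] <- comp_vol[cmp]
    tab$equivalent_diameter_mm[v] <- (6 * comp_vol[cmp] / pi)^(1 / 3)
  }
  d <- tab$equivalent_diameter_mm[!is.na(tab$equivalent_diameter_mm)]
  list(table = tab,
       summary = list(mean_mm = mean(d), sd_mm = stats::sd(d), n = length(d)),
       level_gy = level)
}

#' Per-vertex plan-vs-measurement report
#'
#' Combines [equivalent_diameters()] of the planned and measured dose volumes
#' at the prescription level into one table with the normalized difference
#' `|gel - plan| / plan` per vertex.
#'
#' @param plan,gel planned and measured dose [scalar_volume()]s.
#' @param vset planned [vertex_set()].
#' @param level prescription dose level in Gy.
#' @return list with `table`, and `summary` (mean/sd of each diameter column
#'   and of the normalized difference).
#' @export
vertex_report <- function(plan, gel, vset, level) {
  ep <- equivalent_diameters(plan, level, vset)
  eg <- equivalent_diameters(gel, level, vset)
  tab <- data.frame(label = ep$table$label,
                    x_mm = ep$table$x_mm, y_mm = ep$table$y_mm,
                    z_mm = ep$table$z_mm,
                    plan_diameter_mm = ep$table$equivalent_diameter_mm,
                    gel_diameter_mm = eg$table$equivalent_diameter_mm,
                    gel_centroid_x_mm = eg$table$centroid_x_mm,
                    gel_centroid_y_mm = eg$table$centroid_y_mm,
                    gel_centroid_z_mm = eg$table$centroid_z_mm)
  tab$normalized_difference <-
    abs(tab$gel_diameter_mm - tab$plan_diameter_mm) / tab$plan_diameter_mm
  ok <- stats::complete.cases(tab[, c("plan_diameter_mm", "gel_diameter_mm")])
  list(table = tab,
       summary = list(
         plan_mean_mm = mean(tab$plan_diameter_mm[ok]),
         plan_sd_mm = stats::sd(tab$plan_diameter_mm[ok]),
         gel_mean_mm = mean(tab$gel_diameter_mm[ok]),
         gel_sd_mm = stats::sd(tab$gel_diameter_mm[ok]),
         mean_normalized_difference = mean(tab$normalized_difference[ok]),
         n_matched = sum(ok)),
       level_gy = level)
}

#' Gamma-analysis acceptance criteria
#'
#' @param dose_percent dose-difference criterion as % of the normalization
#'   dose.
#' @param dta_mm distance-to-agreement in mm.
#' @param threshold_percent low-dose cutoff as % of the normalization dose
#'   (default 10); reference voxels below it are excluded.
#' @param mode only `"global"` (dose differences normalized to one
#'   volume-wide dose).
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_percent, dta_mm, threshold_percent = 10,
                           mode = "global") {
  if (!identical(mode, "global")) stop("only global gamma mode is implemented")
  if (dose_percent <= 0 || dta_mm <= 0 || threshold_percent <= 0)
    stop("gamma criteria must be strictly positive")
  if (threshold_percent >= 100) stop("threshold_percent must be < 100")
  structure(list(dose_percent = dose_percent, dta_mm = dta_mm,
                 threshold_percent = threshold_percent, mode = mode),
            class = "gamma_criteria")
}

#' 3D global gamma analysis
#'
#' For each evaluated reference voxel `r`, the gamma index is the minimum
#' over search positions `p` of
#' `sqrt(|p - r|^2 / dta^2 + (Deval(p) - Dref(r))^2 / (dd% * Dnorm / 100)^2)`,
#' with the evaluated dose trilinearly interpolated on a sub-voxel grid
#' (`refine` points per voxel per axis) within a ball of radius
#' `ball_factor * dta`. The normalization dose defaults to the reference
#' maximum (global gamma); voxels below `threshold_percent` of it are
#' excluded, as are voxels outside `mask` if one is given.
#'
#' @param ref reference dose [scalar_volume()] (typically the plan).
#' @param eval evaluated dose [scalar_volume()] (typically the gel
#'   measurement).
#' @param criteria a [gamma_criteria()].
#' @param mask optional [structure_mask()] restricting evaluated voxels
#'   (e.g. the gel container).
#' @param norm_dose normalization dose in Gy; default `max(ref)`.
#' @param refine sub-voxel refinement factor (>= 1, default 3).
#' @param ball_factor search-ball radius in units of `dta_mm` (default 3).
#' @return An object of class `gamma_result`: `gamma_map` (3D array, `NA`
#'   where excluded), `pass_percent`, `evaluated_voxel_count`, `criteria`,
#'   `norm_dose`.
#' @export
gamma_3d <- function(ref, eval, criteria, mask = NULL, norm_dose = NULL,
                     refine = 3L, ball_factor = 3) {
  stopifnot(inherits(ref, "scalar_volume"), inherits(eval, "scalar_volume"),
            inherits(criteria, "gamma_criteria"))
  stop_if_incompatible(ref$geometry, eval$geometry, "gamma volumes")
  refmax <- max(ref$values)
  if (refmax <= 0) stop("reference volume has no positive dose")
  if (is.null(norm_dose)) norm_dose <- refmax
  evalmask <- if (is.null(mask)) logical(0) else {
    stop_if_incompatible(ref$geometry, mask$geometry, "gamma mask")
    as.vector(mask$values)
  }
  g <- ref$geometry
  gm <- .gamma3d_cpp(as.vector(ref$values), as.vector(eval$values),
                     g$dims, g$spacing,
                     dose_tol = criteria$dose_percent / 100 * norm_dose,
                     dta = criteria$dta_mm,
                     threshold = criteria$threshold_percent / 100 * norm_dose,
                     evalmask = evalmask,
                     refine = as.integer(refine),
                     ball_mm = ball_factor * criteria$dta_mm)
  gm <- array(gm, dim = g$dims)
  nev <- sum(!is.na(gm))
  structure(list(criteria = criteria,
                 gamma_map = gm,
                 geometry = g,
                 # boundary criterion gamma = 1 counts as a pass; the 1e-9
                 # slack absorbs float rounding in the dose-term quotient
                 pass_percent = if (nev > 0)
                   100 * sum(gm <= 1 + 1e-9, na.rm = TRUE) / nev else NA_real_,
                 evaluated_voxel_count = nev,
                 norm_dose = norm_dose),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm (threshold %g%%): pass %.2f%% of %d voxels\n",
              x$criteria$dose_percent, x$criteria$dta_mm,
              x$criteria$threshold_percent, x$pass_percent,
              x$evaluated_voxel_count))
  invisible(x)
}

#' Gamma pass-rate sweep over a criterion grid
#'
#' Runs [gamma_3d()] for every combination of dose-difference and
#' distance-to-agreement criteria (default: the 12 combinations of
#' 1/2/3/5% and 1/2/3 mm at a 10% threshold).
#'
#' @inheritParams gamma_3d
#' @param dose_percents numeric vector of dose-difference criteria (%).
#' @param dta_mms numeric vector of distance-to-agreement criteria (mm).
#' @param threshold_percent low-dose cutoff (% of normalization dose).
#' @return data.frame with columns `dose_percent`, `dta_mm`, `pass_percent`,
#'   `evaluated_voxel_count`.
#' @export
gamma_sweep <- function(ref, eval, dose_percents = c(1, 2, 3, 5),
                        dta_mms = c(1, 2, 3), threshold_percent = 10,
                        mask = NULL, norm_dose = NULL, refine = 3L,
                        ball_factor = 3) {
  grid <- expand.grid(dose_percent = dose_percents, dta_mm = dta_mms)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    gr <- gamma_3d(ref, eval,
                   gamma_criteria(grid$dose_percent[i], grid$dta_mm[i],
                                  threshold_percent),
                   mask = mask, norm_dose = norm_dose, refine = refine,
                   ball_factor = ball_factor)
    data.frame(dose_percent = grid$dose_percent[i], dta_mm = grid$dta_mm[i],
               pass_percent = gr$pass_percent,
               evaluated_voxel_count = gr$evaluated_voxel_count)
  })
  do.call(rbind, res)
}
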