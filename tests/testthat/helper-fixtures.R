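# Shared fixtures and independent oracles, built in code at test time.

# canonical 1 mm grid holding the 575.7 cm^3 cylindrical surrogate GTV
canonical_grid_1mm <- function() {
  volume_geometry(c(-47.5, -47.5, -47.5), c(1, 1, 1), c(96, 96, 96))
}

# coarse 2 mm grid for end-to-end pipeline fixtures
closure_grid_2mm <- function() {
  volume_geometry(c(-51, -51, -51), c(2, 2, 2), c(52, 52, 52))
}

small_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         quantity = "cbct_number") {
  g <- volume_geometry(origin, spacing, dim(values))
  scalar_volume(values, g, quantity = quantity)
}

# memoised canonical closure fixture: 19-vertex lattice, plan dose, and the
# full simulated readout on the 2 mm grid
.fixture_env <- new.env(parent = emptyenv())
closure_fixture <- function(seed = 1, noise_sd = 0.6) {
  key <- sprintf("closure_%d_%g", seed, noise_sd)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  g <- closure_grid_2mm()
  phantom <- make_cylinder_mask(phantom_spec(45, 90.5, g))
  vset <- place_vertices(phantom, lattice_spec("hexagonal", 15, 30))
  plan <- make_plan_dose(vset, grid = g)
  sim <- simulate_cbct_pair(plan, phantom,
                            gel_sim_config(noise_sd = noise_sd, seed = seed))
  fx <- list(grid = g, phantom = phantom, vset = vset, plan = plan, sim = sim)
  .fixture_env[[key]] <- fx
  fx
}

# run the full readout chain on a simulated scan pair -> calibrated dose
run_readout <- function(fx) {
  delta <- subtract_background(average_volumes(fx$sim$post_scans),
                               average_volumes(fx$sim$pre_scans))
  delta <- adaptive_mean_filter(delta, 3)
  delta <- remove_remnant_artifacts(delta, 7)
  k <- select_calibration_slice(fx$plan)
  curve <- fit_calibration(delta$values[, , k], fx$plan$values[, , k],
                           mask = fx$phantom$values[, , k])
  list(gel = apply_calibration(delta, curve), curve = curve, delta = delta)
}

# --- independent oracles -------------------------------------------------

# plain-R vectorized trilinear interpolation (independent of the package's
# samplers); idx is an n x 3 matrix of continuous 0-based voxel indices
oracle_trilinear <- function(values, idx) {
  dims <- dim(values)
  out <- rep(NA_real_, nrow(idx))
  ok <- idx[, 1] >= 0 & idx[, 1] <= dims[1] - 1 &
        idx[, 2] >= 0 & idx[, 2] <= dims[2] - 1 &
        idx[, 3] >= 0 & idx[, 3] <= dims[3] - 1
  if (!any(ok)) return(out)
  p <- idx[ok, , drop = FALSE]
  i0 <- floor(p)
  for (a in 1:3) i0[, a] <- pmin(pmax(i0[, a], 0), max(dims[a] - 2, 0))
  f <- p - i0
  at <- function(dx, dy, dz)
    values[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)]
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) f[, 1] else 1 - f[, 1]) *
          (if (dy) f[, 2] else 1 - f[, 2]) *
          (if (dz) f[, 3] else 1 - f[, 3])
    acc <- acc + wt * at(dx, dy, dz)
  }
  out[ok] <- acc
  out
}

# exhaustive brute-force global gamma at refinement 8 without a search-ball
# cap: the per-voxel radius dta * gamma0 is an exact bound, because beyond
# it the spatial term alone already exceeds the no-shift gamma.
oracle_gamma <- function(ref, evalv, spacing, dose_tol, dta, threshold,
                         refine = 8) {
  dims <- dim(ref)
  gamma0 <- abs(evalv - ref) / dose_tol
  maxR <- dta * max(gamma0)
  steps <- lapply(1:3, function(a) {
    m <- ceiling(maxR * refine / spacing[a])
    (-m:m) * spacing[a] / refine
  })
  offs <- as.matrix(expand.grid(steps[[1]], steps[[2]], steps[[3]]))
  d2 <- rowSums(offs^2)
  keep <- d2 <= maxR^2 + 1e-12
  offs <- offs[keep, , drop = FALSE]
  d2 <- d2[keep]
  ord <- order(d2)
  offs_idx <- sweep(offs[ord, , drop = FALSE], 2, spacing, "/")
  d2 <- d2[ord]
  out <- array(NA_real_, dims)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) for (i in seq_len(dims[1])) {
    dr <- ref[i, j, k]
    if (dr < threshold) next
    g0 <- gamma0[i, j, k]
    n_use <- findInterval((dta * g0)^2 + 1e-12, d2)
    best2 <- g0^2
    if (n_use > 0) {
      pts <- sweep(offs_idx[seq_len(n_use), , drop = FALSE], 2,
                   c(i - 1, j - 1, k - 1), "+")
      de <- oracle_trilinear(evalv, pts)
      g2 <- d2[seq_len(n_use)] / dta^2 + (de - dr)^2 / dose_tol^2
      best2 <- min(best2, g2, na.rm = TRUE)
    }
    out[i, j, k] <- sqrt(best2)
  }
  out
}

# smooth random field: sum of a few seeded Gaussian bumps
smooth_field <- function(dims, spacing, n_bumps = 6, amp = 20, seed = 1) {
  set.seed(seed)
  xs <- (seq_len(dims[1]) - 1) * spacing[1]
  ys <- (seq_len(dims[2]) - 1) * spacing[2]
  zs <- (seq_len(dims[3]) - 1) * spacing[3]
  ext <- (dims - 1) * spacing
  out <- array(0, dims)
  for (b in seq_len(n_bumps)) {
    c3 <- stats::runif(3, 0.2, 0.8) * ext
    w <- stats::runif(1, 0.15, 0.35) * max(ext)
    a <- stats::runif(1, 0.4, 1) * amp
    gx <- exp(-((xs - c3[1])^2) / (2 * w^2))
    gy <- exp(-((ys - c3[2])^2) / (2 * w^2))
    gz <- exp(-((zs - c3[3])^2) / (2 * w^2))
    out <- out + a * outer(outer(gx, gy), gz)
  }
  out
}
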