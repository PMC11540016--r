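#' Filter configuration for the gel readout chain
#'
#' @param mean_window odd in-plane window (voxels) of the adaptive mean
#'   filter (default 3, i.e. 3 x 3 pixels per axial slice).
#' @param artefact_span odd moving-mean span (radial samples) of the remnant
#'   artefact removal (default 7).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(mean_window = 3L, artefact_span = 7L) {
  check_odd <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || x < 1 || x %% 2 != 1)
      stop(sprintf("%s must be an odd integer >= 1", what))
    as.integer(x)
  }
  structure(list(mean_window = check_odd(mean_window, "mean_window"),
                 artefact_span = check_odd(artefact_span, "artefact_span")),
            class = "filter_config")
}

## integral-image box sums with border clipping (window w odd)
boxsum2d <- function(m, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  I <- matrix(0, nr + 1L, nc + 1L)
  I[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  r0 <- pmax(seq_len(nr) - h, 1L); r1 <- pmin(seq_len(nr) + h, nr)
  c0 <- pmax(seq_len(nc) - h, 1L); c1 <- pmin(seq_len(nc) + h, nc)
  I[cbind(rep(r1 + 1L, nc), rep(c1 + 1L, each = nr))] -
    I[cbind(rep(r0, nc), rep(c1 + 1L, each = nr))] -
    I[cbind(rep(r1 + 1L, nc), rep(c0, each = nr))] +
    I[cbind(rep(r0, nc), rep(c0, each = nr))]
}

#' Adaptive mean (local Wiener) filtering of a CBCT-difference volume
#'
#' Noise-adaptive smoothing applied per axial slice: with local window mean
#' `mu` and variance `v`, and `nu2` the slice-wide mean local variance (the
#' noise-power estimate), the output is
#' `mu + max(v - nu2, 0) / max(v, nu2) * (x - mu)`. Flat regions collapse to
#' the local mean while strong local structure (variance well above the noise
#' floor) is preserved.
#'
#' @param vol a [scalar_volume()] with quantity `"delta_cbct"`.
#' @param window odd in-plane window size in voxels (default 3).
#' @return Filtered [scalar_volume()], same geometry and quantity.
#' @export
adaptive_mean_filter <- function(vol, window = 3L) {
  stopifnot(inherits(vol, "scalar_volume"))
  if (vol$quantity != "delta_cbct")
    stop("adaptive_mean_filter expects a delta_cbct volume")
  if (window %% 2 != 1 || window < 1)
    stop("window must be an odd integer >= 1")
  out <- vol$values
  nr <- dim(out)[1]; nc <- dim(out)[2]
  counts <- boxsum2d(matrix(1, nr, nc), window)
  for (k in seq_len(dim(out)[3])) {
    x <- out[, , k]
    s1 <- boxsum2d(x, window)
    s2 <- boxsum2d(x * x, window)
    mu <- s1 / counts
    v <- pmax(s2 / counts - mu * mu, 0)
    nu2 <- mean(v)
    gain <- if (nu2 == 0 && all(v == 0)) 0 else pmax(v - nu2, 0) / pmax(v, nu2)
    out[, , k] <- mu + gain * (x - mu)
  }
  scalar_volume(out, vol$geometry, quantity = vol$quantity)
}

bilinear_slice <- function(x, xi, yi) {
  # xi, yi: continuous 1-based matrix coordinates (vectors)
  n1 <- nrow(x); n2 <- ncol(x)
  i0 <- pmin(pmax(floor(xi), 1), n1 - 1)
  j0 <- pmin(pmax(floor(yi), 1), n2 - 1)
  fx <- xi - i0; fy <- yi - j0
  x[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    x[cbind(i0 + 1, j0)] * fx * (1 - fy) +
    x[cbind(i0, j0 + 1)] * (1 - fx) * fy +
    x[cbind(i0 + 1, j0 + 1)] * fx * fy
}

#' Remove remnant ring artefacts from a CBCT-difference volume
#'
#' Ring and cupping residuals that survive background subtraction are
#' azimuthally symmetric about the scanner axis and narrow in radius. Per
#' axial slice, the slice is resampled on polar rings about `axis_center`
#' (radial step = in-plane voxel size) and a low angular quantile (35th
#' percentile) of each ring gives the radial profile — for an azimuthally
#' symmetric remnant every angular quantile equals the remnant value, while
#' a low quantile stays on the valley floor even where lattice spheres cover
#' nearly half of a ring. The remnant is the rapidly varying component of
#' that profile — its residual above a running-median baseline over `span`
#' radial samples, iterated to convergence — and is subtracted at each
#' pixel's exact radius (after removing its own slice mean, so the slice
#' mean is preserved). The median baseline follows broad radial structure,
#' monotone ramps and steps (genuine dose response, the container wall)
#' exactly, so only narrow rings land in the remnant and are removed.
#'
#' @param vol a [scalar_volume()] with quantity `"delta_cbct"`.
#' @param span odd moving-mean span in radial samples (default 7).
#' @param axis_center world (x, y) of the symmetry axis in mm; default the
#'   in-plane centre of the grid.
#' @return Corrected [scalar_volume()].
#' @export
remove_remnant_artifacts <- function(vol, span = 7L, axis_center = NULL) {
  stopifnot(inherits(vol, "scalar_volume"))
  if (vol$quantity != "delta_cbct")
    stop("remove_remnant_artifacts expects a delta_cbct volume")
  if (span %% 2 != 1 || span < 1) stop("span must be an odd integer >= 1")
  g <- vol$geometry
  if (is.null(axis_center)) {
    ctr <- g$origin + (g$dims - 1) / 2 * g$spacing
    axis_center <- ctr[1:2]
  }
  xs <- axis_coords(g, 1) - axis_center[1]
  ys <- axis_coords(g, 2) - axis_center[2]
  rr <- sqrt(outer(xs^2, ys^2, "+"))
  dr <- min(g$spacing[1:2])
  nbins <- ceiling(max(rr) / dr)
  if (span > nbins)
    stop(sprintf("span (%d) exceeds the radial sample count (%d)", span, nbins))
  bin_r <- (seq_len(nbins) - 0.5) * dr
  # polar ring sample positions (continuous 1-based matrix coordinates)
  rings <- lapply(bin_r, function(r) {
    nth <- max(8L, ceiling(2 * pi * r / (dr / 2)))
    th <- (seq_len(nth) - 1) * 2 * pi / nth
    xi <- (axis_center[1] + r * cos(th) - g$origin[1]) / g$spacing[1] + 1
    yi <- (axis_center[2] + r * sin(th) - g$origin[2]) / g$spacing[2] + 1
    ok <- xi >= 1 & xi <= g$dims[1] & yi >= 1 & yi <= g$dims[2]
    if (sum(ok) < 4) NULL else cbind(xi[ok], yi[ok])
  })
  out <- vol$values
  for (k in seq_len(g$dims[3])) {
    x <- out[, , k]
    # a low angular quantile estimates the (angle-constant) remnant exactly
    # while tolerating lattice spheres that cover up to ~65% of a ring
    prof <- vapply(rings, function(ring) {
      if (is.null(ring)) NA_real_
      else stats::quantile(bilinear_slice(x, ring[, 1], ring[, 2]), 0.35,
                           names = FALSE)
    }, numeric(1))
    filled <- which(!is.na(prof))
    if (length(filled) < span) next
    prof_f <- stats::approx(bin_r[filled], prof[filled], xout = bin_r,
                            rule = 2)$y
    # iterated high-pass against a running-median baseline: the baseline
    # follows broad dose structure and steps (e.g. the container wall)
    # exactly, so only narrow rings accumulate into the remnant; iteration
    # recovers the ring fraction the median leaks into the baseline.
    # The profile is mirrored about r = 0 so that a genuine on-axis dose cap
    # is seen as a broad symmetric bump, not a narrow (removable) feature.
    h <- (span - 1L) %/% 2L
    ext <- c(rev(prof_f[seq_len(min(h, nbins))]), prof_f,
             rep(prof_f[nbins], h))
    rem_ext <- rep(0, length(ext))
    for (it in 1:4) {
      resid <- ext - rem_ext
      rem_ext <- rem_ext +
        (resid - stats::runmed(resid, span, endrule = "median"))
    }
    remnant_prof <- rem_ext[min(h, nbins) + seq_len(nbins)]
    # clamp to the knot range: spline extrapolation would amplify the
    # remnant at the axis pixel and beyond the outermost ring
    rq <- pmin(pmax(as.vector(rr), bin_r[1]), bin_r[nbins])
    remnant <- matrix(stats::spline(bin_r, remnant_prof, xout = rq)$y,
                      nrow = nrow(x))
    out[, , k] <- x - (remnant - mean(remnant))
  }
  scalar_volume(out, g, quantity = vol$quantity)
}

#' Tanh dose-response calibration curve
#'
#' The gel's CBCT-number change as a function of dose is modelled as
#' `deltaN = alpha + beta * tanh(gamma * D - phi)`: `alpha` is a CBCT-number
#' offset, `beta` a CBCT-number amplitude (> 0), `gamma` a rate in 1/Gy
#' (> 0) and `phi` a dimensionless shift. The forward curve is strictly
#' increasing in dose.
#'
#' @param alpha,beta,gamma_,phi curve parameters (see above).
#' @param param_cov optional 4 x 4 covariance matrix of the fit.
#' @param rmse residual CBCT-number RMSE of the fit (>= 0).
#' @param dose_range (min, max) dose in Gy seen during fitting.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(alpha, beta, gamma_, phi, param_cov = NULL,
                              rmse = NA_real_, dose_range = NULL) {
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0")
  if (!is.numeric(gamma_) || gamma_ <= 0) stop("gamma_ must be > 0")
  if (!is.na(rmse) && rmse < 0) stop("rmse must be >= 0")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma_ = as.numeric(gamma_), phi = as.numeric(phi),
                 param_cov = param_cov, rmse = as.numeric(rmse),
                 dose_range = dose_range),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(paste0("<calibration_curve> deltaN = %.4g + %.4g * ",
                     "tanh(%.4g * D - %.4g); rmse %.4g\n"),
              x$alpha, x$beta, x$gamma_, x$phi, x$rmse))
  invisible(x)
}

#' Forward dose-response curve
#' @param curve a [calibration_curve()].
#' @param dose_gy dose values in Gy.
#' @return Predicted CBCT-number change.
#' @export
cal_forward <- function(curve, dose_gy) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$alpha + curve$beta * tanh(curve$gamma_ * dose_gy - curve$phi)
}

#' Fit the tanh dose-response curve pixel-by-pixel on a slice
#'
#' Self-calibration: every in-slice pixel provides a (planned dose,
#' CBCT-number change) pair and the four curve parameters are estimated by
#' nonlinear least squares (Levenberg-Marquardt). The calibration slice
#' should span the full dose range; a dose span below half the maximum dose
#' triggers a conditioning warning.
#'
#' @param delta_slice 2D matrix of CBCT-number changes.
#' @param dose_slice congruent 2D matrix of planned dose (Gy).
#' @param mask optional congruent logical matrix restricting the fit (e.g.
#'   to gel pixels, excluding container walls).
#' @return A [calibration_curve()] with parameter covariance and RMSE.
#' @export
fit_calibration <- function(delta_slice, dose_slice, mask = NULL) {
  delta_slice <- as.matrix(delta_slice)
  dose_slice <- as.matrix(dose_slice)
  if (!all(dim(delta_slice) == dim(dose_slice)))
    stop("delta_slice and dose_slice must be congruent")
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(delta_slice)))
      stop("mask must be congruent with the slices")
    d <- dose_slice[mask]; y <- delta_slice[mask]
  } else {
    d <- as.vector(dose_slice); y <- as.vector(delta_slice)
  }
  ok <- is.finite(d) & is.finite(y)
  d <- d[ok]; y <- y[ok]
  if (length(d) < 8L) stop("too few pixels to fit the calibration curve")
  rng <- range(d)
  span <- diff(rng)
  if (span <= 0) stop("degenerate design: the dose slice has no dose span")
  if (span < 0.5 * rng[2])
    warning(sprintf(paste0("dose span (%.3g Gy) is below half the maximum ",
                           "dose (%.3g Gy); the fit may be poorly conditioned"),
                    span, rng[2]))
  # Deterministic multi-start Levenberg-Marquardt. The response amplitude is
  # bounded (beta <= 5x the observed response range) to exclude the
  # degenerate beta -> Inf, gamma -> 0 quasi-linear solution that can trap
  # the fit when the dose histogram is bimodal (valley floor + peaks).
  yr <- diff(range(y))
  if (yr <= 0) stop("degenerate design: the response slice is constant")
  alpha0 <- (min(y) + max(y)) / 2
  beta0 <- max(0.8 * yr, 1e-6)
  starts <- list()
  for (g0 in c(1, 2, 4) / span)
    for (qm in c(0.25, 0.5, 0.75))
      starts[[length(starts) + 1L]] <-
        list(alpha = alpha0, beta = beta0, gamma = g0,
             phi = g0 * (rng[1] + qm * span))
  lower <- c(alpha = -Inf, beta = 1e-9, gamma = 1e-9, phi = -Inf)
  upper <- c(alpha = Inf, beta = 5 * yr, gamma = 50 / span, phi = Inf)
  fit <- NULL
  best_sse <- Inf
  msgs <- character(0)
  for (start in starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(y ~ alpha + beta * tanh(gamma * d - phi),
                        start = start, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        msgs <<- c(msgs, conditionMessage(e))
        NULL
      })
    if (!is.null(cand)) {
      sse <- sum(stats::resid(cand)^2)
      if (sse < best_sse) {
        best_sse <- sse
        fit <- cand
      }
    }
  }
  if (is.null(fit))
    stop(sprintf("calibration fit failed to converge: %s [n = %d, dose range %.3g-%.3g Gy]",
                 paste(unique(msgs), collapse = "; "), length(d), rng[1], rng[2]))
  cf <- stats::coef(fit)
  cv <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  rmse <- sqrt(mean(stats::resid(fit)^2))
  calibration_curve(cf[["alpha"]], cf[["beta"]], cf[["gamma"]], cf[["phi"]],
                    param_cov = cv, rmse = rmse, dose_range = rng)
}

#' Pick the self-calibration slice
#'
#' Returns the axial slice index (1-based) whose planned-dose range is
#' maximal — the slice containing the entire span of dose values.
#'
#' @param plan_dose a [scalar_volume()] of planned dose.
#' @return integer slice index.
#' @export
select_calibration_slice <- function(plan_dose) {
  stopifnot(inherits(plan_dose, "scalar_volume"))
  spans <- apply(plan_dose$values, 3, function(m) diff(range(m)))
  which.max(spans)
}

#' Invert the calibration curve over a volume
#'
#' Maps CBCT-number change to dose:
#' `D = (atanh(clamp((deltaN - alpha) / beta, -1 + eps, 1 - eps)) + phi) / gamma`,
#' then clamps negative doses to zero. The fractions of saturation-clamped
#' and negativity-clamped voxels are attached as attributes
#' `"clamped_fraction"` and `"negative_fraction"`.
#'
#' @param vol a [scalar_volume()] with quantity `"delta_cbct"`.
#' @param curve a [calibration_curve()].
#' @param eps saturation clamp inside the atanh domain (default 1e-6).
#' @return A [scalar_volume()] with quantity `"dose_Gy"`.
#' @export
apply_calibration <- function(vol, curve, eps = 1e-6) {
  stopifnot(inherits(vol, "scalar_volume"), inherits(curve, "calibration_curve"))
  if (vol$quantity != "delta_cbct")
    stop("apply_calibration expects a delta_cbct volume")
  if (curve$beta <= 0) stop("curve with beta <= 0 is invalid")
  u <- (vol$values - curve$alpha) / curve$beta
  n_clamp <- sum(u <= -1 + eps | u >= 1 - eps)
  u <- pmin(pmax(u, -1 + eps), 1 - eps)
  d <- (atanh(u) + curve$phi) / curve$gamma_
  n_neg <- sum(d < 0)
  d <- pmax(d, 0)
  out <- scalar_volume(d, vol$geometry, quantity = "dose_Gy")
  attr(out, "clamped_fraction") <- n_clamp / length(u)
  attr(out, "negative_fraction") <- n_neg / length(u)
  out
}

#' Read/write a calibration curve as JSON
#' @param curve a [calibration_curve()].
#' @param path file path.
#' @return `path` (writer, invisibly) or a [calibration_curve()] (reader).
#' @export
write_calibration_json <- function(curve, path) {
  obj <- list(alpha = curve$alpha, beta = curve$beta, gamma = curve$gamma_,
              phi = curve$phi, rmse = curve$rmse,
              dose_range_gy = curve$dose_range,
              param_cov = curve$param_cov,
              software = paste0("latticeqa ",
                                as.character(utils::packageVersion("latticeqa"))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cov <- obj$param_cov
  if (!is.null(cov)) cov <- matrix(unlist(cov), 4, 4)
  calibration_curve(obj$alpha, obj$beta, obj$gamma, obj$phi,
                    param_cov = cov, rmse = obj$rmse %||% NA_real_,
                    dose_range = obj$dose_range_gy)
}
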