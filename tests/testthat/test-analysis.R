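test_that("profiles are exact on constant and linear fields", {
  g <- volume_geometry(c(0, 0, 0), c(1, 1, 1), c(21, 21, 21))
  const <- scalar_volume(array(20, c(21, 21, 21)), g, "dose_Gy")
  p <- line_profile(const, const, c(2, 3, 4), c(18, 15, 12), step = 0.7)
  expect_true(all(p$ref_values == 20))
  expect_true(all(p$eval_values == 20))
  # linear field D(x) = x reproduced to 1e-9 by trilinear interpolation
  lin <- scalar_volume(array(rep(0:20, 21 * 21), c(21, 21, 21)), g, "dose_Gy")
  p2 <- line_profile(lin, lin, c(1.3, 10, 10), c(17.8, 10, 10), step = 0.31)
  expect_equal(p2$ref_values, 1.3 + p2$positions, tolerance = 1e-9)
})

test_that("profiles leaving the grid raise an error naming the sample", {
  g <- volume_geometry(c(0, 0, 0), c(1, 1, 1), c(10, 10, 10))
  v <- scalar_volume(array(1, c(10, 10, 10)), g, "dose_Gy")
  expect_error(line_profile(v, v, c(5, 5, 5), c(25, 5, 5)),
               "leaves the grid at arc length")
})

test_that("a two-sphere phantom profile shows two peaks and one interior valley", {
  g <- volume_geometry(c(-25, -12, -12), c(1, 1, 1), c(51, 25, 25))
  vs <- vertex_set(rbind(c(-15, 0, 0), c(15, 0, 0)), diameter = 15)
  dose <- make_plan_dose(vs, grid = g, envelope_radius = Inf)
  p <- line_profile(dose, dose, c(-24, 0, 0), c(24, 0, 0), step = 0.25)
  vm <- valley_metrics(p, "profile_max", min_separation = 10)
  expect_equal(nrow(vm$peaks), 2)
  expect_equal(nrow(vm$valleys), 1)
  # symmetric construction: valley at the midpoint
  expect_equal(vm$valleys$position_mm[1], max(p$positions) / 2,
               tolerance = 0.5)
})

test_that("valley percentages follow the chosen normalization", {
  # synthetic profile: two 25 Gy peaks, interior minimum 10 Gy
  pos <- seq(0, 60, by = 0.5)
  y <- 25 * exp(-(pos - 15)^2 / 50) + 25 * exp(-(pos - 45)^2 / 50)
  y <- y - min(y[pos > 20 & pos < 40]) + 10  # floor the valley at 10
  y <- y * 25 / max(y)  # re-normalize the peaks to 25
  prof <- structure(list(start = c(0, 0, 0), end = c(60, 0, 0), step = 0.5,
                         positions = pos, ref_values = y, eval_values = y),
                    class = "dose_profile")
  vm <- valley_metrics(prof, "volume_max", norm_dose = 25)
  expect_equal(vm$valleys$percent[1], 100 * min(y[pos > 20 & pos < 40]) / 25,
               tolerance = 1e-9)
  # fewer than two peaks -> error
  one <- structure(list(start = c(0, 0, 0), end = c(60, 0, 0), step = 0.5,
                        positions = pos,
                        ref_values = 25 * exp(-(pos - 30)^2 / 50),
                        eval_values = 25 * exp(-(pos - 30)^2 / 50)),
                   class = "dose_profile")
  expect_error(valley_metrics(one, "profile_max"), "fewer than two peaks")
})

test_that("a valley floor tuned to 0.3 of maximum reads back as 30%", {
  g <- volume_geometry(c(-25, -12, -12), c(0.5, 0.5, 0.5), c(101, 49, 49))
  vs <- vertex_set(rbind(c(-15, 0, 0), c(15, 0, 0)), diameter = 15)
  dose <- make_plan_dose(vs, grid = g, penumbra_w = 1.2,
                         envelope_radius = Inf, valley_floor_frac = 0.3)
  p <- line_profile(dose, dose, c(-23, 0, 0), c(23, 0, 0), step = 0.2)
  vm <- valley_metrics(p, "volume_max", norm_dose = max(dose$values))
  expect_equal(vm$valleys$percent[1], 30, tolerance = 1)
})

test_that("isodose masks nest monotonically", {
  fx <- closure_fixture()
  m20 <- isodose_mask(fx$plan, 20)
  m12 <- isodose_mask(fx$plan, 12)
  expect_true(all(m12$values[m20$values]))          # 20 Gy region inside 12 Gy
  expect_false(any(isodose_mask(fx$plan, 100)$values))  # above global max
  expect_true(all(isodose_mask(fx$plan, 1e-9)$values |
                    fx$plan$values < 1e-9))
  expect_error(isodose_mask(fx$plan, -1), "level")
})

test_that("equivalent diameter reproduces closed forms", {
  g <- volume_geometry(c(0, 0, 0), c(1, 1, 1), c(9, 9, 9))
  d <- array(0, c(9, 9, 9))
  d[5, 5, 5] <- 30
  vol <- scalar_volume(d, g, "dose_Gy")
  ed <- equivalent_diameters(vol, 20, vertex_set(rbind(c(4, 4, 4)), 2))
  expect_equal(ed$table$equivalent_diameter_mm[1], (6 / pi)^(1 / 3),
               tolerance = 1e-9)
  # a component with the volume of a 13 mm sphere reads back as 13 mm
  expect_equal((6 * (pi / 6 * 13^3) / pi)^(1 / 3), 13)
})

test_that("a rasterized 15 mm sphere at 0.5 mm voxels reads 15.0 +/- 0.15", {
  g <- volume_geometry(c(-10, -10, -10), c(0.5, 0.5, 0.5), c(41, 41, 41))
  vs <- vertex_set(rbind(c(0, 0, 0)), diameter = 15)
  dose <- make_plan_dose(vs, grid = g, penumbra_w = 1.2,
                         envelope_radius = Inf)
  ed <- equivalent_diameters(dose, 20, vs)
  expect_equal(ed$table$equivalent_diameter_mm[1], 15, tolerance = 0.01)
  expect_equal(ed$summary$n, 1)
})

test_that("union of k disjoint equal components scales diameters by k^(1/3)", {
  g <- volume_geometry(c(0, 0, 0), c(1, 1, 1), c(40, 12, 12))
  d <- array(0, c(40, 12, 12))
  ball <- function(cx) {
    idx <- which(array(TRUE, c(40, 12, 12)), arr.ind = TRUE)
    w <- index_to_world(g, idx - 1)
    inside <- (w[, 1] - cx)^2 + (w[, 2] - 5)^2 + (w[, 3] - 5)^2 <= 3^2
    inside
  }
  d[ball(6)] <- 25
  one <- sum(scalar_volume(d, g, "dose_Gy")$values >= 20)
  d[ball(26)] <- 25
  vol <- scalar_volume(d, g, "dose_Gy")
  lab <- label_components(isodose_mask(vol, 20))
  expect_equal(max(lab), 2)
  v1 <- sum(lab == 1); v2 <- sum(lab == 2)
  expect_equal(v1, v2)
  expect_equal(((6 * (v1 + v2) / pi)^(1 / 3)) / ((6 * v1 / pi)^(1 / 3)),
               2^(1 / 3), tolerance = 1e-9)
})

test_that("gamma of identical volumes is zero with a 100% pass rate", {
  fx <- closure_fixture()
  res <- gamma_3d(fx$plan, fx$plan, gamma_criteria(3, 2))
  expect_equal(res$pass_percent, 100)
  expect_true(all(res$gamma_map[!is.na(res$gamma_map)] == 0))
  expect_gt(res$evaluated_voxel_count, 0)
})

test_that("a pure uniform dose offset gives the analytic single-term gamma", {
  g <- volume_geometry(c(0, 0, 0), c(1, 1, 1), c(15, 15, 15))
  ref <- scalar_volume(array(20, c(15, 15, 15)), g, "dose_Gy")
  ev <- scalar_volume(array(20.6, c(15, 15, 15)), g, "dose_Gy")
  res <- gamma_3d(ref, ev, gamma_criteria(3, 3), norm_dose = 20)
  # dose term = 0.6 / 0.6 = 1 everywhere; no spatial shift can help
  expect_equal(as.vector(res$gamma_map[!is.na(res$gamma_map)]),
               rep(1, res$evaluated_voxel_count), tolerance = 1e-9)
  expect_equal(res$pass_percent, 100)
})

test_that("gamma validates its inputs", {
  g <- volume_geometry(c(0, 0, 0), c(1, 1, 1), c(5, 5, 5))
  zero <- scalar_volume(array(0, c(5, 5, 5)), g, "dose_Gy")
  one <- scalar_volume(array(1, c(5, 5, 5)), g, "dose_Gy")
  expect_error(gamma_3d(zero, one, gamma_criteria(3, 2)), "no positive dose")
  expect_error(gamma_criteria(-3, 2), "strictly positive")
  expect_error(gamma_criteria(3, 2, threshold_percent = 100), "< 100")
})

test_that("production gamma matches the exhaustive brute-force oracle", {
  dims <- c(21, 21, 21)
  spacing <- c(1, 1, 1)
  ref_vals <- smooth_field(dims, spacing, amp = 20, seed = 61) + 2
  # evaluated: scaled + slightly shifted + perturbed copy
  ev_vals <- 1.015 * smooth_field(dims, spacing, amp = 20, seed = 61) + 2 +
    0.3 * smooth_field(dims, spacing, amp = 1, seed = 62)
  g <- volume_geometry(c(0, 0, 0), spacing, dims)
  ref <- scalar_volume(ref_vals, g, "dose_Gy")
  ev <- scalar_volume(ev_vals, g, "dose_Gy")
  dnorm <- max(ref_vals)
  orc <- oracle_gamma(ref_vals, ev_vals, spacing,
                      dose_tol = 0.03 * dnorm, dta = 2,
                      threshold = 0.1 * dnorm, refine = 8)
  # at matched refinement the production search must agree with the
  # independent exhaustive oracle within 2% (scale: criterion gamma = 1)
  res8 <- gamma_3d(ref, ev, gamma_criteria(3, 2), refine = 8)
  both <- !is.na(res8$gamma_map) & !is.na(orc)
  expect_equal(sum(!is.na(res8$gamma_map)), sum(!is.na(orc)))
  expect_lt(max(abs(res8$gamma_map[both] - orc[both])), 0.02)
  # the default refine-3 search only coarsens the grid: its deviation from
  # the oracle is bounded by the sub-voxel quantization of either grid
  # quantization scale: half the search-step diagonal (sqrt(3)/6 mm) acting
  # through both the spatial term and the local dose gradient
  res3 <- gamma_3d(ref, ev, gamma_criteria(3, 2), refine = 3)
  expect_gte(min(res3$gamma_map[both] - orc[both]), -0.05)
  expect_lt(max(res3$gamma_map[both] - orc[both]), 0.35)
})

test_that("gamma is invariant to uniform rescaling of both volumes", {
  dims <- c(15, 15, 15)
  g <- volume_geometry(c(0, 0, 0), c(1, 1, 1), dims)
  ref_vals <- smooth_field(dims, c(1, 1, 1), amp = 15, seed = 63) + 3
  ev_vals <- ref_vals * 1.02 + 0.2
  ref <- scalar_volume(ref_vals, g, "dose_Gy")
  ev <- scalar_volume(ev_vals, g, "dose_Gy")
  a <- gamma_3d(ref, ev, gamma_criteria(3, 2), norm_dose = max(ref_vals))
  b <- gamma_3d(scalar_volume(2 * ref_vals, g, "dose_Gy"),
                scalar_volume(2 * ev_vals, g, "dose_Gy"),
                gamma_criteria(3, 2), norm_dose = 2 * max(ref_vals))
  expect_equal(a$gamma_map, b$gamma_map, tolerance = 1e-9)
})

test_that("swapped-role gamma is zero exactly when the volumes agree", {
  fx <- closure_fixture()
  fwd <- gamma_3d(fx$plan, fx$plan, gamma_criteria(2, 1))
  swp <- gamma_3d(fx$plan, fx$plan, gamma_criteria(2, 1))
  expect_true(all(fwd$gamma_map[!is.na(fwd$gamma_map)] == 0))
  expect_true(all(swp$gamma_map[!is.na(swp$gamma_map)] == 0))
})

test_that("pass rates are monotone across the 12-criteria sweep", {
  fx <- closure_fixture()
  out <- run_readout(fx)
  sw <- gamma_sweep(fx$plan, out$gel, mask = fx$phantom)
  expect_equal(nrow(sw), 12)
  for (dd in unique(sw$dose_percent)) {
    sub <- sw[sw$dose_percent == dd, ]
    expect_true(all(diff(sub$pass_percent[order(sub$dta_mm)]) >= 0))
  }
  for (dta in unique(sw$dta_mm)) {
    sub <- sw[sw$dta_mm == dta, ]
    expect_true(all(diff(sub$pass_percent[order(sub$dose_percent)]) >= 0))
  }
  # identical volumes: every entry 100
  sw0 <- gamma_sweep(fx$plan, fx$plan, mask = fx$phantom)
  expect_true(all(sw0$pass_percent == 100))
})
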