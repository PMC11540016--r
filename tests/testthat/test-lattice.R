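test_that("lattice_spec rejects overlapping vertices", {
  expect_error(lattice_spec("hexagonal", 15, 14), "spacing")
  expect_error(lattice_spec("hexagonal", 0, 30), "sphere_diameter")
  expect_s3_class(lattice_spec("rectangular", 15, 15), "lattice_spec")
})

test_that("an interior HCP site has exactly 12 neighbours at distance s", {
  spec <- lattice_spec("hexagonal", 15, 30)
  bb <- list(lo = c(-100, -100, -100), hi = c(100, 100, 100))
  cand <- generate_hcp_candidates(spec, anchor = c(0, 0, 0), bbox = bb)
  d <- sqrt(colSums((t(cand) - c(0, 0, 0))^2))
  expect_true(any(d < 1e-9))  # anchor is a site
  expect_equal(sum(abs(d - 30) < 1e-6), 12)
  # no site closer than s
  expect_equal(min(d[d > 1e-9]), 30, tolerance = 1e-9)
})

test_that("HCP layers are spaced s*sqrt(2/3) apart and alternate A/B", {
  spec <- lattice_spec("hexagonal", 15, 30)
  bb <- list(lo = c(-40, -40, -60), hi = c(40, 40, 60))
  cand <- generate_hcp_candidates(spec, anchor = c(0, 0, 0), bbox = bb)
  zs <- sort(unique(round(cand[, "z"], 9)))
  expect_equal(diff(zs), rep(30 * sqrt(2 / 3), length(zs) - 1),
               tolerance = 1e-9)
  expect_equal(30 * sqrt(2 / 3), 24.49490, tolerance = 1e-6)
})

test_that("minimum pairwise distance over a finite HCP block is exactly s", {
  spec <- lattice_spec("hexagonal", 10, 10)
  bb <- list(lo = c(-25, -25, -25), hi = c(25, 25, 25))  # ~5x5x5 cells
  cand <- generate_hcp_candidates(spec, anchor = c(0, 0, 0), bbox = bb)
  expect_gt(nrow(cand), 50)
  dmat <- as.matrix(stats::dist(cand))
  diag(dmat) <- Inf
  expect_equal(min(dmat), 10, tolerance = 1e-9)
})

test_that("rectangular candidates enumerate a cubic grid", {
  spec <- lattice_spec("rectangular", 15, 30)
  # bbox centred on the anchor: sites at 0, +/-30 per axis -> 27
  bb <- list(lo = c(-45, -45, -45), hi = c(45, 45, 45))
  cand <- generate_rect_candidates(spec, anchor = c(0, 0, 0), bbox = bb)
  expect_equal(nrow(cand), 27)
  # anchor at the bbox corner: sites at -45, -15, 15, 45 per axis -> 64
  cand2 <- generate_rect_candidates(spec, anchor = c(-45, -45, -45), bbox = bb)
  expect_equal(nrow(cand2), 64)
  expect_setequal(unique(round(cand2[, "x"], 9)), c(-45, -15, 15, 45))
  # interior site of a larger block has 6 neighbours at distance s
  bb3 <- list(lo = c(-90, -90, -90), hi = c(90, 90, 90))
  cand3 <- generate_rect_candidates(spec, anchor = c(0, 0, 0), bbox = bb3)
  d <- sqrt(colSums((t(cand3) - c(0, 0, 0))^2))
  expect_equal(sum(abs(d - 30) < 1e-6), 6)
})

test_that("in-plane shift translates every candidate rigidly", {
  for (pat in c("hexagonal", "rectangular")) {
    s0 <- lattice_spec(pat, 15, 30)
    s1 <- lattice_spec(pat, 15, 30, shift_x = 5, shift_y = -2)
    bb <- list(lo = c(-40, -40, -40), hi = c(50, 50, 40))
    gen <- if (pat == "hexagonal") generate_hcp_candidates else
      generate_rect_candidates
    # enlarge bbox so the shifted set is not clipped differently
    c0 <- gen(s0, c(0, 0, 0), bb)
    c1 <- gen(s1, c(0, 0, 0), bb)
    shifted <- sweep(c0, 2, c(5, -2, 0), "+")
    inside <- shifted[, 1] <= 50 & shifted[, 2] >= -40
    expect_true(all(apply(shifted[inside, , drop = FALSE], 1, function(p)
      any(colSums(abs(t(c1) - p)) < 1e-6))))
  }
})

test_that("containment filtering keeps spheres fully inside the target", {
  g <- volume_geometry(c(-20, -20, -20), c(1, 1, 1), c(41, 41, 41))
  ball <- structure_mask(
    array(outer(outer((-20:20)^2, (-20:20)^2, "+"), (-20:20)^2, "+") <= 15^2,
          c(41, 41, 41)), g, "ball")
  cand <- rbind(c(0, 0, 0), c(10, 0, 0), c(14, 0, 0), c(30, 0, 0))
  vs <- filter_contained(cand, ball, radius = 5)
  # kept iff distance transform >= 5: centre yes, 10 yes (15-10=5), 14 no
  expect_equal(nrow(vs$centers), 2)
  dt <- mask_distance_transform(ball)
  idx <- round(world_to_index(g, vs$centers)) + 1
  for (r in seq_len(nrow(idx)))
    expect_gte(dt[idx[r, 1], idx[r, 2], idx[r, 3]], 5)
  # target smaller than the sphere -> nothing fits
  expect_equal(nrow(filter_contained(cand, ball, radius = 16)$centers), 0)
  # radius -> 0+ keeps every in-mask candidate
  vs0 <- filter_contained(cand, ball, radius = 1e-9)
  expect_equal(nrow(vs0$centers), 3)
  # empty target -> empty set, no error
  empty <- structure_mask(array(FALSE, c(41, 41, 41)), g, "empty")
  expect_equal(nrow(filter_contained(cand, empty, radius = 5)$centers), 0)
})

test_that("distance transform matches a brute-force oracle on a small mask", {
  set.seed(31)
  g <- volume_geometry(c(0, 0, 0), c(1, 2, 1), c(9, 7, 8))
  m <- array(runif(9 * 7 * 8) > 0.4, c(9, 7, 8))
  mask <- structure_mask(m, g)
  dt <- mask_distance_transform(mask)
  idx_in <- which(m, arr.ind = TRUE)
  idx_out <- which(!m, arr.ind = TRUE)
  w_in <- index_to_world(g, idx_in - 1)
  w_out <- index_to_world(g, idx_out - 1)
  for (r in sample(nrow(w_in), 20)) {
    expected <- min(sqrt(colSums((t(w_out) - w_in[r, ])^2)))
    expect_equal(dt[idx_in[r, 1], idx_in[r, 2], idx_in[r, 3]], expected,
                 tolerance = 1e-9)
  }
  expect_true(all(dt[!m] == 0))
})

test_that("the 19-sphere arrangement is translation-equivariant on the grid", {
  g <- canonical_grid_1mm()
  gtv <- make_cylinder_mask(phantom_spec(45, 90.5, g))
  spec <- lattice_spec("hexagonal", 15, 30)
  vs <- place_vertices(gtv, spec)
  # shift the whole mask by whole voxels (3, -2, 2) and anchor accordingly
  # (the cylinder leaves >= 3 voxels of slack to every grid face)
  shift <- c(3, -2, 2)
  shifted <- array(FALSE, g$dims)
  src <- gtv$values[1:93, 3:96, 1:94]
  shifted[4:96, 1:94, 3:96] <- src
  vs2 <- filter_contained(
    generate_hcp_candidates(spec, anchor = mask_centroid(gtv) + shift,
                            bbox = geometry_bbox(g)),
    structure_mask(shifted, g), radius = 7.5)
  expect_equal(nrow(vs2$centers), nrow(vs$centers))
  a <- vs$centers[order(vs$centers[, 1], vs$centers[, 2], vs$centers[, 3]), ]
  b <- vs2$centers[order(vs2$centers[, 1], vs2$centers[, 2], vs2$centers[, 3]), ]
  expect_equal(sweep(b, 2, shift, "-"), a, tolerance = 1e-9)
})

test_that("vertex count respects the HCP packing bound", {
  g <- canonical_grid_1mm()
  gtv <- make_cylinder_mask(phantom_spec(45, 90.5, g))
  vs <- place_vertices(gtv, lattice_spec("hexagonal", 15, 30))
  cell_volume <- 30^3 / sqrt(2)
  expect_lte(nrow(vs$centers),
             mask_volume_cm3(gtv) * 1000 / cell_volume)
})

test_that("vertices_to_mask rasterizes spheres to the analytic volume", {
  g <- volume_geometry(c(-15, -15, -15), c(1, 1, 1), c(31, 31, 31))
  vs <- vertex_set(rbind(c(0, 0, 0)), diameter = 15)
  m <- vertices_to_mask(vs, g)
  vol <- sum(m$values) * voxel_volume_mm3(g)
  expect_equal(vol, pi / 6 * 15^3, tolerance = 0.03)
  # empty set -> all-false mask
  m0 <- vertices_to_mask(vertex_set(NULL, 15), g)
  expect_false(any(m0$values))
  # centre outside the grid -> error naming the vertex
  expect_error(vertices_to_mask(vertex_set(rbind(c(0, 0, 40)), 15), g),
               "outside the grid")
})

test_that("the 19-vertex lattice rasterizes to 19 components (26-connectivity)", {
  g <- closure_grid_2mm()
  phantom <- make_cylinder_mask(phantom_spec(45, 90.5, g))
  vs <- place_vertices(phantom, lattice_spec("hexagonal", 15, 30))
  m <- vertices_to_mask(vs, g)
  expect_equal(max(label_components(m)), nrow(vs$centers))
  lab <- vertices_to_mask(vs, g, labeled = TRUE)
  expect_equal(sort(unique(as.vector(lab$labels[lab$labels > 0]))),
               seq_len(nrow(vs$centers)))
})

test_that("vertex sets round trip through CSV and JSON", {
  vs <- vertex_set(rbind(c(1.5, -2, 3), c(10, 20, -30)), diameter = 15,
                   anchor = c(0, 0, 0))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_vertices_json(vs, jpath, spec = lattice_spec("hexagonal", 15, 30))
  back <- read_vertices_json(jpath)
  expect_equal(back$centers, vs$centers, tolerance = 1e-12)
  expect_equal(back$diameter, 15)
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_vertices_csv(vs, cpath)
  df <- utils::read.csv(cpath)
  expect_equal(df$x_mm, vs$centers[, 1])
  expect_equal(df$label, 1:2)
})
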