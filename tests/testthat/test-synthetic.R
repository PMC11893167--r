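# The synthetic scene generator: planted spacing fields, CJ wells, ground-
# truth labels, decoration modes, and full determinism.

test_that("same seed reproduces a scene exactly", {
  a <- make_mitochondrion(2000, spacing = 120, n_cj_wells = 2, level = 3,
                          seed = 5)
  b <- make_mitochondrion(2000, spacing = 120, n_cj_wells = 2, level = 3,
                          seed = 5)
  expect_identical(a$omm$vertices, b$omm$vertices)
  expect_identical(a$imm$vertices, b$imm$vertices)
  expect_identical(a$truth$crista_triangles, b$truth$crista_triangles)
  da <- decorate_particles(a$omm, 40, mode = "clustered", seed = 8)
  db <- decorate_particles(b$omm, 40, mode = "clustered", seed = 8)
  expect_identical(da$particles, db$particles)
  dc <- decorate_particles(a$omm, 40, mode = "clustered", seed = 9)
  expect_false(identical(da$particles, dc$particles))
})

test_that("constant spacing field is reproduced by measured distances", {
  sc <- make_mitochondrion(3000, spacing = 100, n_cj_wells = 0, level = 4)
  fld <- intermembrane_distance(sc$omm, sc$imm, method = "nearest-point")
  expect_true(all(abs(fld$distance - 100) <= 2)) # within 2% of spacing
  # and with the cone method
  fld2 <- intermembrane_distance(sc$omm, sc$imm, method = "normal-cone")
  expect_true(all(is.finite(fld2$distance)))
  expect_true(all(abs(fld2$distance - 100) <= 2))
})

test_that("wells produce the requested number of crista truth components", {
  sc <- make_mitochondrion(3000, n_cj_wells = 3, level = 4, seed = 21)
  comp <- label_components(sc$omm, sc$truth$crista_triangles)
  expect_identical(max(comp), 3L)
  # planted well spacing sits inside the CJ band
  expect_true(all(sc$truth$planted_spacing[sc$truth$crista_triangles] >= 180))
  expect_true(all(sc$truth$planted_spacing[sc$truth$crista_triangles] <= 300))
})

test_that("two-level spacing zones are reproduced within tolerance", {
  zones <- list(centers = rbind(c(0, 0, 1), c(1, 0, 0)), arc = 600,
                spacing = 110)
  sc <- make_mitochondrion(3000, spacing = 135, zones = zones, level = 4)
  fld <- intermembrane_distance(sc$omm, sc$imm, method = "nearest-point")
  inz <- sc$truth$zone_triangles
  # compare against the analytic two-level offset field away from the
  # zone boundary (boundary triangles mix the two levels)
  cen_dir <- sc$omm$centroids / sqrt(rowSums(sc$omm$centroids^2))
  ang1 <- acos(pmax(-1, pmin(1, cen_dir %*% c(0, 0, 1)))) * 3000
  ang2 <- acos(pmax(-1, pmin(1, cen_dir %*% c(1, 0, 0)))) * 3000
  core <- pmin(ang1, ang2) < 400
  rim <- pmin(ang1, ang2) > 800
  expect_true(all(abs(fld$distance[core] - 110) < 5))
  expect_true(all(abs(fld$distance[rim] - 135) < 5))
})

test_that("generated import particles satisfy the classifier's own rule", {
  # this is the test that pins the Euler convention end to end
  sc <- scene_plain(level = 5)
  deco <- decorate_particles(sc$omm, 150, import_fraction = 1, seed = 13)
  rec <- compute_context(deco$particles, sc$omm)
  expect_true(all(rec$orientation_class == "import_oriented"))
  expect_true(all(rec$exit_to_omm <= 95))
  # and planted non-import particles are at least membrane-proximal
  deco0 <- decorate_particles(sc$omm, 100, import_fraction = 0, seed = 14)
  rec0 <- compute_context(deco0$particles, sc$omm)
  expect_true(all(rec0$orientation_class != "background"))
})

test_that("area-weighted sampling occupies triangles proportionally to area", {
  s <- icosphere(1000, level = 2) # 320 faces
  sp <- sample_surface_points(s, 10000, seed = 31)
  counts <- tabulate(sp$triangle, nbins = nrow(s$faces))
  p <- suppressWarnings(
    stats::chisq.test(counts, p = s$areas / sum(s$areas))$p.value)
  expect_gt(p, 0.01)
  # points lie on their sampled triangle's plane
  i <- sp$triangle[1]
  v <- s$vertices[s$faces[i, 1], ]
  expect_lt(abs(sum((sp$points[1, ] - v) * s$normals[i, ])), 1e-6)
})

test_that("chain decorations have near-collinear 5'->3' geometry", {
  sc <- scene_plain(level = 4)
  deco <- decorate_particles(sc$omm, 5, mode = "chains",
                             chain_lengths = 5L, chain_spacing = 300,
                             seed = 17)
  offs <- body_frame_offsets()
  p <- deco$particles
  expect_identical(deco$truth$chains[[1]], 1:5)
  ctr <- pc(p)
  # consecutive centers are chain_spacing apart (chord vs arc: < 0.1%)
  gaps <- sqrt(rowSums((ctr[-1, ] - ctr[-5, ])^2))
  expect_true(all(abs(gaps - 300) < 1))
  # marker-based end-to-end: 4 * spacing plus the terminal site offsets
  exit1 <- body_point_to_tomogram(ctr[1, ], as.numeric(p[1, 4:6]),
                                  offs$mrna_exit)
  entry5 <- body_point_to_tomogram(ctr[5, ], as.numeric(p[5, 4:6]),
                                   offs$mrna_entry)
  e2e <- sqrt(sum((exit1 - entry5)^2))
  expect_equal(e2e, 4 * 300 + 250, tolerance = 0.05)
})

test_that("decoration guards reject impossible requests", {
  s <- icosphere(300, level = 2)
  expect_error(decorate_particles(s, 1000, seed = 1), "packing")
  expect_error(decorate_particles(s, 4, import_fraction = 1.5, seed = 1),
               "import_fraction")
  sc <- scene_plain(level = 3)
  expect_error(decorate_particles(sc$omm, 3, mode = "chains",
                                  chain_lengths = c(3L, 2L), seed = 1),
               "chain_lengths")
})
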