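# OMM patch construction, the randomized null, intermembrane distance
# fields, crista-associated OMM detection, overlap fractions and distance
# histograms.

test_that("patch membership equals the brute-force radius scan", {
  mesh <- flat_grid_mesh(nx = 20, ny = 20, pitch = 50)
  seed_id <- nearest_triangle(c(500, 500, 0), mesh)$index
  lab <- build_patches(seed_id, mesh, radius = 150)
  want <- sqrt(colSums((t(mesh$centroids) -
                        mesh$centroids[seed_id, ])^2)) <= 150
  expect_identical(lab$patch_member, want)
  expect_identical(lab$centers, seed_id)

  # radius 0 keeps the seeds only
  lab0 <- build_patches(c(3L, 7L), mesh, radius = 0)
  expect_identical(which(lab0$patch_member), c(3L, 7L))

  # overlapping seeds form a union; each triangle counted once
  two <- build_patches(c(seed_id, seed_id + 1L), mesh, radius = 150)
  a <- sqrt(colSums((t(mesh$centroids) - mesh$centroids[seed_id, ])^2)) <= 150
  b <- sqrt(colSums((t(mesh$centroids) -
                     mesh$centroids[seed_id + 1L, ])^2)) <= 150
  expect_identical(two$patch_member, a | b)
  expect_equal(sum(two$areas), sum(mesh$areas))
})

test_that("patch and complement partition the surface exactly", {
  sc <- scene_plain(level = 3)
  lab <- build_patches(c(10L, 200L, 900L), sc$omm, radius = 300)
  expect_true(all(xor(lab$patch_member, lab$complement_member)))
  expect_equal(unname(lab$areas["patch"] + lab$areas["complement"]),
               sum(sc$omm$areas))
  expect_equal(sum(lab$patch_member) + sum(lab$complement_member),
               nrow(sc$omm$faces))
  # empty seed set is valid: empty patch, full complement
  lab0 <- build_patches(integer(0), sc$omm, radius = 150)
  expect_equal(sum(lab0$patch_member), 0L)
  expect_equal(unname(lab0$areas["complement"]), sum(sc$omm$areas))
})

test_that("randomized patches match the count and spacing constraints", {
  s <- icosphere(3000, level = 2)
  obs <- build_patches(c(5L, 80L, 200L, 310L, 17L), s, radius = 150)
  for (seed in 1:50) {
    rnd <- randomize_patches(obs, s, seed = seed, min_spacing = 150)
    expect_equal(length(rnd$centers), length(obs$centers))
    expect_true(all(stats::dist(s$centroids[rnd$centers, ]) > 150))
    expect_identical(rnd$provenance$type, "randomized")
  }
  # unsatisfiable packing fails loudly
  tiny <- icosphere(100, level = 1)
  obs2 <- build_patches(seq_len(30L), tiny, radius = 50)
  expect_error(randomize_patches(obs2, tiny, seed = 1, min_spacing = 1e5,
                                 max_attempts = 20), "packing")
})

test_that("intermembrane distances recover planar and concentric geometry", {
  a <- flat_grid_mesh(nx = 15, ny = 15, pitch = 50, z = 100)
  b <- flat_grid_mesh(nx = 15, ny = 15, pitch = 50, z = 0)
  np <- intermembrane_distance(a, b, method = "nearest-point")
  expect_true(all(abs(np$distance - 100) < 1e-9))
  nc <- intermembrane_distance(a, b, method = "normal-cone")
  # the grid's downward cone hits the matching triangle directly below
  expect_true(all(abs(nc$distance - 100) < 1e-9) ||
              all(abs(nc$distance[is.finite(nc$distance)] - 100) < 1e-9))

  outer_s <- icosphere(1000, level = 3)
  inner_s <- icosphere(900, level = 3)
  d1 <- intermembrane_distance(outer_s, inner_s, method = "nearest-point")
  expect_true(all(abs(d1$distance - 100) / 100 < 0.02))
  d2 <- intermembrane_distance(outer_s, inner_s, method = "normal-cone")
  expect_true(all(abs(d2$distance - 100) / 100 < 0.02))

  # a source facing away from the target is undefined, not large
  away <- triangle_surface(rbind(c(0, 0, 500), c(10, 0, 500),
                                 c(0, 10, 500)), rbind(c(1, 2, 3)))
  miss <- intermembrane_distance(away, b, method = "normal-cone",
                                 cone_direction = "outward")
  expect_true(is.na(miss$distance))
})

test_that("crista-associated OMM recovers planted CJ wells", {
  sc <- make_mitochondrion(3000, n_cj_wells = 3, level = 4, seed = 33)
  cfg <- run_config()
  crista <- crista_associated_omm(sc$omm, sc$imm, cfg)
  truth_comp <- label_components(sc$omm, sc$truth$crista_triangles)
  got_comp <- label_components(sc$omm, crista$patch_member)
  expect_gte(max(got_comp), 3L)
  for (k in seq_len(max(truth_comp))) {
    truth_set <- truth_comp == k
    # the recovered component overlapping this well
    hit <- unique(got_comp[truth_set & crista$patch_member])
    hit <- hit[hit > 0]
    expect_length(hit, 1L)
    got_set <- got_comp == hit
    jaccard <- sum(truth_set & got_set) / sum(truth_set | got_set)
    expect_gt(jaccard, 0.5)
  }

  # spacing outside the band yields an empty set with a warning
  flat_sc <- scene_plain(level = 3)
  expect_warning(none <- crista_associated_omm(flat_sc$omm, flat_sc$imm,
                                               cfg), "CJ band")
  expect_equal(sum(none$patch_member), 0L)

  # zero expansion leaves exactly the CJ-projected set
  cfg0 <- run_config(crista_expand = 1)
  cfg0$crista_expand <- 0
  proj_only <- crista_associated_omm(sc$omm, sc$imm, cfg0)
  expect_identical(which(proj_only$patch_member), proj_only$centers)
})

test_that("overlap fraction is exact area arithmetic", {
  mesh <- flat_grid_mesh(nx = 2, ny = 1, pitch = 100) # 4 equal triangles
  ribo <- build_patches(integer(0), mesh, radius = 0)
  ribo$patch_member <- c(TRUE, TRUE, TRUE, TRUE)
  ribo$complement_member <- !ribo$patch_member
  crista <- build_patches(integer(0), mesh, radius = 0)
  crista$patch_member <- c(TRUE, FALSE, TRUE, FALSE)
  crista$complement_member <- !crista$patch_member
  expect_equal(overlap_fraction(ribo, crista), 0.5)

  sub <- ribo
  sub$patch_member <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(overlap_fraction(sub, crista), 1)
  disj <- ribo
  disj$patch_member <- c(FALSE, TRUE, FALSE, TRUE)
  expect_equal(overlap_fraction(disj, crista), 0)
  none <- ribo
  none$patch_member <- rep(FALSE, 4)
  expect_true(is.na(overlap_fraction(none, crista)))
  other <- build_patches(integer(0), flat_grid_mesh(nx = 3, ny = 1),
                         radius = 0)
  expect_error(overlap_fraction(ribo, other), "different surfaces")
})

test_that("decorations inside CJ wells raise the overlap fraction", {
  cfg <- run_config()
  inside <- numeric(0); outside <- numeric(0)
  for (s in 1:5) {
    sc <- make_mitochondrion(3000, n_cj_wells = 3, level = 4, seed = 40 + s)
    crista <- crista_associated_omm(sc$omm, sc$imm, cfg)
    score <- function(region, seed) {
      deco <- decorate_particles(sc$omm, 40, import_fraction = 1,
                                 region = region, seed = seed)
      near <- nearest_triangle(pc(deco$particles), sc$omm)
      overlap_fraction(build_patches(near$index, sc$omm,
                                     radius = cfg$patch_radius), crista)
    }
    inside <- c(inside, score(sc$truth$crista_triangles, 70 + s))
    outside <- c(outside, score(!sc$truth$crista_triangles, 80 + s))
  }
  expect_gt(mean(inside), mean(outside))
  expect_lt(mann_whitney_u(inside, outside)$p_two_sided, 0.05)
})

test_that("distance histograms conserve counts and find planted peaks", {
  # constant field: peak at the common value
  f <- structure(list(distance = rep(100, 50), method = "nearest-point",
                      source_id = "OMM", target_id = "IMM",
                      tomogram_id = "t"), class = "distance_field")
  mesh_lab <- list(patch_member = rep(TRUE, 50),
                   complement_member = rep(FALSE, 50))
  h <- patch_distance_histograms(f, mesh_lab, bins = 100, sets = "patch")
  expect_equal(h$patch$peak, 100)

  # bimodal planted field: 110 A under the co-translational zones, 135
  # elsewhere
  zones <- list(centers = rbind(c(0, 0, 1), c(0, 0, -1)), arc = 900,
                spacing = 110)
  sc <- make_mitochondrion(3000, spacing = 135, zones = zones, level = 4)
  fld <- intermembrane_distance(sc$omm, sc$imm, method = "nearest-point")
  lab <- build_patches(which(sc$truth$zone_triangles), sc$omm, radius = 0)
  h2 <- patch_distance_histograms(fld, lab, bins = 100)
  # one bin width plus the mesh discretization allowance (distances are
  # measured centroid-to-centroid on a subdivided sphere: < 2% of spacing)
  binw_p <- diff(h2$patch$breaks[1:2])
  binw_c <- diff(h2$complement$breaks[1:2])
  expect_lt(abs(h2$patch$peak - 110), binw_p + 0.02 * 110)
  expect_lt(abs(h2$complement$peak - 135), binw_c + 0.02 * 135)
  # conservation: counts sum to the number of defined distances
  expect_equal(sum(h2$patch$counts), sum(lab$patch_member))
  expect_equal(sum(h2$complement$counts), sum(lab$complement_member))
  expect_equal(sum(h2$all$counts), length(fld$distance))

  # fewer than 2 defined distances: peak flagged undefined
  f1 <- f; f1$distance <- c(5, rep(NA_real_, 49))
  h3 <- patch_distance_histograms(f1, mesh_lab, bins = 10, sets = "patch")
  expect_true(is.na(h3$patch$peak))
})
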