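# Rotation conventions, body-frame transforms, nearest-triangle queries and
# the relative-angle formula.

test_that("euler_to_matrix follows the transposed-ZYZ convention", {
  expect_equal(euler_to_matrix(0, 0, 0), diag(3))
  # tilt 180 flips the body z axis
  expect_equal(as.numeric(euler_to_matrix(0, 180, 0) %*% c(0, 0, 1)),
               c(0, 0, -1), tolerance = 1e-12)
  # hand-multiplied: R = t(Rz(90)), so R e1 = (0, -1, 0)
  expect_equal(as.numeric(euler_to_matrix(90, 0, 0) %*% c(1, 0, 0)),
               c(0, -1, 0), tolerance = 1e-12)
  expect_error(euler_to_matrix(NA, 0, 0), "finite")
})

test_that("euler_to_matrix is always orthonormal with det +1", {
  set.seed(42)
  for (i in 1:1000) {
    ang <- runif(3, -360, 360)
    R <- euler_to_matrix(ang)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_lt(abs(det(R) - 1), 1e-9)
  }
})

test_that("matrix_to_euler inverts euler_to_matrix, including gimbal lock", {
  set.seed(7)
  for (i in 1:200) {
    R <- euler_to_matrix(runif(3, -180, 180))
    expect_lt(max(abs(euler_to_matrix(matrix_to_euler(R)) - R)), 1e-9)
  }
  for (tilt in c(0, 180)) {
    R <- euler_to_matrix(c(35, tilt, -20))
    expect_lt(max(abs(euler_to_matrix(matrix_to_euler(R)) - R)), 1e-9)
  }
})

test_that("body_point_to_tomogram composes center + rotated offset", {
  expect_equal(body_point_to_tomogram(c(10, 0, 0), c(0, 0, 0), c(0, 0, 5)),
               c(10, 0, 5))
  expect_equal(body_point_to_tomogram(c(3, 4, 5), c(77, -13, 129), c(0, 0, 0)),
               c(3, 4, 5))
  expect_equal(body_point_to_tomogram(c(0, 0, 0), c(0, 180, 0), c(0, 0, 5)),
               c(0, 0, -5), tolerance = 1e-9)
  # rotation preserves the offset norm
  set.seed(11)
  for (i in 1:50) {
    off <- rnorm(3)
    p <- body_point_to_tomogram(c(1, 2, 3), runif(3, -180, 180), off)
    expect_equal(sqrt(sum((p - c(1, 2, 3))^2)), sqrt(sum(off^2)),
                 tolerance = 1e-9)
  }
})

test_that("relative_angle folds sign and stays in [0, 90]", {
  expect_equal(relative_angle(c(0, 0, 1), c(0, 0, 0), c(0, 0, 1)), 0)
  expect_equal(relative_angle(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0)), 90)
  expect_equal(relative_angle(c(0, 0, 1), c(0, 0, 0), c(0, 0, -1)), 0)
  set.seed(5)
  for (i in 1:50) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    nn <- rnorm(3); nn <- nn / sqrt(sum(nn^2))
    ang <- runif(3, -180, 180)
    a <- relative_angle(ax, ang, nn)
    expect_gte(a, 0); expect_lte(a, 90)
    expect_equal(a, relative_angle(-ax, ang, nn), tolerance = 1e-9)
    expect_equal(a, relative_angle(ax, ang, -nn), tolerance = 1e-9)
  }
  expect_error(relative_angle(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)), "norm")
})

test_that("nearest_triangle matches exhaustive search and breaks ties low", {
  # single triangle with centroid at the origin
  s1 <- triangle_surface(rbind(c(-1, -1, 0), c(2, -1, 0), c(-1, 2, 0)),
                         rbind(c(1, 2, 3)))
  expect_equal(nearest_triangle(c(0, 0, 10), s1),
               list(index = 1L, distance = 10))
  # two equidistant centroids: lowest index wins
  s2 <- triangle_surface(
    rbind(c(-1, -1, 5), c(2, -1, 5), c(-1, 2, 5),
          c(-1, -1, -5), c(2, -1, -5), c(-1, 2, -5)),
    rbind(c(1, 2, 3), c(4, 5, 6)))
  hit <- nearest_triangle(c(0, 0, 0), s2)
  expect_identical(hit$index, 1L)

  # random mesh vs brute force, exact agreement
  set.seed(99)
  V <- matrix(runif(3 * 300, -100, 100), ncol = 3)
  F <- matrix(sample.int(300, 3 * 500, replace = TRUE), ncol = 3)
  F <- F[F[, 1] != F[, 2] & F[, 2] != F[, 3] & F[, 1] != F[, 3], ]
  s3 <- suppressMessages(triangle_surface(V, F))
  q <- matrix(runif(3 * 100, -150, 150), ncol = 3)
  got <- nearest_triangle(q, s3)
  want <- brute_nearest(q, s3$centroids)
  expect_identical(got$index, as.integer(want$index))
  expect_equal(got$distance, want$distance, tolerance = 1e-12)

  expect_error(nearest_triangle(c(0, 0, 0),
                                triangle_surface(matrix(0, 0, 3),
                                                 matrix(0L, 0, 3))),
               "no triangles")
})

test_that("exact point-to-triangle mode refines the centroid distance", {
  s <- triangle_surface(rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0)),
                        rbind(c(1, 2, 3)))
  # directly above the triangle interior: exact distance is the height
  got <- nearest_triangle(c(5, 5, 7), s, exact = TRUE)
  expect_equal(got$distance, 7)
  expect_lt(got$distance, nearest_triangle(c(5, 5, 7), s)$distance)
  # beyond a vertex: exact distance is to that vertex
  got2 <- nearest_triangle(c(-3, -4, 0), s, exact = TRUE)
  expect_equal(got2$distance, 5)
})
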