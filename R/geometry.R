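# Rotation and mesh query primitives shared by every pipeline stage.
#
# Euler convention: the star-dialect (rot, tilt, psi) triple is ZYZ in
# degrees, and the body->tomogram rotation is the transpose of
# Rz(rot) %*% Ry(tilt) %*% Rz(psi) (the reference->particle matrix used by
# subtomogram-averaging software, transposed). The synthetic generator uses
# the same convention, and the generator/classifier consistency test pins it.

rot_z <- function(deg) {
  th <- deg * pi / 180
  c0 <- cos(th); s0 <- sin(th)
  matrix(c(c0, s0, 0, -s0, c0, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  th <- deg * pi / 180
  c0 <- cos(th); s0 <- sin(th)
  matrix(c(c0, 0, -s0, 0, 1, 0, s0, 0, c0), 3, 3)
}

#' Convert ZYZ Euler angles to a body-to-tomogram rotation matrix
#'
#' The (rot, tilt, psi) triple follows the star-file convention (degrees,
#' intrinsic ZYZ). The returned matrix is
#' `t(Rz(rot) %*% Ry(tilt) %*% Rz(psi))`: applying it to a body-frame
#' direction yields the tomogram-frame direction.
#'
#' @param rot,tilt,psi Euler angles in degrees. `rot` may also be a length-3
#'   vector holding all three.
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' euler_to_matrix(0, 0, 0)            # identity
#' euler_to_matrix(0, 180, 0) %*% c(0, 0, 1)  # -> (0, 0, -1)
#' @export
euler_to_matrix <- function(rot, tilt = NULL, psi = NULL) {
  if (is.null(tilt) && length(rot) == 3L) {
    tilt <- rot[2L]; psi <- rot[3L]; rot <- rot[1L]
  }
  ang <- c(rot, tilt, psi)
  if (length(ang) != 3L || !all(is.finite(ang)))
    stopf("Euler angles must be three finite numbers")
  t(rot_z(rot) %*% rot_y(tilt) %*% rot_z(psi))
}

#' Recover ZYZ Euler angles from a body-to-tomogram rotation matrix
#'
#' Inverse of [euler_to_matrix()]. At the gimbal-lock points (tilt = 0 or
#' 180 degrees) `psi` is set to 0 and the full in-plane rotation is folded
#' into `rot`.
#'
#' @param R 3x3 rotation matrix as returned by [euler_to_matrix()].
#' @return Numeric vector `c(rot, tilt, psi)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  M <- t(R) # Rz(rot) Ry(tilt) Rz(psi)
  ct <- max(-1, min(1, M[3, 3]))
  tilt <- acos(ct) * 180 / pi
  if (abs(abs(ct) - 1) < 1e-12) {
    # gimbal lock: tilt 0 gives M = Rz(rot+psi); tilt 180 gives
    # M = Rz(rot-psi) %*% diag(-1, 1, -1); fold everything into rot
    rot <- if (ct > 0) atan2(M[2, 1], M[1, 1]) * 180 / pi
           else        atan2(-M[2, 1], -M[1, 1]) * 180 / pi
    psi <- 0
  } else {
    rot <- atan2(M[2, 3], M[1, 3]) * 180 / pi
    psi <- atan2(M[3, 2], -M[3, 1]) * 180 / pi
  }
  c(rot = rot, tilt = tilt, psi = psi)
}

#' Map a body-frame offset to tomogram coordinates
#'
#' Returns `center + R %*% offset` where `R` is the particle's rotation.
#' Used to place the peptide exit tunnel and the mRNA entry/exit sites of a
#' ribosome whose pose is known.
#'
#' @param center Particle center, tomogram frame (Angstrom); length-3 vector
#'   or n x 3 matrix.
#' @param angles Euler triple(s): length-3 vector or n x 3 matrix (degrees).
#' @param offset Body-frame offset (Angstrom), length-3 vector.
#' @return Tomogram-frame coordinates, same shape as `center`.
#' @export
body_point_to_tomogram <- function(center, angles, offset) {
  ctr <- as_xyz(center, "center")
  ang <- as_xyz(angles, "angles")
  if (nrow(ang) == 1L && nrow(ctr) > 1L)
    ang <- ang[rep(1L, nrow(ctr)), , drop = FALSE]
  if (nrow(ang) != nrow(ctr)) stopf("center and angles row counts differ")
  offset <- as.numeric(offset)
  out <- ctr
  for (i in seq_len(nrow(ctr)))
    out[i, ] <- ctr[i, ] + as.numeric(euler_to_matrix(ang[i, ]) %*% offset)
  if (is.null(dim(center))) out[1, ] else out
}

#' Nearest mesh triangle to a query point
#'
#' Distance is point-to-centroid Euclidean distance (the convention used
#' throughout: membrane position is represented by triangle coordinates).
#' Queries go through a uniform-grid spatial index with expected sublinear
#' lookup; results are exactly those of an exhaustive scan, with ties broken
#' by the lowest triangle index. Set `exact = TRUE` for true point-to-triangle
#' (surface) distance instead of point-to-centroid.
#'
#' @param point Length-3 vector or n x 3 matrix of query points (Angstrom).
#' @param surface A [triangle_surface()].
#' @param exact Use exact point-to-triangle distance (default FALSE).
#' @return A list with `index` (1-based triangle ids) and `distance`
#'   (Angstrom), each of length n.
#' @export
nearest_triangle <- function(point, surface, exact = FALSE) {
  stopifnot(inherits(surface, "triangle_surface"))
  if (nrow(surface$faces) == 0L) stopf("surface has no triangles")
  pts <- as_xyz(point, "point")
  res <- cpp_nearest_point(pts, surface$centroids)
  if (exact) {
    for (i in seq_len(nrow(pts))) {
      hit <- point_triangle_refine(pts[i, ], surface)
      res$index[i] <- hit$index
      res$distance[i] <- hit$distance
    }
  }
  res
}

# exact point-to-triangle distance, brute force over faces (non-default path)
point_triangle_refine <- function(p, surface) {
  V <- surface$vertices
  F <- surface$faces
  best <- Inf; besti <- NA_integer_
  for (j in seq_len(nrow(F))) {
    d <- point_triangle_distance(p, V[F[j, 1], ], V[F[j, 2], ], V[F[j, 3], ])
    if (d < best) { best <- d; besti <- j }
  }
  list(index = besti, distance = best)
}

point_triangle_distance <- function(p, a, b, c) {
  # project p on the triangle plane, clamp to the triangle (Ericson-style)
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(vnorm(p - a))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(vnorm(p - b))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(vnorm(p - (a + v * ab)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(vnorm(p - c))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(vnorm(p - (a + w * ac)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(vnorm(p - (b + w * (c - b))))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  vnorm(p - (a + ab * v + ac * w))
}

#' Relative angle between a rotated body axis and a surface normal
#'
#' Computes `acos(|(R %*% body_axis) . normal|)` in degrees, where `R` is the
#' particle rotation from its Euler triple. The absolute value folds the sign
#' of either vector, so the result lies in \[0, 90\] degrees.
#'
#' @param body_axis Unit vector in the ribosome body frame.
#' @param angles Euler triple (degrees).
#' @param normal Unit surface normal (tomogram frame).
#' @return Angle in degrees, in \[0, 90\].
#' @export
relative_angle <- function(body_axis, angles, normal) {
  u <- unitize(as.numeric(body_axis), "body_axis")
  n <- unitize(as.numeric(normal), "normal")
  v <- as.numeric(euler_to_matrix(as.numeric(angles)) %*% u)
  d <- abs(sum(v * n))
  acos(max(-1, min(1, d))) * 180 / pi
}

# Haar-uniform random rotation matrix (via normalized quaternion)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}
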