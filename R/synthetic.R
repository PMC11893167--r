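# Synthetic ground-truth scenes: nested OMM/IMM icosphere meshes with a
# controllable intermembrane spacing field (including crista-junction wells
# where the IMM recedes into the 18-30 nm band) and particle decorations
# with planted orientation classes, clustering, and polysome chains. Both
# membranes are built from the same subdivision so that, under a constant
# spacing field, every OMM triangle has a radially aligned IMM partner and
# the measured intermembrane distance reproduces the planted field to well
# under a percent.

#' Generate a synthetic mitochondrion (nested OMM/IMM meshes)
#'
#' The OMM is a closed icosphere of the given radius; the IMM is its inward
#' offset by a spacing field. Crista-junction (CJ) wells are localized
#' regions where the IMM additionally recedes so that the IMM-to-OMM
#' distance falls inside `well_band` (default 18-30 nm, matching the CJ
#' selection rule); the spacing tapers smoothly (cosine) from the local base
#' value to `well_spacing` over the well radius. Ground truth records which
#' OMM triangles are crista-associated (planted spacing inside `well_band`)
#' and which lie in reduced-spacing zones.
#'
#' @param radius OMM radius (Angstrom).
#' @param spacing Base OMM-IMM spacing (Angstrom): a constant or a function
#'   taking an n x 3 matrix of unit directions and returning spacings.
#' @param n_cj_wells Number of crista-junction wells.
#' @param well_spacing Spacing at a well center (Angstrom; default 240 =
#'   24 nm, the middle of the CJ band).
#' @param well_arc Well radius along the surface (Angstrom of arc;
#'   default 900).
#' @param well_band CJ truth band (Angstrom; default `c(180, 300)`).
#' @param zones Optional reduced/increased-spacing zones: a list with unit
#'   direction matrix `centers`, arc radius `arc` (Angstrom) and `spacing`
#'   (Angstrom); inside a zone the base spacing is replaced (hard edge).
#' @param level Icosphere subdivision level for both membranes (default 5).
#' @param seed Seed for well placement.
#' @param tomogram_id Token carried by both surfaces.
#' @return A list of class `mito_scene` with elements `omm`, `imm`
#'   ([triangle_surface()]s) and `truth` (planted labels and parameters).
#' @export
make_mitochondrion <- function(radius = 3000, spacing = 135,
                               n_cj_wells = 0, well_spacing = 240,
                               well_arc = 900, well_band = c(180, 300),
                               zones = NULL, level = 5L, seed = 1L,
                               tomogram_id = "tomo_1") {
  base_fun <- if (is.function(spacing)) spacing else {
    if (!is.numeric(spacing) || spacing <= 0)
      stopf("spacing must be positive")
    function(dirs) rep(spacing, nrow(dirs))
  }

  well_centers <- if (n_cj_wells > 0) {
    with_seed(seed, place_well_centers(n_cj_wells, 2.4 * well_arc / radius))
  } else matrix(0, 0, 3)

  spacing_at <- function(dirs) {
    s <- base_fun(dirs)
    if (!is.null(zones)) {
      zc <- as_xyz(zones$centers, "zone centers")
      for (k in seq_len(nrow(zc))) {
        ang <- acos(pmax(-1, pmin(1, dirs %*% zc[k, ])))
        s[ang * radius <= zones$arc] <- zones$spacing
      }
    }
    if (nrow(well_centers)) {
      for (k in seq_len(nrow(well_centers))) {
        ang <- acos(pmax(-1, pmin(1, dirs %*% well_centers[k, ])))
        arc <- ang * radius
        inw <- arc < well_arc
        if (any(inw)) {
          w <- 0.5 * (1 + cos(pi * arc[inw] / well_arc)) # 1 at center -> 0
          s[inw] <- s[inw] + w * (well_spacing - s[inw])
        }
      }
    }
    s
  }

  mesh <- unit_icosphere(level)
  s_v <- spacing_at(mesh$V)
  if (any(s_v >= radius))
    stopf("spacing (max %.1f) must stay below the radius (%.1f): surfaces would intersect",
          max(s_v), radius)
  if (any(s_v <= 0)) stopf("spacing field must stay positive")

  omm <- triangle_surface(mesh$V * radius, mesh$F, surface_id = "OMM",
                          tomogram_id = tomogram_id, orient = TRUE)
  imm <- triangle_surface(mesh$V * (radius - s_v), mesh$F,
                          surface_id = "IMM", tomogram_id = tomogram_id,
                          orient = TRUE)

  cen_dir <- omm$centroids / rownorms(omm$centroids)
  s_cen <- spacing_at(cen_dir)
  crista <- s_cen >= well_band[1] & s_cen <= well_band[2]
  zone_member <- rep(FALSE, nrow(omm$faces))
  if (!is.null(zones)) {
    zc <- as_xyz(zones$centers, "zone centers")
    for (k in seq_len(nrow(zc))) {
      ang <- acos(pmax(-1, pmin(1, cen_dir %*% zc[k, ])))
      zone_member <- zone_member | (ang * radius <= zones$arc)
    }
  }
  omm <- set_label(omm, "crista_associated_truth", crista)
  if (!is.null(zones)) omm <- set_label(omm, "zone_truth", zone_member)

  truth <- list(
    crista_triangles = crista,
    zone_triangles = zone_member,
    well_centers = well_centers,
    planted_spacing = s_cen,
    params = list(radius = radius, n_cj_wells = n_cj_wells,
                  well_spacing = well_spacing, well_arc = well_arc,
                  well_band = well_band, level = level),
    seed = seed
  )
  structure(list(omm = omm, imm = imm, truth = truth), class = "mito_scene")
}

#' @export
print.mito_scene <- function(x, ...) {
  cat(sprintf("<mito_scene> %s: OMM %d faces, IMM %d faces, %d CJ well(s)\n",
              x$omm$tomogram_id, nrow(x$omm$faces), nrow(x$imm$faces),
              x$truth$params$n_cj_wells))
  invisible(x)
}

# well centers: random unit directions with pairwise angular separation
# > min_sep (radians), by rejection
place_well_centers <- function(n, min_sep, max_attempts = 5000) {
  for (att in seq_len(max_attempts)) {
    d <- matrix(rnorm(3 * n), n, 3)
    d <- d / rownorms(d)
    ok <- TRUE
    if (n > 1) {
      g <- d %*% t(d)
      ang <- acos(pmax(-1, pmin(1, g[upper.tri(g)])))
      ok <- all(ang > min_sep)
    }
    if (ok) return(d)
  }
  stopf("could not place %d wells with separation %.2f rad", n, min_sep)
}

#' Area-weighted uniform points on a surface mesh
#'
#' Samples triangles proportionally to their area and positions uniformly
#' inside each sampled triangle -- the complete-spatial-randomness placement
#' on a membrane.
#'
#' @param surface A [triangle_surface()].
#' @param n Number of points.
#' @param region Optional restriction: logical over faces or face ids.
#' @param seed Optional seed (NULL uses the current RNG stream).
#' @return List with `points` (n x 3), `triangle` (face ids), `normals`
#'   (n x 3 outward unit normals of the sampled faces).
#' @export
sample_surface_points <- function(surface, n, region = NULL, seed = NULL) {
  with_seed(seed, {
    m <- nrow(surface$faces)
    w <- surface$areas
    if (!is.null(region)) {
      keep <- if (is.logical(region)) region else {
        l <- rep(FALSE, m); l[as.integer(region)] <- TRUE; l
      }
      w <- ifelse(keep, w, 0)
      if (sum(w) <= 0) stopf("sampling region has zero area")
    }
    tri <- sample.int(m, n, replace = TRUE, prob = w)
    r1 <- sqrt(runif(n)); r2 <- runif(n)
    A <- surface$vertices[surface$faces[tri, 1], , drop = FALSE]
    B <- surface$vertices[surface$faces[tri, 2], , drop = FALSE]
    C <- surface$vertices[surface$faces[tri, 3], , drop = FALSE]
    pts <- (1 - r1) * A + (r1 * (1 - r2)) * B + (r1 * r2) * C
    list(points = pts, triangle = tri,
         normals = surface$normals[tri, , drop = FALSE])
  })
}

# rotation taking unit vector u to unit vector v (Rodrigues)
rotation_between <- function(u, v) {
  u <- unitize(u); v <- unitize(v)
  c0 <- sum(u * v)
  if (c0 > 1 - 1e-12) return(diag(3))
  if (c0 < -1 + 1e-12) {
    # 180 degrees about any axis perpendicular to u
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a <- unitize(a - sum(a * u) * u)
    return(2 * tcrossprod(a) - diag(3))
  }
  ax <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c0)
}

# pose with the exit axis pointing at the membrane (-normal), random spin
# about that axis; returns Euler triple
import_pose <- function(normal, offsets, spin = runif(1, 0, 360)) {
  z_t <- -unitize(normal)
  R0 <- rotation_between(c(0, 0, 1), z_t)
  Rspin <- euler_to_matrix(c(spin, 0, 0)) # rotation about body z
  B <- rotation_between(offsets$exit_direction, c(0, 0, 1))
  matrix_to_euler(R0 %*% Rspin %*% B)
}

#' Decorate an OMM surface with ribosome particles of known ground truth
#'
#' Particle centers sit `standoff` Angstrom above the membrane along the
#' local outward normal. Import-labeled particles are oriented with the
#' peptide exit tunnel toward the membrane (random spin about that axis), so
#' their exit-to-OMM distance passes the 95 Angstrom rule by construction;
#' the rest get Haar-uniform random orientations (a geometric chance
#' fraction of which will also pass). Placement modes: `"csr"` (area-
#' weighted uniform), `"clustered"` (Thomas-like parent-offspring process
#' with tangential Gaussian scatter of scale `cluster_scale`), `"chains"`
#' (linear polysome chains along great circles with mRNA entry-next-to-exit
#' geometry).
#'
#' @param omm OMM [triangle_surface()] (an icosphere-based scene membrane).
#' @param n Number of particles (for `"chains"`, particles beyond
#'   `sum(chain_lengths)` are placed CSR with random orientation).
#' @param import_fraction Planted fraction of import-oriented particles.
#' @param mode `"csr"`, `"clustered"` or `"chains"`.
#' @param cluster_scale Offspring scatter scale, nm (default 35).
#' @param offspring_mean Mean offspring per cluster parent (default 5).
#' @param chain_lengths Integer vector of chain lengths (chains mode).
#' @param chain_spacing Center-to-center spacing along a chain (Angstrom).
#' @param offsets [body_frame_offsets()].
#' @param standoff Center height above the membrane (Angstrom; default 135).
#' @param region Optional placement restriction (logical over OMM faces or
#'   face ids).
#' @param seed Seed; the same seed reproduces the scene exactly.
#' @return List with `particles` (a [particle_table()] whose `truth_label`
#'   is `import_oriented` / `proximal_non_import`) and `truth` (planted
#'   parameters, per-particle labels, chain memberships).
#' @export
decorate_particles <- function(omm, n, import_fraction = 0.5,
                               mode = c("csr", "clustered", "chains"),
                               cluster_scale = 35, offspring_mean = 5,
                               chain_lengths = c(5L), chain_spacing = 300,
                               offsets = body_frame_offsets(),
                               standoff = 135, region = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (import_fraction < 0 || import_fraction > 1)
    stopf("import_fraction must be in [0, 1]")
  radius <- mean(rownorms(omm$vertices))
  # crude packing guard: ~ pi * (80 A)^2 of membrane per particle center
  # (placement is soft -- no hard-core exclusion -- so this only rejects
  # absurd densities)
  if (n * 2e4 > sum(omm$areas))
    stopf("n = %d exceeds the packing capacity of this membrane", n)

  with_seed(seed, {
    centers <- matrix(0, 0, 3)
    normals <- matrix(0, 0, 3)
    angles <- matrix(0, 0, 3)
    labels <- character(0)
    chains <- list()

    emit <- function(pos, nrm, import) {
      ang <- if (import) import_pose(nrm, offsets)
             else matrix_to_euler(random_rotation())
      centers <<- rbind(centers, pos + standoff * nrm)
      normals <<- rbind(normals, nrm)
      angles <<- rbind(angles, ang)
      labels <<- c(labels,
                   if (import) "import_oriented" else "proximal_non_import")
    }

    if (mode == "chains") {
      chain_lengths <- as.integer(chain_lengths)
      if (sum(chain_lengths) > n)
        stopf("sum(chain_lengths) exceeds n")
      for (L in chain_lengths) {
        d0 <- unitize(rnorm(3))
        t0 <- rnorm(3)
        t0 <- unitize(t0 - sum(t0 * d0) * d0)
        dth <- chain_spacing / (radius + standoff)
        first <- nrow(centers) + 1L
        for (k in seq_len(L) - 1L) {
          th <- k * dth
          dk <- cos(th) * d0 + sin(th) * t0
          tk <- -sin(th) * d0 + cos(th) * t0
          ang <- chain_pose(dk, tk, offsets)
          centers <- rbind(centers, dk * (radius + standoff))
          normals <- rbind(normals, dk)
          angles <- rbind(angles, ang)
          labels <- c(labels, "import_oriented")
        }
        chains[[length(chains) + 1L]] <- seq.int(first, nrow(centers))
      }
      n_rest <- n - sum(chain_lengths)
      if (n_rest > 0) {
        sp <- sample_surface_points(omm, n_rest, region = region)
        for (i in seq_len(n_rest))
          emit(sp$points[i, ], sp$normals[i, ], FALSE)
      }
    } else {
      n_import <- round(n * import_fraction)
      import_flag <- rep(FALSE, n)
      if (n_import > 0) import_flag[sample.int(n, n_import)] <- TRUE
      if (mode == "csr") {
        sp <- sample_surface_points(omm, n, region = region)
        pts <- sp$points
        nrm <- sp$normals
      } else {
        sigma <- cluster_scale * 10 # nm -> A
        n_parents <- max(1L, round(n / offspring_mean))
        par <- sample_surface_points(omm, n_parents, region = region)
        assign_to <- sample.int(n_parents, n, replace = TRUE)
        pts <- matrix(0, n, 3)
        nrm <- matrix(0, n, 3)
        for (i in seq_len(n)) {
          p <- par$points[assign_to[i], ]
          d <- unitize(p)
          # tangential Gaussian displacement, reprojected radially
          e1 <- unitize(if (abs(d[1]) < 0.9) c(1, 0, 0) - d[1] * d
                        else c(0, 1, 0) - d[2] * d)
          e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
                  d[1] * e1[2] - d[2] * e1[1])
          q <- p + rnorm(1, 0, sigma) * e1 + rnorm(1, 0, sigma) * e2
          dq <- unitize(q)
          pts[i, ] <- dq * radius
          nrm[i, ] <- dq
        }
      }
      for (i in seq_len(n)) emit(pts[i, ], nrm[i, ], import_flag[i])
    }

    particles <- particle_table(centers, angles,
                                tomogram_id = omm$tomogram_id,
                                truth_label = labels)
    truth <- list(
      labels = labels, chains = chains,
      params = list(n = n, import_fraction = import_fraction, mode = mode,
                    cluster_scale = cluster_scale,
                    chain_lengths = if (mode == "chains") chain_lengths
                                    else integer(0),
                    chain_spacing = chain_spacing, standoff = standoff),
      seed = seed
    )
    list(particles = particles, truth = truth)
  })
}

# pose for a chain member: exit axis to the membrane, mRNA entry axis (+x)
# along the chain tangent so each entry faces the next member's exit
chain_pose <- function(dir, tangent, offsets) {
  z_t <- -unitize(dir)
  x_t <- unitize(tangent - sum(tangent * z_t) * z_t)
  y_t <- c(z_t[2] * x_t[3] - z_t[3] * x_t[2],
           z_t[3] * x_t[1] - z_t[1] * x_t[3],
           z_t[1] * x_t[2] - z_t[2] * x_t[1])
  R0 <- cbind(x_t, y_t, z_t)
  B <- rotation_between(offsets$exit_direction, c(0, 0, 1))
  matrix_to_euler(R0 %*% B)
}
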