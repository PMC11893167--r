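# Indexed triangle mesh with per-triangle derived attributes and named
# label sets -- the stand-in for the attributed membrane meshes produced by
# surface-morphometrics pipelines.

#' Construct a triangle surface
#'
#' An indexed triangle mesh carrying, per triangle, its centroid, unit
#' normal and area, plus named boolean label sets over triangles (e.g.
#' `"crista_associated"`). Degenerate (zero-area) faces are dropped with a
#' message. For closed surfaces normals can be oriented consistently outward
#' with `orient = TRUE` (enforces positive signed volume).
#'
#' @param vertices n x 3 numeric matrix (Angstrom).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param surface_id Token such as `"OMM"`, `"IMM"`, `"ER"`.
#' @param tomogram_id Token naming the tomogram the mesh belongs to.
#' @param labels Named list of logical vectors (length = number of faces).
#' @param orient Re-orient face winding so the signed volume is positive
#'   (sensible for closed surfaces only).
#' @return An object of class `triangle_surface`.
#' @export
triangle_surface <- function(vertices, faces, surface_id = "OMM",
                             tomogram_id = "tomo_1", labels = list(),
                             orient = FALSE) {
  V <- as_xyz(vertices, "vertices")
  F <- as.matrix(faces)
  if (ncol(F) != 3L) stopf("faces must have 3 columns")
  storage.mode(F) <- "integer"
  if (nrow(F) > 0 && (min(F) < 1L || max(F) > nrow(V)))
    stopf("faces index vertices outside 1..%d", nrow(V))

  geom <- face_geometry(V, F)
  degen <- geom$area <= 0 | !is.finite(geom$area)
  if (any(degen)) {
    message(sprintf("dropping %d degenerate (zero-area) triangle(s)",
                    sum(degen)))
    F <- F[!degen, , drop = FALSE]
    labels <- lapply(labels, function(l) l[!degen])
    geom <- face_geometry(V, F)
  }

  s <- structure(list(
    vertices = V, faces = F,
    centroids = geom$centroid, normals = geom$normal, areas = geom$area,
    labels = labels, surface_id = surface_id, tomogram_id = tomogram_id
  ), class = "triangle_surface")

  if (orient && mesh_signed_volume(s) < 0) {
    s$faces <- F[, c(1L, 3L, 2L), drop = FALSE]
    geom <- face_geometry(V, s$faces)
    s$centroids <- geom$centroid; s$normals <- geom$normal
    s$areas <- geom$area
  }
  for (nm in names(labels))
    if (length(labels[[nm]]) != nrow(s$faces))
      stopf("label '%s' length differs from face count", nm)
  s
}

face_geometry <- function(V, F) {
  m <- nrow(F)
  if (m == 0L)
    return(list(centroid = matrix(0, 0, 3), normal = matrix(0, 0, 3),
                area = numeric(0)))
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c0 <- V[F[, 3], , drop = FALSE]
  cen <- (a + b + c0) / 3
  e1 <- b - a; e2 <- c0 - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- rownorms(cr)
  area <- nrm / 2
  unit <- cr / ifelse(nrm > 0, nrm, 1)
  list(centroid = cen, normal = unit, area = area)
}

#' @export
print.triangle_surface <- function(x, ...) {
  cat(sprintf("<triangle_surface> %s / %s: %d vertices, %d faces, area %.4g A^2\n",
              x$tomogram_id, x$surface_id, nrow(x$vertices), nrow(x$faces),
              sum(x$areas)))
  if (length(x$labels))
    cat("  labels:", paste(sprintf("%s (%d)", names(x$labels),
                                   vapply(x$labels, sum, 0L)),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Signed volume of a (closed) triangle mesh
#'
#' Sum of signed tetrahedron volumes against the origin; positive when face
#' winding / normals are consistently outward.
#'
#' @param surface A [triangle_surface()].
#' @return Signed volume in cubic Angstrom.
#' @export
mesh_signed_volume <- function(surface) {
  V <- surface$vertices; F <- surface$faces
  if (nrow(F) == 0L) return(0)
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c0 <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c0[, 3] - b[, 3] * c0[, 2]) -
      a[, 2] * (b[, 1] * c0[, 3] - b[, 3] * c0[, 1]) +
      a[, 3] * (b[, 1] * c0[, 2] - b[, 2] * c0[, 1])) / 6
}

#' Set or replace a triangle label set
#'
#' @param surface A [triangle_surface()].
#' @param name Label name.
#' @param members Logical vector over faces, or integer vector of face ids.
#' @return The surface with the label attached.
#' @export
set_label <- function(surface, name, members) {
  m <- nrow(surface$faces)
  if (is.logical(members)) {
    if (length(members) != m) stopf("logical label must have length %d", m)
    l <- members
  } else {
    l <- rep(FALSE, m)
    l[as.integer(members)] <- TRUE
  }
  surface$labels[[name]] <- l
  surface
}

#' Face adjacency over shared edges
#'
#' @param surface A [triangle_surface()].
#' @return List of integer vectors: for each face, the faces sharing an edge.
#' @export
face_adjacency <- function(surface) {
  F <- surface$faces
  m <- nrow(F)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  face <- rep(seq_len(m), 3L)
  grp <- split(face, key)
  adj <- vector("list", m)
  for (g in grp) {
    if (length(g) < 2L) next
    for (f in g) adj[[f]] <- c(adj[[f]], setdiff(g, f))
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Connected components of a face subset
#'
#' @param surface A [triangle_surface()].
#' @param members Logical vector or face ids defining the subset.
#' @param adjacency Optional precomputed [face_adjacency()].
#' @return Integer vector over faces: component id (0 outside the subset).
#' @export
label_components <- function(surface, members, adjacency = NULL) {
  m <- nrow(surface$faces)
  inset <- if (is.logical(members)) members else {
    l <- rep(FALSE, m); l[as.integer(members)] <- TRUE; l
  }
  if (is.null(adjacency)) adjacency <- face_adjacency(surface)
  comp <- integer(m)
  cur <- 0L
  for (start in which(inset)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      f <- queue[1L]; queue <- queue[-1L]
      nb <- adjacency[[f]]
      nb <- nb[inset[nb] & comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# ---- icosphere -------------------------------------------------------------

# unit icosahedron, consistently wound outward
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  V <- V / rownorms(V)
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(V = V, F = F)
}

subdivide_once <- function(V, F) {
  nv <- nrow(V)
  nf <- nrow(F)
  # each edge is shared by two faces on a closed mesh: 3*nf/2 new vertices
  Vout <- rbind(V, matrix(0, nf * 3L, 3L))
  mid <- new.env(parent = emptyenv())
  get_mid <- function(i, j) {
    k <- paste(min(i, j), max(i, j))
    id <- mid[[k]]
    if (!is.null(id)) return(id)
    p <- (Vout[i, ] + Vout[j, ]) / 2
    nv <<- nv + 1L
    Vout[nv, ] <<- p / vnorm(p)
    assign(k, nv, envir = mid)
    nv
  }
  newF <- matrix(0L, nf * 4L, 3L)
  r <- 0L
  for (f in seq_len(nf)) {
    a <- F[f, 1]; b <- F[f, 2]; c0 <- F[f, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, c0); ca <- get_mid(c0, a)
    newF[r + 1L, ] <- c(a, ab, ca)
    newF[r + 2L, ] <- c(b, bc, ab)
    newF[r + 3L, ] <- c(c0, ca, bc)
    newF[r + 4L, ] <- c(ab, bc, ca)
    r <- r + 4L
  }
  list(V = Vout[seq_len(nv), , drop = FALSE], F = newF)
}

.icosphere_cache <- new.env(parent = emptyenv())

# unit icosphere at a subdivision level (20 * 4^level faces), memoised
unit_icosphere <- function(level = 4L) {
  key <- as.character(level)
  got <- .icosphere_cache[[key]]
  if (!is.null(got)) return(got)
  m <- icosahedron()
  for (i in seq_len(level)) m <- subdivide_once(m$V, m$F)
  .icosphere_cache[[key]] <- m
  m
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere -- the mesh primitive the
#' synthetic scene generator builds membranes from. `20 * 4^level` faces.
#'
#' @param radius Sphere radius (Angstrom).
#' @param level Subdivision level (default 4, 5120 faces).
#' @param center Sphere center (Angstrom).
#' @param ... Passed to [triangle_surface()] (e.g. `surface_id`).
#' @return A [triangle_surface()] with outward normals.
#' @export
icosphere <- function(radius, level = 4L, center = c(0, 0, 0), ...) {
  m <- unit_icosphere(level)
  V <- m$V * radius
  V <- sweep(V, 2, as.numeric(center), "+")
  triangle_surface(V, m$F, orient = TRUE, ...)
}
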