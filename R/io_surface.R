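# STL mesh I/O plus a per-triangle CSV attribute sidecar. The sidecar carries
# what the original attributed-mesh container would: recomputed normals,
# areas, and named boolean label sets, keyed by triangle index. STL stores no
# shared vertex indexing, so vertices are welded on read (exact coordinate
# match) to recover an indexed mesh.

#' Read a surface mesh from STL (binary or ASCII)
#'
#' Vertices are welded by exact coordinate match; per-triangle centroid,
#' normal and area are recomputed (recomputed normals override any normals
#' stored in the file). Degenerate triangles are dropped with a message. When
#' a sidecar CSV is given, its label columns are attached to the surface.
#'
#' @param stl_path Path to an STL file.
#' @param sidecar_path Optional per-triangle attribute CSV written by
#'   [write_surface()].
#' @param ... Passed to [triangle_surface()] (`surface_id`, `tomogram_id`,
#'   `orient`).
#' @return A [triangle_surface()].
#' @export
read_surface <- function(stl_path, sidecar_path = NULL, ...) {
  if (!file.exists(stl_path)) stopf("no such file: %s", stl_path)
  tri <- if (is_binary_stl(stl_path)) read_stl_binary(stl_path)
         else read_stl_ascii(stl_path)
  nv <- nrow(tri) / 3L
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "/")
  uid <- match(key, key[!duplicated(key)])
  V <- tri[!duplicated(key), , drop = FALSE]
  F <- matrix(uid, ncol = 3L, byrow = TRUE)
  s <- triangle_surface(V, F, ...)
  if (!is.null(sidecar_path)) {
    sc <- read.csv(sidecar_path, check.names = FALSE)
    if (nrow(sc) != nrow(s$faces))
      stopf("sidecar has %d rows but surface has %d triangles",
            nrow(sc), nrow(s$faces))
    for (col in setdiff(names(sc),
                        c("triangle", "nx", "ny", "nz", "area"))) {
      v <- sc[[col]]
      if (is.logical(v) || all(v %in% c(0, 1, NA)))
        s$labels[[col]] <- as.logical(v)
    }
  }
  s
}

#' Write a surface mesh to STL plus an attribute sidecar
#'
#' @param surface A [triangle_surface()].
#' @param stl_path Output STL path.
#' @param sidecar_path Optional output CSV with per-triangle normals, areas
#'   and label sets.
#' @param binary Write binary STL (default) or ASCII.
#' @return Invisibly, `stl_path`.
#' @export
write_surface <- function(surface, stl_path, sidecar_path = NULL,
                          binary = TRUE) {
  V <- surface$vertices; F <- surface$faces
  if (binary) write_stl_binary(V, F, surface$normals, stl_path)
  else write_stl_ascii(V, F, surface$normals, stl_path)
  if (!is.null(sidecar_path)) {
    sc <- data.frame(triangle = seq_len(nrow(F)),
                     nx = surface$normals[, 1], ny = surface$normals[, 2],
                     nz = surface$normals[, 3], area = surface$areas)
    for (nm in names(surface$labels)) sc[[nm]] <- surface$labels[[nm]]
    write.csv(sc, sidecar_path, row.names = FALSE)
  }
  invisible(stl_path)
}

is_binary_stl <- function(path) {
  sz <- file.info(path)$size
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  # binary iff the declared triangle count matches the file size
  sz == 84 + 50 * as.numeric(ntri)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  out <- matrix(0, ntri * 3L, 3L)
  for (i in seq_len(ntri)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    out[3L * i - 2L, ] <- rec[4:6]
    out[3L * i - 1L, ] <- rec[7:9]
    out[3L * i, ] <- rec[10:12]
    readBin(con, "raw", 2)
  }
  out
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L) stopf("truncated ASCII STL: %s", path)
  toks <- strsplit(trimws(vl), "\\s+")
  bad <- which(vapply(toks, length, 0L) != 4L)
  if (length(bad)) stopf("malformed vertex line in %s", path)
  matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))), ncol = 3L, byrow = TRUE)
}

write_stl_binary <- function(V, F, N, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(F))) {
    rec <- c(N[i, ], V[F[i, 1], ], V[F[i, 2], ], V[F[i, 3], ])
    writeBin(rec, con, size = 4, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
  invisible(path)
}

write_stl_ascii <- function(V, F, N, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid surface", con)
  for (i in seq_len(nrow(F))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                       N[i, 1], N[i, 2], N[i, 3]), con)
    writeLines("    outer loop", con)
    for (k in 1:3) {
      v <- V[F[i, k], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]),
                 con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid surface", con)
  invisible(path)
}
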