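# Star-dialect particle tables: the loop_ block format used by
# subtomogram-averaging software, with rlnCoordinateX/Y/Z (pixels) and
# rlnAngleRot/Tilt/Psi (degrees) columns. Only coordinates, angles,
# tomogram names and an optional truth label are consumed; optics/CTF
# blocks are ignored.

particle_cols <- c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
                   "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi")

#' Construct a particle table
#'
#' Per-particle poses: center (Angstrom, tomogram frame) and ZYZ Euler
#' triple (degrees), with the tomogram id and an optional ground-truth label.
#'
#' @param center n x 3 matrix of centers (Angstrom).
#' @param angles n x 3 matrix of Euler triples (rot, tilt, psi; degrees).
#' @param tomogram_id Token (recycled) naming the source tomogram.
#' @param truth_label Optional per-particle token (synthetic scenes).
#' @return A `data.frame` of class `particle_table` with columns `x, y, z,
#'   rot, tilt, psi, tomogram_id` (+ `truth_label`).
#' @export
particle_table <- function(center, angles, tomogram_id = "tomo_1",
                           truth_label = NULL) {
  ctr <- as_xyz(center, "center")
  ang <- as_xyz(angles, "angles")
  if (nrow(ctr) != nrow(ang)) stopf("center and angles row counts differ")
  if (!all(is.finite(ctr))) stopf("non-finite particle coordinates")
  df <- data.frame(x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                   rot = ang[, 1], tilt = ang[, 2], psi = ang[, 3],
                   tomogram_id = rep_len(tomogram_id, nrow(ctr)))
  if (!is.null(truth_label)) df$truth_label <- rep_len(truth_label, nrow(ctr))
  class(df) <- c("particle_table", "data.frame")
  df
}

particle_centers <- function(p) as.matrix(p[, c("x", "y", "z")])
particle_angles <- function(p) as.matrix(p[, c("rot", "tilt", "psi")])

#' @export
print.particle_table <- function(x, ...) {
  cat(sprintf("<particle_table> %d particle(s) in %d tomogram(s)\n",
              nrow(x), length(unique(x$tomogram_id))))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 5))
  invisible(x)
}

#' Read particles from a star-dialect file
#'
#' Parses the first `loop_` block containing the coordinate columns.
#' Coordinates are converted from pixels to Angstrom with `pixel_size`;
#' angle columns pass through in degrees; row order is preserved.
#'
#' @param path Star file path.
#' @param pixel_size Angstrom per pixel (one value per source file).
#' @return A [particle_table()].
#' @export
read_particles <- function(path, pixel_size = 1) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stopf("pixel_size must be a single positive number")
  blk <- read_star_block(path)
  cols <- blk$cols
  missing_cols <- setdiff(particle_cols, cols)
  if (length(missing_cols))
    stopf("star file %s is missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  get <- function(nm) {
    v <- blk$data[[match(nm, cols)]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num) && !anyNA(v))
      stopf("non-numeric value in column %s at row %d of %s", nm,
            which(is.na(num))[1], path)
    num
  }
  if (length(blk$data[[1]]) == 0L)
    return(particle_table(matrix(0, 0, 3), matrix(0, 0, 3)))
  ctr <- cbind(get("rlnCoordinateX"), get("rlnCoordinateY"),
               get("rlnCoordinateZ")) * pixel_size
  ang <- cbind(get("rlnAngleRot"), get("rlnAngleTilt"), get("rlnAnglePsi"))
  tomo <- if ("rlnTomoName" %in% cols) blk$data[[match("rlnTomoName", cols)]]
          else "tomo_1"
  truth <- if ("rlnTruthLabel" %in% cols)
    blk$data[[match("rlnTruthLabel", cols)]] else NULL
  particle_table(ctr, ang, tomogram_id = tomo, truth_label = truth)
}

#' Write particles to a star-dialect file
#'
#' Coordinates are converted from Angstrom back to pixels with `pixel_size`.
#'
#' @param particles A [particle_table()].
#' @param path Output path.
#' @param pixel_size Angstrom per pixel.
#' @return Invisibly, `path`.
#' @export
write_particles <- function(particles, path, pixel_size = 1) {
  cols <- c(particle_cols, "rlnTomoName")
  mat <- cbind(
    format(particle_centers(particles) / pixel_size, digits = 10,
           trim = TRUE, scientific = FALSE),
    format(particle_angles(particles), digits = 10, trim = TRUE,
           scientific = FALSE),
    particles$tomogram_id
  )
  if (!is.null(particles$truth_label)) {
    cols <- c(cols, "rlnTruthLabel")
    mat <- cbind(mat, particles$truth_label)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "data_particles", "", "loop_",
               sprintf("_%s #%d", cols, seq_along(cols))), con)
  if (nrow(particles))
    writeLines(apply(mat, 1, paste, collapse = "\t"), con)
  invisible(path)
}

# minimal star parser: first loop_ block that carries the coordinate columns
read_star_block <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines, perl = FALSE)
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L
      cols <- character(0)
      while (j <= n && grepl("^\\s*_", lines[j])) {
        cols <- c(cols, sub("^\\s*_(\\S+).*$", "\\1", lines[j]))
        j <- j + 1L
      }
      rows <- character(0)
      while (j <= n && nzchar(trimws(lines[j])) &&
             !grepl("^\\s*(data_|loop_)", lines[j])) {
        rows <- c(rows, trimws(lines[j]))
        j <- j + 1L
      }
      if (all(c("rlnCoordinateX", "rlnCoordinateY") %in% cols) ||
          !any(grepl("^\\s*loop_\\s*$", lines[seq.int(j, length.out = max(0, n - j + 1))]))) {
        toks <- strsplit(rows, "\\s+")
        if (length(rows)) {
          nt <- vapply(toks, length, 0L)
          if (any(nt != length(cols)))
            stopf("star row %d has %d fields, expected %d (truncated file?)",
                  which(nt != length(cols))[1], nt[nt != length(cols)][1],
                  length(cols))
        }
        data <- lapply(seq_along(cols), function(k)
          vapply(toks, `[`, "", k))
        return(list(cols = cols, data = data))
      }
      i <- j
    } else i <- i + 1L
  }
  stopf("no loop_ block found in %s", path)
}
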