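# Stage 1: per-ribosome membrane context. For each particle: the minimum
# distance to the nearest OMM triangle (point-to-centroid), the three
# relative angles between the rotated body axes and that triangle's normal,
# the peptide-exit-tunnel position and its own nearest-OMM distance, and the
# orientation class:
#   import_oriented     exit_to_omm <= exit_cutoff (95 A default)
#   proximal_non_import otherwise, if center_to_omm <= proximity_cutoff (250 A)
#   background          otherwise

#' Compute per-ribosome membrane context records
#'
#' @param particles A [particle_table()] sharing the OMM's tomogram frame.
#' @param omm OMM [triangle_surface()].
#' @param offsets [body_frame_offsets()] giving the exit-tunnel position.
#' @param cfg [run_config()] holding `exit_cutoff` and `proximity_cutoff`.
#' @return A `context_records` data frame: one row per particle with
#'   `center_to_omm`, `angle_x/y/z` (degrees, in \[0, 90\]),
#'   `nearest_triangle_id`, `exit_to_omm`, `orientation_class`.
#' @export
compute_context <- function(particles, omm, offsets = body_frame_offsets(),
                            cfg = run_config()) {
  stopifnot(inherits(omm, "triangle_surface"))
  n <- nrow(particles)
  ctr <- particle_centers(particles)
  ang <- particle_angles(particles)

  if (n > 0) {
    bb <- apply(omm$vertices, 2, range)
    diam <- vnorm(bb[2, ] - bb[1, ])
    mid <- colMeans(bb)
    off <- rownorms(sweep(ctr, 2, mid))
    if (all(off > 10 * diam))
      warnf("all particles are > 10x the mesh bounding box away: frame mismatch?")
  }

  near <- if (n > 0) nearest_triangle(ctr, omm)
          else list(index = integer(0), distance = numeric(0))

  exit_pos <- if (n > 0)
    body_point_to_tomogram(ctr, ang, offsets$exit_tunnel) else ctr
  exit_near <- if (n > 0) nearest_triangle(exit_pos, omm)
               else list(distance = numeric(0))

  ax <- ay <- az <- numeric(n)
  for (i in seq_len(n)) {
    nrm <- omm$normals[near$index[i], ]
    ax[i] <- relative_angle(c(1, 0, 0), ang[i, ], nrm)
    ay[i] <- relative_angle(c(0, 1, 0), ang[i, ], nrm)
    az[i] <- relative_angle(c(0, 0, 1), ang[i, ], nrm)
  }

  cls <- ifelse(exit_near$distance <= cfg$exit_cutoff, "import_oriented",
         ifelse(near$distance <= cfg$proximity_cutoff, "proximal_non_import",
                "background"))

  df <- data.frame(
    particle_id = seq_len(n),
    tomogram_id = if (n > 0) particles$tomogram_id else character(0),
    center_to_omm = near$distance,
    angle_x = ax, angle_y = ay, angle_z = az,
    nearest_triangle_id = near$index,
    exit_to_omm = exit_near$distance,
    orientation_class = cls,
    stringsAsFactors = FALSE
  )
  attr(df, "exit_cutoff") <- cfg$exit_cutoff
  attr(df, "proximity_cutoff") <- cfg$proximity_cutoff
  class(df) <- c("context_records", "data.frame")
  df
}

#' @export
print.context_records <- function(x, ...) {
  cat(sprintf("<context_records> %d particle(s): %s\n", nrow(x),
              paste(sprintf("%s %d", names(table(x$orientation_class)),
                            table(x$orientation_class)), collapse = ", ")))
  invisible(x)
}

#' Summarize orientation classes
#'
#' Import fraction = n_import / (n_import + n_proximal_non_import), i.e. the
#' fraction of membrane-proximal ribosomes optimally oriented for import.
#' Reported per tomogram and pooled; a zero denominator yields `NA`, not 0.
#'
#' @param records `context_records` from [compute_context()] (may span
#'   several tomograms).
#' @return List with `pooled` (named counts + `import_fraction` +
#'   `import_percent`) and `per_tomogram` (data frame).
#' @export
summarize_classes <- function(records) {
  one <- function(df) {
    n_imp <- sum(df$orientation_class == "import_oriented")
    n_prox <- sum(df$orientation_class == "proximal_non_import")
    n_bg <- sum(df$orientation_class == "background")
    denom <- n_imp + n_prox
    frac <- if (denom > 0) n_imp / denom else NA_real_
    data.frame(n_import = n_imp, n_proximal_non_import = n_prox,
               n_background = n_bg, import_fraction = frac,
               import_percent = 100 * frac)
  }
  per <- do.call(rbind, lapply(split(as.data.frame(records),
                                     records$tomogram_id), one))
  if (!is.null(per)) per <- cbind(tomogram_id = rownames(per), per)
  rownames(per) <- NULL
  pooled <- one(as.data.frame(records))
  list(pooled = pooled, per_tomogram = per)
}

#' Import-class counts across a sweep of exit cutoffs
#'
#' Numeric stand-in for the visual cutoff calibration: class counts as the
#' exit cutoff moves across 0-120 Angstrom (default grid includes the 95 /
#' 110 / 120 values explored when the threshold was set).
#'
#' @param records `context_records` from [compute_context()].
#' @param cutoffs Exit cutoffs to evaluate (Angstrom).
#' @param proximity_cutoff Proximity rule held fixed (Angstrom).
#' @return Data frame with `cutoff`, `n_import`, `n_proximal_non_import`.
#' @export
sweep_exit_cutoff <- function(records, cutoffs = seq(0, 120, by = 5),
                              proximity_cutoff = attr(records,
                                                      "proximity_cutoff")) {
  if (is.null(proximity_cutoff)) proximity_cutoff <- 250
  out <- lapply(cutoffs, function(ct) {
    imp <- records$exit_to_omm <= ct
    prox <- !imp & records$center_to_omm <= proximity_cutoff
    data.frame(cutoff = ct, n_import = sum(imp),
               n_proximal_non_import = sum(prox))
  })
  do.call(rbind, out)
}
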