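# Intermembrane distance fields (OMM <-> IMM), crista-associated OMM
# detection from the crista-junction distance band, and per-patch distance
# histograms with peak extraction.

#' Per-triangle distance from one membrane to another
#'
#' `nearest-point`: distance from each source triangle centroid to the
#' nearest target centroid (k-d-tree-style query). `normal-cone`: distance
#' to the nearest target centroid lying within a half-angle cone around the
#' source triangle's normal (surface-morphometrics style); `NA` when no
#' target centroid falls in the cone within `max_range`. The cone axis
#' points along the source normal flipped `cone_direction`-ward: `"inward"`
#' (toward the enclosed side, for OMM -> IMM) or `"outward"` (for
#' IMM -> OMM).
#'
#' @param source,target [triangle_surface()]s in one tomogram frame.
#' @param method `"nearest-point"` or `"normal-cone"`.
#' @param cone_half_angle Cone half-angle in degrees (default 30).
#' @param cone_direction `"inward"` or `"outward"` (see above).
#' @param max_range Maximum search range for the cone method (Angstrom).
#' @return A `distance_field`: per-source-triangle distances (Angstrom,
#'   `NA` where undefined) plus a method tag.
#' @export
intermembrane_distance <- function(source, target,
                                   method = c("nearest-point",
                                              "normal-cone"),
                                   cone_half_angle = 30,
                                   cone_direction = c("inward", "outward"),
                                   max_range = 2000) {
  method <- match.arg(method)
  cone_direction <- match.arg(cone_direction)
  if (nrow(target$faces) == 0L) stopf("target surface is empty")
  if (method == "nearest-point") {
    d <- cpp_nearest_point(source$centroids, target$centroids)$distance
  } else {
    axis <- if (cone_direction == "inward") -source$normals
            else source$normals
    d <- cpp_cone_nearest(source$centroids, axis, target$centroids,
                          cos(cone_half_angle * pi / 180), max_range)
  }
  structure(list(distance = d, method = method,
                 source_id = source$surface_id,
                 target_id = target$surface_id,
                 tomogram_id = source$tomogram_id),
            class = "distance_field")
}

#' @export
print.distance_field <- function(x, ...) {
  ok <- is.finite(x$distance)
  cat(sprintf(
    "<distance_field> %s -> %s (%s): %d triangles, %d defined, median %.1f A\n",
    x$source_id, x$target_id, x$method, length(x$distance), sum(ok),
    if (any(ok)) median(x$distance[ok]) else NA))
  invisible(x)
}

#' Crista-associated OMM from the crista-junction distance band
#'
#' Three steps: (1) select IMM triangles whose IMM-to-OMM distance lies in
#' `cfg$cj_band` (default 18-30 nm, the crista-junction regime); (2)
#' project each selected IMM triangle to its nearest OMM triangle
#' ("CJ-projected OMM"); (3) expand by marking every OMM triangle within
#' `cfg$crista_expand` (default 15 nm, half a crista body width) of a
#' CJ-projected triangle. An optional minimum component area drops spurious
#' isolated CJ components (the stand-in for manual clean-up).
#'
#' @param omm,imm [triangle_surface()]s.
#' @param cfg [run_config()].
#' @param method Distance method for the band selection (default
#'   `"normal-cone"`, the surface-morphometrics-style full-surface map).
#' @param min_component_area Drop CJ-projected components smaller than this
#'   area (square Angstrom; 0 disables).
#' @return A `patch_labeling` whose `patch_member` is the crista-associated
#'   OMM set and whose `centers` are the CJ-projected triangles.
#' @export
crista_associated_omm <- function(omm, imm, cfg = run_config(),
                                  method = "normal-cone",
                                  min_component_area = 0) {
  band <- cfg$cj_band * 10 # nm -> A
  fld <- intermembrane_distance(imm, omm, method = method,
                                cone_direction = "outward")
  sel <- which(is.finite(fld$distance) & fld$distance >= band[1] &
               fld$distance <= band[2])
  if (!length(sel)) {
    warnf("no IMM triangle lies in the %g-%g nm CJ band", cfg$cj_band[1],
          cfg$cj_band[2])
    lab <- new_patch_labeling(omm, rep(FALSE, nrow(omm$faces)),
                              centers = integer(0),
                              radius = cfg$crista_expand * 10,
                              provenance = list(type = "crista", seed = NA))
    return(lab)
  }
  proj <- unique(cpp_nearest_point(imm$centroids[sel, , drop = FALSE],
                                   omm$centroids)$index)
  if (min_component_area > 0) {
    comp <- label_components(omm, proj)
    keep_comp <- which(vapply(seq_len(max(comp)), function(k)
      sum(omm$areas[comp == k]), 0) >= min_component_area)
    proj <- which(comp %in% keep_comp)
  }
  member <- cpp_within_radius(omm$centroids,
                              omm$centroids[proj, , drop = FALSE],
                              cfg$crista_expand * 10)
  member[proj] <- TRUE
  lab <- new_patch_labeling(omm, member, centers = sort(proj),
                            radius = cfg$crista_expand * 10,
                            provenance = list(type = "crista", seed = NA))
  lab
}

#' Distance histograms and peaks per patch set
#'
#' For each requested set (patch members, complement, whole surface) bins
#' the defined distances into `bins` equal-width bins over that set's own
#' \[min, max\] range and reports the peak: the center of the most populated
#' bin, ties resolved to the lower bin. Peaks are `NA` (flagged) for sets
#' with fewer than 2 defined distances.
#'
#' @param field A `distance_field` on the labeled surface.
#' @param labeling A `patch_labeling` on the same surface.
#' @param bins Bin count (default 100).
#' @param sets Which sets to histogram (default patch / complement / all).
#' @return Named list per set: `counts`, `breaks` (Angstrom), `peak`
#'   (Angstrom), `n`.
#' @export
patch_distance_histograms <- function(field, labeling, bins = 100,
                                      sets = c("patch", "complement",
                                               "all")) {
  if (length(field$distance) != length(labeling$patch_member))
    stopf("distance field and labeling cover different triangle counts")
  pick <- list(patch = labeling$patch_member,
               complement = labeling$complement_member,
               all = rep(TRUE, length(field$distance)))
  out <- list()
  for (nm in sets) {
    d <- field$distance[pick[[nm]]]
    d <- d[is.finite(d)]
    out[[nm]] <- histogram_peak(d, bins)
  }
  out
}

histogram_peak <- function(d, bins) {
  n <- length(d)
  if (n < 2)
    return(list(counts = integer(0), breaks = numeric(0), peak = NA_real_,
                n = n))
  rng <- range(d)
  if (rng[1] == rng[2]) # all values identical: one occupied bin at d
    return(list(counts = n, breaks = rng[1] + c(-0.5, 0.5),
                peak = rng[1], n = n))
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- pmin(pmax(findInterval(d, breaks, rightmost.closed = TRUE), 1L),
              bins)
  counts <- tabulate(idx, nbins = bins)
  top <- which.max(counts) # which.max takes the first (lower) tie
  peak <- (breaks[top] + breaks[top + 1]) / 2
  list(counts = counts, breaks = breaks, peak = peak, n = n)
}
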