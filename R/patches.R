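# Stages 3-4: ribosome-associated OMM patches (150 A around the OMM
# triangles nearest to import-oriented ribosomes), a count- and spacing-
# matched randomized null, crista-associated OMM from the 18-30 nm CJ band,
# the overlap-fraction statistic, and per-patch OMM-IMM distance histograms.

#' Build OMM patches around seed triangles
#'
#' `patch_member` = seed triangles plus every triangle whose centroid lies
#' within `radius` (Euclidean, inclusive) of any seed centroid; the
#' complement is the rest of the surface. Patch radius is Euclidean between
#' centroids, not geodesic.
#'
#' @param seed_ids Seed triangle ids (typically the nearest OMM triangles of
#'   import-oriented ribosomes). Duplicates are collapsed.
#' @param omm OMM [triangle_surface()].
#' @param radius Patch radius (Angstrom; default 150).
#' @return A `patch_labeling`: logical `patch_member` / `complement_member`
#'   over triangles, `centers`, per-set areas, and provenance.
#' @export
build_patches <- function(seed_ids, omm, radius = 150) {
  m <- nrow(omm$faces)
  seed_ids <- sort(unique(as.integer(seed_ids)))
  if (length(seed_ids) && (min(seed_ids) < 1L || max(seed_ids) > m))
    stopf("seed ids outside 1..%d", m)
  member <- rep(FALSE, m)
  if (length(seed_ids)) {
    member <- cpp_within_radius(omm$centroids,
                                omm$centroids[seed_ids, , drop = FALSE],
                                radius)
    member[seed_ids] <- TRUE
  }
  new_patch_labeling(omm, member, centers = seed_ids, radius = radius,
                     provenance = list(type = "observed", seed = NA))
}

new_patch_labeling <- function(surface, member, centers, radius,
                               provenance) {
  structure(list(
    surface_id = surface$surface_id, tomogram_id = surface$tomogram_id,
    patch_member = member, complement_member = !member,
    centers = centers, radius = radius,
    triangle_areas = surface$areas,
    areas = c(patch = sum(surface$areas[member]),
              complement = sum(surface$areas[!member])),
    provenance = provenance
  ), class = "patch_labeling")
}

#' @export
print.patch_labeling <- function(x, ...) {
  cat(sprintf(
    "<patch_labeling> %s/%s (%s): %d centers, %d member / %d complement triangles, areas %.4g / %.4g A^2\n",
    x$tomogram_id, x$surface_id, x$provenance$type, length(x$centers),
    sum(x$patch_member), sum(x$complement_member), x$areas["patch"],
    x$areas["complement"]))
  invisible(x)
}

#' Randomized patches matched to an observed labeling
#'
#' Draws the same number of center triangles area-weighted uniformly on the
#' surface, rejecting any draw in which two centers are `<= min_spacing`
#' apart (the constraint is strict: centers must be > 150 A apart), then
#' builds patches with the observed radius.
#'
#' @param observed A `patch_labeling` from [build_patches()].
#' @param omm The same OMM [triangle_surface()].
#' @param seed Seed recorded in the provenance.
#' @param min_spacing Pairwise center spacing that must be exceeded
#'   (Angstrom; default 150).
#' @param max_attempts Rejection-sampling budget.
#' @return A `patch_labeling` with provenance `randomized`.
#' @export
randomize_patches <- function(observed, omm, seed = 1L, min_spacing = 150,
                              max_attempts = 10000) {
  k <- length(observed$centers)
  if (k < 1) stopf("observed labeling has no patch centers")
  m <- nrow(omm$faces)
  with_seed(seed, {
    for (att in seq_len(max_attempts)) {
      ctr <- sample.int(m, k, replace = FALSE, prob = omm$areas)
      if (k == 1L || all(stats::dist(omm$centroids[ctr, , drop = FALSE]) >
                         min_spacing)) {
        lab <- build_patches(ctr, omm, radius = observed$radius)
        lab$provenance <- list(type = "randomized", seed = seed)
        return(lab)
      }
    }
    stopf("could not place %d centers > %.0f A apart in %d attempts: packing limit",
          k, min_spacing, max_attempts)
  })
}

#' Overlap fraction between two OMM triangle label sets
#'
#' `area(ribo intersect crista) / area(ribo)`; in \[0, 1\], `NA` when the
#' ribosome-associated set has zero area.
#'
#' @param ribo_patches Ribosome-associated `patch_labeling`.
#' @param crista Crista-associated `patch_labeling` on the same surface.
#' @return Overlap fraction.
#' @export
overlap_fraction <- function(ribo_patches, crista) {
  if (!identical(ribo_patches$surface_id, crista$surface_id) ||
      !identical(ribo_patches$tomogram_id, crista$tomogram_id) ||
      length(ribo_patches$patch_member) != length(crista$patch_member))
    stopf("labelings come from different surfaces")
  ar <- ribo_patches$triangle_areas
  denom <- sum(ar[ribo_patches$patch_member])
  if (denom <= 0) return(NA_real_)
  sum(ar[ribo_patches$patch_member & crista$patch_member]) / denom
}
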