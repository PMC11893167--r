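# Run configuration: every threshold the pipeline applies, in one place,
# serialisable to JSON so a run's parameters travel with its outputs.

#' Pipeline run configuration
#'
#' Thresholds and grids for every analysis stage. Lengths are Angstrom
#' unless the name says nm.
#'
#' @param exit_cutoff Max peptide-exit-to-OMM distance for the
#'   import-oriented class (Angstrom; default 95).
#' @param proximity_cutoff Max center-to-OMM distance for the proximal
#'   (membrane-associated) population (Angstrom; default 250).
#' @param patch_radius Radius around seed triangles defining
#'   ribosome-associated OMM patches (Angstrom; default 150).
#' @param cj_band IMM-to-OMM distance band selecting crista-junction IMM
#'   triangles (nm; default `c(18, 30)`).
#' @param crista_expand Expansion radius around CJ-projected OMM triangles,
#'   half a crista body width (nm; default 15).
#' @param k_r_range Radius range for Ripley's K (nm; default `c(27, 166)`).
#' @param k_interval Interval width for K-ratio maxima (nm; default 10).
#' @param k_grid_n Number of radii in the K grid (default 140).
#' @param polysome_neighbor Max center-to-center neighbor distance for
#'   polysome links (nm; default 30).
#' @param adjacency_cutoff Max mRNA-entry-to-exit distance for "directly
#'   adjacent" sites (Angstrom; default 60).
#' @param histogram_bins Bin count for OMM-IMM distance histograms
#'   (default 100).
#' @param seed Integer seed driving every random draw of a run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(exit_cutoff = 95, proximity_cutoff = 250,
                       patch_radius = 150, cj_band = c(18, 30),
                       crista_expand = 15, k_r_range = c(27, 166),
                       k_interval = 10, k_grid_n = 140,
                       polysome_neighbor = 30, adjacency_cutoff = 60,
                       histogram_bins = 100, seed = 1L) {
  cfg <- list(exit_cutoff = exit_cutoff, proximity_cutoff = proximity_cutoff,
              patch_radius = patch_radius, cj_band = as.numeric(cj_band),
              crista_expand = crista_expand,
              k_r_range = as.numeric(k_r_range), k_interval = k_interval,
              k_grid_n = as.integer(k_grid_n),
              polysome_neighbor = polysome_neighbor,
              adjacency_cutoff = adjacency_cutoff,
              histogram_bins = as.integer(histogram_bins),
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  scalars <- c("exit_cutoff", "proximity_cutoff", "patch_radius",
               "k_interval", "polysome_neighbor", "adjacency_cutoff")
  for (nm in scalars)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      stopf("config field %s must be a single positive number", nm)
  if (!is.numeric(cfg$crista_expand) || cfg$crista_expand < 0)
    stopf("crista_expand must be >= 0 (0 disables the expansion)")
  for (nm in c("cj_band", "k_r_range")) {
    v <- cfg[[nm]]
    if (length(v) != 2L || v[1] <= 0 || v[1] >= v[2])
      stopf("config field %s must be an increasing positive (min, max) pair",
            nm)
  }
  if (cfg$histogram_bins < 1L) stopf("histogram_bins must be >= 1")
  if (cfg$k_grid_n < 2L) stopf("k_grid_n must be >= 2")
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = "-")))
  invisible(x)
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_config()` returns a [run_config()]; `write_config()`
#'   returns the path invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' @rdname read_config
#' @param cfg A [run_config()].
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Body-frame landmark offsets of the ribosome
#'
#' Positions, in the ribosome body frame (Angstrom), of the peptide exit
#' tunnel and the mRNA entry/exit sites, plus the unit axis pointing out of
#' the exit tunnel. The defaults put the exit tunnel 120 Angstrom from the
#' particle center along +z (so a ribosome standing 135 Angstrom off the
#' membrane with +z pointing at it has its exit ~15 Angstrom above the
#' surface), and the mRNA entry/exit sites on opposite flanks along x.
#'
#' @param exit_tunnel Peptide exit tunnel offset (Angstrom).
#' @param mrna_entry 3' mRNA entry site offset (Angstrom).
#' @param mrna_exit 5' mRNA exit site offset (Angstrom).
#' @param exit_direction Unit body axis of the exit tunnel.
#' @return A list of class `body_frame_offsets`.
#' @export
body_frame_offsets <- function(exit_tunnel = c(0, 0, 120),
                               mrna_entry = c(125, 0, 40),
                               mrna_exit = c(-125, 0, 40),
                               exit_direction = c(0, 0, 1)) {
  if (!all(is.finite(c(exit_tunnel, mrna_entry, mrna_exit))))
    stopf("offsets must be finite")
  structure(list(exit_tunnel = as.numeric(exit_tunnel),
                 mrna_entry = as.numeric(mrna_entry),
                 mrna_exit = as.numeric(mrna_exit),
                 exit_direction = unitize(as.numeric(exit_direction),
                                          "exit_direction")),
            class = "body_frame_offsets")
}
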