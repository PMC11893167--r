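# Orchestration: classify -> cluster -> patches -> polysomes per tomogram,
# then study-level statistics on the per-tomogram quantities (interval
# maxima, overlap fractions, distance peaks), mirroring per-tomogram
# violin-plot quantification rather than pooling particles.

#' Analyse one scene (tomogram)
#'
#' Runs all pipeline stages on one OMM/IMM mesh pair plus its particle
#' table and returns every per-tomogram quantity the study-level statistics
#' need.
#'
#' @param omm,imm [triangle_surface()]s for the tomogram.
#' @param particles A [particle_table()].
#' @param offsets [body_frame_offsets()].
#' @param cfg [run_config()].
#' @param n_resamples Resamples for the K null (default 50).
#' @param standoff Shell height for the K null (Angstrom): where particle
#'   centers sit relative to the membrane (default 135).
#' @param seed Seed for this tomogram's random stages (K null,
#'   randomized patches).
#' @return A list with `records`, `class_summary`, `k_import` /
#'   `k_nonimport` ([k_curve()]s or NULL), `interval_max_import` /
#'   `interval_max_nonimport`, `patches` / `patches_nonimport` /
#'   `patches_random` / `crista`, `overlap` (named fractions), `omm_imm`
#'   (distance field), `histograms`, `peaks` (named Angstrom values),
#'   `chains`, `chain_table`.
#' @export
analyze_scene <- function(omm, imm, particles,
                          offsets = body_frame_offsets(),
                          cfg = run_config(), n_resamples = 50,
                          standoff = 135, seed = cfg$seed) {
  rec <- compute_context(particles, omm, offsets, cfg)
  cls <- summarize_classes(rec)
  imp <- rec$orientation_class == "import_oriented"
  prox <- rec$orientation_class == "proximal_non_import"
  ctr <- particle_centers(particles)

  kcurve_for <- function(sel, label, sub_seed) {
    if (sum(sel) < 2) return(NULL)
    k_curve(ctr[sel, , drop = FALSE], omm, cfg, n_resamples = n_resamples,
            standoff = standoff, class_label = label, seed = sub_seed)
  }
  k_imp <- kcurve_for(imp, "import_oriented", seed + 1L)
  k_non <- kcurve_for(prox, "proximal_non_import", seed + 2L)

  patches <- patches_non <- patches_rand <- crista <- NULL
  overlap <- c(import = NA_real_, non_import = NA_real_,
               randomized = NA_real_)
  peaks <- c(patch = NA_real_, complement = NA_real_, all = NA_real_,
             randomized = NA_real_)
  hist_list <- NULL
  omm_imm <- intermembrane_distance(omm, imm, method = "nearest-point")
  crista <- crista_associated_omm(omm, imm, cfg)

  if (any(imp)) {
    patches <- build_patches(rec$nearest_triangle_id[imp], omm,
                             radius = cfg$patch_radius)
    patches_rand <- randomize_patches(patches, omm, seed = seed + 3L,
                                      min_spacing = cfg$patch_radius)
    overlap["import"] <- overlap_fraction(patches, crista)
    overlap["randomized"] <- overlap_fraction(patches_rand, crista)
    hist_list <- patch_distance_histograms(omm_imm, patches,
                                           bins = cfg$histogram_bins)
    hr <- patch_distance_histograms(omm_imm, patches_rand,
                                    bins = cfg$histogram_bins,
                                    sets = "patch")
    peaks["patch"] <- hist_list$patch$peak
    peaks["complement"] <- hist_list$complement$peak
    peaks["all"] <- hist_list$all$peak
    peaks["randomized"] <- hr$patch$peak
  }
  if (any(prox)) {
    patches_non <- build_patches(rec$nearest_triangle_id[prox], omm,
                                 radius = cfg$patch_radius)
    overlap["non_import"] <- overlap_fraction(patches_non, crista)
  }

  chains <- detect_chains(particles[imp, , drop = FALSE], offsets, cfg)

  list(records = rec, class_summary = cls,
       k_import = k_imp, k_nonimport = k_non,
       interval_max_import = if (!is.null(k_imp))
         interval_maxima(k_imp, cfg$k_interval) else NULL,
       interval_max_nonimport = if (!is.null(k_non))
         interval_maxima(k_non, cfg$k_interval) else NULL,
       patches = patches, patches_nonimport = patches_non,
       patches_random = patches_rand, crista = crista,
       overlap = overlap, omm_imm = omm_imm, histograms = hist_list,
       peaks = peaks, chains = chains, chain_table = chain_report(chains))
}

#' Run the full pipeline over simulated tomograms
#'
#' Generates `n_tomograms` synthetic scenes from one configuration, runs
#' [analyze_scene()] on each, writes per-tomogram CSVs (context records, a
#' filtered star table of import-oriented particles, K curves, interval
#' maxima, chain tables) plus study-level tables and a JSON summary
#' (class counts and import fraction; interval-maxima comparison with
#' Mann-Whitney p; overlap fractions for the import / non-import /
#' randomized sets with p-values; distance peaks per patch class with
#' p-values; polysome count and end-to-end range). Fully deterministic
#' under a fixed config seed.
#'
#' @param config A list (or JSON path) with optional elements `cfg` (fields
#'   for [run_config()]), `scene` (fields for [make_mitochondrion()]:
#'   `radius`, `spacing`, `n_cj_wells`, `level`), `decorate` (fields for
#'   [decorate_particles()]: `n`, `import_fraction`, `mode`,
#'   `cluster_scale`), `n_tomograms` (default 3), `n_resamples` (default
#'   20).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the summary list (also written to
#'   `summary.json`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- do.call(run_config,
                 as.list(config$cfg)[intersect(names(config$cfg),
                                               names(formals(run_config)))])
  scene_args <- as.list(config$scene)
  deco_args <- as.list(config$decorate)
  n_tomo <- if (!is.null(config$n_tomograms)) config$n_tomograms else 3L
  n_res <- if (!is.null(config$n_resamples)) config$n_resamples else 20L
  offsets <- body_frame_offsets()

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat(sprintf("ribomesh pipeline run, seed %d\n", cfg$seed),
      file = log_path)
  logf("thresholds in force:")
  for (nm in names(cfg)) logf("  %s = %s", nm,
                              paste(cfg[[nm]], collapse = "-"))

  per_tomo <- list()
  for (t in seq_len(n_tomo)) {
    tomo_id <- sprintf("tomo_%03d", t)
    tomo_seed <- cfg$seed + 1000L * t
    sa <- scene_args
    sa$seed <- tomo_seed
    sa$tomogram_id <- tomo_id
    scene <- do.call(make_mitochondrion, sa)
    da <- deco_args
    da$omm <- scene$omm
    da$seed <- tomo_seed + 1L
    da$offsets <- offsets
    if (is.null(da$n)) da$n <- 150L
    deco <- do.call(decorate_particles, da)
    standoff <- deco$truth$params$standoff

    res <- analyze_scene(scene$omm, scene$imm, deco$particles, offsets,
                         cfg, n_resamples = n_res, standoff = standoff,
                         seed = tomo_seed + 2L)
    res$tomogram_id <- tomo_id
    per_tomo[[t]] <- res

    rec_path <- file.path(out_dir, sprintf("%s_context.csv", tomo_id))
    write_context_records(res$records, rec_path)
    manifest <- c(manifest, rec_path)
    imp <- res$records$orientation_class == "import_oriented"
    star_path <- file.path(out_dir, sprintf("%s_import.star", tomo_id))
    write_particles(deco$particles[imp, , drop = FALSE], star_path)
    manifest <- c(manifest, star_path)
    for (nm in c("k_import", "k_nonimport")) {
      if (is.null(res[[nm]])) next
      p <- file.path(out_dir, sprintf("%s_%s_kcurve.csv", tomo_id, nm))
      write.csv(as.data.frame(res[[nm]]), p, row.names = FALSE)
      manifest <- c(manifest, p)
    }
    ct_path <- file.path(out_dir, sprintf("%s_chains.csv", tomo_id))
    write.csv(res$chain_table, ct_path, row.names = FALSE)
    manifest <- c(manifest, ct_path)
    logf("%s: %d particles, %d import-oriented, %d chain(s)", tomo_id,
         nrow(res$records), sum(imp), length(res$chains))
  }

  # study-level tables: per-tomogram interval maxima, overlaps, peaks
  pull_interval <- function(field) {
    do.call(rbind, lapply(per_tomo, function(r) {
      im <- r[[field]]
      if (is.null(im)) return(NULL)
      cbind(tomogram_id = r$tomogram_id, im)
    }))
  }
  im_imp <- pull_interval("interval_max_import")
  im_non <- pull_interval("interval_max_nonimport")
  band <- function(im, lo) if (is.null(im)) numeric(0) else
    im$max_ratio[im$lo == lo & is.finite(im$max_ratio)]
  focus_lo <- 30
  mw_cluster <- if (length(band(im_imp, focus_lo)) &&
                    length(band(im_non, focus_lo)))
    mann_whitney_u(band(im_imp, focus_lo), band(im_non, focus_lo))
  else NULL

  ov <- do.call(rbind, lapply(per_tomo, function(r)
    data.frame(tomogram_id = r$tomogram_id, t(r$overlap))))
  pk <- do.call(rbind, lapply(per_tomo, function(r)
    data.frame(tomogram_id = r$tomogram_id, t(r$peaks))))
  ov_path <- file.path(out_dir, "overlap_fractions.csv")
  write.csv(ov, ov_path, row.names = FALSE)
  pk_path <- file.path(out_dir, "distance_peaks.csv")
  write.csv(pk, pk_path, row.names = FALSE)
  manifest <- c(manifest, ov_path, pk_path)
  if (!is.null(im_imp)) {
    p <- file.path(out_dir, "interval_maxima_import.csv")
    write.csv(im_imp, p, row.names = FALSE)
    manifest <- c(manifest, p)
  }
  if (!is.null(im_non)) {
    p <- file.path(out_dir, "interval_maxima_nonimport.csv")
    write.csv(im_non, p, row.names = FALSE)
    manifest <- c(manifest, p)
  }

  mw_or_null <- function(x, y) {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) && length(y)) mann_whitney_u(x, y) else NULL
  }
  mw_overlap <- mw_or_null(ov$import, ov$randomized)
  mw_overlap_non <- mw_or_null(ov$import, ov$non_import)
  mw_peaks <- mw_or_null(pk$patch, pk$complement)
  mw_peaks_rand <- mw_or_null(pk$randomized, pk$all)

  all_chains <- do.call(rbind, lapply(per_tomo, function(r) r$chain_table))
  pooled <- summarize_classes(do.call(rbind, lapply(per_tomo,
                                                    function(r)
                                                      as.data.frame(r$records))))

  pval <- function(mw) if (is.null(mw)) NA_real_ else mw$p_two_sided
  summary <- list(
    seed = cfg$seed,
    n_tomograms = n_tomo,
    class_counts = as.list(pooled$pooled[c("n_import",
                                           "n_proximal_non_import",
                                           "n_background")]),
    import_fraction = pooled$pooled$import_fraction,
    interval_max_30_40 = list(
      import_median = if (length(band(im_imp, focus_lo)))
        median(band(im_imp, focus_lo)) else NA_real_,
      nonimport_median = if (length(band(im_non, focus_lo)))
        median(band(im_non, focus_lo)) else NA_real_,
      p_mann_whitney = pval(mw_cluster)),
    overlap_fraction = list(
      import_mean = mean(ov$import, na.rm = TRUE),
      non_import_mean = mean(ov$non_import, na.rm = TRUE),
      randomized_mean = mean(ov$randomized, na.rm = TRUE),
      p_import_vs_randomized = pval(mw_overlap),
      p_import_vs_non_import = pval(mw_overlap_non)),
    distance_peaks = list(
      patch_median = median(pk$patch, na.rm = TRUE),
      complement_median = median(pk$complement, na.rm = TRUE),
      all_median = median(pk$all, na.rm = TRUE),
      randomized_median = median(pk$randomized, na.rm = TRUE),
      p_patch_vs_complement = pval(mw_peaks),
      p_randomized_vs_all = pval(mw_peaks_rand)),
    polysomes = list(
      n_chains = if (is.null(all_chains)) 0L else nrow(all_chains),
      end_to_end_range = if (!is.null(all_chains) && nrow(all_chains))
        range(all_chains$end_to_end) else c(NA_real_, NA_real_))
  )
  sum_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  manifest <- c(manifest, sum_path)
  writeLines(basename(manifest), file.path(out_dir, "MANIFEST"))
  invisible(summary)
}
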