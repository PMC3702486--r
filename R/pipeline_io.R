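#' Write / read volumes as NIfTI
#'
#' Volumes travel as NIfTI-1 with the voxel geometry in the header
#' (`pixdim`, mm). Label volumes are stored as integers and restored with
#' [label_volume()]; 4-D series carry their inversion times in a JSON
#' sidecar (`<stem>_tis.json`, ms).
#'
#' @param x An [image_volume()], [label_volume()], or [mcle_series()].
#' @param path Output path; `.nii.gz` is appended when no NIfTI extension
#'   is given.
#' @return `path`, invisibly (writers); the reconstructed object (readers).
#' @export
write_volume <- function(x, path) {
  g <- unclass(vol_geometry(x))
  nim <- oro.nifti::nifti(unclass(x) + 0, pixdim = c(1, g, 1),
                          datatype = 64, bitpix = 64)
  write_nifti_path(nim, path)
}

nifti_stem <- function(path) sub("\\.nii(\\.gz)?$", "", path)

write_nifti_path <- function(nim, path) {
  oro.nifti::writeNIfTI(nim, nifti_stem(path), gzipped = grepl("gz$", path))
  invisible(path)
}

read_geometry <- function(nim) {
  pd <- oro.nifti::pixdim(nim)[2:4]
  vox_geometry(pd[1], pd[2], pd[3])
}

#' @rdname write_volume
#' @param labels Read as a [label_volume()]?
#' @export
read_volume <- function(path, labels = FALSE) {
  nim <- oro.nifti::readNIfTI(path)
  arr <- array(as.numeric(nim), dim(nim))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  g <- read_geometry(nim)
  if (labels) label_volume(round(arr), g) else image_volume(arr, g)
}

sidecar_path <- function(path) paste0(nifti_stem(path), "_tis.json")

#' @rdname write_volume
#' @export
write_series <- function(x, path) {
  g <- unclass(x$geometry)
  nim <- oro.nifti::nifti(x$data, pixdim = c(1, g, 1, 1),
                          datatype = 64, bitpix = 64)
  write_nifti_path(nim, path)
  jsonlite::write_json(list(ti_ms = x$tis), sidecar_path(path),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_series <- function(path) {
  nim <- oro.nifti::readNIfTI(path)
  tis <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)$ti_ms
  mcle_series(array(as.numeric(nim), dim(nim)), tis, read_geometry(nim))
}

#' Write / read a cohort table as CSV
#'
#' @param cohort Cohort tibble from [simulate_cohort()].
#' @param path CSV path.
#' @return `path` invisibly; [read_cohort()] returns the tibble.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("icd_therapy" %in% names(out)) {
    out$icd_therapy <- as.logical(out$icd_therapy)
  }
  out
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end phantom analysis: the phantom
#' spec, acquisition (inversion times), frame selection, clustering
#' parameters, classification thresholds, despeckling, density, and the
#' master seed from which all per-stage seeds are derived.
#'
#' @param phantom A [phantom_spec()].
#' @param tis MCLE inversion times (ms); default 20 cardiac-phase frames
#'   spanning one cycle, 75..1025 ms in 50 ms steps.
#' @param frames_k Frames kept for fitting (largest TIs); `NULL` (default)
#'   fits every frame, appropriate for phantoms whose frames are
#'   co-registered by construction. Real acquisitions should restrict to
#'   the 6-8 diastolic frames with minimal cardiac motion.
#' @param fcm_m,fcm_tol,fcm_max_iter,fcm_restarts FCM parameters.
#' @param gz_band Gray-zone membership band.
#' @param blood_override Blood-membership override threshold.
#' @param despeckle_min_size Minimum surviving component size.
#' @param pm_fraction PM infarct-fraction threshold.
#' @param density Myocardial density (g/cm^3).
#' @param seed Master integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(phantom = phantom_spec(),
                       tis = seq(75, 1025, by = 50),
                       frames_k = NULL,
                       fcm_m = 2, fcm_tol = 1e-5, fcm_max_iter = 300,
                       fcm_restarts = 5,
                       gz_band = c(0.25, 0.75), blood_override = 0.5,
                       despeckle_min_size = 2, pm_fraction = 0.5,
                       density = MYO_DENSITY, seed = 1L) {
  structure(list(phantom = phantom, tis = tis, frames_k = frames_k,
                 fcm_m = fcm_m, fcm_tol = fcm_tol,
                 fcm_max_iter = fcm_max_iter, fcm_restarts = fcm_restarts,
                 gz_band = gz_band, blood_override = blood_override,
                 despeckle_min_size = despeckle_min_size,
                 pm_fraction = pm_fraction, density = density,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Independent per-stage seeds derived from the master seed.
stage_seed <- function(seed, stage) {
  (as.double(seed) * 7919 + stage) %% 2147483629
}

#' Run the full phantom analysis pipeline
#'
#' Chains phantom construction, MCLE and IR-FGRE simulation, recovery-curve
#' fitting, FWHM and fuzzy-clustering segmentation, despeckling, mass and
#' PM-score quantification, and a simulated-cohort statistical report.
#' All results are returned; when `out_dir` is given, intermediates
#' (NIfTI volumes, CSV, JSON results, class-map figures, run log) are
#' written there as well.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return A `pipeline_result` list: phantom, series, maps, both
#'   segmentations, heterogeneity tibble (both methods plus ground truth),
#'   PM scores, cohort report.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  ph <- make_phantom(config$phantom)
  noise <- config$phantom$noise_sd
  series <- simulate_mcle(ph$truth, config$tis, noise_sd = noise,
                          seed = stage_seed(config$seed, 1))
  lge <- simulate_ir_fgre(ph$truth, noise_sd = noise,
                          seed = stage_seed(config$seed, 2))

  sel <- if (is.null(config$frames_k)) series else {
    select_frames(series, k = config$frames_k)
  }
  fit_mask <- ph$masks$myocardium | ph$masks$blood |
    ph$masks$pm[[1]] | ph$masks$pm[[2]]
  maps <- fit_recovery(sel, mask = fit_mask)

  # conventional path
  rstats <- remote_stats(lge, ph$masks$remote)
  fwhm <- fwhm_segment(lge, ph$masks$myocardium, rstats)

  # MCLE path
  feats <- build_features(maps, fit_mask)
  fcm_fit <- fcm(feats, m = config$fcm_m, tol = config$fcm_tol,
                 max_iter = config$fcm_max_iter,
                 seed = stage_seed(config$seed, 3),
                 restarts = config$fcm_restarts)
  mapping <- label_clusters(fcm_fit)
  classmap <- classify(fcm_fit, mapping, ph$masks$myocardium,
                       band = config$gz_band,
                       blood_override = config$blood_override)
  classmap <- despeckle(classmap, min_size = config$despeckle_min_size)

  myo <- ph$masks$myocardium
  het <- dplyr::bind_rows(
    dplyr::mutate(heterogeneity(ph$labels, myo, config$density),
                  method = "ground_truth", .before = 1),
    dplyr::mutate(heterogeneity(classmap, myo, config$density),
                  method = "mcle", .before = 1),
    dplyr::mutate(heterogeneity(fwhm, myo, config$density),
                  method = "ir_fgre", .before = 1)
  )

  pm_mcle <- pm_score(classify(fcm_fit, mapping,
                               myo | ph$masks$pm[[1]] | ph$masks$pm[[2]],
                               band = config$gz_band,
                               blood_override = config$blood_override),
                      ph$masks$pm,
                      fraction_threshold = config$pm_fraction)
  pm_lge <- pm_score(lge, ph$masks$pm, peak_infarct = fwhm$peak_infarct)

  cohort <- simulate_cohort(seed = stage_seed(config$seed, 4))
  report <- build_report(cohort)

  res <- structure(
    list(phantom = ph, series = series, lge = lge, maps = maps,
         remote_stats = rstats, fwhm = fwhm, fcm = fcm_fit,
         mapping = mapping, classmap = classmap, heterogeneity = het,
         pm_mcle = pm_mcle, pm_lge = pm_lge, cohort = cohort,
         report = report, config = config),
    class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_volume(res$phantom$labels, p("labels.nii.gz"))
  write_series(res$series, p("mcle.nii.gz"))
  write_volume(res$lge, p("ir_fgre.nii.gz"))
  write_volume(image_volume(ifelse(res$maps$valid, res$maps$t1star, 0),
                            res$maps$geometry), p("t1star.nii.gz"))
  write_volume(image_volume(ifelse(res$maps$valid, res$maps$a, 0),
                            res$maps$geometry), p("steady_state.nii.gz"))
  write_volume(res$classmap, p("classmap_mcle.nii.gz"))
  write_cohort(res$cohort, p("cohort.csv"))
  utils::write.csv(res$heterogeneity, p("heterogeneity.csv"),
                   row.names = FALSE)
  utils::write.csv(res$report, p("cohort_report.csv"), row.names = FALSE)
  results <- list(
    heterogeneity = res$heterogeneity,
    pm_score_mcle = res$pm_mcle$score,
    pm_score_ir_fgre = res$pm_lge$score,
    fwhm_thresholds = res$fwhm$thresholds,
    remote_stats = res$remote_stats,
    seed = res$config$seed
  )
  jsonlite::write_json(results, p("results.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (capabilities("png")) {
    try(render_classmap(res$classmap, p("classmap_mcle.png")), silent = TRUE)
  }
  log_lines <- c(
    sprintf("mclegz %s", as.character(utils::packageVersion("mclegz"))),
    sprintf("R %s", R.version.string),
    sprintf("seed %d", res$config$seed),
    sprintf("phantom %dx%dx%d, noise sd %g", res$config$phantom$nx,
            res$config$phantom$ny, res$config$phantom$n_slices,
            res$config$phantom$noise_sd),
    sprintf("frames_k %s, fcm m=%g restarts=%d",
            if (is.null(res$config$frames_k)) "all" else res$config$frames_k,
            res$config$fcm_m, res$config$fcm_restarts))
  writeLines(log_lines, p("run.log"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$heterogeneity)
  cat(sprintf("PM-MI score: MCLE %d, IR-FGRE %d\n", x$pm_mcle$score,
              x$pm_lge$score))
  invisible(x)
}

# Late-enhancement display convention: gray zone yellow, core green,
# blood red, healthy myocardium blue.
CLASSMAP_COLORS <- c(
  background = "grey15", blood = "red3", healthy = "royalblue3",
  gray_zone = "yellow2", core = "green3",
  pm_healthy = "steelblue1", pm_infarct = "green4"
)

#' Plot a tissue class map
#'
#' One panel per slice using the conventional color map: yellow gray zone,
#' green core, red blood pool, blue healthy myocardium.
#'
#' @param object A [label_volume()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.label_volume <- function(object, ...) {
  df <- tidy.label_volume(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$tissue)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = CLASSMAP_COLORS, drop = FALSE) +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "tissue") +
    ggplot2::theme_minimal()
}

#' Render a class map to a PNG file
#'
#' @param classmap A [label_volume()].
#' @param path Output PNG path.
#' @param width,height,dpi Figure size (inches) and resolution.
#' @return `path`, invisibly.
#' @export
render_classmap <- function(classmap, path, width = 8, height = 4,
                            dpi = 120) {
  if (sum(classmap != LABELS[["background"]]) == 0) {
    warn("class map is empty; rendering background only")
  }
  gg <- autoplot.label_volume(classmap)
  ggplot2::ggsave(path, gg, width = width, height = height, dpi = dpi)
  invisible(path)
}

#' Plot clustered (T1*, steady-state) features
#'
#' @param object An `fcm_fit` built on a feature table.
#' @param mapping Optional tissue mapping from [label_clusters()] to name
#'   the clusters.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fcm_fit <- function(object, mapping = NULL, ...) {
  df <- tidy.fcm_fit(object)
  if (is.null(df$t1star)) abort("fit lacks raw features; cluster on a feature_table")
  df$cluster <- if (is.null(mapping)) {
    factor(df$cluster)
  } else {
    factor(names(mapping)[match(df$cluster, mapping)])
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t1star, y = .data$steady_state,
                                   color = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "T1* (ms)", y = "steady state (a.u.)") +
    ggplot2::theme_minimal()
}
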