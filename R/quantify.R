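MYO_DENSITY <- 1.05  # g/cm^3, standard CMR convention for myocardium

#' Tissue mass of a voxel mask
#'
#' @param mask Logical volume.
#' @param geometry A [vox_geometry()].
#' @param density Tissue density (g/cm^3); default 1.05.
#' @return Mass in grams.
#' @export
tissue_mass <- function(mask, geometry, density = MYO_DENSITY) {
  sum(mask) * voxel_volume_cm3(geometry) * density
}

#' Infarct heterogeneity measures
#'
#' Converts core and gray-zone masks to grams and percent of LV myocardial
#' mass. The gray zone counts toward the total infarct and toward LV mass;
#' papillary muscles are excluded from the wall by convention (pass a
#' myocardium mask that includes them to change this).
#'
#' @param x A classified [label_volume()] (MCLE path) or `fwhm_result`
#'   (conventional path).
#' @param myo_mask Logical LV-wall myocardium mask; defines LV mass.
#' @param density Tissue density (g/cm^3).
#' @param ... Passed between methods.
#' @return A one-row tibble: `core_g`, `gz_g`, `total_g`, `lvm_g`,
#'   `core_pct`, `gz_pct`, `total_pct`.
#' @export
heterogeneity <- function(x, myo_mask, density = MYO_DENSITY, ...) {
  UseMethod("heterogeneity")
}

heterogeneity_from_masks <- function(core, gz, myo_mask, geometry, density) {
  if (any(core & gz)) abort("core and gray-zone masks must be disjoint")
  if (any((core | gz) & !myo_mask)) {
    abort("infarct masks must lie within the myocardium mask")
  }
  lvm <- tissue_mass(myo_mask, geometry, density)
  if (lvm == 0) abort("LV mass is zero")
  core_g <- tissue_mass(core, geometry, density)
  gz_g <- tissue_mass(gz, geometry, density)
  tibble(
    core_g = core_g, gz_g = gz_g, total_g = core_g + gz_g, lvm_g = lvm,
    core_pct = 100 * core_g / lvm, gz_pct = 100 * gz_g / lvm,
    total_pct = 100 * (core_g + gz_g) / lvm
  )
}

#' @rdname heterogeneity
#' @export
heterogeneity.label_volume <- function(x, myo_mask, density = MYO_DENSITY,
                                       ...) {
  core <- label_mask(x, "core") & myo_mask
  gz <- label_mask(x, "gray_zone") & myo_mask
  heterogeneity_from_masks(core, gz, myo_mask, vol_geometry(x), density)
}

#' @rdname heterogeneity
#' @export
heterogeneity.fwhm_result <- function(x, myo_mask, density = MYO_DENSITY,
                                      ...) {
  heterogeneity_from_masks(x$core, x$gray_zone, myo_mask, x$geometry,
                           density)
}

#' Papillary-muscle infarct score
#'
#' Scores papillary-muscle (PM) involvement 2, 1, or 0 for both, one, or no
#' infarcted PM. A PM counts as infarcted when at least
#' `fraction_threshold` of its voxels are classified core or gray zone
#' (classification path), or when its mean signal intensity reaches the
#' FWHM core cutoff `0.5 * peak_infarct` — i.e. enhancement comparable to
#' the adjacent hyperenhanced infarct (intensity path). An empty PM mask
#' scores not-infarcted with a warning.
#'
#' @param x A classified [label_volume()] or an [image_volume()].
#' @param pm_masks List of exactly two logical PM masks.
#' @param peak_infarct Infarct peak intensity (intensity path only).
#' @param fraction_threshold Infarct-voxel fraction that declares a PM
#'   infarcted (classification path); inclusive, default 0.5.
#' @param ... Passed between methods.
#' @return A `pm_score`: list with integer `score` and `per_pm` tibble
#'   (`pm`, `n_voxels`, `criterion`, `infarcted`).
#' @export
pm_score <- function(x, pm_masks, ...) UseMethod("pm_score")

pm_score_result <- function(per_pm) {
  structure(list(score = sum(per_pm$infarcted), per_pm = per_pm),
            class = "pm_score")
}

check_pm_masks <- function(pm_masks, dims) {
  if (length(pm_masks) != 2L) abort("exactly two papillary-muscle masks expected")
  for (mk in pm_masks) {
    if (!identical(dim(mk), dims)) abort("PM mask geometry mismatch")
  }
}

#' @rdname pm_score
#' @export
pm_score.label_volume <- function(x, pm_masks, fraction_threshold = 0.5,
                                  ...) {
  check_pm_masks(pm_masks, dim(x))
  infarct_like <- label_mask(x, c("core", "gray_zone", "pm_infarct"))
  per_pm <- purrr::map_dfr(seq_along(pm_masks), function(ii) {
    mk <- pm_masks[[ii]]
    n <- sum(mk)
    if (n == 0L) {
      warn(sprintf("PM mask %d is empty; scored not-infarcted", ii))
      return(tibble(pm = ii, n_voxels = 0L, criterion = NA_real_,
                    infarcted = FALSE))
    }
    frac <- sum(infarct_like & mk) / n
    tibble(pm = ii, n_voxels = n, criterion = frac,
           infarcted = frac >= fraction_threshold)
  })
  pm_score_result(per_pm)
}

#' @rdname pm_score
#' @export
pm_score.image_volume <- function(x, pm_masks, peak_infarct, ...) {
  check_pm_masks(pm_masks, dim(x))
  if (missing(peak_infarct) || !is.finite(peak_infarct)) {
    abort("intensity-path PM scoring needs a finite peak_infarct")
  }
  cutoff <- 0.5 * peak_infarct
  per_pm <- purrr::map_dfr(seq_along(pm_masks), function(ii) {
    mk <- pm_masks[[ii]]
    n <- sum(mk)
    if (n == 0L) {
      warn(sprintf("PM mask %d is empty; scored not-infarcted", ii))
      return(tibble(pm = ii, n_voxels = 0L, criterion = NA_real_,
                    infarcted = FALSE))
    }
    mean_si <- mean(x[mk])
    tibble(pm = ii, n_voxels = n, criterion = mean_si,
           infarcted = mean_si >= cutoff)
  })
  pm_score_result(per_pm)
}

#' @export
print.pm_score <- function(x, ...) {
  cat(sprintf("<pm_score> %d of 2 papillary muscles infarcted\n", x$score))
  print(x$per_pm)
  invisible(x)
}

#' @rdname pm_score
#' @export
tidy.pm_score <- function(x, ...) x$per_pm

#' @rdname pm_score
#' @export
glance.pm_score <- function(x, ...) {
  tibble(score = x$score, n_pm = nrow(x$per_pm))
}

#' LV functional parameters from segmentation masks
#'
#' Summation-of-disks volumetry: the cavity volume at each cardiac phase is
#' the endocardial mask volume; EDV and ESV are the maximum and minimum
#' over phases; LV mass is the epicardium-minus-endocardium shell at
#' end-diastole times myocardial density; SV and EF follow by definition.
#'
#' @param endo_masks List (>= 2 phases) of logical endocardial masks.
#' @param epi_mask_ed Logical epicardial mask at end-diastole.
#' @param geometry A [vox_geometry()].
#' @param density Myocardial density (g/cm^3).
#' @return A one-row tibble: `edv_ml`, `esv_ml`, `sv_ml`, `ef_pct`,
#'   `lvm_g`, `ed_phase`, `es_phase`.
#' @export
lv_function <- function(endo_masks, epi_mask_ed, geometry,
                        density = MYO_DENSITY) {
  if (length(endo_masks) < 2L) abort("need at least 2 cardiac phases")
  vv <- voxel_volume_cm3(geometry)  # 1 cm^3 = 1 ml
  vols <- vapply(endo_masks, function(mk) sum(mk) * vv, numeric(1))
  edv <- max(vols); esv <- min(vols)
  if (edv <= 0) abort("end-diastolic volume is zero")
  ed <- which.max(vols); es <- which.min(vols)
  if (!identical(dim(epi_mask_ed), dim(endo_masks[[ed]]))) {
    abort("epicardial mask geometry mismatch")
  }
  shell <- epi_mask_ed & !endo_masks[[ed]]
  lvm <- sum(shell) * vv * density
  sv <- edv - esv
  tibble(edv_ml = edv, esv_ml = esv, sv_ml = sv, ef_pct = 100 * sv / edv,
         lvm_g = lvm, ed_phase = ed, es_phase = es)
}
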