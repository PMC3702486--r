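#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Tissue label codes shared by the whole package. Myocardium proper is
# {healthy, gray_zone, core}; papillary muscles are kept as separate classes
# because routine heterogeneity analysis excludes them from the LV wall.
LABELS <- c(
  background = 0L, blood = 1L, healthy = 2L, gray_zone = 3L,
  core = 4L, pm_healthy = 5L, pm_infarct = 6L
)

#' Voxel geometry
#'
#' Physical voxel dimensions of an image grid: in-plane resolution and slice
#' thickness, both in millimetres.
#'
#' @param dx,dy In-plane voxel size (mm).
#' @param dz Slice thickness (mm).
#' @return A `vox_geometry` object (named numeric vector, mm).
#' @export
vox_geometry <- function(dx = 1.5, dy = dx, dz = 8) {
  g <- c(dx = dx, dy = dy, dz = dz)
  if (any(!is.finite(g)) || any(g <= 0)) {
    abort("voxel dimensions must be positive and finite")
  }
  structure(g, class = "vox_geometry")
}

#' @export
print.vox_geometry <- function(x, ...) {
  cat(sprintf("<vox_geometry> %g x %g mm in-plane, %g mm slices\n",
              x[["dx"]], x[["dy"]], x[["dz"]]))
  invisible(x)
}

# Volume of one voxel in cm^3 (mm^3 / 1000).
voxel_volume_cm3 <- function(geometry) {
  unclass(geometry)[["dx"]] * unclass(geometry)[["dy"]] *
    unclass(geometry)[["dz"]] / 1000
}

new_volume <- function(data, geometry, class) {
  stopifnot(length(dim(data)) == 3L)
  structure(data, geometry = geometry, class = c(class, "array"))
}

#' Label volume
#'
#' A 3-D array of integer tissue labels (background, blood, healthy
#' myocardium, gray zone, core infarct, and healthy/infarcted papillary
#' muscle) with voxel geometry attached.
#'
#' @param data Integer 3-D array with values in `0:6`.
#' @param geometry A [vox_geometry()].
#' @return A `label_volume`.
#' @export
label_volume <- function(data, geometry = vox_geometry()) {
  storage.mode(data) <- "integer"
  if (!all(data %in% LABELS)) abort("unknown label codes in volume")
  new_volume(data, geometry, "label_volume")
}

#' Image volume
#'
#' A real-valued 3-D intensity array (arbitrary units) with voxel geometry.
#'
#' @param data Numeric 3-D array of finite values.
#' @param geometry A [vox_geometry()].
#' @return An `image_volume`.
#' @export
image_volume <- function(data, geometry = vox_geometry()) {
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) abort("image intensities must be finite")
  new_volume(data, geometry, "image_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  counts <- table(factor(x, levels = LABELS, labels = names(LABELS)))
  cat(sprintf("<label_volume> %d x %d x %d\n", d[1], d[2], d[3]))
  print(counts)
  invisible(x)
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_volume> %d x %d x %d, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

vol_geometry <- function(x) attr(x, "geometry", exact = TRUE)

#' Multi-contrast late enhancement series
#'
#' An ordered stack of co-registered image volumes acquired at strictly
#' increasing inversion times, the raw material for per-voxel T1* fitting.
#'
#' @param data Numeric 4-D array `[x, y, z, frame]`.
#' @param tis Inversion times (ms), one per frame, strictly increasing.
#' @param geometry A [vox_geometry()].
#' @return An `mcle_series` (list with elements `data`, `tis`, `geometry`).
#' @export
mcle_series <- function(data, tis, geometry = vox_geometry()) {
  if (length(dim(data)) != 4L) abort("series data must be a 4-D array")
  if (length(tis) != dim(data)[4]) abort("need exactly one TI per frame")
  if (length(tis) == 0L) abort("TI list must be non-empty")
  if (any(tis <= 0) || any(diff(tis) <= 0)) {
    abort("inversion times must be positive and strictly increasing")
  }
  structure(list(data = data, tis = as.numeric(tis), geometry = geometry),
            class = "mcle_series")
}

#' @export
print.mcle_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mcle_series> %d frames of %d x %d x %d, TI %g..%g ms\n",
              d[4], d[1], d[2], d[3], min(x$tis), max(x$tis)))
  invisible(x)
}

#' @export
length.mcle_series <- function(x) dim(x$data)[4]

#' Per-voxel inversion-recovery parameter maps
#'
#' T1* (ms), steady-state amplitude A, inversion amplitude B, residual RMS,
#' and a validity mask, all on a shared grid. Values outside the validity
#' mask are `NA`.
#'
#' @param t1star,a,b,rms Numeric 3-D arrays (T1* in ms, A/B/RMS in a.u.).
#' @param valid Logical 3-D array: where the fit is trusted.
#' @param geometry A [vox_geometry()].
#' @return A `parameter_maps` object.
#' @export
parameter_maps <- function(t1star, a, b, rms, valid,
                           geometry = vox_geometry()) {
  dims <- dim(t1star)
  for (m in list(a, b, rms, valid)) {
    if (!identical(dim(m), dims)) abort("all maps must share one grid")
  }
  v <- which(valid)
  if (length(v)) {
    if (any(!is.finite(t1star[v])) || any(t1star[v] <= 0)) {
      abort("valid voxels must have finite positive T1*")
    }
    if (any(!is.finite(a[v]))) abort("valid voxels must have finite A")
    if (any(rms[v] < 0, na.rm = TRUE)) abort("residual RMS must be >= 0")
  }
  structure(list(t1star = t1star, a = a, b = b, rms = rms,
                 valid = valid, geometry = geometry),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  d <- dim(x$t1star)
  cat(sprintf("<parameter_maps> %d x %d x %d, %d valid voxels\n",
              d[1], d[2], d[3], sum(x$valid)))
  invisible(x)
}

#' Tidy a label volume into a long voxel table
#'
#' @param x A `label_volume`.
#' @param ... Unused.
#' @return A tibble with voxel indices (`i`, `j`, `k`, 1-based) and the
#'   tissue label as a factor.
#' @export
tidy.label_volume <- function(x, ...) {
  d <- dim(x)
  idx <- arrayInd(seq_along(x), d)
  tibble(
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    tissue = factor(names(LABELS)[match(as.integer(x), LABELS)],
                    levels = names(LABELS))
  )
}

label_mask <- function(labels, which) {
  array(as.integer(labels) %in% LABELS[which], dim = dim(labels))
}

#' Extract the LV-wall myocardium mask from a label volume
#'
#' Myocardium proper is the union of healthy, gray-zone, and core labels;
#' papillary muscles are excluded (set `include_pm = TRUE` to add them).
#'
#' @param labels A `label_volume`.
#' @param include_pm Count papillary-muscle voxels as myocardium?
#' @return Logical 3-D array.
#' @export
myocardium_mask <- function(labels, include_pm = FALSE) {
  which <- c("healthy", "gray_zone", "core")
  if (include_pm) which <- c(which, "pm_healthy", "pm_infarct")
  label_mask(labels, which)
}
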