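#' Default tissue signal table
#'
#' Post-gadolinium steady-state amplitude `a` (a.u.) and apparent relaxation
#' time `t1star` (ms) per tissue class. The ordering encodes late-enhancement
#' contrast: blood and infarct recover fast (short T1*), nulled healthy
#' myocardium recovers slowest; blood has the largest steady-state amplitude.
#' The exact values are free phantom parameters, not measured constants.
#'
#' @param gz_mix Mixing fraction for gray-zone ground truth: `gz_mix` of the
#'   core parameters plus `1 - gz_mix` of the healthy parameters. Default 0.5.
#' @return A tibble with columns `tissue`, `a`, `t1star`.
#' @export
default_tissue_table <- function(gz_mix = 0.5) {
  stopifnot(gz_mix >= 0, gz_mix <= 1)
  base <- tibble(
    tissue = c("blood", "core", "healthy"),
    a = c(120, 100, 80),
    t1star = c(250, 320, 600)
  )
  core <- base[base$tissue == "core", ]
  healthy <- base[base$tissue == "healthy", ]
  gz <- tibble(
    tissue = "gray_zone",
    a = gz_mix * core$a + (1 - gz_mix) * healthy$a,
    t1star = gz_mix * core$t1star + (1 - gz_mix) * healthy$t1star
  )
  pm <- tibble(
    tissue = c("pm_healthy", "pm_infarct"),
    a = c(healthy$a, core$a),
    t1star = c(healthy$t1star, core$t1star)
  )
  bg <- tibble(tissue = "background", a = 0, t1star = 1000)
  dplyr::bind_rows(base, gz, pm, bg)
}

#' Phantom specification
#'
#' Describes a short-axis left-ventricular phantom: an annular myocardium
#' around a blood pool, a transmural or subendocardial infarct wedge with a
#' gray-zone rim, and two papillary muscles inside the cavity.
#'
#' @param nx,ny,n_slices Grid shape (voxels).
#' @param res_xy In-plane resolution (mm/voxel).
#' @param thickness Slice thickness (mm).
#' @param center LV center in physical mm (length 2); default grid center.
#' @param endo_radius,epi_radius Endocardial / epicardial radii (mm).
#' @param infarct_extent Angular extent of the infarct wedge (degrees).
#' @param infarct_angle Direction of the wedge center (degrees, 0 = +x axis).
#' @param transmural_fraction Fraction of the wall the core spans, from the
#'   endocardium outward; in (0, 1].
#' @param rim_width Gray-zone rim width around the core (mm, >= 0).
#' @param pm Papillary-muscle descriptors: list of two lists, each with
#'   `center` (mm, relative to LV center), `radius` (mm), `infarcted`
#'   (logical).
#' @param tissue_table Tissue signal table; see [default_tissue_table()].
#' @param inversion_ratio B/A ratio of the inversion-recovery model
#'   (2 = ideal inversion).
#' @param noise_sd Default additive Gaussian noise sd (a.u.) used when the
#'   phantom is imaged.
#' @param seed Integer seed for any stochastic use of the spec.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(nx = 64, ny = 64, n_slices = 3,
                         res_xy = 1.5, thickness = 8,
                         center = NULL,
                         endo_radius = 20, epi_radius = 30,
                         infarct_extent = 90, infarct_angle = 0,
                         transmural_fraction = 1.0, rim_width = 3,
                         pm = list(
                           list(center = c(0, 12), radius = 3.5,
                                infarcted = TRUE),
                           list(center = c(0, -12), radius = 3.5,
                                infarcted = FALSE)
                         ),
                         tissue_table = default_tissue_table(),
                         inversion_ratio = 2,
                         noise_sd = 2.4, seed = 1L) {
  if (is.null(center)) center <- c(nx / 2 * res_xy, ny / 2 * res_xy)
  spec <- structure(
    list(nx = as.integer(nx), ny = as.integer(ny),
         n_slices = as.integer(n_slices),
         res_xy = res_xy, thickness = thickness, center = center,
         endo_radius = endo_radius, epi_radius = epi_radius,
         infarct_extent = infarct_extent, infarct_angle = infarct_angle,
         transmural_fraction = transmural_fraction, rim_width = rim_width,
         pm = pm, tissue_table = tissue_table,
         inversion_ratio = inversion_ratio,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(s) {
  if (any(c(s$nx, s$ny, s$n_slices) < 1)) abort("grid shape must be positive")
  if (s$endo_radius >= s$epi_radius) {
    abort("endocardial radius must be smaller than epicardial radius")
  }
  if (s$transmural_fraction <= 0 || s$transmural_fraction > 1) {
    abort("transmural fraction must be in (0, 1]")
  }
  if (s$rim_width < 0) abort("gray-zone rim width must be >= 0")
  if (s$infarct_extent < 0) abort("infarct angular extent must be >= 0")
  if (s$noise_sd < 0) abort("noise sd must be >= 0")
  tt <- s$tissue_table
  if (any(tt$t1star <= 0) || any(tt$a < 0)) {
    abort("tissue table needs T1* > 0 and A >= 0")
  }
  if (length(s$pm) != 2L) abort("exactly two papillary muscles are expected")
  for (p in s$pm) {
    if (sqrt(sum(p$center^2)) >= s$endo_radius) {
      abort("papillary-muscle centers must lie inside the blood pool")
    }
  }
  invisible(s)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %dx%dx%d @ %g mm / %g mm; endo %g, epi %g mm; wedge %g deg, transmural %g, rim %g mm\n",
    x$nx, x$ny, x$n_slices, x$res_xy, x$thickness, x$endo_radius,
    x$epi_radius, x$infarct_extent, x$transmural_fraction, x$rim_width))
  invisible(x)
}

# Signed angular difference in (-180, 180].
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Build a ground-truth LV phantom
#'
#' Rasterizes the phantom geometry to a [label_volume()] and fills
#' ground-truth inversion-recovery parameter maps from the tissue table.
#' Voxels are classified by the physical position of their centers
#' (1-based array indices; voxel `i` spans `[(i-1)*dx, i*dx)`).
#'
#' The core is the wedge of myocardium within the stated angular extent out
#' to the transmural fraction of the wall; the gray zone is every other
#' myocardial voxel whose center lies within `rim_width` mm of a core voxel
#' center. Gray-zone ground-truth parameters are a linear core/healthy mix
#' (see [default_tissue_table()]).
#'
#' @param spec A [phantom_spec()].
#' @return An `lv_phantom`: list with `labels` ([label_volume()]), `truth`
#'   ([parameter_maps()]), `masks` (myocardium, blood, remote ROI, per-PM),
#'   and the `spec`.
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  geom <- vox_geometry(spec$res_xy, spec$res_xy, spec$thickness)
  dims <- c(spec$nx, spec$ny, spec$n_slices)

  # physical in-plane coordinates of voxel centers, relative to LV center
  xc <- (seq_len(spec$nx) - 0.5) * spec$res_xy - spec$center[1]
  yc <- (seq_len(spec$ny) - 0.5) * spec$res_xy - spec$center[2]
  X <- matrix(xc, spec$nx, spec$ny)
  Y <- matrix(yc, spec$nx, spec$ny, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  TH <- atan2(Y, X) * 180 / pi

  blood2d <- R < spec$endo_radius
  myo2d <- R >= spec$endo_radius & R < spec$epi_radius
  wall <- spec$epi_radius - spec$endo_radius
  in_wedge <- spec$infarct_extent > 0 &
    abs(angle_diff(TH, spec$infarct_angle)) < spec$infarct_extent / 2
  core2d <- myo2d & in_wedge &
    R < spec$endo_radius + spec$transmural_fraction * wall

  # gray zone: myocardial, non-core, within rim_width of a core voxel center
  gz2d <- matrix(FALSE, spec$nx, spec$ny)
  if (any(core2d) && spec$rim_width > 0) {
    cand <- which(myo2d & !core2d)
    cx <- X[core2d]; cy <- Y[core2d]
    for (v in cand) {
      d2 <- (X[v] - cx)^2 + (Y[v] - cy)^2
      if (min(d2) <= spec$rim_width^2) gz2d[v] <- TRUE
    }
    if (all(gz2d[myo2d & !core2d])) {
      warn("gray-zone rim covers all remaining myocardium; clipped to the wall")
    }
  }

  slice <- matrix(LABELS[["background"]], spec$nx, spec$ny)
  slice[blood2d] <- LABELS[["blood"]]
  slice[myo2d] <- LABELS[["healthy"]]
  slice[gz2d] <- LABELS[["gray_zone"]]
  slice[core2d] <- LABELS[["core"]]
  for (p in spec$pm) {
    pm2d <- blood2d & ((X - p$center[1])^2 + (Y - p$center[2])^2 <= p$radius^2)
    slice[pm2d] <- if (isTRUE(p$infarcted)) LABELS[["pm_infarct"]] else
      LABELS[["pm_healthy"]]
  }
  labels <- label_volume(array(slice, dims), geom)

  # ground-truth parameter maps from the tissue table
  tt <- spec$tissue_table
  a_of <- stats::setNames(tt$a, tt$tissue)
  t1_of <- stats::setNames(tt$t1star, tt$tissue)
  tissue_names <- names(LABELS)[match(as.integer(labels), LABELS)]
  a_map <- array(unname(a_of[tissue_names]), dims)
  t1_map <- array(unname(t1_of[tissue_names]), dims)
  b_map <- spec$inversion_ratio * a_map
  valid <- array(as.integer(labels) != LABELS[["background"]], dims)
  truth <- parameter_maps(t1_map, a_map, b_map,
                          rms = array(0, dims), valid = valid,
                          geometry = geom)

  # remote ROI: healthy myocardium opposite the infarct (+-30 degrees)
  remote2d <- myo2d & !core2d & !gz2d &
    abs(angle_diff(TH, spec$infarct_angle + 180)) <= 30
  masks <- list(
    myocardium = array(myo2d, dims),
    blood = array(slice == LABELS[["blood"]], dims),
    remote = array(remote2d, dims),
    pm = lapply(spec$pm, function(p) {
      pm2d <- blood2d &
        ((X - p$center[1])^2 + (Y - p$center[2])^2 <= p$radius^2)
      array(pm2d, dims)
    })
  )

  structure(list(labels = labels, truth = truth, masks = masks, spec = spec),
            class = "lv_phantom")
}

#' @export
print.lv_phantom <- function(x, ...) {
  print(x$spec)
  print(x$labels)
  invisible(x)
}

# Evaluate S(t) = A - B exp(-t / T1*) for every voxel at one TI.
ir_signal <- function(truth, ti) {
  truth$a - truth$b * exp(-ti / truth$t1star)
}

# Run fn with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Simulate a multi-contrast late-enhancement series
#'
#' Evaluates the inversion-recovery model `S(t) = A - B exp(-t / T1*)` at
#' each inversion time on ground-truth parameter maps, adds independent
#' Gaussian noise per voxel per frame, and optionally takes the magnitude.
#'
#' @param truth Ground-truth [parameter_maps()].
#' @param tis Inversion times (ms), strictly increasing.
#' @param noise_sd Gaussian noise sd (a.u.).
#' @param seed Integer seed.
#' @param magnitude Take `abs()` after adding noise (magnitude
#'   reconstruction)? Default `FALSE` so signed signals reach the fitter.
#' @return An [mcle_series()].
#' @export
simulate_mcle <- function(truth, tis, noise_sd = 0, seed = 1L,
                          magnitude = FALSE) {
  if (length(tis) == 0L) abort("TI list must be non-empty")
  if (any(tis <= 0)) abort("all inversion times must be positive")
  dims <- dim(truth$a)
  data <- array(0, c(dims, length(tis)))
  for (f in seq_along(tis)) data[, , , f] <- ir_signal(truth, tis[f])
  if (noise_sd > 0) {
    data <- data + with_local_seed(seed, function() {
      array(stats::rnorm(length(data), 0, noise_sd), dim(data))
    })
  }
  if (magnitude) data <- abs(data)
  mcle_series(data, tis, truth$geometry)
}

#' Simulate a conventional IR-FGRE late-enhancement image
#'
#' A single magnitude inversion-recovery image at one TI, by default the
#' null point of the healthy-myocardium tissue entry (`T1*_healthy * ln 2`),
#' so healthy myocardium is suppressed and infarct appears hyperenhanced.
#'
#' @param truth Ground-truth [parameter_maps()].
#' @param ti Inversion time (ms); default nulls healthy myocardium.
#' @param noise_sd,seed As in [simulate_mcle()].
#' @return An [image_volume()].
#' @export
simulate_ir_fgre <- function(truth, ti = NULL, noise_sd = 0, seed = 1L) {
  if (is.null(ti)) {
    tt <- default_tissue_table()
    ti <- tt$t1star[tt$tissue == "healthy"] * log(2)
  }
  if (ti <= 0) abort("inversion time must be positive")
  img <- abs(ir_signal(truth, ti))
  if (noise_sd > 0) {
    img <- img + with_local_seed(seed, function() {
      array(stats::rnorm(length(img), 0, noise_sd), dim(img))
    })
  }
  image_volume(img, truth$geometry)
}
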