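#' Remote-ROI signal statistics
#'
#' Mean, peak, and standard deviation of signal intensity within a remote
#' healthy-myocardium region of interest. The SD uses the sample convention
#' (ddof = 1); a single-voxel ROI returns SD 0 with a warning.
#'
#' @param image An [image_volume()].
#' @param remote_roi Logical volume marking the remote ROI.
#' @return A one-row tibble: `mean_remote`, `peak_remote`, `sd_remote`,
#'   `n_voxels`.
#' @export
remote_stats <- function(image, remote_roi) {
  if (!identical(dim(remote_roi), dim(image))) {
    abort("remote ROI must match image geometry")
  }
  vals <- image[remote_roi]
  if (length(vals) == 0L) abort("remote ROI is empty")
  s <- if (length(vals) == 1L) {
    warn("remote ROI has a single voxel; SD set to 0")
    0
  } else stats::sd(vals)
  tibble(mean_remote = mean(vals), peak_remote = max(vals),
         sd_remote = s, n_voxels = length(vals))
}

#' Full-width-half-maximum infarct segmentation
#'
#' The conventional late-enhancement heterogeneity rule. Candidate infarct
#' is every myocardial voxel brighter than the remote peak; `peak_infarct`
#' is the maximum intensity over that region. Core is signal above half the
#' infarct peak; gray zone is signal between the remote peak (exclusive)
#' and half the infarct peak. A voxel exactly at half the infarct peak goes
#' to the gray zone by default (`gz_upper_inclusive = FALSE` makes the
#' upper bound strict so such voxels stay unclassified).
#'
#' @param image An [image_volume()] (conventional LGE).
#' @param myo_mask Logical myocardium mask (non-empty).
#' @param stats Remote-ROI statistics from [remote_stats()].
#' @param gz_upper_inclusive Include signal exactly at `0.5 * peak_infarct`
#'   in the gray zone?
#' @return An `fwhm_result`: list with `core`, `gray_zone` (logical
#'   volumes), `peak_infarct`, `thresholds` (tibble), and `empty` flag set
#'   when no myocardial voxel exceeds the remote peak.
#' @export
fwhm_segment <- function(image, myo_mask, stats, gz_upper_inclusive = TRUE) {
  if (!identical(dim(myo_mask), dim(image))) {
    abort("myocardium mask must match image geometry")
  }
  if (!any(myo_mask)) abort("myocardium mask is empty")
  peak_remote <- stats$peak_remote[[1]]

  candidate <- myo_mask & image > peak_remote
  if (!any(candidate)) {
    empty <- array(FALSE, dim(image))
    return(structure(
      list(core = empty, gray_zone = empty, peak_infarct = NA_real_,
           thresholds = tibble(peak_remote = peak_remote,
                               half_peak_infarct = NA_real_),
           empty = TRUE, geometry = vol_geometry(image)),
      class = "fwhm_result"))
  }
  peak_infarct <- max(image[candidate])
  half <- 0.5 * peak_infarct
  core <- myo_mask & image > half
  gz <- if (gz_upper_inclusive) {
    myo_mask & image > peak_remote & image <= half
  } else {
    myo_mask & image > peak_remote & image < half
  }
  structure(
    list(core = core, gray_zone = gz, peak_infarct = peak_infarct,
         thresholds = tibble(peak_remote = peak_remote,
                             half_peak_infarct = half),
         empty = FALSE, geometry = vol_geometry(image)),
    class = "fwhm_result")
}

#' @export
print.fwhm_result <- function(x, ...) {
  cat(sprintf(
    "<fwhm_result> core %d voxels, gray zone %d voxels (peak_infarct %.4g, remote peak %.4g)\n",
    sum(x$core), sum(x$gray_zone),
    x$peak_infarct, x$thresholds$peak_remote[[1]]))
  invisible(x)
}
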