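# Shared fixtures and independent oracles, built in code at test time.

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

tissue_mask_of <- function(labels, tissue) {
  codes <- c(background = 0L, blood = 1L, healthy = 2L, gray_zone = 3L,
             core = 4L, pm_healthy = 5L, pm_infarct = 6L)
  array(as.integer(labels) %in% codes[tissue], dim(labels))
}

# Brute-force per-voxel FWHM predicate scan (independent of fwhm_segment).
fwhm_oracle <- function(img, myo, peak_remote, inclusive = TRUE) {
  dims <- dim(img)
  cand <- logical(length(img))
  for (v in seq_along(img)) cand[v] <- myo[v] && img[v] > peak_remote
  if (!any(cand)) {
    return(list(core = array(FALSE, dims), gz = array(FALSE, dims)))
  }
  peak_inf <- max(img[cand])
  core <- gz <- logical(length(img))
  for (v in seq_along(img)) {
    if (!myo[v]) next
    si <- img[v]
    if (si > 0.5 * peak_inf) core[v] <- TRUE
    else if (si > peak_remote &&
             (si < 0.5 * peak_inf || (inclusive && si == 0.5 * peak_inf))) {
      gz[v] <- TRUE
    }
  }
  list(core = array(core, dims), gz = array(gz, dims),
       peak_infarct = peak_inf)
}

# Exhaustive two-sided Fisher p by hypergeometric enumeration over all
# tables with the observed margins (probability-mass convention).
fisher_oracle <- function(tb) {
  r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ])
  c1 <- sum(tb[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tb[, 2]) == 0) return(1)
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  probs <- dhyper(lo:hi, r1, r2, c1)
  p_obs <- dhyper(tb[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Three well-separated 2-D point clouds with known hard labels.
make_clouds <- function(n_per = 60, sep = 10, sd = 1, seed = 42) {
  set.seed(seed)
  centers <- matrix(c(0, 0, sep, 0, sep / 2, sep), ncol = 2, byrow = TRUE)
  x <- do.call(rbind, lapply(1:3, function(k) {
    cbind(rnorm(n_per, centers[k, 1], sd), rnorm(n_per, centers[k, 2], sd))
  }))
  list(x = x, labels = rep(1:3, each = n_per), centers = centers)
}

# Small noiseless series from known (A, B, T1*) maps on an arbitrary grid.
synth_series <- function(a, b, t1, tis, geometry = vox_geometry(1, 1, 1),
                         noise_sd = 0, seed = 1) {
  dims <- dim(a)
  dat <- array(0, c(dims, length(tis)))
  for (f in seq_along(tis)) {
    dat[, , , f] <- a - b * exp(-tis[f] / t1)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    dat <- dat + array(rnorm(length(dat), 0, noise_sd), dim(dat))
  }
  mcle_series(dat, tis, geometry)
}
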