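#' Select fitting frames from an MCLE series
#'
#' Curve fitting typically uses only the diastolic frames with minimal
#' cardiac motion; lacking cardiac-phase metadata the default keeps the last
#' `k` frames (largest inversion times). An explicit frame-index override is
#' accepted.
#'
#' @param series An [mcle_series()].
#' @param k Number of frames to keep (default 8, capped at series length).
#' @param indices Optional explicit frame indices (1-based); overrides `k`.
#' @return An [mcle_series()] with the selected frames in TI order.
#' @export
select_frames <- function(series, k = 8, indices = NULL) {
  n <- length(series)
  if (is.null(indices)) {
    if (k < 2 || k > n) abort(sprintf("k must be in [2, %d]", n))
    indices <- seq.int(n - k + 1L, n)
  } else {
    indices <- sort(unique(as.integer(indices)))
    if (any(indices < 1L) || any(indices > n)) {
      abort("frame indices out of range")
    }
  }
  mcle_series(series$data[, , , indices, drop = FALSE],
              series$tis[indices], series$geometry)
}

# Profiled linear solve: for fixed T1*, S = A - B exp(-t/T1*) is linear in
# (A, B). Y is an n_frames x n_voxels matrix. Returns A, B, and SSR vectors.
profile_linear <- function(e, Y) {
  k <- length(e)
  se <- sum(e); see <- sum(e * e)
  det <- k * see - se * se
  sy <- colSums(Y)
  sey <- as.vector(crossprod(e, Y))
  if (abs(det) < 1e-12) {
    a <- sy / k
    b <- rep(0, ncol(Y))
  } else {
    # minimize || y - (a - b e) ||^2
    a <- (see * sy - se * sey) / det
    b <- (se * sy - k * sey) / det
  }
  fit <- outer(rep(1, k), a) - outer(e, b)
  ssr <- colSums((Y - fit)^2)
  list(a = a, b = b, ssr = ssr)
}

ssr_at_t1 <- function(t1, tis, y) {
  e <- exp(-tis / t1)
  pl <- profile_linear(e, matrix(y, ncol = 1))
  pl$ssr[1]
}

#' Fit per-voxel inversion-recovery curves
#'
#' Fits the three-parameter model `S(t) = A - B exp(-t / T1*)` to every
#' masked voxel of a series. Because the model is linear in (A, B) for
#' fixed T1*, fitting profiles them out: a coarse log-spaced T1* grid with
#' exact linear solves locates the basin, Brent refinement of the profiled
#' objective polishes T1*, and a bounded Levenberg-Marquardt step over all
#' three parameters finishes; the best objective of the stages is kept, so
#' refinement never worsens the grid start. Voxels with (numerically)
#' constant signal, failed fits, or T1* outside `t1_limits` are marked
#' invalid.
#'
#' For magnitude input the signal polarity before the zero crossing is
#' lost; with `magnitude = TRUE` the fitter tries restoring it by negating
#' the earliest 0..n-1 frames and keeps the sign pattern with the lowest
#' residual.
#'
#' @param series An [mcle_series()] (>= 3 frames).
#' @param mask Logical volume of voxels to fit; default all voxels.
#' @param magnitude Is the input magnitude-reconstructed? Enables polarity
#'   restoration.
#' @param t1_limits Acceptance bounds for T1* (ms); default `c(10, 5000)`.
#' @param grid_size Number of log-spaced T1* grid candidates.
#' @return A [parameter_maps()] object.
#' @export
fit_recovery <- function(series, mask = NULL, magnitude = FALSE,
                         t1_limits = c(10, 5000), grid_size = 40) {
  dims <- dim(series$data)[1:3]
  tis <- series$tis
  k <- length(tis)
  if (k < 3) abort("at least 3 frames are required for a 3-parameter fit")
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (!identical(dim(mask), dims)) abort("mask geometry does not match series")

  vox <- which(mask)
  n <- length(vox)
  t1 <- a <- b <- rms <- array(NA_real_, dims)
  valid <- array(FALSE, dims)
  if (n == 0L) {
    warn("empty mask: no voxels fitted")
    return(parameter_maps(t1, a, b, rms, valid, series$geometry))
  }

  flat <- matrix(series$data, prod(dims), k)
  Y <- t(flat[vox, , drop = FALSE])          # k x n

  sign_patterns <- if (magnitude) {
    lapply(0:(k - 1), function(j) c(rep(-1, j), rep(1, k - j)))
  } else list(rep(1, k))

  best <- list(ssr = rep(Inf, n), a = rep(NA_real_, n),
               b = rep(NA_real_, n), t1 = rep(NA_real_, n))
  grid <- exp(seq(log(t1_limits[1]), log(t1_limits[2]),
                  length.out = grid_size))

  for (sg in sign_patterns) {
    Ys <- Y * sg
    # vectorized grid search over T1* candidates
    ssr_grid <- matrix(Inf, grid_size, n)
    ab_grid <- vector("list", grid_size)
    for (g in seq_len(grid_size)) {
      pl <- profile_linear(exp(-tis / grid[g]), Ys)
      ssr_grid[g, ] <- pl$ssr
      ab_grid[[g]] <- pl
    }
    g_best <- max.col(-t(ssr_grid))
    for (i in seq_len(n)) {
      y <- Ys[, i]
      if (diff(range(y)) < 1e-10 * max(1, abs(mean(y)))) next  # constant: B ~ 0
      gi <- g_best[i]
      ssr0 <- ssr_grid[gi, i]
      lo <- grid[max(1L, gi - 1L)]
      hi <- grid[min(grid_size, gi + 1L)]
      opt <- stats::optimize(ssr_at_t1, c(lo, hi), tis = tis, y = y,
                             tol = 1e-7)
      t1_hat <- if (opt$objective <= ssr0) opt$minimum else grid[gi]
      pl <- profile_linear(exp(-tis / t1_hat), matrix(y, ncol = 1))
      cur <- list(t1 = t1_hat, a = pl$a[1], b = pl$b[1], ssr = pl$ssr[1])

      # bounded LM polish over (A, B, T1*)
      res_fn <- function(p) p[1] - p[2] * exp(-tis / p[3]) - y
      jac_fn <- function(p) {
        e <- exp(-tis / p[3])
        cbind(1, -e, -p[2] * e * tis / p[3]^2)
      }
      start <- pmin(pmax(c(cur$a, cur$b, cur$t1),
                         c(0, 0, t1_limits[1])),
                    c(Inf, Inf, t1_limits[2]))
      # nls.lm emits its own iteration-count warnings; the fit is accepted
      # on residual improvement alone, so they are silenced here
      lm <- tryCatch(
        suppressWarnings(minpack.lm::nls.lm(
          par = start, fn = res_fn, jac = jac_fn,
          lower = c(0, 0, t1_limits[1]), upper = c(Inf, Inf, t1_limits[2]),
          control = minpack.lm::nls.lm.control(
            maxiter = 200, ftol = 1e-12, ptol = 1e-10))),
        error = function(e) NULL)
      if (!is.null(lm)) {
        ssr_lm <- sum(lm$fvec^2)
        if (is.finite(ssr_lm) && ssr_lm <= cur$ssr) {
          cur <- list(t1 = lm$par[3], a = lm$par[1], b = lm$par[2],
                      ssr = ssr_lm)
        }
      }
      if (cur$ssr < best$ssr[i]) {
        best$ssr[i] <- cur$ssr
        best$a[i] <- cur$a; best$b[i] <- cur$b; best$t1[i] <- cur$t1
      }
    }
  }

  ok <- is.finite(best$t1) &
    best$t1 >= t1_limits[1] & best$t1 <= t1_limits[2] &
    is.finite(best$a) & best$a >= 0
  t1[vox] <- ifelse(ok, best$t1, NA_real_)
  a[vox] <- ifelse(ok, best$a, NA_real_)
  b[vox] <- ifelse(ok, best$b, NA_real_)
  rms[vox] <- ifelse(ok, sqrt(best$ssr / k), NA_real_)
  valid[vox] <- ok
  if (!any(valid)) warn("no voxel produced a valid fit")
  parameter_maps(t1, a, b, rms, valid, series$geometry)
}
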