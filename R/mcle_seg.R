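#' Build a clustering feature table from parameter maps
#'
#' Collects the per-voxel (T1*, steady-state) pairs inside an analysis mask,
#' dropping voxels with invalid fits, and z-scores each feature over the
#' included voxels. The standardization parameters are stored so raw
#' feature space (ms, a.u.) can be recovered exactly.
#'
#' @param maps A [parameter_maps()] object.
#' @param analysis_mask Logical volume of voxels to cluster.
#' @return A `feature_table`: tibble with voxel indices (`i`, `j`, `k`),
#'   raw features (`t1star`, `steady_state`), and z-scored features
#'   (`z_t1star`, `z_steady_state`); attributes `center` and `scale`.
#' @export
build_features <- function(maps, analysis_mask) {
  if (!identical(dim(analysis_mask), dim(maps$t1star))) {
    abort("analysis mask must match map geometry")
  }
  keep <- analysis_mask & maps$valid
  n_dropped <- sum(analysis_mask) - sum(keep)
  if (n_dropped > 0) {
    message(sprintf("dropping %d masked voxels with invalid fits", n_dropped))
  }
  vox <- which(keep)
  if (length(vox) < 3L) {
    abort("fewer than 3 valid voxels: cannot form 3 clusters")
  }
  idx <- arrayInd(vox, dim(maps$t1star))
  raw <- cbind(t1star = maps$t1star[vox], steady_state = maps$a[vox])
  center <- colMeans(raw)
  scale <- apply(raw, 2, stats::sd)
  scale[scale == 0] <- 1  # degenerate constant feature: leave centered only
  z <- sweep(sweep(raw, 2, center), 2, scale, "/")
  out <- tibble(
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    t1star = raw[, 1], steady_state = raw[, 2],
    z_t1star = z[, 1], z_steady_state = z[, 2]
  )
  structure(out, center = center, scale = scale,
            dims = dim(maps$t1star), geometry = maps$geometry,
            class = c("feature_table", class(out)))
}

# k-means++-style seeding on distinct points.
seed_centroids <- function(x, k) {
  n <- nrow(x)
  cen <- matrix(NA_real_, k, ncol(x))
  cen[1, ] <- x[sample.int(n, 1), ]
  for (j in 2:k) {
    d2 <- apply(x, 1, function(p) {
      min(colSums((t(cen[seq_len(j - 1), , drop = FALSE]) - p)^2))
    })
    if (all(d2 == 0)) {
      cen[j, ] <- x[sample.int(n, 1), ]
    } else {
      cen[j, ] <- x[sample.int(n, 1, prob = d2), ]
    }
  }
  cen
}

fcm_memberships <- function(d2, m) {
  # u_ik = 1 / sum_j (d_ik / d_jk)^(1/(m-1)) on squared distances;
  # points coinciding with a centroid get membership 1 there (split if tied)
  n <- nrow(d2); k <- ncol(d2)
  u <- matrix(0, n, k)
  zero <- d2 <= .Machine$double.eps
  has_zero <- rowSums(zero) > 0
  if (any(has_zero)) {
    zz <- zero[has_zero, , drop = FALSE]
    u[has_zero, ] <- zz / rowSums(zz)
  }
  if (any(!has_zero)) {
    p <- d2[!has_zero, , drop = FALSE]^(-1 / (m - 1))
    u[!has_zero, ] <- p / rowSums(p)
  }
  u
}

fcm_objective <- function(d2, u, m) sum(u^m * d2)

fcm_once <- function(x, k, m, tol, max_iter, retries = 20) {
  n <- nrow(x)
  for (try in seq_len(retries)) {
    cen <- seed_centroids(x, k)
    if (nrow(unique(cen)) == k) break
    if (try == retries) abort("could not seed distinct centroids")
  }
  d2 <- pairwise_sqdist(x, cen)
  u <- fcm_memberships(d2, m)
  j_prev <- fcm_objective(d2, u, m)
  trace <- j_prev
  for (it in seq_len(max_iter)) {
    um <- u^m
    w <- colSums(um)
    w[w == 0] <- .Machine$double.eps
    cen <- sweep(crossprod(um, x), 1, w, "/")
    d2 <- pairwise_sqdist(x, cen)
    u <- fcm_memberships(d2, m)
    j_cur <- fcm_objective(d2, u, m)
    trace <- c(trace, j_cur)
    if (abs(j_prev - j_cur) <= tol * max(1, j_prev)) {
      j_prev <- j_cur
      break
    }
    j_prev <- j_cur
  }
  list(u = u, centroids = cen, objective = j_prev, trace = trace,
       iterations = length(trace) - 1L)
}

pairwise_sqdist <- function(x, cen) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(cen))) -
    2 * x %*% t(cen) + outer(rep(1, nrow(x)), rowSums(cen^2))
  pmax(d2, 0)
}

#' Fuzzy C-means clustering of (T1*, steady-state) features
#'
#' Minimizes the fuzzified within-cluster objective
#' `J = sum_i sum_k u_ik^m ||x_i - c_k||^2` by alternating membership and
#' centroid updates, with seeded k-means++-style initialization and
#' multiple restarts; the restart with the lowest objective is returned.
#' Clustering runs in z-scored feature space; centroids are reported both
#' standardized and in raw (ms, a.u.) units when the input is a
#' [build_features()] table.
#'
#' @param features A `feature_table` (preferred) or a numeric matrix of
#'   points.
#' @param centers Number of clusters (3: infarct / healthy / blood).
#' @param m Fuzzifier (> 1); default 2.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum alternating iterations per restart.
#' @param seed Integer seed (initialization is the only randomness).
#' @param restarts Number of seeded restarts.
#' @return An `fcm_fit`: memberships (n x k), `centroids` (standardized),
#'   `centroids_raw` (de-standardized, when available), objective value and
#'   per-iteration `trace` of the winning restart, and the feature table.
#' @export
fcm <- function(features, centers = 3, m = 2, tol = 1e-5, max_iter = 300,
                seed = 1L, restarts = 5) {
  if (m <= 1) abort("fuzzifier m must be > 1")
  is_ft <- inherits(features, "feature_table")
  x <- if (is_ft) {
    cbind(features$z_t1star, features$z_steady_state)
  } else as.matrix(features)
  if (nrow(unique(x)) < centers) {
    abort(sprintf("need at least %d distinct points", centers))
  }
  runs <- with_local_seed(seed, function() {
    lapply(seq_len(restarts), function(r) {
      fcm_once(x, centers, m, tol, max_iter)
    })
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]
  centroids_raw <- NULL
  if (is_ft) {
    cen <- best$centroids
    centroids_raw <- sweep(sweep(cen, 2, attr(features, "scale"), "*"),
                           2, -attr(features, "center"), "-")
    colnames(centroids_raw) <- c("t1star", "steady_state")
  }
  structure(
    list(memberships = best$u, centroids = best$centroids,
         centroids_raw = centroids_raw, m = m,
         objective = best$objective, trace = best$trace,
         iterations = best$iterations,
         restart_objectives = vapply(runs, `[[`, numeric(1), "objective"),
         features = if (is_ft) features else NULL),
    class = "fcm_fit")
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("<fcm_fit> %d points, %d clusters, objective %.6g (%d iterations)\n",
              nrow(x$memberships), ncol(x$memberships), x$objective,
              x$iterations))
  if (!is.null(x$centroids_raw)) {
    cat("centroids (raw units):\n")
    print(round(x$centroids_raw, 2))
  }
  invisible(x)
}

#' @rdname fcm
#' @param x An `fcm_fit`.
#' @param ... Unused.
#' @export
tidy.fcm_fit <- function(x, ...) {
  u <- as_tibble(x$memberships, .name_repair = ~ paste0("u_", seq_along(.x)))
  out <- if (!is.null(x$features)) {
    dplyr::bind_cols(x$features[, c("i", "j", "k", "t1star", "steady_state")],
                     u)
  } else u
  out$cluster <- max.col(x$memberships)
  out
}

#' @rdname fcm
#' @export
glance.fcm_fit <- function(x, ...) {
  tibble(n = nrow(x$memberships), k = ncol(x$memberships), m = x$m,
         objective = x$objective, iterations = x$iterations,
         restarts = length(x$restart_objectives))
}

#' Name FCM clusters as blood / infarct / healthy
#'
#' In late-enhancement feature space blood has the largest steady-state
#' amplitude; of the two remaining clusters the infarct recovers faster
#' (shorter T1*) than nulled healthy myocardium. Ties on amplitude are
#' broken toward shorter T1* (then lower amplitude) with a warning.
#'
#' @param fit An `fcm_fit` with de-standardized centroids.
#' @return Named integer vector mapping tissue name (`blood`, `infarct`,
#'   `healthy`) to cluster index.
#' @export
label_clusters <- function(fit) {
  cen <- fit$centroids_raw
  if (is.null(cen)) abort("fit lacks raw-unit centroids; cluster on a feature_table")
  if (nrow(cen) != 3L) abort("tissue naming expects exactly 3 clusters")
  amp <- cen[, "steady_state"]
  t1 <- cen[, "t1star"]
  top <- which(amp == max(amp))
  if (length(top) > 1L) {
    warn("tied maximal steady-state amplitude; breaking tie by shorter T1*")
    top <- top[order(t1[top], amp[top])][1]
  }
  rest <- setdiff(1:3, top)
  if (t1[rest[1]] == t1[rest[2]]) {
    warn("tied T1* between non-blood clusters; breaking tie by amplitude")
    rest <- rest[order(t1[rest], cen[rest, "steady_state"])]
  } else {
    rest <- rest[order(t1[rest])]
  }
  c(blood = top, infarct = rest[1], healthy = rest[2])
}

#' Classify voxels from fuzzy memberships
#'
#' Applies the probability-band rule within the myocardium mask: core where
#' the infarct membership exceeds the upper band limit, gray zone where it
#' lies within the band (bounds inclusive), healthy below it. Voxels whose
#' blood membership exceeds `blood_override` are labeled blood regardless
#' (cavity partial-volume guard). Clustered voxels outside the myocardium
#' are labeled blood when blood is their strongest membership and excluded
#' otherwise; voxels never clustered stay excluded (label 0).
#'
#' @param fit An `fcm_fit` built from a `feature_table`.
#' @param mapping Tissue-to-cluster mapping from [label_clusters()].
#' @param myo_mask Logical myocardium mask.
#' @param band Gray-zone membership band; default `c(0.25, 0.75)`.
#' @param blood_override Blood-membership threshold; default 0.5.
#' @return A [label_volume()] with labels excluded (0), blood, healthy,
#'   gray_zone, core.
#' @export
classify <- function(fit, mapping, myo_mask, band = c(0.25, 0.75),
                     blood_override = 0.5) {
  ft <- fit$features
  if (is.null(ft)) abort("fit lacks voxel indices; cluster on a feature_table")
  dims <- attr(ft, "dims")
  if (!identical(dim(myo_mask), dims)) abort("myocardium mask geometry mismatch")
  u_inf <- fit$memberships[, mapping[["infarct"]]]
  u_blood <- fit$memberships[, mapping[["blood"]]]
  vox <- (ft$k - 1L) * dims[1] * dims[2] + (ft$j - 1L) * dims[1] + ft$i
  in_myo <- myo_mask[vox]

  lab <- integer(length(vox))
  lab[in_myo & u_inf > band[2]] <- LABELS[["core"]]
  lab[in_myo & u_inf >= band[1] & u_inf <= band[2]] <- LABELS[["gray_zone"]]
  lab[in_myo & u_inf < band[1]] <- LABELS[["healthy"]]
  lab[in_myo & u_blood > blood_override] <- LABELS[["blood"]]
  hard <- max.col(fit$memberships)
  lab[!in_myo] <- ifelse(hard[!in_myo] == mapping[["blood"]],
                         LABELS[["blood"]], LABELS[["background"]])

  out <- array(LABELS[["background"]], dims)
  out[vox] <- lab
  label_volume(out, attr(ft, "geometry"))
}

# Label face-connected components of a logical volume (3-D, 6-neighborhood).
connected_components <- function(mask) {
  dims <- dim(mask)
  comp <- array(0L, dims)
  cur <- 0L
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  todo <- which(mask)
  for (start in todo) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- integer(64)
    queue[1] <- start
    head <- 1L; tail <- 1L
    comp[start] <- cur
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      ind <- arrayInd(v, dims)
      for (o in seq_len(6)) {
        ni <- ind + offsets[o, , drop = FALSE]
        if (any(ni < 1) || any(ni > dims)) next
        nv <- ni[1] + (ni[2] - 1L) * dims[1] + (ni[3] - 1L) * dims[1] * dims[2]
        if (mask[nv] && comp[nv] == 0L) {
          comp[nv] <- cur
          tail <- tail + 1L
          if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[tail] <- nv
        }
      }
    }
  }
  comp
}

face_neighbors <- function(vox, dims) {
  ind <- arrayInd(vox, dims)
  out <- integer(0)
  for (d in 1:3) {
    for (s in c(-1L, 1L)) {
      ni <- ind
      ni[, d] <- ni[, d] + s
      ok <- ni[, d] >= 1L & ni[, d] <= dims[d]
      if (any(ok)) {
        nn <- ni[ok, , drop = FALSE]
        out <- c(out, nn[, 1] + (nn[, 2] - 1L) * dims[1] +
                   (nn[, 3] - 1L) * dims[1] * dims[2])
      }
    }
  }
  setdiff(unique(out), vox)
}

#' Remove isolated noise-classified voxels
#'
#' Automated surrogate for the manual cleanup step of late-enhancement
#' analysis: face-connected components of core-or-gray-zone voxels smaller
#' than `min_size` whose entire neighborhood is healthy myocardium are
#' relabeled healthy. Components touching blood, other infarct tissue, or
#' the analysis boundary are left untouched.
#'
#' @param classmap A classified [label_volume()].
#' @param min_size Components strictly smaller than this are candidates
#'   (default 2, i.e. single voxels).
#' @param connectivity Only `"face"` (6-neighborhood) is implemented.
#' @return The cleaned [label_volume()].
#' @export
despeckle <- function(classmap, min_size = 2, connectivity = "face") {
  if (!identical(connectivity, "face")) {
    abort("only face connectivity is implemented")
  }
  dims <- dim(classmap)
  target <- array(as.integer(classmap) %in%
                    LABELS[c("core", "gray_zone")], dims)
  comp <- connected_components(target)
  out <- array(as.integer(classmap), dims)
  if (max(comp) > 0) {
    for (cc in seq_len(max(comp))) {
      vox <- which(comp == cc)
      if (length(vox) >= min_size) next
      nb <- face_neighbors(vox, dims)
      nb <- setdiff(nb, vox)
      if (length(nb) && all(out[nb] == LABELS[["healthy"]])) {
        out[vox] <- LABELS[["healthy"]]
      }
    }
  }
  label_volume(out, vol_geometry(classmap))
}
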