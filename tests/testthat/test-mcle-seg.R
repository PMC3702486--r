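small_maps <- function(t1_vals, a_vals, valid = NULL) {
  n <- length(t1_vals)
  dims <- c(n, 1, 1)
  if (is.null(valid)) valid <- array(TRUE, dims)
  parameter_maps(array(t1_vals, dims), array(a_vals, dims),
                 array(2 * a_vals, dims), array(0, dims), valid)
}

test_that("feature standardization is exact and reversible", {
  set.seed(20)
  t1 <- rnorm(50, 400, 10)        # sd ~10
  a <- rnorm(50, 100, 1000)       # sd ~1000
  maps <- small_maps(t1, a)
  ft <- build_features(maps, array(TRUE, c(50, 1, 1)))
  expect_equal(sd(ft$z_t1star), 1, tolerance = 1e-12)
  expect_equal(sd(ft$z_steady_state), 1, tolerance = 1e-12)
  expect_equal(mean(ft$z_t1star), 0, tolerance = 1e-12)
  back <- ft$z_t1star * attr(ft, "scale")[1] + attr(ft, "center")[1]
  expect_equal(back, ft$t1star, tolerance = 1e-12)
})

test_that("invalid voxels are dropped and too-few voxels error", {
  maps <- small_maps(c(300, 400, 500, 600), c(1, 2, 3, 4),
                     valid = array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1)))
  expect_message(ft <- build_features(maps, array(TRUE, c(4, 1, 1))),
                 "dropping 1")
  expect_equal(nrow(ft), 3)
  all_bad <- small_maps(c(300, 400, 500), c(1, 2, 3),
                        valid = array(FALSE, c(3, 1, 1)))
  expect_error(build_features(all_bad, array(TRUE, c(3, 1, 1))),
               "fewer than 3")
})

test_that("fcm memberships are simplex-valued and the objective descends", {
  cl <- make_clouds(n_per = 50, sep = 8, sd = 1)
  fit <- fcm(cl$x, seed = 1)
  expect_true(all(fit$memberships >= 0 & fit$memberships <= 1))
  expect_equal(rowSums(fit$memberships), rep(1, nrow(cl$x)),
               tolerance = 1e-9)
  expect_true(all(diff(fit$trace) <= 1e-9 * max(1, fit$trace[1])))
})

test_that("well-separated clouds get confident, correct memberships", {
  cl <- make_clouds(n_per = 60, sep = 8, sd = 1, seed = 6)
  fit <- fcm(cl$x, seed = 2)
  hard <- max.col(fit$memberships)
  # map clusters to true labels by majority vote
  remap <- vapply(1:3, function(k) {
    as.integer(names(which.max(table(cl$labels[hard == k]))))
  }, integer(1))
  acc <- mean(remap[hard] == cl$labels)
  expect_gte(acc, 0.99)
  # winning memberships are confident on average (points in the overlap
  # tails are legitimately fuzzier under m = 2)
  own <- fit$memberships[cbind(seq_len(nrow(cl$x)), hard)]
  expect_gte(mean(own), 0.9)
  expect_gte(median(own), 0.95)
})

test_that("a point exactly at a centroid has membership one there", {
  x <- rbind(c(0, 0), c(10, 0), c(5, 10), c(0, 0.01), c(10, 0.01),
             c(5, 9.99))
  fit <- fcm(x, seed = 3, tol = 1e-12)
  # the first three points coincide (numerically) with the converged
  # centroids; their maximal membership must be ~1
  d <- as.matrix(dist(rbind(fit$centroids, x[1, ])))[4, 1:3]
  u1 <- fit$memberships[1, which.min(d)]
  expect_gte(u1, 0.999)
})

test_that("duplicating every point leaves the centroids unchanged", {
  cl <- make_clouds(n_per = 40, sep = 9, sd = 0.8, seed = 7)
  f1 <- fcm(cl$x, seed = 4, tol = 1e-10, restarts = 8)
  f2 <- fcm(rbind(cl$x, cl$x), seed = 5, tol = 1e-10, restarts = 8)
  sort_cen <- function(c) c[order(c[, 1], c[, 2]), ]
  expect_equal(sort_cen(f1$centroids), sort_cen(f2$centroids),
               tolerance = 1e-3)
})

test_that("fcm is deterministic given a seed and improves over restarts", {
  cl <- make_clouds(n_per = 30, sep = 8, sd = 1, seed = 8)
  f1 <- fcm(cl$x, seed = 99)
  f2 <- fcm(cl$x, seed = 99)
  expect_identical(f1$memberships, f2$memberships)
  expect_equal(f1$objective, min(f1$restart_objectives))
})

test_that("cluster naming follows the amplitude-then-T1* rule", {
  # emulate converged centroids through a tiny synthetic fit
  t1 <- c(rep(250, 30), rep(320, 30), rep(600, 30)) + rnorm(90, 0, 2)
  a <- c(rep(120, 30), rep(100, 30), rep(80, 30)) + rnorm(90, 0, 0.5)
  maps <- small_maps(t1, a)
  ft <- build_features(maps, array(TRUE, c(90, 1, 1)))
  fit <- fcm(ft, seed = 6)
  mp <- label_clusters(fit)
  cen <- fit$centroids_raw
  expect_equal(unname(cen[mp[["blood"]], "t1star"]), 250, tolerance = 10)
  expect_equal(unname(cen[mp[["infarct"]], "t1star"]), 320, tolerance = 10)
  expect_equal(unname(cen[mp[["healthy"]], "t1star"]), 600, tolerance = 10)
})

test_that("probability-band classification applies inclusive bounds", {
  dims <- c(5L, 1L, 1L)
  ft <- structure(
    tibble::tibble(i = 1:5, j = 1L, k = 1L,
                   t1star = rep(400, 5), steady_state = rep(90, 5),
                   z_t1star = 0, z_steady_state = 0),
    center = c(t1star = 400, steady_state = 90),
    scale = c(t1star = 1, steady_state = 1),
    dims = dims, geometry = vox_geometry(),
    class = c("feature_table", "tbl_df", "tbl", "data.frame"))
  u <- rbind(
    c(0.50, 0.45, 0.05),  # mid-band -> gray zone
    c(1.00, 0.00, 0.00),  # -> core
    c(0.25, 0.75, 0.00),  # lower bound inclusive -> gray zone
    c(0.10, 0.88, 0.02),  # -> healthy
    c(0.30, 0.10, 0.60))  # blood override
  fit <- structure(list(memberships = u, features = ft), class = "fcm_fit")
  mapping <- c(blood = 3L, infarct = 1L, healthy = 2L)
  myo <- array(TRUE, dims)
  cm <- classify(fit, mapping, myo)
  expect_equal(as.integer(cm), c(3L, 4L, 3L, 2L, 1L))
})

test_that("despeckling relabels isolated infarct voxels inside healthy", {
  dims <- c(5, 5, 1)
  arr <- array(2L, dims)            # healthy everywhere
  arr[3, 3, 1] <- 4L                # isolated core voxel
  cm <- label_volume(arr)
  out <- despeckle(cm)
  expect_equal(out[3, 3, 1], 2L)

  # a 5-voxel blob survives
  arr2 <- array(2L, dims)
  arr2[2:4, 3, 1] <- 4L; arr2[3, 2, 1] <- 4L; arr2[3, 4, 1] <- 4L
  expect_equal(sum(despeckle(label_volume(arr2)) == 4L), 5L)

  # an isolated gray-zone voxel adjacent to core is not "within healthy"
  arr3 <- array(2L, dims)
  arr3[3, 3, 1] <- 3L; arr3[3, 4, 1] <- 4L; arr3[3, 5, 1] <- 4L
  out3 <- despeckle(label_volume(arr3))
  expect_equal(out3[3, 3, 1], 3L)

  # a voxel bordered by blood is left alone
  arr4 <- array(2L, dims)
  arr4[3, 3, 1] <- 4L; arr4[3, 2, 1] <- 1L
  expect_equal(despeckle(label_volume(arr4))[3, 3, 1], 4L)
})

test_that("hard FCM labels agree with a k-means oracle on separated data", {
  cl <- make_clouds(n_per = 70, sep = 10, sd = 1, seed = 30)
  fit <- fcm(cl$x, seed = 31)
  hard <- max.col(fit$memberships)
  km <- kmeans(cl$x, centers = 3, nstart = 25)
  # align cluster indices via centroid proximity
  map_km <- apply(fit$centroids, 1, function(cen) {
    which.min(colSums((t(km$centers) - cen)^2))
  })
  agree <- mean(map_km[hard] == km$cluster)
  expect_gte(agree, 0.99)
})
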