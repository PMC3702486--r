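test_that("tissue mass is voxel count times voxel volume times density", {
  g <- vox_geometry(1.5, 1.5, 8)
  mask <- array(FALSE, c(100, 10, 1))
  expect_equal(tissue_mass(mask, g), 0)
  mask[seq_len(1000)] <- TRUE
  expect_equal(tissue_mass(mask, g), 18 * 1.05)   # 18 cm^3 -> 18.9 g
})

test_that("heterogeneity percentages follow the definitions", {
  g <- vox_geometry(10, 10, 10)  # 1 cm^3 voxels for round numbers
  dims <- c(20, 10, 1)
  arr <- array(0L, dims)
  arr[1:100] <- 2L      # healthy
  arr[1:10] <- 4L       # core
  arr[11:15] <- 3L      # gray zone
  cm <- label_volume(arr, g)
  myo <- array(arr %in% c(2L, 3L, 4L), dims)
  h <- heterogeneity(cm, myo)
  expect_equal(h$core_pct, 10)
  expect_equal(h$gz_pct, 5)
  expect_equal(h$total_pct, 15)
  expect_equal(h$total_g, h$core_g + h$gz_g, tolerance = 1e-12)
  expect_equal(h$lvm_g, 100 * 1.05)
  # mass conservation: core + GZ + healthy = LVM with one bookkeeping
  healthy_g <- tissue_mass(array(arr == 2L, dims), g)
  expect_equal(h$core_g + h$gz_g + healthy_g, h$lvm_g, tolerance = 1e-12)
})

test_that("an all-healthy wall yields zero percentages and LVM errors out at 0", {
  g <- vox_geometry(10, 10, 10)
  dims <- c(10, 1, 1)
  arr <- array(2L, dims)
  h <- heterogeneity(label_volume(arr, g), array(TRUE, dims))
  expect_equal(c(h$core_pct, h$gz_pct, h$total_pct), c(0, 0, 0))
  expect_error(heterogeneity(label_volume(array(0L, dims), g),
                             array(FALSE, dims)), "zero")
})

test_that("percentages are invariant to uniform voxel-volume changes", {
  dims <- c(20, 10, 1)
  arr <- array(0L, dims); arr[1:100] <- 2L; arr[1:10] <- 4L
  myo <- array(arr %in% c(2L, 4L), dims)
  h1 <- heterogeneity(label_volume(arr, vox_geometry(1, 1, 1)), myo)
  h2 <- heterogeneity(label_volume(arr, vox_geometry(2.5, 2.5, 9)), myo)
  expect_equal(h1$core_pct, h2$core_pct, tolerance = 1e-12)
  expect_gt(h2$core_g, h1$core_g)
})

test_that("heterogeneity on the phantom equals brute-force voxel arithmetic", {
  ph <- make_phantom(phantom_spec())
  myo <- myocardium_mask(ph$labels)
  h <- heterogeneity(ph$labels, myo)
  vv <- 1.5 * 1.5 * 8 / 1000
  n_core <- sum(ph$labels == 4L)
  n_gz <- sum(ph$labels == 3L)
  n_myo <- sum(myo)
  expect_equal(h$core_g, n_core * vv * 1.05, tolerance = 1e-12)
  expect_equal(h$gz_pct, 100 * n_gz / n_myo, tolerance = 1e-12)
})

test_that("PM scoring counts infarcted papillary muscles", {
  dims <- c(10, 10, 1)
  pm1 <- array(FALSE, dims); pm1[1:4, 1, 1] <- TRUE
  pm2 <- array(FALSE, dims); pm2[1:4, 2, 1] <- TRUE
  base <- array(1L, dims)

  fully <- base; fully[pm1] <- 4L; fully[pm2] <- 4L
  expect_equal(pm_score(label_volume(fully), list(pm1, pm2))$score, 2)

  one <- base; one[pm1] <- 4L
  expect_equal(pm_score(label_volume(one), list(pm1, pm2))$score, 1)

  expect_equal(pm_score(label_volume(base), list(pm1, pm2))$score, 0)

  # boundary: exactly half the voxels infarcted counts (inclusive)
  half <- base; half[1:2, 1, 1] <- 4L
  s <- pm_score(label_volume(half), list(pm1, pm2))
  expect_true(s$per_pm$infarcted[1])
  expect_equal(s$score, 1)

  # empty PM mask scores not-infarcted with a warning
  expect_warning(
    s2 <- pm_score(label_volume(fully), list(pm1, array(FALSE, dims))),
    "empty")
  expect_equal(s2$score, 1)
})

test_that("intensity-path PM scoring uses the half-peak cutoff", {
  dims <- c(10, 1, 1)
  img <- image_volume(array(c(rep(60, 5), rep(5, 5)), dims))
  pm1 <- array(c(rep(TRUE, 5), rep(FALSE, 5)), dims)
  pm2 <- array(c(rep(FALSE, 5), rep(TRUE, 5)), dims)
  s <- pm_score(img, list(pm1, pm2), peak_infarct = 100)
  expect_true(s$per_pm$infarcted[1])    # mean 60 >= 50
  expect_false(s$per_pm$infarcted[2])   # mean 5 < 50
  expect_equal(s$score, 1)
})

test_that("summation-of-disks LV function matches hand arithmetic", {
  g <- vox_geometry(10, 10, 8)   # 0.8 cm^3 per voxel
  dims <- c(10, 10, 3)
  ed <- array(FALSE, dims); ed[1:10, 1, ] <- TRUE   # 10 voxels x 3 slices
  es <- array(FALSE, dims); es[1:5, 1, ] <- TRUE
  epi <- array(FALSE, dims); epi[1:10, 1:4, ] <- TRUE
  lv <- lv_function(list(ed, es), epi, g)
  expect_equal(lv$edv_ml, 30 * 0.8)   # 24 ml
  expect_equal(lv$esv_ml, 15 * 0.8)
  expect_equal(lv$sv_ml, 12)
  expect_equal(lv$ef_pct, 50)
  # shell = 120 - 30 voxels = 90 * 0.8 cm3 * 1.05
  expect_equal(lv$lvm_g, 90 * 0.8 * 1.05)

  lv0 <- lv_function(list(ed, ed), epi, g)
  expect_equal(lv0$sv_ml, 0)
  expect_equal(lv0$ef_pct, 0)
  empty <- array(FALSE, dims)
  expect_error(lv_function(list(empty, empty), epi, g), "zero")
})
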