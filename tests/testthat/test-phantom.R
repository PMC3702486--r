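test_that("phantom geometry matches an independent per-voxel scan", {
  spec <- phantom_spec(noise_sd = 0)
  ph <- make_phantom(spec)
  labs <- ph$labels

  # independent triple-loop rasterization of the core-wedge predicates
  core_count <- 0L
  myo_count <- 0L
  wall <- spec$epi_radius - spec$endo_radius
  for (i in seq_len(spec$nx)) {
    for (j in seq_len(spec$ny)) {
      x <- (i - 0.5) * spec$res_xy - spec$center[1]
      y <- (j - 0.5) * spec$res_xy - spec$center[2]
      r <- sqrt(x^2 + y^2)
      th <- atan2(y, x) * 180 / pi
      d <- (th - spec$infarct_angle) %% 360
      if (d > 180) d <- d - 360
      if (r >= spec$endo_radius && r < spec$epi_radius) {
        myo_count <- myo_count + 1L
        if (abs(d) < spec$infarct_extent / 2 &&
            r < spec$endo_radius + spec$transmural_fraction * wall) {
          core_count <- core_count + 1L
        }
      }
    }
  }
  expect_identical(sum(labs[, , 1] == 4L), core_count)
  expect_identical(sum(tissue_mask_of(labs, c("healthy", "gray_zone",
                                              "core"))[, , 1]), myo_count)
})

test_that("label bookkeeping conserves the grid and classes are disjoint", {
  ph <- make_phantom(phantom_spec())
  counts <- table(as.integer(ph$labels))
  expect_identical(sum(counts), length(ph$labels))
  myo <- myocardium_mask(ph$labels)
  expect_false(any(myo & tissue_mask_of(ph$labels, "blood")))
  expect_false(any(myo & tissue_mask_of(ph$labels, "background")))
})

test_that("zero infarct extent yields no core and no gray zone", {
  ph <- make_phantom(phantom_spec(infarct_extent = 0))
  expect_identical(sum(ph$labels == 4L), 0L)
  expect_identical(sum(ph$labels == 3L), 0L)
})

test_that("phantom construction is deterministic", {
  a <- make_phantom(phantom_spec())
  b <- make_phantom(phantom_spec())
  expect_identical(as.integer(a$labels), as.integer(b$labels))
  expect_identical(a$truth$t1star, b$truth$t1star)
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(endo_radius = 30, epi_radius = 20), "radius")
  expect_error(phantom_spec(transmural_fraction = 0), "transmural")
  expect_error(phantom_spec(rim_width = -1), "rim")
  expect_error(phantom_spec(pm = list(
    list(center = c(0, 30), radius = 3, infarcted = FALSE),
    list(center = c(0, -12), radius = 3, infarcted = FALSE))), "blood pool")
})

test_that("gray-zone ground truth is a 50/50 core/healthy parameter mix", {
  ph <- make_phantom(phantom_spec())
  gz <- tissue_mask_of(ph$labels, "gray_zone")
  expect_true(all(ph$truth$t1star[gz] == (320 + 600) / 2))
  expect_true(all(ph$truth$a[gz] == (100 + 80) / 2))
})

test_that("inversion-recovery signal simulation matches the closed form", {
  a <- array(100, c(1, 1, 1)); t1 <- array(300, c(1, 1, 1))
  truth <- parameter_maps(t1, a, 2 * a, array(0, c(1, 1, 1)),
                          array(TRUE, c(1, 1, 1)))
  # null point: TI = T1* ln 2
  s_null <- simulate_mcle(truth, 300 * log(2), noise_sd = 0)
  expect_equal(s_null$data[1, 1, 1, 1], 0, tolerance = 1e-12)
  # direct evaluation at TI = 600
  s <- simulate_mcle(truth, 600, noise_sd = 0)
  expect_equal(s$data[1, 1, 1, 1], 100 - 200 * exp(-2), tolerance = 1e-12)
  # steady-state limit
  s_inf <- simulate_mcle(truth, 3000, noise_sd = 0)
  expect_equal(s_inf$data[1, 1, 1, 1], 100, tolerance = 1e-4 * 100)
  # strictly increasing in TI before magnitude
  s_all <- simulate_mcle(truth, seq(50, 1000, by = 50), noise_sd = 0)
  expect_true(all(diff(s_all$data[1, 1, 1, ]) > 0))
})

test_that("mcle simulation is seed-reproducible and rejects empty TIs", {
  ph <- make_phantom(phantom_spec(nx = 16, ny = 16, n_slices = 1))
  s1 <- simulate_mcle(ph$truth, c(100, 300, 600), noise_sd = 3, seed = 11)
  s2 <- simulate_mcle(ph$truth, c(100, 300, 600), noise_sd = 3, seed = 11)
  expect_identical(s1$data, s2$data)
  expect_error(simulate_mcle(ph$truth, numeric(0)), "non-empty")
})

test_that("IR-FGRE nulls healthy myocardium and hyperenhances core", {
  ph <- make_phantom(phantom_spec(noise_sd = 0))
  img <- simulate_ir_fgre(ph$truth, noise_sd = 0)
  healthy <- tissue_mask_of(ph$labels, "healthy")
  core <- tissue_mask_of(ph$labels, "core")
  expect_equal(max(abs(img[healthy])), 0, tolerance = 1e-12)
  expect_true(all(img[core] > 0))
  expect_gt(mean(img[core]), mean(img[healthy]))
})

test_that("cohort simulation honors group parameters and the seed", {
  params <- default_cohort_params()
  # degenerate sd = 0 collapses every subject onto the group mean
  p0 <- params
  p0$measures$sd1[] <- 0
  p0$measures$sd2[] <- 0
  co <- simulate_cohort(p0, seed = 5)
  g1 <- co[co$icd_therapy, ]
  expect_true(all(abs(g1$gz_mcle_pct - 14.8) < 1e-12))
  expect_true(all(abs(g1$lvef_pct - 22.1) < 1e-12))
  # totals are exact sums
  co2 <- simulate_cohort(params, seed = 9)
  expect_equal(co2$total_mcle_pct, co2$core_mcle_pct + co2$gz_mcle_pct,
               tolerance = 1e-12)
  expect_true(all(co2$pm_score %in% 0:2))
  # determinism
  expect_identical(simulate_cohort(params, seed = 9), co2)
  # invalid probability vector
  bad <- params
  bad$pm_probs[1, ] <- c(0.5, 0.5, 0.5)
  expect_error(simulate_cohort(bad, seed = 1), "probabilities")
})

test_that("replicate cohort means concentrate on the group parameter", {
  params <- default_cohort_params()
  means <- vapply(1:300, function(s) {
    co <- simulate_cohort(params, seed = s)
    mean(co$gz_mcle_pct[co$icd_therapy])
  }, numeric(1))
  # Monte-Carlo error of the mean of 300 sample means: 4.8/sqrt(12*300) ~ 0.08
  expect_equal(mean(means), 14.8, tolerance = 0.35)
})
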