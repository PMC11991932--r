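test_that("an empty scene rasterizes to bath and tube only", {
  sc <- phantom_scene(list(), extent_mm = c(10, 30, 30))
  vol <- rasterize_scene(sc)
  expect_true(all(vol$voxels %in% 0:15))
  # interior bath voxels are exactly 0 HU
  expect_equal(vol$voxels[5, 3, 3], 0L)
  expect_equal(vol$voxels[5, 22, 22], 0L)  # tube lumen is water too
  # the wall ring exists
  expect_true(any(vol$voxels == 15L))
})

test_that("voxels fully inside a stone take its density exactly", {
  sc <- test_scene(5.2, 1000)
  vol <- rasterize_scene(sc)
  ctr <- round(c(15 / 1, 15 / 0.7, 15 / 0.7) + 0.5)
  expect_equal(vol$voxels[ctr[1], ctr[2], ctr[3]], 1000L)
})

test_that("partial-volume occupancy conserves the cylinder's volume", {
  for (dmm in c(2.6, 5.2, 8.6)) {
    sc <- test_scene(dmm, 1000)
    vol <- rasterize_scene(sc)
    # occupancy recovered from HU (bath 0, tube ring excluded by HU > 20)
    occ <- pmax(vol$voxels - 0, 0) / 1000
    occ[vol$voxels <= 20] <- 0
    fg_volume <- sum(occ) * prod(sc$spacing)
    analytic <- pi * (dmm / 2)^2 * 10
    expect_lt(abs(fg_volume - analytic) / analytic, 0.02)
  }
})

test_that("overlapping stones are a hard error", {
  expect_error(
    phantom_scene(list(
      phantom_stone(5, 1000, centre = c(15, 15, 15)),
      phantom_stone(5, 3000, centre = c(15, 15, 18))
    )),
    "too close"
  )
  # bypass the scene-level spacing check: rasterizer still refuses overlap
  sc <- phantom_scene(phantom_stone(5, 1000, centre = c(15, 15, 15)))
  sc$stones <- c(sc$stones,
                 list(phantom_stone(5, 3000, centre = c(15, 15, 17))))
  expect_error(rasterize_scene(sc), "overlap")
})

test_that("the identity acquisition returns the ideal volume exactly", {
  sc <- test_scene(3.8, 1000)  # psf 0, noise 0, bloom off
  ideal <- rasterize_scene(sc)
  out <- apply_acquisition(ideal, sc, seed = 1)
  expect_identical(out$voxels, ideal$voxels)
})

test_that("acquisition is seed-reproducible and water stays near 0 HU", {
  sc <- test_scene(3.8, 1000, noiseless = FALSE)
  ideal <- rasterize_scene(sc)
  a1 <- apply_acquisition(ideal, sc, seed = 5)
  a2 <- apply_acquisition(ideal, sc, seed = 5)
  a3 <- apply_acquisition(ideal, sc, seed = 6)
  expect_identical(a1$voxels, a2$voxels)
  expect_false(identical(a1$voxels, a3$voxels))
  # pure-water region mean within 0 +/- 7 HU
  water <- a1$voxels[, 1:5, 1:5]
  expect_lt(abs(mean(water)), 7)
  expect_error(apply_acquisition(ideal,
                                 modifyList(sc, list(noise_sd_hu = -1))),
               ">= 0")
})

test_that("blooming strictly enlarges dense stones; blur shrinks faint ones", {
  sc_off <- test_scene(5.2, 3000, noiseless = FALSE)
  sc_on <- test_scene(5.2, 3000, noiseless = FALSE,
                      bloom = bloom_config(enabled = TRUE))
  ideal <- rasterize_scene(sc_off)
  size_of <- function(vol) {
    measure_stones(detect_stones(vol))$size_mm
  }
  s_off <- size_of(apply_acquisition(ideal, sc_off, seed = 2))
  s_on <- size_of(apply_acquisition(ideal, sc_on, seed = 2))
  expect_gt(s_on, s_off)

  # increasing PSF sigma at 100 HU decreases the mean measured size
  # (a stone blurred beyond measurability counts as size 0)
  mean_size <- vapply(c(0.2, 0.5, 0.8), function(sig) {
    sizes <- vapply(c(4.6, 6.6, 8.6), function(dmm) {
      sc <- test_scene(dmm, 100, noiseless = FALSE)
      sc$psf_sigma_mm <- c(sig, sig)
      m <- measure_stones(detect_stones(
        apply_acquisition(rasterize_scene(sc), sc, seed = 3)))
      if (nrow(m) == 0 || is.na(m$size_mm[1])) 0 else m$size_mm[1]
    }, 0)
    mean(sizes)
  }, 0)
  expect_true(all(diff(mean_size) < 0))
})

test_that("synthesize_study reproduces the study design", {
  study <- synthesize_study(seed = 3, acquire = FALSE)
  expect_length(study$volumes, 6L)
  expect_equal(nrow(study$truth), 24L)
  expect_equal(as.integer(table(study$truth$density_hu)), rep(8L, 3))
  expect_equal(as.integer(table(study$truth$tube)), rep(4L, 6))
  for (d in stone_densities()) {
    expect_equal(sort(study$truth$true_mm[study$truth$density_hu == d]),
                 stone_sizes())
  }
  # seed-deterministic assignment
  study2 <- synthesize_study(seed = 3, acquire = FALSE)
  expect_identical(study$truth, study2$truth)
  study3 <- synthesize_study(seed = 4, acquire = FALSE)
  expect_false(identical(study$truth$tube, study3$truth$tube))
  expect_error(synthesize_study(seed = 1, slot_spacing_mm = 10),
               "separation")
})

test_that("simulate_raters applies bias and noise as specified", {
  truth <- synthesize_study(seed = 1, acquire = FALSE)$truth
  # zero bias, zero noise: measurements equal truth, MAE 0 downstream
  rec0 <- simulate_raters(truth, rater_model(n_raters = 5, bias = 0, sd = 0),
                          seed = 1)
  expect_equal(rec0$measured_mm, rec0$true_mm)
  expect_true(all(mae_table(rec0)$mae == 0))
  # bias +2, sd 0: every absolute error exactly 2
  rec2 <- simulate_raters(truth, rater_model(n_raters = 5, bias = 2, sd = 0),
                          seed = 1)
  expect_true(all(abs(add_absolute_errors(rec2)$abs_error - 2) < 1e-12))
  expect_error(rater_model(sd = -1), ">= 0")
})

test_that("rater noise reproduces the half-normal mean error", {
  truth <- synthesize_study(seed = 2, acquire = FALSE)$truth
  rec <- simulate_raters(truth, rater_model(n_raters = 52, bias = 0, sd = 1),
                         seed = 9)
  err <- abs(rec$measured_mm - rec$true_mm)
  n <- length(err)
  se <- sqrt(1 - 2 / pi) / sqrt(n)
  expect_lt(abs(mean(err) - sqrt(2 / pi)), 3 * se)
})
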