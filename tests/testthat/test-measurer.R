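test_that("slice_centre is the binary centroid", {
  m <- matrix(FALSE, 10, 12)
  m[5, 7] <- TRUE
  expect_equal(slice_centre(m), c(5, 7))
  # symmetric disc: centre within half a pixel of the disc centre
  yy <- row(matrix(0, 21, 21)); xx <- col(matrix(0, 21, 21))
  disc <- (yy - 11)^2 + (xx - 11)^2 <= 36
  expect_equal(slice_centre(disc), c(11, 11), tolerance = 0.5)
  # random blob equals the scalar-loop mean of member coordinates
  blob <- withr::with_seed(4, matrix(runif(200) < 0.3, 10, 20))
  got <- slice_centre(blob)
  acc <- c(0, 0); n <- 0
  for (i in 1:10) for (j in 1:20) if (blob[i, j]) {
    acc <- acc + c(i, j); n <- n + 1
  }
  expect_equal(got, acc / n)
  expect_null(slice_centre(matrix(FALSE, 3, 3)))
})

test_that("cast_ray samples constants and lattice rows exactly", {
  flat <- matrix(500, 9, 9)
  for (a in c(0, pi / 3, 2)) {
    r <- cast_ray(flat, c(1, 1), c(5, 5), a, 0.5)
    expect_true(all(abs(r$samples - 500) < 1e-9))
    expect_true(all(diff(r$positions) > 0))
  }
  grid <- withr::with_seed(2, matrix(rnorm(81), 9, 9))
  r0 <- cast_ray(grid, c(1, 1), c(4, 2), 0, sample_step = 1)
  expect_equal(r0$samples, grid[4, 2:9], tolerance = 1e-12)
  expect_error(cast_ray(grid, c(1, 1), c(20, 4), 0), "outside")
})

test_that("cast_ray matches the scalar bilinear oracle", {
  sl <- withr::with_seed(6, matrix(runif(30 * 30, -100, 2000), 30, 30))
  angles <- withr::with_seed(7, runif(20, 0, 2 * pi))
  for (a in angles) {
    r <- cast_ray(sl, c(0.7, 0.7), c(14.3, 16.8), a, 0.5)
    t <- seq_along(r$samples) - 1
    ys <- 14.3 + t * 0.5 * sin(a)
    xs <- 16.8 + t * 0.5 * cos(a)
    oracle <- mapply(function(y, x) bilinear_oracle(sl, y, x), ys, xs)
    expect_equal(r$samples, unname(oracle), tolerance = 1e-9)
    # positions follow the direction-dependent physical step
    expect_equal(r$positions,
                 t * 0.5 * sqrt((0.7 * sin(a))^2 + (0.7 * cos(a))^2),
                 tolerance = 1e-12)
  }
})

test_that("haar_response is the first forward difference", {
  expect_equal(haar_response(rep(7, 10)), rep(0, 9))
  st <- c(rep(1000, 5), rep(0, 5))
  r <- haar_response(st)
  expect_equal(which.min(r), 5L)
  expect_equal(min(r), -1000)
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rnorm(50))
    oracle <- x[-1] - x[-50]
    expect_equal(haar_response(x), oracle, tolerance = 1e-12)
  }
  expect_error(haar_response(3), "at least 2")
})

test_that("locate_edge finds an ideal disc edge at its analytic radius", {
  pos <- seq(0, 8, by = 0.25)
  samples <- ifelse(pos < 3.0, 1000, 0)
  prof <- list(angle = 0, samples = samples, positions = pos)
  edge <- locate_edge(prof, measurer_config())
  expect_lt(abs(edge - 3.0), 0.25 + 1e-9)
})

test_that("locate_edge honours the response threshold and arg-min rule", {
  pos <- seq(0, 8, by = 0.5)
  up <- list(angle = 0, samples = seq(0, 1600, by = 100), positions = pos)
  expect_true(is.na(locate_edge(up, measurer_config(tau = 50))))
  # two descents: -800 at 2 mm and -200 at 5 mm; global min rule picks 2 mm
  samples <- rep(1000, length(pos))
  samples[pos >= 2] <- 200
  samples[pos >= 5] <- 0
  prof <- list(angle = 0, samples = samples, positions = pos)
  edge <- locate_edge(prof, measurer_config(refine = FALSE))
  expect_lt(abs(edge - 2.0), 0.5 + 1e-9)
  edge_first <- locate_edge(prof, measurer_config(edge_rule = "first-min",
                                                  refine = FALSE))
  expect_lt(abs(edge_first - 2.0), 0.5 + 1e-9)
})

test_that("measure_slice recovers a disc diameter and reports edge points", {
  # ideal disc, radius 3 mm, on a 0.5 mm grid
  n <- 41
  yy <- (row(matrix(0, n, n)) - 21) * 0.5
  xx <- (col(matrix(0, n, n)) - 21) * 0.5
  hu <- ifelse(yy^2 + xx^2 <= 9, 1000, 0)
  mask <- hu > 80
  res <- measure_slice(hu, mask, c(0.5, 0.5), measurer_config())
  expect_true(is.na(res$skipped))
  expect_equal(res$n_edges, 360L)
  expect_lt(abs(res$diameter_mm - 6), 0.5 + 1e-9)
  # all edge points lie within a sample step of the circle
  ctr <- (slice_centre(mask) - 1) * 0.5
  r <- sqrt((res$points[, 1] - ctr[1])^2 + (res$points[, 2] - ctr[2])^2)
  expect_true(all(abs(r - 3) < 0.5))
})

test_that("slices without contrast are skipped with a reason", {
  flat <- matrix(10, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[9:11, 9:11] <- TRUE
  res <- measure_slice(flat, mask, c(0.7, 0.7), measurer_config())
  expect_true(is.na(res$diameter_mm))
  expect_match(res$skipped, "edge points")
})

test_that("measure_stone recovers a noiseless cylinder within one pixel", {
  sc <- test_scene(5.2, 1000, spacing = c(1, 0.5, 0.5))
  vol <- rasterize_scene(sc)
  det <- detect_stones(vol)
  m <- measure_stones(det)
  expect_equal(nrow(m), 1L)
  expect_lt(abs(m$size_mm - 5.2), 0.5 + 1e-9)
  expect_gte(m$n_slices_used, 8L)
  # determinism: identical inputs give identical measurements
  m2 <- measure_stones(det)
  expect_identical(m$size_mm, m2$size_mm)
})

test_that("measured size is invariant to in-plane rotation of the scene", {
  base <- test_scene(5.2, 1000, centre = c(15, 15 + 5, 15))
  ang <- 30 * pi / 180
  rot <- test_scene(5.2, 1000,
                    centre = c(15, 15 + 5 * cos(ang), 15 + 5 * sin(ang)))
  sizes <- vapply(list(base, rot), function(sc) {
    measure_stones(detect_stones(rasterize_scene(sc)))$size_mm
  }, 0)
  expect_lt(abs(diff(sizes)), 0.7)
})

test_that("measured sizes increase with true diameter (noiseless study)", {
  sizes <- vapply(stone_sizes(), function(dmm) {
    sc <- test_scene(dmm, 1000)
    measure_stones(detect_stones(rasterize_scene(sc)))$size_mm
  }, 0)
  expect_true(all(diff(sizes) > 0))
  expect_true(all(abs(sizes - stone_sizes()) <= 0.7 + 1e-9))
})

test_that("measurement failure carries the candidate id", {
  roi <- ct_volume(array(0L, dim = c(3, 10, 10)), spacing = c(1, 0.7, 0.7))
  mask <- cbind(z = 2L, y = 5L, x = 5L)
  expect_error(measure_stone(roi, mask, label = 42L), "42")
})

test_that("tidy and glance summarise a stone_measurement", {
  sc <- test_scene(3.8, 1000)
  det <- detect_stones(rasterize_scene(sc))
  mask_local <- sweep(det$mask[[1]], 2, det$roi_offset[[1]], "-")
  m <- measure_stone(det$roi[[1]], mask_local, label = 3L)
  td <- tidy(m)
  expect_true(all(c("slice", "diameter_mm", "n_edges") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$label, 3L)
  expect_equal(gl$size_mm, m$size_mm)
})
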