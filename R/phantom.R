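#' The study's stone sizes and densities
#'
#' The eight actual cylinder diameters (mm) and the three nominal densities
#' (HU) of the phantom study the generator emulates. The printed reference
#' table lists "6.6" twice in its 100 HU block where the other density blocks
#' list 5.2 then 6.6 -- almost certainly a typographical duplication; the
#' generator uses this 8-size set for all three densities (see
#' [reference_stone_errors()] for the values as printed).
#'
#' @return Numeric vector of diameters (mm) or densities (HU).
#' @export
stone_sizes <- function() c(1.4, 2.6, 3.8, 4.6, 5.2, 6.6, 7.4, 8.6)

#' @rdname stone_sizes
#' @export
stone_densities <- function() c(100, 1000, 3000)

#' Cylindrical stone phantom specification
#'
#' @param diameter_mm Cylinder diameter > 0 (the quantity being measured).
#' @param density_hu Material density in HU, in `[-1024, 4095]`.
#' @param length_mm Cylinder length. Default 10 mm.
#' @param centre `(z, y, x)` centre position in mm.
#' @param axis Unit axis direction `(z, y, x)`. Default `(1, 0, 0)`: the
#'   cylinder axis runs along the slice normal, so axial images show a round
#'   cross-section whose diameter is the stone size (the physical phantoms
#'   were laid perpendicular to the scan plane).
#' @return A `phantom_stone` list.
#' @export
phantom_stone <- function(diameter_mm, density_hu, length_mm = 10,
                          centre = c(0, 0, 0), axis = c(1, 0, 0)) {
  if (diameter_mm <= 0) stop("`diameter_mm` must be > 0", call. = FALSE)
  if (length_mm <= 0) stop("`length_mm` must be > 0", call. = FALSE)
  if (density_hu < -1024 || density_hu > 4095) {
    stop("`density_hu` must lie in [-1024, 4095]", call. = FALSE)
  }
  axis <- axis / sqrt(sum(axis^2))
  structure(list(diameter_mm = diameter_mm, length_mm = length_mm,
                 density_hu = density_hu, centre = as.numeric(centre),
                 axis = as.numeric(axis)),
            class = "phantom_stone")
}

#' Blooming artifact model parameters
#'
#' Blooming (the artifactual enlargement of very dense objects) is modelled
#' phenomenologically on the high-attenuation component of the image (HU
#' above `threshold_hu`): in-plane grey dilation whose radius grows with the
#' component's peak density (`radius_mm_per_1000hu` millimetres per 1000 HU
#' above the threshold), extra Gaussian blur of that component
#' (`sigma_mm`), and a rim gain amplifying the spread component. Disabled by
#' default; with radius, sigma and gain all zero the model is the identity.
#'
#' @param enabled Logical.
#' @param radius_mm_per_1000hu Dilation radius scaling. Default 0.8.
#' @param sigma_mm Extra in-plane blur of the high component. Default 0.3.
#' @param rim_gain Overshoot gain on the spread component. Default 0.3.
#' @param threshold_hu High-attenuation threshold. Default 1500.
#' @return A `bloom_config` list.
#' @export
bloom_config <- function(enabled = FALSE, radius_mm_per_1000hu = 0.8,
                         sigma_mm = 0.3, rim_gain = 0.3,
                         threshold_hu = 1500) {
  if (radius_mm_per_1000hu < 0 || sigma_mm < 0 || rim_gain < 0) {
    stop("blooming parameters must be >= 0", call. = FALSE)
  }
  structure(list(enabled = isTRUE(enabled),
                 radius_mm_per_1000hu = radius_mm_per_1000hu,
                 sigma_mm = sigma_mm, rim_gain = rim_gain,
                 threshold_hu = threshold_hu),
            class = "bloom_config")
}

#' Phantom scene specification
#'
#' Describes one synthetic "tube in a water bath" scene: a latex-like tube
#' (default 15 HU, within the 10-20 HU of the physical tube) running along
#' the slice normal inside a water bath (0 HU), containing cylindrical stone
#' phantoms, plus the acquisition model (point-spread blur, noise, blooming).
#'
#' Stones must keep centre-to-centre separation of at least twice the largest
#' diameter, mirroring the "sufficient spacing" of the physical phantoms.
#'
#' @param stones List of [phantom_stone()] objects.
#' @param extent_mm Scene extent `(z, y, x)` in mm.
#' @param spacing `(dz, dy, dx)` in mm. Default `c(1, 0.7, 0.7)`: the 1.0 mm
#'   slice thickness of the study protocol and a typical abdominal in-plane
#'   pixel.
#' @param bath_hu Water HU. Default 0.
#' @param tube_inner_mm,tube_outer_mm Tube radii in mm. Defaults 6 / 7.5.
#' @param tube_hu Tube wall HU, in `[10, 20]` by default. Default 15.
#' @param supersample Sub-cells per axis for partial-volume rasterization.
#'   Default 3 (27 sub-cells per voxel).
#' @param psf_sigma_mm Gaussian point-spread sigma `(axial, in-plane)` in mm.
#'   Default `c(0.5, 0.5)`.
#' @param noise_sd_hu Additive Gaussian noise sd in HU. Default 5.
#' @param bloom A [bloom_config()].
#' @param seed Default seed used by [apply_acquisition()].
#' @return A `phantom_scene` list.
#' @export
phantom_scene <- function(stones = list(), extent_mm = c(30, 30, 30),
                          spacing = c(1, 0.7, 0.7), bath_hu = 0,
                          tube_inner_mm = 6, tube_outer_mm = 7.5,
                          tube_hu = 15, supersample = 3,
                          psf_sigma_mm = c(0.5, 0.5), noise_sd_hu = 5,
                          bloom = bloom_config(), seed = 1L) {
  if (inherits(stones, "phantom_stone")) stones <- list(stones)
  stopifnot(all(vapply(stones, inherits, TRUE, "phantom_stone")))
  if (tube_outer_mm <= tube_inner_mm) {
    stop("`tube_outer_mm` must exceed `tube_inner_mm`", call. = FALSE)
  }
  if (any(psf_sigma_mm < 0) || noise_sd_hu < 0) {
    stop("PSF sigma and noise sd must be >= 0", call. = FALSE)
  }
  if (length(stones) > 1) {
    dmax <- max(vapply(stones, function(s) s$diameter_mm, 0))
    ctr <- t(vapply(stones, function(s) s$centre, numeric(3)))
    dd <- as.matrix(stats::dist(ctr))
    diag(dd) <- Inf
    if (min(dd) < 2 * dmax) {
      stop(sprintf(
        "stones are too close: min centre separation %.1f mm < 2 x max diameter %.1f mm",
        min(dd), 2 * dmax), call. = FALSE)
    }
  }
  structure(list(stones = stones, extent_mm = as.numeric(extent_mm),
                 spacing = as.numeric(spacing), bath_hu = bath_hu,
                 tube_inner_mm = tube_inner_mm, tube_outer_mm = tube_outer_mm,
                 tube_hu = tube_hu, supersample = as.integer(supersample),
                 psf_sigma_mm = as.numeric(psf_sigma_mm),
                 noise_sd_hu = noise_sd_hu, bloom = bloom,
                 seed = as.integer(seed)),
            class = "phantom_scene")
}

# sub-cell centre offsets within a voxel, in units of one voxel edge
subcell_offsets <- function(s) ((seq_len(s) - 0.5) / s) - 0.5

#' Rasterize a phantom scene to an ideal CT volume
#'
#' Each output voxel's HU is the volume-weighted average of the material HUs
#' over its `supersample^3` sub-cells -- the partial-volume model. The result
#' is noise-free and unblurred; [apply_acquisition()] adds the scanner
#' artifacts. Deterministic.
#'
#' @param scene A [phantom_scene()].
#' @return A [ct_volume()] (integer HU).
#' @export
rasterize_scene <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  sp <- scene$spacing
  d <- pmax(round(scene$extent_mm / sp), c(1, 2, 2))
  s <- scene$supersample
  off <- subcell_offsets(s)
  zc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  xc <- (seq_len(d[3]) - 0.5) * sp[3]

  # tube wall occupancy depends only on (y, x): supersample in 2D
  tube_ctr <- c(scene$extent_mm[2] / 2, scene$extent_mm[3] / 2)
  occ_wall_yx <- matrix(0, d[2], d[3])
  for (oy in off) for (ox in off) {
    yy <- yc + oy * sp[2]
    xx <- xc + ox * sp[3]
    r2 <- outer((yy - tube_ctr[1])^2, (xx - tube_ctr[2])^2, "+")
    occ_wall_yx <- occ_wall_yx +
      (r2 > scene$tube_inner_mm^2 & r2 <= scene$tube_outer_mm^2)
  }
  occ_wall_yx <- occ_wall_yx / (s * s)

  occ_wall <- array(rep(occ_wall_yx, each = d[1]), dim = d)
  occ_stone_total <- array(0, dim = d)
  hu_stone <- array(0, dim = d)

  for (st in scene$stones) {
    half <- sqrt((st$length_mm / 2)^2 + (st$diameter_mm / 2)^2) +
      max(sp) * 1.5
    zi <- which(abs(zc - st$centre[1]) <= half)
    yi <- which(abs(yc - st$centre[2]) <= half)
    xi <- which(abs(xc - st$centre[3]) <= half)
    if (!length(zi) || !length(yi) || !length(xi)) next
    occ <- array(0, dim = c(length(zi), length(yi), length(xi)))
    r2max <- (st$diameter_mm / 2)^2
    hl <- st$length_mm / 2
    for (oz in off) for (oy in off) for (ox in off) {
      pz <- zc[zi] + oz * sp[1] - st$centre[1]
      py <- yc[yi] + oy * sp[2] - st$centre[2]
      px <- xc[xi] + ox * sp[3] - st$centre[3]
      proj <- outer(outer(pz * st$axis[1], py * st$axis[2], "+"),
                    px * st$axis[3], "+")
      norm2 <- outer(outer(pz^2, py^2, "+"), px^2, "+")
      occ <- occ + (abs(proj) <= hl & (norm2 - proj^2) <= r2max)
    }
    occ <- occ / (s^3)
    occ_stone_total[zi, yi, xi] <- occ_stone_total[zi, yi, xi] + occ
    hu_stone[zi, yi, xi] <- hu_stone[zi, yi, xi] + st$density_hu * occ
  }
  if (any(occ_stone_total > 1 + 1e-9)) {
    stop("overlapping stones in scene", call. = FALSE)
  }
  occ_wall <- pmin(occ_wall, 1 - occ_stone_total)
  hu <- scene$bath_hu * (1 - occ_wall - occ_stone_total) +
    scene$tube_hu * occ_wall + hu_stone
  vol <- ct_volume(array(as.integer(round(hu)), dim = d), spacing = sp,
                   meta = list(source = "rasterize_scene"))
  vol
}

# separable Gaussian blur; sigma in voxels per array dimension
gaussian_blur <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-6) next
    k <- ceiling(3 * s)
    kern <- exp(-((-k:k)^2) / (2 * s^2))
    kern <- kern / sum(kern)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dp <- dim(a)
    m <- matrix(a, nrow = dp[1])
    # edge-replicated padding, then filter each column
    m <- rbind(m[rep(1L, k), , drop = FALSE], m,
               m[rep(nrow(m), k), , drop = FALSE])
    f <- stats::filter(m, kern, sides = 2)
    f <- f[(k + 1):(k + dp[1]), , drop = FALSE]
    arr <- aperm(array(f, dim = dp), order(perm))
  }
  arr
}

# In-plane grey dilation with a disc of physical radius radius_mm.
# Displacements are continuous (bilinear-interpolated shifts over 8 ray
# directions plus any full-voxel offsets), so sub-voxel radii genuinely
# enlarge the bright component instead of flooring to zero.
dilate_inplane <- function(arr, radius_mm, spacing) {
  if (radius_mm < 1e-9) return(arr)
  d <- dim(arr)
  # candidate displacement vectors (dy_mm, dx_mm)
  ang <- 2 * pi * (0:7) / 8
  disp <- cbind(radius_mm * sin(ang), radius_mm * cos(ang))
  ky <- floor(radius_mm / spacing[2])
  kx <- floor(radius_mm / spacing[3])
  if (ky > 0 || kx > 0) {
    gr <- as.matrix(expand.grid(oy = -ky:ky, ox = -kx:kx))
    gmm <- cbind(gr[, 1] * spacing[2], gr[, 2] * spacing[3])
    keep <- rowSums(gmm^2) <= radius_mm^2 & rowSums(abs(gmm)) > 0
    disp <- rbind(disp, gmm[keep, , drop = FALSE])
  }
  shift_arr <- function(oy, ox) {
    # integer shift with edge clamping, along y (dim 2) and x (dim 3)
    ys <- pmin(pmax(seq_len(d[2]) + oy, 1L), d[2])
    xs <- pmin(pmax(seq_len(d[3]) + ox, 1L), d[3])
    arr[, ys, xs, drop = FALSE]
  }
  out <- arr
  for (k in seq_len(nrow(disp))) {
    fy <- disp[k, 1] / spacing[2]
    fx <- disp[k, 2] / spacing[3]
    y0 <- floor(fy); x0 <- floor(fx)
    wy <- fy - y0; wx <- fx - x0
    sh <- (1 - wy) * (1 - wx) * shift_arr(y0, x0) +
      wy * (1 - wx) * shift_arr(y0 + 1L, x0) +
      (1 - wy) * wx * shift_arr(y0, x0 + 1L) +
      wy * wx * shift_arr(y0 + 1L, x0 + 1L)
    out <- pmax(out, sh)
  }
  out
}

#' Apply the acquisition model to an ideal volume
#'
#' Gaussian point-spread blur (anisotropic, sigmas from the scene), the
#' optional blooming model on the high-attenuation component, additive
#' Gaussian noise, and rounding/clamping to the integer HU range.
#' Reproducible for a fixed seed; with zero sigma, zero noise and blooming
#' disabled the output equals the input exactly.
#'
#' @param ideal [ct_volume()] from [rasterize_scene()].
#' @param scene The [phantom_scene()] that produced it.
#' @param seed Integer seed for the noise; defaults to the scene's seed.
#' @return A [ct_volume()].
#' @export
apply_acquisition <- function(ideal, scene, seed = scene$seed) {
  assert_ct_volume(ideal, "ideal")
  sp <- ideal$spacing
  if (any(scene$psf_sigma_mm < 0) || scene$noise_sd_hu < 0) {
    stop("PSF sigma and noise sd must be >= 0", call. = FALSE)
  }
  v <- ideal$voxels * 1.0
  sig <- c(scene$psf_sigma_mm[1] / sp[1],
           scene$psf_sigma_mm[2] / sp[2],
           scene$psf_sigma_mm[2] / sp[3])
  if (any(sig > 0)) v <- gaussian_blur(v, sig)
  bl <- scene$bloom
  if (isTRUE(bl$enabled)) {
    hi <- pmax(v - bl$threshold_hu, 0)
    if (max(hi) > 0) {
      peak <- max(v)
      radius <- bl$radius_mm_per_1000hu * (peak - bl$threshold_hu) / 1000
      hi_d <- dilate_inplane(hi, radius, sp)
      if (bl$sigma_mm > 0) {
        hi_d <- gaussian_blur(hi_d, c(0, bl$sigma_mm / sp[2],
                                      bl$sigma_mm / sp[3]))
      }
      v <- pmin(v, bl$threshold_hu) + (1 + bl$rim_gain) * hi_d
    }
  }
  if (scene$noise_sd_hu > 0) {
    noise <- withr::with_seed(seed, {
      stats::rnorm(length(v), sd = scene$noise_sd_hu)
    })
    v <- v + noise
  }
  v <- pmin(pmax(round(v), -1024), 4095)
  ct_volume(array(as.integer(v), dim = dim(ideal$voxels)), spacing = sp,
            origin = ideal$origin,
            meta = c(ideal$meta, list(acquisition_seed = seed)))
}

#' Synthesize the full phantom study
#'
#' Generates the digital twin of the study design: 24 cylindrical stone
#' phantoms (the eight [stone_sizes()] at each of the three
#' [stone_densities()]) randomly assigned across six tubes, four stones per
#' tube, with centre spacing respecting the separation constraint. The
#' assignment permutation is seed-deterministic.
#'
#' @param seed Integer seed driving the stone-to-tube assignment and, offset
#'   per tube, the acquisition noise.
#' @param sizes,densities Stone diameters (mm) and densities (HU).
#' @param stone_length_mm Cylinder length. Default 10 mm.
#' @param slot_spacing_mm Centre-to-centre spacing of the four stone slots
#'   along a tube. Default 30 mm (>= 2 x the largest diameter).
#' @param acquire If `FALSE`, return the ideal (noise-free, unblurred)
#'   volumes.
#' @param ... Scene parameters passed to [phantom_scene()]
#'   (`spacing`, `psf_sigma_mm`, `noise_sd_hu`, `bloom`, ...).
#' @return List with `volumes` (list of 6 [ct_volume()]), `truth` (tibble:
#'   `stone_id`, `tube`, `slot`, `density_hu`, `true_mm`, voxel-space
#'   centroid, analytic voxel count), and `scenes`.
#' @export
synthesize_study <- function(seed = 1L, sizes = stone_sizes(),
                             densities = stone_densities(),
                             stone_length_mm = 10, slot_spacing_mm = 30,
                             acquire = TRUE, ...) {
  specs <- tidyr::expand_grid(density_hu = densities, true_mm = sizes)
  n <- nrow(specs)
  n_tubes <- ceiling(n / 4)
  if (slot_spacing_mm < 2 * max(sizes)) {
    stop("`slot_spacing_mm` violates the stone separation constraint",
         call. = FALSE)
  }
  perm <- withr::with_seed(seed, sample.int(n))
  specs <- specs[perm, ]
  specs$tube <- rep(seq_len(n_tubes), each = 4)[seq_len(n)]
  specs$slot <- unlist(lapply(table(specs$tube), seq_len), use.names = FALSE)
  specs$stone_id <- sprintf("d%d_s%.1f", specs$density_hu, specs$true_mm)

  z_extent <- slot_spacing_mm * 4 + 10
  scenes <- vector("list", n_tubes)
  volumes <- vector("list", n_tubes)
  truth <- vector("list", n_tubes)
  for (tb in seq_len(n_tubes)) {
    rows <- specs[specs$tube == tb, ]
    ctr_yx <- c(15, 15)
    stones <- purrr::pmap(rows[c("true_mm", "density_hu", "slot")],
      function(true_mm, density_hu, slot) {
        phantom_stone(true_mm, density_hu, length_mm = stone_length_mm,
                      centre = c(slot_spacing_mm * slot - slot_spacing_mm / 2 + 5,
                                 ctr_yx[1], ctr_yx[2]))
      })
    scene <- phantom_scene(stones, extent_mm = c(z_extent, 30, 30),
                           seed = seed + tb, ...)
    ideal <- rasterize_scene(scene)
    volumes[[tb]] <- if (acquire) apply_acquisition(ideal, scene) else ideal
    scenes[[tb]] <- scene
    sp <- scene$spacing
    rows$centroid_z <- (vapply(stones, function(s) s$centre[1], 0) / sp[1]) + 0.5
    rows$centroid_y <- (vapply(stones, function(s) s$centre[2], 0) / sp[2]) + 0.5
    rows$centroid_x <- (vapply(stones, function(s) s$centre[3], 0) / sp[3]) + 0.5
    rows$analytic_voxels <- pi * (rows$true_mm / 2)^2 * stone_length_mm /
      prod(sp)
    truth[[tb]] <- rows
  }
  truth <- dplyr::bind_rows(truth)
  truth <- truth[order(truth$density_hu, truth$true_mm), ]
  list(volumes = volumes, truth = tibble::as_tibble(truth), scenes = scenes,
       seed = seed)
}

#' Simulate a panel of manual raters
#'
#' Synthetic stand-in for the human reader panel: each rater measures each
#' stone once per window setting as `truth + bias + Gaussian noise`,
#' truncated at 0. Bias and noise sd may vary by density and method.
#' Seed-deterministic.
#'
#' @param truth Truth tibble with `stone_id`, `density_hu`, `true_mm`
#'   (e.g. from [synthesize_study()]).
#' @param model A [rater_model()].
#' @param seed Integer seed.
#' @return A measurement-record tibble: `rater`, `method`, `stone_id`,
#'   `density_hu`, `true_mm`, `measured_mm`.
#' @export
simulate_raters <- function(truth, model = rater_model(), seed = 1L) {
  stopifnot(inherits(model, "rater_model"))
  rm <- model
  grid <- tidyr::expand_grid(rater = sprintf("r%02d", seq_len(rm$n_raters)),
                             method = rm$methods,
                             stone_id = truth$stone_id)
  grid <- dplyr::left_join(grid,
    truth[c("stone_id", "density_hu", "true_mm")], by = "stone_id")
  grid <- dplyr::left_join(grid, rm$params, by = c("method", "density_hu"))
  if (anyNA(grid$bias) || anyNA(grid$sd)) {
    stop("rater model does not cover every (method, density) cell",
         call. = FALSE)
  }
  grid$measured_mm <- withr::with_seed(seed, {
    pmax(grid$true_mm + grid$bias + stats::rnorm(nrow(grid), sd = grid$sd), 0)
  })
  tibble::as_tibble(grid[c("rater", "method", "stone_id", "density_hu",
                           "true_mm", "measured_mm")])
}

#' Rater panel model
#'
#' Per-rater bias and noise standard deviation for the synthetic reader
#' panel, optionally varying by `(method, density)` cell.
#'
#' @param n_raters Panel size. Default 52, the size of the reader panel the
#'   study design calls for.
#' @param bias,sd Either scalars applied to every cell, or data frames with
#'   columns `method`, `density_hu` and `bias` / `sd`.
#' @param methods Manual window settings measured. Default
#'   `c("mediastinum", "bone")`.
#' @param densities Densities covered. Default [stone_densities()].
#' @return A `rater_model` list with a fully crossed `params` tibble.
#' @export
rater_model <- function(n_raters = 52, bias = 0, sd = 1,
                        methods = c("mediastinum", "bone"),
                        densities = stone_densities()) {
  if (is.numeric(sd) && any(sd < 0)) {
    stop("rater noise `sd` must be >= 0", call. = FALSE)
  }
  params <- tidyr::expand_grid(method = methods, density_hu = densities)
  if (is.data.frame(bias)) {
    params <- dplyr::left_join(params, bias, by = c("method", "density_hu"))
  } else {
    params$bias <- bias
  }
  if (is.data.frame(sd)) {
    params <- dplyr::left_join(params, sd, by = c("method", "density_hu"))
  } else {
    params$sd <- sd
  }
  if (any(params$sd < 0, na.rm = TRUE)) {
    stop("rater noise `sd` must be >= 0", call. = FALSE)
  }
  structure(list(n_raters = as.integer(n_raters), methods = methods,
                 params = params),
            class = "rater_model")
}
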