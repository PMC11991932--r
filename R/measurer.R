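#' Measurer configuration
#'
#' Parameters of the automated stone measurer. Per axial slice of a
#' candidate's ROI, rays are cast from the stone centre; Hounsfield units are
#' sampled along each ray by bilinear interpolation; a first-order Haar
#' differential filter (kernel `[+1, -1]` at unit scale) is applied; and the
#' most negative response marks the stone outline. The reported stone size is
#' the maximum pairwise Euclidean distance between outline points, converted
#' to millimetres, maximized over slices.
#'
#' @param n_rays Rays per slice (>= 8). Default 360, i.e. 1 degree spacing.
#' @param sample_step Sampling step along a ray as a fraction of an in-plane
#'   pixel, in `(0, 1]`. Default 0.5.
#' @param min_radius Exclusion zone around the centre in mm, so the flat top
#'   of the stone never wins the arg-min. Default 0.5 mm.
#' @param edge_rule `"global-min"` (default): the most negative Haar response
#'   beyond `min_radius`; `"first-min"`: the first local minimum below
#'   `-tau` beyond `min_radius`.
#' @param tau Response threshold in HU per sample: a ray yields no edge if
#'   its selected minimum is shallower than `-tau`. Default 30.
#' @param refine Parabolic sub-sample refinement of the edge position over
#'   the minimizing response and its two neighbours. Default `TRUE`.
#' @param centre `"per-slice"` (default): binary centroid of the candidate
#'   mask restricted to the slice; `"fixed-3d"`: the in-plane projection of
#'   the 3D mask centroid used for every slice.
#' @param edge_window Optional [window_setting()] (or preset name); when set,
#'   HU are clipped to the window interval before edge detection, emulating
#'   an internal bone-window display stage. Default `NULL` (raw HU).
#' @return A `measurer_config` list.
#' @export
measurer_config <- function(n_rays = 360, sample_step = 0.5,
                            min_radius = 0.5,
                            edge_rule = c("global-min", "first-min"),
                            tau = 30, refine = TRUE,
                            centre = c("per-slice", "fixed-3d"),
                            edge_window = NULL) {
  edge_rule <- match.arg(edge_rule)
  centre <- match.arg(centre)
  if (n_rays < 8) stop("`n_rays` must be >= 8", call. = FALSE)
  if (sample_step <= 0 || sample_step > 1) {
    stop("`sample_step` must lie in (0, 1]", call. = FALSE)
  }
  if (min_radius < 0) stop("`min_radius` must be >= 0", call. = FALSE)
  if (!is.null(edge_window) && is.character(edge_window)) {
    edge_window <- window_preset(edge_window)
  }
  structure(list(n_rays = as.integer(n_rays), sample_step = sample_step,
                 min_radius = min_radius, edge_rule = edge_rule, tau = tau,
                 refine = isTRUE(refine), centre = centre,
                 edge_window = edge_window),
            class = "measurer_config")
}

#' Binary centroid of a mask slice
#'
#' @param mask_slice 2D logical matrix `[y, x]`, or an `n x 2` matrix of
#'   `(y, x)` member coordinates.
#' @return Continuous `(y, x)` voxel coordinates, or `NULL` when the slice
#'   mask is empty (the slice is skipped).
#' @export
slice_centre <- function(mask_slice) {
  if (is.logical(mask_slice)) {
    idx <- which(mask_slice, arr.ind = TRUE)
  } else {
    idx <- mask_slice
  }
  if (is.null(dim(idx)) || nrow(idx) == 0L) return(NULL)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Cast a radial ray and sample HU by bilinear interpolation
#'
#' Samples at index positions `centre + t * sample_step * (sin a, cos a)`,
#' `t = 0, 1, 2, ...`, until the ray leaves the slice. Reported positions are
#' physical millimetres from the centre; with anisotropic in-plane spacing
#' the physical step length depends on the ray direction.
#'
#' @param slice_hu 2D numeric matrix of HU, `[y, x]`.
#' @param spacing Length-2 `(dy, dx)` in mm.
#' @param centre `(y, x)` continuous voxel coordinates inside the slice.
#' @param angle Ray angle in radians.
#' @param sample_step Step as a fraction of an in-plane pixel.
#' @return List with `angle`, `samples` (HU), `positions` (mm from centre,
#'   strictly increasing).
#' @export
cast_ray <- function(slice_hu, spacing, centre, angle, sample_step = 0.5) {
  ny <- nrow(slice_hu); nx <- ncol(slice_hu)
  if (centre[1] < 1 || centre[1] > ny || centre[2] < 1 || centre[2] > nx) {
    stop("ray centre lies outside the slice", call. = FALSE)
  }
  dy <- sin(angle) * sample_step
  dx <- cos(angle) * sample_step
  # number of whole steps until either coordinate exits [1, n]
  t_exit <- function(c0, d, n) {
    if (abs(d) < 1e-12) return(Inf)
    if (d > 0) (n - c0) / d else (1 - c0) / d
  }
  tmax <- floor(min(t_exit(centre[1], dy, ny), t_exit(centre[2], dx, nx)))
  t <- 0:max(tmax, 0)
  ys <- centre[1] + t * dy
  xs <- centre[2] + t * dx
  samples <- bilinear_sample(slice_hu, ys, xs)
  step_mm <- sample_step * sqrt((spacing[1] * sin(angle))^2 +
                                (spacing[2] * cos(angle))^2)
  list(angle = angle, samples = samples, positions = t * step_mm)
}

# Vectorized bilinear interpolation at continuous [y, x] voxel coordinates.
bilinear_sample <- function(m, ys, xs) {
  ny <- nrow(m); nx <- ncol(m)
  i0 <- pmin(pmax(floor(ys), 1), ny - 1)
  j0 <- pmin(pmax(floor(xs), 1), nx - 1)
  fy <- ys - i0
  fx <- xs - j0
  idx <- function(i, j) m[cbind(i, j)]
  idx(i0, j0) * (1 - fy) * (1 - fx) + idx(i0 + 1, j0) * fy * (1 - fx) +
    idx(i0, j0 + 1) * (1 - fy) * fx + idx(i0 + 1, j0 + 1) * fy * fx
}

#' First-order Haar differential response
#'
#' The two-tap kernel `[+1, -1]` at unit scale: `response[i] =
#' samples[i + 1] - samples[i]`. Minima of the response along an outward ray
#' mark the steepest HU decrease, i.e. the stone edge.
#'
#' @param samples Numeric vector of at least 2 HU samples.
#' @return Numeric vector of length `length(samples) - 1`.
#' @export
haar_response <- function(samples) {
  if (length(samples) < 2L) {
    stop("haar_response needs at least 2 samples", call. = FALSE)
  }
  diff(samples)
}

#' Locate the stone edge along one radial profile
#'
#' Under the default `global-min` rule, the edge is at the midpoint of the
#' sample pair with the most negative Haar response beyond `min_radius`;
#' optional parabolic refinement interpolates the minimum to sub-sample
#' precision. Returns `NA` when the minimum is shallower than `-tau` (no
#' material edge along this ray).
#'
#' @param profile A list as returned by [cast_ray()].
#' @param config A [measurer_config()].
#' @return Edge position in mm from the centre, or `NA_real_`.
#' @export
locate_edge <- function(profile, config = measurer_config()) {
  r <- haar_response(profile$samples)
  mid <- (profile$positions[-1] + profile$positions[-length(profile$positions)]) / 2
  step_mm <- profile$positions[2] - profile$positions[1]
  valid <- mid >= config$min_radius
  if (!any(valid)) return(NA_real_)
  rv <- ifelse(valid, r, Inf)
  if (config$edge_rule == "global-min") {
    i <- which.min(rv)
  } else {
    below <- which(rv < -config$tau)
    if (length(below) == 0L) return(NA_real_)
    i <- NA_integer_
    for (k in below) {
      left_ok <- k == 1L || r[k - 1L] >= r[k]
      right_ok <- k == length(r) || r[k + 1L] >= r[k]
      if (left_ok && right_ok) { i <- k; break }
    }
    if (is.na(i)) i <- below[1]
  }
  if (r[i] > -config$tau) return(NA_real_)
  pos <- mid[i]
  if (config$refine && i > 1L && i < length(r)) {
    denom <- r[i - 1] - 2 * r[i] + r[i + 1]
    if (denom > 1e-12) {
      delta <- 0.5 * (r[i - 1] - r[i + 1]) / denom
      pos <- pos + max(min(delta, 0.5), -0.5) * step_mm
    }
  }
  pos
}

# Vectorized per-slice ray fan: all rays of one slice at once.
# Returns an n x 2 matrix of edge points in (y_mm, x_mm) physical
# coordinates, possibly with fewer rows than rays (rays without an edge are
# dropped).
slice_edge_points <- function(slice_hu, spacing, centre, config) {
  ny <- nrow(slice_hu); nx <- ncol(slice_hu)
  angles <- 2 * pi * (seq_len(config$n_rays) - 1) / config$n_rays
  sin_a <- sin(angles); cos_a <- cos(angles)
  step <- config$sample_step
  # common step count: distance to the farthest corner in index units
  corners_y <- c(1, 1, ny, ny); corners_x <- c(1, nx, 1, nx)
  rad <- sqrt(max((corners_y - centre[1])^2 + (corners_x - centre[2])^2))
  nt <- floor(rad / step) + 2L
  t <- 0:(nt - 1L)
  ys <- outer(sin_a * step, t) + centre[1]   # n_rays x nt
  xs <- outer(cos_a * step, t) + centre[2]
  inside <- ys >= 1 & ys <= ny & xs >= 1 & xs <= nx
  samp <- matrix(NA_real_, nrow = length(angles), ncol = nt)
  samp[inside] <- bilinear_sample(slice_hu, ys[inside], xs[inside])
  resp <- samp[, -1, drop = FALSE] - samp[, -nt, drop = FALSE]
  step_mm <- step * sqrt((spacing[1] * sin_a)^2 + (spacing[2] * cos_a)^2)
  mid_t <- (t[-1] + t[-nt]) / 2  # midpoints in step units
  mid_mm <- outer(step_mm, mid_t)
  bad <- is.na(resp) | mid_mm < config$min_radius
  rv <- resp
  rv[bad] <- Inf
  if (config$edge_rule == "global-min") {
    imin <- max.col(-rv, ties.method = "first")
  } else {
    nr <- ncol(rv)
    rl <- cbind(Inf, rv[, -nr, drop = FALSE])
    rr <- cbind(rv[, -1, drop = FALSE], Inf)
    ok <- rv < -config$tau & rv <= rl & rv <= rr
    imin <- apply(ok, 1, function(z) {
      w <- which(z)
      if (length(w)) w[1] else 1L
    })
    no_first <- !ok[cbind(seq_len(nrow(rv)), imin)]
    if (any(no_first)) {
      # fall back to the first sub-threshold response
      fb <- apply(rv < -config$tau, 1, function(z) {
        w <- which(z)
        if (length(w)) w[1] else 1L
      })
      imin[no_first] <- fb[no_first]
    }
  }
  sel <- cbind(seq_along(angles), imin)
  rmin <- rv[sel]
  has_edge <- is.finite(rmin) & rmin <= -config$tau
  pos <- mid_mm[sel]
  if (config$refine) {
    iL <- pmax(imin - 1L, 1L); iR <- pmin(imin + 1L, ncol(rv))
    a <- resp[cbind(seq_along(angles), iL)]
    b <- resp[sel]
    cc <- resp[cbind(seq_along(angles), iR)]
    denom <- a - 2 * b + cc
    delta <- ifelse(is.finite(denom) & denom > 1e-12,
                    pmax(pmin(0.5 * (a - cc) / denom, 0.5), -0.5), 0)
    delta[imin == 1L | imin == ncol(rv) | is.na(delta)] <- 0
    pos <- pos + delta * step_mm
  }
  keep <- which(has_edge)
  if (length(keep) == 0L) return(matrix(numeric(), ncol = 2))
  centre_mm <- c((centre[1] - 1) * spacing[1], (centre[2] - 1) * spacing[2])
  norm <- sqrt((spacing[1] * sin_a[keep])^2 + (spacing[2] * cos_a[keep])^2)
  cbind(y = centre_mm[1] + pos[keep] * spacing[1] * sin_a[keep] / norm,
        x = centre_mm[2] + pos[keep] * spacing[2] * cos_a[keep] / norm)
}

#' Measure one axial slice of a stone ROI
#'
#' Casts the configured ray fan from the slice centre, locates one edge point
#' per ray, and reports the maximum pairwise Euclidean distance between edge
#' points in millimetres. Slices yielding fewer than 3 edge points are
#' skipped.
#'
#' @param slice_hu 2D HU matrix `[y, x]`.
#' @param mask_slice 2D logical matrix (or `(y, x)` coordinate matrix) of the
#'   candidate mask on this slice; defines the centre.
#' @param spacing `(dy, dx)` in mm.
#' @param config A [measurer_config()].
#' @param centre Optional explicit `(y, x)` centre, overriding the mask
#'   centroid.
#' @return A list with `diameter_mm`, `n_edges`, `points` (edge points in mm,
#'   `(y, x)`) and `skipped` (`NA`, or the reason the slice was skipped, in
#'   which case `diameter_mm` is `NA`).
#' @export
measure_slice <- function(slice_hu, mask_slice, spacing,
                          config = measurer_config(), centre = NULL) {
  skipped <- function(reason) {
    list(diameter_mm = NA_real_, n_edges = 0L, points = NULL,
         skipped = reason)
  }
  if (is.null(centre)) centre <- slice_centre(mask_slice)
  if (is.null(centre)) return(skipped("empty mask slice"))
  hu <- slice_hu
  if (!is.null(config$edge_window)) {
    hu <- clip_to_window(hu, config$edge_window)
  }
  pts <- slice_edge_points(hu, spacing, centre, config)
  if (nrow(pts) < 3L) {
    return(skipped(sprintf("only %d edge points", nrow(pts))))
  }
  list(diameter_mm = max(stats::dist(pts)), n_edges = nrow(pts),
       points = pts, skipped = NA_character_)
}

#' Measure a stone candidate
#'
#' Applies [measure_slice()] to every ROI slice intersecting the candidate
#' mask; the reported stone size is the maximum of the per-slice maxima, in
#' millimetres. Deterministic for fixed input and configuration.
#'
#' @param roi ROI [ct_volume()] for the candidate (see [crop_roi()]).
#' @param mask Candidate mask as an `n x 3` `(z, y, x)` integer matrix in ROI
#'   coordinates, or a 3D logical array matching the ROI.
#' @param config A [measurer_config()].
#' @param label Candidate label carried into the result.
#' @return A `stone_measurement` object: list with `label`, `size_mm`,
#'   `n_slices_used`, and a `slices` tibble (slice index, `diameter_mm`,
#'   `n_edges`, edge `points`, skip reason).
#' @export
measure_stone <- function(roi, mask, config = measurer_config(),
                          label = 1L) {
  assert_ct_volume(roi, "roi")
  if (is.logical(mask)) {
    mask <- which(mask, arr.ind = TRUE)
    colnames(mask) <- c("z", "y", "x")
  }
  if (nrow(mask) == 0L) {
    stop("measurement failed for candidate ", label, ": empty mask",
         call. = FALSE)
  }
  sp <- roi$spacing[2:3]
  zs <- sort(unique(mask[, 1]))
  fixed_centre <- if (config$centre == "fixed-3d") {
    c(mean(mask[, 2]), mean(mask[, 3]))
  } else NULL
  recs <- purrr::map(zs, function(z) {
    mz <- mask[mask[, 1] == z, c(2, 3), drop = FALSE]
    res <- measure_slice(roi$voxels[z, , , drop = TRUE], mz, sp, config,
                         centre = fixed_centre)
    tibble::tibble(slice = z, diameter_mm = res$diameter_mm,
                   n_edges = res$n_edges, points = list(res$points),
                   skipped = res$skipped)
  })
  slices <- dplyr::bind_rows(recs)
  used <- !is.na(slices$diameter_mm)
  if (!any(used)) {
    stop("measurement failed for candidate ", label,
         ": no slice yielded >= 3 edge points", call. = FALSE)
  }
  structure(list(label = label,
                 size_mm = max(slices$diameter_mm[used]),
                 n_slices_used = sum(used),
                 slices = slices,
                 config = config),
            class = "stone_measurement")
}

#' @export
print.stone_measurement <- function(x, ...) {
  cat(sprintf("<stone_measurement> candidate %s: size %.2f mm (%d slices used)\n",
              x$label, x$size_mm, x$n_slices_used))
  invisible(x)
}

#' Measure every detected stone candidate
#'
#' Convenience wrapper chaining [detect_stones()] output into
#' [measure_stone()]. Candidates whose measurement fails (no usable slice)
#' get `size_mm = NA` and the failure message in `note`.
#'
#' @param detections Tibble from [detect_stones()].
#' @param config A [measurer_config()].
#' @return The detections tibble with `size_mm`, `n_slices_used`, `note`, and
#'   a `measurement` list-column of `stone_measurement` objects.
#' @export
#' @examples
#' vol <- ct_volume(array(0L, dim = c(6, 24, 24)), spacing = c(1, 0.7, 0.7))
#' vol$voxels[2:5, 8:16, 8:16] <- 1000L
#' detect_stones(vol) |> measure_stones()
measure_stones <- function(detections, config = measurer_config()) {
  n <- nrow(detections)
  out <- detections
  out$size_mm <- NA_real_
  out$n_slices_used <- NA_integer_
  out$note <- NA_character_
  out$measurement <- vector("list", n)
  for (i in seq_len(n)) {
    mask_local <- sweep(detections$mask[[i]], 2,
                        detections$roi_offset[[i]], "-")
    res <- tryCatch(
      measure_stone(detections$roi[[i]], mask_local, config,
                    label = detections$label[i]),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      out$note[i] <- conditionMessage(res)
    } else {
      out$size_mm[i] <- res$size_mm
      out$n_slices_used[i] <- res$n_slices_used
      out$measurement[[i]] <- res
    }
  }
  out
}
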