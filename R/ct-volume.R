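#' CT volume container
#'
#' A `ct_volume` holds a 3D grid of Hounsfield units together with its voxel
#' spacing and physical origin. Voxels are indexed `[z, y, x]` (slice, row,
#' column), 1-based as usual in R. Spacing is `(dz, dy, dx)` in millimetres.
#'
#' @param voxels 3D numeric array of Hounsfield units, indexed `[z, y, x]`.
#'   Values must lie in the CT range -1024..4095 and the array must have at
#'   least 1 slice, 2 rows and 2 columns.
#' @param spacing Numeric length-3 vector `(dz, dy, dx)` in mm, all > 0.
#' @param origin Numeric length-3 vector `(z0, y0, x0)` in mm. Default all 0.
#' @param meta Named list of free-form series provenance (kVp, mAs,
#'   description, ...).
#'
#' @return An object of class `ct_volume`.
#' @export
#' @examples
#' vol <- ct_volume(array(0L, dim = c(3, 8, 8)), spacing = c(1, 0.7, 0.7))
#' dim(vol)
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      meta = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array indexed [z, y, x]", call. = FALSE)
  }
  d <- dim(voxels)
  if (d[1] < 1L || d[2] < 2L || d[3] < 2L) {
    stop("volume needs >= 1 slice, >= 2 rows and >= 2 columns", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive numbers (dz, dy, dx) in mm",
         call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite numbers (z0, y0, x0) in mm",
         call. = FALSE)
  }
  rng <- range(voxels)
  if (!all(is.finite(rng)) || rng[1] < -1024 || rng[2] > 4095) {
    stop("Hounsfield units must be finite and lie in [-1024, 4095]",
         call. = FALSE)
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin, meta = meta),
    class = "ct_volume"
  )
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %d slices x %d rows x %d cols, spacing (dz, dy, dx) = (%g, %g, %g) mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf("  HU range [%g, %g], origin (%g, %g, %g) mm\n",
              min(x$voxels), max(x$voxels),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @rdname ct_volume
#' @param x Object to test or print.
#' @export
is_ct_volume <- function(x) inherits(x, "ct_volume")

assert_ct_volume <- function(x, arg = "vol") {
  if (!is_ct_volume(x)) {
    stop(sprintf("`%s` must be a ct_volume (see ct_volume())", arg),
         call. = FALSE)
  }
  invisible(x)
}
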