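#' CT window settings
#'
#' A window setting maps the Hounsfield interval
#' `[level - width/2, level + width/2]` linearly onto display grey values in
#' `[0, 1]`; values outside the interval are clipped. Three named presets are
#' provided: the mediastinum (soft-tissue) setting of width 350 HU / level
#' 30 HU, the bone setting of width 1500 HU / level 600 HU, and
#' `measurer_bone`, the internal bone-like window the automated measurer can
#' optionally apply before edge detection. The latter is written "(500, 1600)"
#' in its source material without saying which number is the width; it is read
#' here as level 500 / width 1600 (nearly the standard bone window); the
#' opposite reading is available via `measurer_bone_as_width_level = TRUE`.
#'
#' @param width Window width in HU, > 0.
#' @param level Window level (centre) in HU.
#' @param name Optional label.
#' @return A `window_setting` object (a named list with `name`, `width`,
#'   `level`).
#' @export
#' @examples
#' window_setting(350, 30, "mediastinum")
#' window_preset("bone")
window_setting <- function(width, level, name = "custom") {
  width <- as.numeric(width)[1]
  level <- as.numeric(level)[1]
  if (!is.finite(width) || width <= 0) {
    stop("window `width` must be a positive number of HU", call. = FALSE)
  }
  if (!is.finite(level)) stop("window `level` must be finite", call. = FALSE)
  structure(list(name = as.character(name), width = width, level = level),
            class = "window_setting")
}

#' @export
print.window_setting <- function(x, ...) {
  cat(sprintf("<window_setting> %s: width %g HU, level %g HU\n",
              x$name, x$width, x$level))
  invisible(x)
}

#' @rdname window_setting
#' @param preset One of `"mediastinum"`, `"bone"`, `"measurer_bone"`.
#' @param measurer_bone_as_width_level If `TRUE`, read the measurer's internal
#'   window constants `(500, 1600)` as (width, level) instead of the default
#'   (level, width).
#' @export
window_preset <- function(preset, measurer_bone_as_width_level = FALSE) {
  known <- c("mediastinum", "bone", "measurer_bone")
  if (!is.character(preset) || length(preset) != 1L || !(preset %in% known)) {
    stop(sprintf("unknown window preset %s; valid presets: %s",
                 deparse(substitute(preset)),
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  switch(preset,
    mediastinum = window_setting(350, 30, "mediastinum"),
    bone = window_setting(1500, 600, "bone"),
    measurer_bone = if (measurer_bone_as_width_level) {
      window_setting(500, 1600, "measurer_bone")
    } else {
      window_setting(1600, 500, "measurer_bone")
    }
  )
}

#' Apply a display window to Hounsfield units
#'
#' Maps HU linearly onto `[0, 1]`: `clip((hu - level) / width + 0.5, 0, 1)`.
#' The map is monotone non-decreasing in HU and the window centre maps to 0.5.
#'
#' @param hu Numeric vector, matrix or array of Hounsfield units, or a
#'   [ct_volume()] (whose voxel array is windowed; a plain array is returned).
#' @param setting A [window_setting()] or a preset name accepted by
#'   [window_preset()].
#' @return Numeric object of the same shape with values in `[0, 1]`.
#' @export
#' @examples
#' apply_window(c(-1000, 30, 2000), "mediastinum")
apply_window <- function(hu, setting) {
  if (is.character(setting)) setting <- window_preset(setting)
  if (!inherits(setting, "window_setting")) {
    stop("`setting` must be a window_setting or a preset name", call. = FALSE)
  }
  if (is_ct_volume(hu)) hu <- hu$voxels
  pmin(pmax((hu - setting$level) / setting$width + 0.5, 0), 1)
}

# Clip HU to a window's interval without rescaling. Used by the measurer's
# optional internal window: the arg-min of the Haar response is invariant to
# the affine display scaling, so clipping in HU keeps tau in HU units.
clip_to_window <- function(hu, setting) {
  lo <- setting$level - setting$width / 2
  hi <- setting$level + setting$width / 2
  pmin(pmax(hu, lo), hi)
}
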