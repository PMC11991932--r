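#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a stone measurement
#'
#' One row per analysed ROI slice: slice index, per-slice diameter, number
#' of edge points, skip reason.
#'
#' @param x A `stone_measurement` from [measure_stone()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.stone_measurement <- function(x, ...) {
  dplyr::mutate(x$slices[c("slice", "diameter_mm", "n_edges", "skipped")],
                label = x$label, .before = 1)
}

#' @rdname tidy.stone_measurement
#' @export
glance.stone_measurement <- function(x, ...) {
  tibble::tibble(label = x$label, size_mm = x$size_mm,
                 n_slices_used = x$n_slices_used,
                 n_slices_total = nrow(x$slices))
}

#' Tidy a study evaluation
#'
#' `tidy()` returns the per-stone variability rows; `glance()` the one-row
#' overall summary (records, raters, methods, overall MAE).
#'
#' @param x A `stone_eval` from [evaluate_study()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.stone_eval <- function(x, ...) x$per_stone

#' @rdname tidy.stone_eval
#' @export
glance.stone_eval <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$records),
    n_methods = length(unique(x$records$method)),
    n_stones = length(unique(x$records$stone_id)),
    overall_mae = mean(x$records$abs_error)
  )
}
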