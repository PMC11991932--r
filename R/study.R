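#' Run the automated pipeline over a synthetic study
#'
#' Detects and measures stones in every volume of a [synthesize_study()]
#' result and matches candidates to ground-truth stones by nearest centroid.
#' Unmatched truth stones (e.g. faint stones falling below the detector
#' threshold after blur) get `measured_mm = NA`.
#'
#' @param study A list from [synthesize_study()].
#' @param detector A [detector_config()].
#' @param measurer A [measurer_config()].
#' @param max_match_mm Maximum centroid distance for a truth match.
#'   Default 5 mm.
#' @return A measurement-record tibble (`rater = "automated"`,
#'   `method = "automated"`) with one row per truth stone: `stone_id`,
#'   `density_hu`, `true_mm`, `measured_mm`, plus `tube`, `label`, `note`.
#' @export
#' @examples
#' \donttest{
#' study <- synthesize_study(seed = 1)
#' records <- measure_study(study)
#' mae_table(records)
#' }
measure_study <- function(study, detector = detector_config(),
                          measurer = measurer_config(), max_match_mm = 5) {
  out <- purrr::map_dfr(seq_along(study$volumes), function(tb) {
    vol <- study$volumes[[tb]]
    truth_tb <- study$truth[study$truth$tube == tb, ]
    meas <- detect_stones(vol, detector) |> measure_stones(measurer)
    sp <- vol$spacing
    res <- truth_tb[c("stone_id", "density_hu", "true_mm", "tube")]
    res$measured_mm <- NA_real_
    res$label <- NA_integer_
    res$note <- "not detected"
    if (nrow(meas) > 0) {
      cand_mm <- cbind(meas$centroid_z * sp[1], meas$centroid_y * sp[2],
                       meas$centroid_x * sp[3])
      truth_mm <- cbind(truth_tb$centroid_z * sp[1],
                        truth_tb$centroid_y * sp[2],
                        truth_tb$centroid_x * sp[3])
      for (i in seq_len(nrow(truth_tb))) {
        dd <- sqrt(rowSums(sweep(cand_mm, 2, truth_mm[i, ])^2))
        j <- which.min(dd)
        if (length(j) == 1L && dd[j] <= max_match_mm) {
          res$measured_mm[i] <- meas$size_mm[j]
          res$label[i] <- meas$label[j]
          res$note[i] <- meas$note[j]
        }
      }
    }
    res
  })
  out$rater <- "automated"
  out$method <- "automated"
  tibble::as_tibble(out[c("rater", "method", "stone_id", "density_hu",
                          "true_mm", "measured_mm", "tube", "label", "note")])
}
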