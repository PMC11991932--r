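#' Detector configuration
#'
#' Parameters of the automated stone detector: the Hounsfield threshold used
#' to binarize the volume, the 3D neighbourhood for connected-component
#' labelling, the candidate size gate, and the margin added around each
#' candidate's bounding box when cropping its region of interest (ROI).
#'
#' Defaults: threshold 80 HU sits below the lowest stone density studied
#' (about 100 HU) but far above water (0 +/- 7 HU) and the latex tube
#' (10-20 HU); 26-connectivity is the usual choice for blob isolation;
#' `min_voxels = 4` suppresses single-voxel noise while keeping a 1.4 mm
#' stone at default spacing; `roi_margin = 5` voxels gives the measurer's
#' rays genuine background to traverse.
#'
#' @param hu_threshold Binarization threshold in HU.
#' @param connectivity One of 6, 18, 26 neighbours.
#' @param min_voxels,max_voxels Keep candidates with
#'   `min_voxels <= voxel_count <= max_voxels`.
#' @param roi_margin Non-negative margin in voxels added per axis to the ROI.
#' @return A `detector_config` list.
#' @export
detector_config <- function(hu_threshold = 80, connectivity = 26,
                            min_voxels = 4, max_voxels = Inf,
                            roi_margin = 5) {
  if (!connectivity %in% c(6, 18, 26)) {
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  }
  if (min_voxels < 1) stop("`min_voxels` must be >= 1", call. = FALSE)
  if (roi_margin < 0) stop("`roi_margin` must be >= 0", call. = FALSE)
  structure(list(hu_threshold = hu_threshold,
                 connectivity = as.integer(connectivity),
                 min_voxels = as.integer(min_voxels),
                 max_voxels = max_voxels,
                 roi_margin = as.integer(roi_margin)),
            class = "detector_config")
}

#' Binarize a CT volume at a Hounsfield threshold
#'
#' @param vol A [ct_volume()] or a 3D HU array.
#' @param hu_threshold Threshold in HU; voxels `>= hu_threshold` are
#'   foreground.
#' @return A 3D logical array of the same shape.
#' @export
binarize <- function(vol, hu_threshold) {
  v <- if (is_ct_volume(vol)) vol$voxels else vol
  v >= hu_threshold
}

neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  s <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = s == 1, "18" = s >= 1 & s <= 2, "26" = s >= 1)
  g <- g[keep, , drop = FALSE]
  # half-space: one offset per unordered neighbour pair
  lex_pos <- g[, 1] > 0 | (g[, 1] == 0 & (g[, 2] > 0 |
                                          (g[, 2] == 0 & g[, 3] > 0)))
  g[lex_pos, , drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' Partitions the foreground of a 3D logical mask into maximal connected
#' components under a 6-, 18- or 26-neighbourhood. Voxel adjacency pairs are
#' enumerated geometrically; graph connectivity is resolved by
#' [igraph::components()]. Labels are assigned 1..K in order of decreasing
#' voxel count, ties broken by the lexicographically smallest member voxel
#' in `(z, y, x)` order, so the labelling is fully reproducible.
#'
#' @param mask 3D logical array.
#' @param connectivity One of 6, 18, 26.
#' @return A tibble with one row per component: `label`, `voxel_count`,
#'   `centroid_z`/`_y`/`_x` (continuous voxel coordinates), bounding-box
#'   columns `zmin`..`xmax` (1-based, inclusive), and a `mask` list-column of
#'   `n x 3` integer matrices of member voxels in lexicographic order.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!connectivity %in% c(6, 18, 26)) {
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  }
  d <- dim(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(empty_candidates())
  coords <- arrayInd(fg, d)  # columns z, y, x
  rank_of <- integer(prod(d))
  rank_of[fg] <- seq_along(fg)

  offs <- neighbour_offsets(connectivity)
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
          nb[, 2] >= 1L & nb[, 2] <= d[2] &
          nb[, 3] >= 1L & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * (d[1] * d[2]) + (nb[ok, 2] - 1L) * d[1] +
      nb[ok, 1]
    nb_rank <- rank_of[nb_lin]
    hit <- nb_rank > 0L
    if (any(hit)) {
      edges[[k]] <- rbind(which(ok)[hit], nb_rank[hit])
    }
  }
  edges <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && ncol(edges) > 0) {
    g <- igraph::add_edges(g, as.vector(edges))
  }
  membership <- igraph::components(g)$membership

  sizes <- tabulate(membership)
  # lexicographically smallest voxel of each raw component
  lex <- order(coords[, 1], coords[, 2], coords[, 3])
  first_lex <- integer(length(sizes))
  seen <- logical(length(sizes))
  for (i in lex) {
    m <- membership[i]
    if (!seen[m]) {
      seen[m] <- TRUE
      first_lex[m] <- match(i, lex)
    }
  }
  ord <- order(-sizes, first_lex)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(ord)
  lab <- relabel[membership]

  purrr::map_dfr(seq_along(ord), function(L) {
    sel <- lab == L
    cc <- coords[sel, , drop = FALSE]
    cc <- cc[order(cc[, 1], cc[, 2], cc[, 3]), , drop = FALSE]
    colnames(cc) <- c("z", "y", "x")
    tibble::tibble(
      label = L,
      voxel_count = nrow(cc),
      centroid_z = mean(cc[, 1]), centroid_y = mean(cc[, 2]),
      centroid_x = mean(cc[, 3]),
      zmin = min(cc[, 1]), zmax = max(cc[, 1]),
      ymin = min(cc[, 2]), ymax = max(cc[, 2]),
      xmin = min(cc[, 3]), xmax = max(cc[, 3]),
      mask = list(cc)
    )
  })
}

empty_candidates <- function() {
  tibble::tibble(label = integer(), voxel_count = integer(),
                 centroid_z = numeric(), centroid_y = numeric(),
                 centroid_x = numeric(),
                 zmin = integer(), zmax = integer(), ymin = integer(),
                 ymax = integer(), xmin = integer(), xmax = integer(),
                 mask = list())
}

#' Filter candidate components and attach mean HU
#'
#' Keeps candidates whose voxel count lies within the configured gate and
#' fills in `mean_hu` from the volume; candidate order is preserved.
#'
#' @param candidates Tibble from [label_components()].
#' @param vol The [ct_volume()] the mask came from.
#' @param config A [detector_config()].
#' @return The filtered candidate tibble with a `mean_hu` column.
#' @export
filter_candidates <- function(candidates, vol, config = detector_config()) {
  assert_ct_volume(vol)
  keep <- candidates$voxel_count >= config$min_voxels &
    candidates$voxel_count <= config$max_voxels
  out <- candidates[keep, , drop = FALSE]
  out$mean_hu <- purrr::map_dbl(out$mask, function(cc) {
    mean(vol$voxels[cc])
  })
  out
}

#' Crop a candidate's region of interest
#'
#' Expands the candidate's bounding box by `roi_margin` voxels per axis,
#' clamps to the volume bounds, and returns the sub-volume plus the index
#' offset mapping ROI indices back to volume indices
#' (`vol index = roi index + offset`).
#'
#' @param vol A [ct_volume()].
#' @param candidate One row of a candidate tibble (or a list with the bbox
#'   fields).
#' @param roi_margin Margin in voxels.
#' @return List with `roi` (a [ct_volume()]) and `offset` (integer 3-vector,
#'   `(z, y, x)`).
#' @export
crop_roi <- function(vol, candidate, roi_margin = 5) {
  assert_ct_volume(vol)
  if (is.data.frame(candidate)) candidate <- as.list(candidate[1, ])
  if (is.null(candidate$zmin) || candidate$voxel_count < 1) {
    stop("cannot crop an empty candidate", call. = FALSE)
  }
  d <- dim(vol$voxels)
  lo <- pmax(c(candidate$zmin, candidate$ymin, candidate$xmin) - roi_margin,
             1L)
  hi <- pmin(c(candidate$zmax, candidate$ymax, candidate$xmax) + roi_margin,
             d)
  sub <- vol$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  roi <- ct_volume(sub, spacing = vol$spacing,
                   origin = vol$origin + (lo - 1) * vol$spacing,
                   meta = vol$meta)
  list(roi = roi, offset = as.integer(lo - 1L))
}

#' Detect stone candidates in a CT volume
#'
#' The automated stone detector: binarize at the HU threshold, label 3D
#' connected components, gate them by voxel count, and crop a region of
#' interest around each survivor. Deterministic for a fixed input and
#' configuration.
#'
#' @param vol A [ct_volume()].
#' @param config A [detector_config()].
#' @return A tibble of candidates (see [label_components()]) with `mean_hu`,
#'   plus list-columns `roi` ([ct_volume()] sub-volumes) and `roi_offset`.
#' @export
#' @examples
#' vol <- ct_volume(array(0L, dim = c(4, 10, 10)), spacing = c(1, 0.7, 0.7))
#' vol$voxels[2:3, 4:6, 4:6] <- 1000L
#' detect_stones(vol)
detect_stones <- function(vol, config = detector_config()) {
  assert_ct_volume(vol)
  mask <- binarize(vol, config$hu_threshold)
  cand <- label_components(mask, config$connectivity)
  cand <- filter_candidates(cand, vol, config)
  if (nrow(cand) == 0L) {
    cand$roi <- list()
    cand$roi_offset <- list()
    return(cand)
  }
  rois <- purrr::map(seq_len(nrow(cand)), function(i) {
    crop_roi(vol, cand[i, ], config$roi_margin)
  })
  cand$roi <- purrr::map(rois, "roi")
  cand$roi_offset <- purrr::map(rois, "offset")
  attr(cand, "detector_config") <- config
  cand
}
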