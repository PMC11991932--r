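# Independent oracles and fixture builders used across the suite.

# Breadth-first flood-fill connected-component labelling; deliberately
# written against a different representation (a coordinate queue walked one
# voxel at a time) than the package's adjacency-graph implementation.
flood_fill_labels <- function(mask, connectivity) {
  d <- dim(mask)
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  s <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = s == 1, "18" = s >= 1 & s <= 2, "26" = s >= 1)
  offs <- g[keep, , drop = FALSE]
  labels <- array(0L, dim = d)
  nxt <- 0L
  fg <- which(mask, arr.ind = TRUE)
  nfg <- nrow(fg)
  queue <- matrix(0L, nrow = nfg, ncol = 3)
  for (r in seq_len(nfg)) {
    v <- fg[r, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    nxt <- nxt + 1L
    queue[1, ] <- v
    head_i <- 1L; tail_i <- 1L
    labels[v[1], v[2], v[3]] <- nxt
    while (head_i <= tail_i) {
      cur <- queue[head_i, ]
      head_i <- head_i + 1L
      nb <- sweep(offs, 2, cur, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      for (q in seq_len(nrow(nb))) {
        w <- nb[q, ]
        if (mask[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- nxt
          tail_i <- tail_i + 1L
          queue[tail_i, ] <- w
        }
      }
    }
  }
  labels
}

# membership vector over foreground voxels (sorted linear index order) from a
# candidate tibble as returned by label_components()
candidates_membership <- function(cand, dim3) {
  lin <- integer(0)
  lab <- integer(0)
  for (i in seq_len(nrow(cand))) {
    cc <- cand$mask[[i]]
    lin <- c(lin, (cc[, 3] - 1L) * (dim3[1] * dim3[2]) +
               (cc[, 2] - 1L) * dim3[1] + cc[, 1])
    lab <- c(lab, rep(cand$label[i], nrow(cc)))
  }
  o <- order(lin)
  list(lin = lin[o], lab = lab[o])
}

# TRUE if two labelings of the same voxel set agree up to label permutation
same_partition <- function(lab1, lab2) {
  if (length(lab1) != length(lab2)) return(FALSE)
  key <- paste(lab1, lab2)
  length(unique(key)) == length(unique(lab1)) &&
    length(unique(lab1)) == length(unique(lab2))
}

# scalar bilinear interpolation oracle
bilinear_oracle <- function(m, y, x) {
  ny <- nrow(m); nx <- ncol(m)
  i0 <- min(max(floor(y), 1), ny - 1)
  j0 <- min(max(floor(x), 1), nx - 1)
  fy <- y - i0; fx <- x - j0
  m[i0, j0] * (1 - fy) * (1 - fx) + m[i0 + 1, j0] * fy * (1 - fx) +
    m[i0, j0 + 1] * (1 - fy) * fx + m[i0 + 1, j0 + 1] * fy * fx
}

random_hu_volume <- function(dim3 = c(4, 8, 8), seed = 1) {
  withr::with_seed(seed, {
    ct_volume(array(sample(-1000:3000, prod(dim3), replace = TRUE),
                    dim = dim3),
              spacing = c(1, 0.7, 0.7))
  })
}

# small single-stone scene used by measurement tests
test_scene <- function(diameter_mm, density_hu, spacing = c(1, 0.7, 0.7),
                       centre = c(15, 15, 15), noiseless = TRUE, ...) {
  phantom_scene(phantom_stone(diameter_mm, density_hu, centre = centre),
                extent_mm = c(30, 30, 30), spacing = spacing,
                psf_sigma_mm = if (noiseless) c(0, 0) else c(0.5, 0.5),
                noise_sd_hu = if (noiseless) 0 else 5, ...)
}
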