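#' Read and write CT volumes as NIfTI
#'
#' The portable research container for fixtures and intermediate volumes.
#' Voxels and spacing round-trip losslessly; the `[z, y, x]` array convention
#' of [ct_volume()] is mapped to NIfTI's `[x, y, z]` on disk.
#'
#' @param vol A [ct_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a [ct_volume()]; `write_volume()` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  assert_ct_volume(vol)
  img <- aperm(vol$voxels, c(3, 2, 1))
  storage.mode(img) <- "integer"
  nii <- RNifti::asNifti(img)
  sp <- vol$spacing
  RNifti::pixdim(nii) <- c(sp[3], sp[2], sp[1])
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D volume, got ", length(dim(arr)), " dimensions",
         call. = FALSE)
  }
  pd <- RNifti::pixdim(nii)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0)) {
    stop("volume is missing positive spacing metadata (pixdim)",
         call. = FALSE)
  }
  ct_volume(aperm(arr, c(3, 2, 1)), spacing = c(pd[3], pd[2], pd[1]))
}

# ---------------------------------------------------------------------------
# Minimal single-frame CT DICOM codec (little endian; explicit VR written,
# explicit and implicit VR read). Sequences, compressed transfer syntaxes and
# multi-frame objects are out of scope.
# ---------------------------------------------------------------------------

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
SOP_CT_IMAGE <- "1.2.840.10008.5.1.4.1.1.2"
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

u16le <- function(x) {
  x <- as.integer(x)
  as.raw(as.vector(rbind(x %% 256L, (x %/% 256L) %% 256L)))
}

u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

dcm_pad <- function(val, pad = as.raw(0x20)) {
  if (length(val) %% 2L == 1L) val <- c(val, pad)
  val
}

dcm_element <- function(group, elem, vr, value, implicit = FALSE) {
  pad <- if (vr %in% c("UI", "OB", "OW")) as.raw(0) else as.raw(0x20)
  value <- dcm_pad(value, pad)
  tag <- c(u16le(group), u16le(elem))
  if (implicit) {
    c(tag, u32le(length(value)), value)
  } else if (vr %in% LONG_VRS) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)), u32le(length(value)), value)
  } else {
    c(tag, charToRaw(vr), u16le(length(value)), value)
  }
}

dcm_str <- function(x) charToRaw(paste(x, collapse = "\\"))

dcm_ds <- function(x) dcm_str(sprintf("%.10g", x))

fresh_uid <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    sprintf("1.2.826.0.1.3680043.9590.%d.%d.%d",
            as.integer(Sys.time()) %% 100000L, Sys.getpid() %% 10000L, counter)
  }
})

encode_pixels <- function(stored) {
  # little-endian 16-bit; negative values two's complement
  v <- as.integer(round(stored))
  v <- ifelse(v < 0L, v + 65536L, v)
  as.raw(as.vector(rbind(v %% 256L, v %/% 256L)))
}

#' Write a CT volume as a DICOM series
#'
#' Writes one single-frame axial CT Image Storage file per slice (explicit VR
#' little endian by default), encoding pixels as 16-bit stored values with the
#' given rescale slope/intercept so that `HU = stored * slope + intercept`.
#' A `manifest.json` listing the files in slice order is written alongside.
#'
#' @param vol A [ct_volume()].
#' @param dir Output directory (created if needed).
#' @param slope,intercept Rescale slope/intercept used for encoding.
#' @param implicit_vr Write implicit instead of explicit VR little endian
#'   (mainly to exercise the reader's implicit-VR path).
#' @return A tibble manifest with `file`, `instance`, `position_mm`,
#'   invisibly.
#' @export
write_dicom_series <- function(vol, dir, slope = 1, intercept = -1024,
                               implicit_vr = FALSE) {
  assert_ct_volume(vol)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir, call. = FALSE)
  }
  stored_rng <- range((c(-1024, 4095) - intercept) / slope)
  if (stored_rng[1] < -32768 || stored_rng[2] > 65535) {
    stop("slope/intercept cannot encode the HU range in 16 bits",
         call. = FALSE)
  }
  stored_all <- (vol$voxels - intercept) / slope
  if (any(abs(stored_all - round(stored_all)) > 1e-6)) {
    stop("slope/intercept do not encode these HU values losslessly",
         call. = FALSE)
  }
  pixel_rep <- if (min(stored_all) < 0) 1L else 0L
  if (pixel_rep == 1L && max(stored_all) > 32767) {
    stop("stored values exceed the signed 16-bit range", call. = FALSE)
  }
  d <- dim(vol$voxels)
  sp <- vol$spacing
  series_uid <- fresh_uid()
  study_uid <- fresh_uid()
  files <- character(d[1])
  positions <- numeric(d[1])
  for (i in seq_len(d[1])) {
    sop_uid <- fresh_uid()
    pos <- c(vol$origin[3], vol$origin[2], vol$origin[1] + (i - 1) * sp[1])
    positions[i] <- pos[3]
    slice <- vol$voxels[i, , , drop = TRUE]
    stored <- (slice - intercept) / slope
    pix <- encode_pixels(as.vector(t(stored)))
    el <- function(g, e, vr, val) dcm_element(g, e, vr, val, implicit_vr)
    body <- c(
      el(0x0008, 0x0016, "UI", dcm_str(SOP_CT_IMAGE)),
      el(0x0008, 0x0018, "UI", dcm_str(sop_uid)),
      el(0x0008, 0x0060, "CS", dcm_str("CT")),
      el(0x0018, 0x0050, "DS", dcm_ds(sp[1])),
      el(0x0020, 0x000D, "UI", dcm_str(study_uid)),
      el(0x0020, 0x000E, "UI", dcm_str(series_uid)),
      el(0x0020, 0x0013, "IS", dcm_str(i)),
      el(0x0020, 0x0032, "DS", dcm_ds(pos)),
      el(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
      el(0x0028, 0x0002, "US", u16le(1)),
      el(0x0028, 0x0004, "CS", dcm_str("MONOCHROME2")),
      el(0x0028, 0x0010, "US", u16le(d[2])),
      el(0x0028, 0x0011, "US", u16le(d[3])),
      el(0x0028, 0x0030, "DS", dcm_ds(c(sp[2], sp[3]))),
      el(0x0028, 0x0100, "US", u16le(16)),
      el(0x0028, 0x0101, "US", u16le(16)),
      el(0x0028, 0x0102, "US", u16le(15)),
      el(0x0028, 0x0103, "US", u16le(pixel_rep)),
      el(0x0028, 0x1052, "DS", dcm_ds(intercept)),
      el(0x0028, 0x1053, "DS", dcm_ds(slope)),
      dcm_element(0x7FE0, 0x0010, "OW", pix, implicit = implicit_vr)
    )
    ts <- if (implicit_vr) TS_IMPLICIT_LE else TS_EXPLICIT_LE
    meta_body <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dcm_element(0x0002, 0x0002, "UI", dcm_str(SOP_CT_IMAGE)),
      dcm_element(0x0002, 0x0003, "UI", dcm_str(sop_uid)),
      dcm_element(0x0002, 0x0010, "UI", dcm_str(ts)),
      dcm_element(0x0002, 0x0012, "UI", dcm_str("1.2.826.0.1.3680043.9590.1"))
    )
    meta <- c(dcm_element(0x0002, 0x0000, "UL", u32le(length(meta_body))),
              meta_body)
    file_i <- file.path(dir, sprintf("slice_%04d.dcm", i))
    con <- file(file_i, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
    files[i] <- basename(file_i)
  }
  manifest <- tibble::tibble(file = files, instance = seq_len(d[1]),
                             position_mm = positions)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA)
  invisible(manifest)
}

# --- reading ---------------------------------------------------------------

rd_u16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}

rd_u32 <- function(bytes, at) {
  as.numeric(bytes[at]) + 256 * as.numeric(bytes[at + 1L]) +
    65536 * as.numeric(bytes[at + 2L]) + 16777216 * as.numeric(bytes[at + 3L])
}

rd_str <- function(raw_val) {
  s <- rawToChar(raw_val[raw_val != as.raw(0)])
  trimws(s)
}

# Parse one DICOM file into a named list of the elements this codec uses.
parse_dicom_file <- function(path) {
  bytes <- readBin(path, what = "raw", n = file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM part-10 file (missing DICM marker): ", path,
         call. = FALSE)
  }
  pos <- 133L
  out <- list()
  implicit <- FALSE
  in_meta <- TRUE
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- rd_u16(bytes, pos)
    elem <- rd_u16(bytes, pos + 2L)
    if (in_meta && group != 0x0002) {
      in_meta <- FALSE
      ts <- out[["transfer_syntax"]]
      if (is.null(ts)) stop("missing TransferSyntaxUID (0002,0010) in ", path,
                            call. = FALSE)
      if (ts == TS_IMPLICIT_LE) {
        implicit <- TRUE
      } else if (ts != TS_EXPLICIT_LE) {
        stop("unsupported transfer syntax ", ts, " in ", path, call. = FALSE)
      }
    }
    use_implicit <- implicit && !in_meta
    if (use_implicit) {
      len <- rd_u32(bytes, pos + 4L)
      val_at <- pos + 8L
    } else {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- rd_u32(bytes, pos + 8L)
        val_at <- pos + 12L
      } else {
        len <- rd_u16(bytes, pos + 6L)
        val_at <- pos + 8L
      }
    }
    if (len == 4294967295) {
      stop("undefined-length elements (sequences) are not supported: ", path,
           call. = FALSE)
    }
    val <- if (len > 0) bytes[val_at:(val_at + len - 1L)] else raw(0)
    key <- sprintf("%04X%04X", group, elem)
    keep <- c(
      "00020010" = "transfer_syntax", "0020000E" = "series_uid",
      "00200032" = "position", "00200037" = "orientation",
      "00200013" = "instance", "00280010" = "rows", "00280011" = "cols",
      "00280030" = "pixel_spacing", "00180050" = "slice_thickness",
      "00280100" = "bits_allocated", "00280103" = "pixel_representation",
      "00281052" = "intercept", "00281053" = "slope",
      "7FE00010" = "pixel_data", "00080060" = "modality"
    )
    if (!is.na(keep[key])) {
      name <- keep[[key]]
      out[[name]] <- switch(name,
        transfer_syntax = , series_uid = , modality = rd_str(val),
        position = , orientation = , pixel_spacing = , slice_thickness = ,
        intercept = , slope = as.numeric(strsplit(rd_str(val), "\\\\")[[1]]),
        instance = as.integer(rd_str(val)),
        rows = , cols = , bits_allocated = ,
        pixel_representation = rd_u16(val, 1L),
        pixel_data = val
      )
    }
    pos <- val_at + len
  }
  out
}

dicom_need <- function(x, field, tag, path) {
  if (is.null(x[[field]])) {
    stop(sprintf("missing required DICOM tag %s (%s) in %s", tag, field,
                 path), call. = FALSE)
  }
  x[[field]]
}

#' Read a DICOM series as a CT volume
#'
#' Reads every DICOM file in `dir` (one series of single-frame axial CT
#' slices), converts stored values to Hounsfield units via each slice's
#' rescale slope/intercept, and orders slices by the projection of their image
#' position onto the slice normal -- never by file name. In-plane spacing
#' comes from PixelSpacing; inter-slice spacing from the positions of adjacent
#' sorted slices, falling back to SliceThickness (with a warning) for
#' single-slice series.
#'
#' @param dir Directory containing exactly one DICOM series.
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  paths <- list.files(dir, full.names = TRUE)
  paths <- paths[!grepl("\\.json$", paths)]
  if (length(paths) == 0) stop("no DICOM files in ", dir, call. = FALSE)
  slices <- lapply(paths, parse_dicom_file)

  uids <- vapply(seq_along(slices), function(i)
    dicom_need(slices[[i]], "series_uid", "(0020,000E)", paths[i]), "")
  if (length(unique(uids)) != 1L) {
    stop("directory mixes multiple series UIDs (0020,000E)", call. = FALSE)
  }
  rows <- vapply(seq_along(slices), function(i)
    dicom_need(slices[[i]], "rows", "(0028,0010)", paths[i]), 1L)
  cols <- vapply(seq_along(slices), function(i)
    dicom_need(slices[[i]], "cols", "(0028,0011)", paths[i]), 1L)
  if (length(unique(rows)) != 1L || length(unique(cols)) != 1L) {
    stop("inconsistent Rows/Columns (0028,0010)/(0028,0011) across series",
         call. = FALSE)
  }
  psp <- lapply(seq_along(slices), function(i)
    dicom_need(slices[[i]], "pixel_spacing", "(0028,0030)", paths[i]))
  if (length(unique(vapply(psp, paste, "", collapse = ","))) != 1L) {
    stop("inconsistent PixelSpacing (0028,0030) across series", call. = FALSE)
  }
  ori <- lapply(seq_along(slices), function(i)
    dicom_need(slices[[i]], "orientation", "(0020,0037)", paths[i]))
  pos <- lapply(seq_along(slices), function(i)
    dicom_need(slices[[i]], "position", "(0020,0032)", paths[i]))

  u <- ori[[1]][1:3]
  v <- ori[[1]][4:6]
  normal <- c(u[2] * v[3] - u[3] * v[2],
              u[3] * v[1] - u[1] * v[3],
              u[1] * v[2] - u[2] * v[1])
  proj <- vapply(pos, function(p) sum(p * normal), 0)
  ord <- order(proj)
  slices <- slices[ord]
  pos <- pos[ord]
  proj <- proj[ord]

  nz <- length(slices)
  if (nz > 1L) {
    gaps <- diff(proj)
    if (any(gaps <= 0) || diff(range(gaps)) > 1e-3 * max(gaps)) {
      stop("non-uniform or duplicate slice positions (0020,0032)",
           call. = FALSE)
    }
    dz <- mean(gaps)
  } else {
    st <- slices[[1]][["slice_thickness"]]
    if (is.null(st)) {
      stop("single slice without SliceThickness (0018,0050): cannot infer dz",
           call. = FALSE)
    }
    warning("single-slice series: using SliceThickness tag for dz")
    dz <- st[1]
  }

  vox <- array(0, dim = c(nz, rows[1], cols[1]))
  for (i in seq_len(nz)) {
    s <- slices[[i]]
    pix <- dicom_need(s, "pixel_data", "(7FE0,0010)", "slice")
    ba <- s[["bits_allocated"]] %||% 16L
    if (ba != 16L) stop("only 16-bit pixel data supported", call. = FALSE)
    stored <- rd_u16(pix, seq(1L, length(pix), by = 2L))
    if (isTRUE(s[["pixel_representation"]] == 1L)) {
      stored <- ifelse(stored > 32767L, stored - 65536L, stored)
    }
    slope <- (s[["slope"]] %||% 1)[1]
    intercept <- (s[["intercept"]] %||% 0)[1]
    hu <- stored * slope + intercept
    vox[i, , ] <- matrix(hu, nrow = rows[1], byrow = TRUE)
  }
  p1 <- pos[[1]]
  ct_volume(vox,
            spacing = c(dz, psp[[1]][1], psp[[1]][2]),
            origin = c(p1[3], p1[2], p1[1]),
            meta = list(series_uid = uids[1],
                        modality = slices[[1]][["modality"]] %||% "CT"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
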