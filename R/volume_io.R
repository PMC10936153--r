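#' Aligned two-channel intensity volume
#'
#' The shared container of the pipeline: red and green voxel grids of
#' identical shape, either 3D `(z,y,x)` or 4D `(t,z,y,x)` for time-lapse
#' data, with the voxel spacing in micrometres. Intensities must be
#' non-negative; 2D matrices are promoted to single-slice 3D stacks.
#'
#' @param red,green numeric arrays of identical shape.
#' @param voxel_size_um numeric (dz, dy, dx) in micrometres.
#' @return An object of class `channel_pair_volume`.
#' @export
channel_pair_volume <- function(red, green, voxel_size_um = c(1, 1, 1)) {
  if (is.null(dim(red)) || is.null(dim(green)))
    stopf("channels must be arrays")
  if (length(dim(red)) == 2L) red <- array(red, c(1L, dim(red)))
  if (length(dim(green)) == 2L) green <- array(green, c(1L, dim(green)))
  if (!identical(dim(red), dim(green)))
    stopf("channel shapes differ: red %s vs green %s",
          paste(dim(red), collapse = "x"), paste(dim(green), collapse = "x"))
  nd <- length(dim(red))
  if (!nd %in% c(3L, 4L))
    stopf("volumes must be 3D (z,y,x) or 4D (t,z,y,x); got %dD", nd)
  if (min(red) < 0 || min(green) < 0) stopf("intensities must be >= 0")
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stopf("voxel_size_um must be 3 positive spacings")
  structure(list(red = red, green = green,
                 voxel_size_um = as.numeric(voxel_size_um)),
            class = "channel_pair_volume")
}

#' @export
print.channel_pair_volume <- function(x, ...) {
  d <- dim(x$red)
  ax <- if (length(d) == 4L) "(t,z,y,x)" else "(z,y,x)"
  cat(sprintf("<channel_pair_volume> %s %s, voxel %s um\n",
              paste(d, collapse = "x"), ax,
              paste(signif(x$voxel_size_um, 3), collapse = " x ")))
  invisible(x)
}

n_timepoints <- function(pair) {
  if (length(dim(pair$red)) == 4L) dim(pair$red)[1] else 1L
}

#' Extract one timepoint of a (possibly 4D) pair as a 3D pair
#' @param pair a [channel_pair_volume()].
#' @param t 1-based timepoint index (must be 1 for 3D input).
#' @return A 3D `channel_pair_volume`.
#' @export
get_frame <- function(pair, t = 1L) {
  stopifnot(inherits(pair, "channel_pair_volume"))
  if (length(dim(pair$red)) == 3L) {
    if (t != 1L) stopf("volume has a single timepoint; t = %d requested", t)
    return(pair)
  }
  d <- dim(pair$red)
  if (t < 1L || t > d[1]) stopf("t = %d outside 1..%d", t, d[1])
  channel_pair_volume(array(pair$red[t, , , ], d[-1]),
                      array(pair$green[t, , , ], d[-1]),
                      pair$voxel_size_um)
}

# ---- TIFF -------------------------------------------------------------------

# TIFF pages hold unsigned integers normalized to [0, 1]. Integer-valued
# volumes in 16-bit range are stored exactly as 16-bit pages; anything else
# goes to 32-bit pages under a fixed-point convention (value / 65536), i.e.
# a resolution of 65536 / (2^32 - 1) ~ 1.5e-5 intensity units over
# [0, 65536) — ample for photon-count data.
tiff_float_scale <- 65536

write_volume_tiff <- function(vol, path) {
  vol <- as_volume3d(vol)
  integerish <- max(vol) <= 65535 && all(vol == round(vol))
  if (integerish) {
    slices <- lapply(seq_len(dim(vol)[1]), function(i) vol[i, , ] / 65535)
    tiff::writeTIFF(slices, path, bits.per.sample = 16)
  } else {
    if (max(vol) >= tiff_float_scale)
      stopf("intensities above %d are not representable; rescale first",
            tiff_float_scale - 1L)
    slices <- lapply(seq_len(dim(vol)[1]),
                     function(i) vol[i, , ] / tiff_float_scale)
    tiff::writeTIFF(slices, path, bits.per.sample = 32)
  }
  invisible(path)
}

read_volume_tiff <- function(path) {
  if (!file.exists(path)) stopf("cannot read volume: no such file '%s'", path)
  info <- tiff::readTIFF(path, payload = FALSE)
  bits <- info$bits.per.sample[1]
  as_integers <- !is.null(bits) && bits %in% c(8L, 16L)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_integers)
  if (!is.list(pages)) pages <- list(pages)
  slices <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # ignore extra samples per pixel
    p
  })
  vol <- array(0, c(length(slices), dim(slices[[1]])))
  for (i in seq_along(slices)) vol[i, , ] <- slices[[i]]
  if (!as_integers) vol <- vol * tiff_float_scale
  vol
}

#' Read a two-channel volume from per-channel multi-page TIFFs
#'
#' Each file holds one channel as a stack of z pages (a 4D time-lapse is
#' stored as `t * z` pages; pass `nz` to fold the time axis back). 16-bit
#' pages are returned as integer photon counts, 32-bit pages as fixed-point
#' intensities (resolution 1/65536 of an intensity unit).
#'
#' @param red_path,green_path paths to the red and green TIFF files.
#' @param voxel_size_um numeric (dz, dy, dx) in micrometres.
#' @param nz slices per timepoint; `NULL` (default) means the file is a
#'   single 3D stack.
#' @return A [channel_pair_volume()]; single-page files become z = 1 stacks.
#' @export
read_pair <- function(red_path, green_path, voxel_size_um = c(1, 1, 1),
                      nz = NULL) {
  red <- read_volume_tiff(red_path)
  green <- read_volume_tiff(green_path)
  if (!identical(dim(red), dim(green)))
    stopf("channel shapes differ: red %s ('%s') vs green %s ('%s')",
          paste(dim(red), collapse = "x"), red_path,
          paste(dim(green), collapse = "x"), green_path)
  if (!is.null(nz)) {
    np <- dim(red)[1]
    if (np %% nz != 0)
      stopf("%d pages do not divide into stacks of nz = %d slices", np, nz)
    nt <- np %/% nz
    fold <- function(v) aperm(array(v, c(nz, nt, dim(v)[2:3])), c(2, 1, 3, 4))
    if (nt > 1L) {
      red <- fold(red)
      green <- fold(green)
    }
  }
  channel_pair_volume(red, green, voxel_size_um)
}

#' Write a two-channel volume as per-channel multi-page TIFFs
#'
#' Integer-valued volumes within 16-bit range are written losslessly as
#' 16-bit pages; anything else as 32-bit fixed point (values below 65536,
#' quantized at ~1.5e-5 intensity units). A 4D pair is flattened to
#' `t * z` pages per file (fold back with `nz` in [read_pair()]).
#'
#' @param pair a [channel_pair_volume()].
#' @param red_path,green_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_pair <- function(pair, red_path, green_path) {
  stopifnot(inherits(pair, "channel_pair_volume"))
  flatten <- function(v) {
    d <- dim(v)
    if (length(d) == 4L) array(aperm(v, c(2, 1, 3, 4)), c(d[1] * d[2], d[3], d[4]))
    else v
  }
  write_volume_tiff(flatten(pair$red), red_path)
  write_volume_tiff(flatten(pair$green), green_path)
  invisible(c(red = red_path, green = green_path))
}

# ---- results CSV ------------------------------------------------------------

coloc_csv_columns <- c("image_id", "t", "pcc", "m1", "m2", "overlap",
                       "threshold_green", "threshold_red_low",
                       "threshold_red_high", "n_region_voxels",
                       "region_mode", "qc_fail")

#' Write colocalization results to CSV
#'
#' One row per image/timepoint, fixed column order: `image_id, t, pcc, m1,
#' m2, overlap, threshold_green, threshold_red_low, threshold_red_high,
#' n_region_voxels, region_mode, qc_fail`. An undefined Pearson coefficient
#' (zero variance or empty analysis region) is written as an empty cell with
#' `qc_fail = TRUE`. Numeric values survive a write/read round trip to at
#' least 12 significant digits.
#'
#' @param results a non-empty list of [coloc_image()] results (class
#'   `coloc_result`), or a single result.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_coloc_csv <- function(results, path) {
  if (inherits(results, "coloc_result")) results <- list(results)
  if (!length(results)) stopf("no results to write")
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "coloc_result"))
    data.frame(
      image_id = r$image_id %||% NA_character_,
      t = r$t_index %||% NA_integer_,
      pcc = r$pcc, m1 = r$m1, m2 = r$m2, overlap = r$overlap_k,
      threshold_green = r$thresholds$green %||% NA_real_,
      threshold_red_low = (r$thresholds$red %||% c(NA_real_, NA_real_))[1],
      threshold_red_high = (r$thresholds$red %||% c(NA_real_, NA_real_))[2],
      n_region_voxels = r$n_region_voxels,
      region_mode = r$region_mode, qc_fail = isTRUE(r$qc_fail),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)[, coloc_csv_columns]
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    v <- df[[j]]
    s <- vapply(v, function(x) {
      if (is.na(x)) "" else format(x, digits = 15, scientific = FALSE, trim = TRUE)
    }, character(1))
    df[[j]] <- s
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a colocalization CSV written by [write_coloc_csv()]
#' @param path file path.
#' @return A data frame with the documented columns; empty `pcc` cells of
#'   qc-failed rows are returned as `NaN`.
#' @export
read_coloc_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), coloc_csv_columns))
    stopf("'%s' is not a coloc CSV (unexpected columns)", path)
  for (col in c("pcc", "m1", "m2", "overlap")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    v[is.na(v) & df$qc_fail] <- NaN
    df[[col]] <- v
  }
  df
}
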