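# histogram whose bin centers are the threshold candidates everywhere in
# this module. Integer-valued data whose range fits the bin budget get
# unit-width bins centred on the integer intensities (so thresholds are
# exact intensity values); otherwise `bins` equal-width bins over
# [min, max].
intensity_histogram <- function(v, bins) {
  rng <- range(v)
  if (rng[1] == rng[2])
    stopf("degenerate input: constant volume (all voxels = %g)", rng[1])
  if (all(v == round(v)) && diff(rng) <= bins - 1) {
    return(list(counts = tabulate(v - rng[1] + 1, nbins = bins),
                centers = rng[1] + seq_len(bins) - 1))
  }
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  list(counts = tabulate(idx, nbins = bins),
       centers = (breaks[-1] + breaks[-(bins + 1L)]) / 2)
}

#' Two-class Otsu threshold
#'
#' Selects, among the histogram bin centers, the cut maximizing the
#' between-class variance of the two resulting intensity classes; ties are
#' broken toward the smallest candidate. Foreground is defined throughout
#' the package as intensity strictly greater than the threshold. Used for
#' the green channel, whose background is clean enough for a single cut.
#'
#' @param volume numeric 2D/3D array (2D promoted to one slice).
#' @param bins number of histogram bins (default 256; for floating-point
#'   data the bins are equal-width over the observed range).
#' @return An object of class `threshold_result`: list with `thresholds`
#'   (length 1), `n_classes = 2`, `histogram_bins`.
#' @export
otsu_threshold <- function(volume, bins = 256L) {
  v <- as.numeric(as_volume3d(volume))
  h <- intensity_histogram(v, bins)
  p <- h$counts / sum(h$counts)
  w <- cumsum(p)
  s <- cumsum(p * h$centers)
  mu_t <- s[bins]
  # between-class variance for a cut after bin k
  k <- seq_len(bins - 1L)
  valid <- w[k] > 0 & w[k] < 1
  sigma_b <- rep(-Inf, bins - 1L)
  sigma_b[valid] <- (mu_t * w[k][valid] - s[k][valid])^2 /
    (w[k][valid] * (1 - w[k][valid]))
  if (!any(is.finite(sigma_b)))
    stopf("degenerate input: fewer than 2 occupied histogram bins")
  best <- which.max(sigma_b)  # first max = smallest candidate on ties
  structure(list(thresholds = h$centers[best], n_classes = 2L,
                 histogram_bins = as.integer(bins)),
            class = "threshold_result")
}

#' Multi-Otsu thresholds (three classes by default)
#'
#' Exhaustively searches all ascending pairs of histogram bin centers for
#' the partition into `n_classes` contiguous intensity classes that
#' maximizes the between-class variance; ties resolve to the
#' lexicographically smallest tuple. Used for the red channel, whose
#' noisier diffuse background needs its own intermediate class.
#'
#' @inheritParams otsu_threshold
#' @param n_classes number of classes (only 3 is supported).
#' @return A `threshold_result` with two ascending `thresholds`.
#' @export
multi_otsu_thresholds <- function(volume, n_classes = 3L, bins = 256L) {
  if (n_classes != 3L)
    stopf("only n_classes = 3 is supported (got %s)", n_classes)
  v <- as.numeric(as_volume3d(volume))
  h <- intensity_histogram(v, bins)
  if (sum(h$counts > 0) < n_classes)
    stopf("degenerate input: %d occupied bins < %d classes",
          sum(h$counts > 0), n_classes)
  p <- h$counts / sum(h$counts)
  W <- cumsum(p)
  S <- cumsum(p * h$centers)
  # maximize sum_c S_c^2 / W_c over cuts (i, j), classes [1..i],(i..j],(j..B]
  best <- c(NA_integer_, NA_integer_)
  best_val <- -Inf
  B <- length(p)
  for (i in seq_len(B - 2L)) {
    if (W[i] <= 0) next
    j <- (i + 1L):(B - 1L)
    w2 <- W[j] - W[i]
    w3 <- W[B] - W[j]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    val <- rep(-Inf, length(j))
    val[ok] <- S[i]^2 / W[i] +
      (S[j][ok] - S[i])^2 / w2[ok] +
      (S[B] - S[j][ok])^2 / w3[ok]
    m <- which.max(val)
    if (val[m] > best_val) {  # strict: keeps lexicographically smallest tie
      best_val <- val[m]
      best <- c(i, j[m])
    }
  }
  if (!is.finite(best_val))
    stopf("degenerate input: cannot form %d non-empty classes", n_classes)
  structure(list(thresholds = h$centers[best], n_classes = 3L,
                 histogram_bins = as.integer(bins)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %d classes, thresholds: %s (%d bins)\n",
              x$n_classes, paste(signif(x$thresholds, 6), collapse = ", "),
              x$histogram_bins))
  invisible(x)
}

# ---- binary morphology ------------------------------------------------------

new_binary_mask <- function(mask, source_channel, provenance,
                            threshold = NULL) {
  structure(list(mask = mask, source_channel = source_channel,
                 provenance = provenance, threshold = threshold),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s channel via %s, %d / %d voxels foreground\n",
              x$source_channel, x$provenance, sum(x$mask), length(x$mask)))
  invisible(x)
}

as_mask_array <- function(m, arg = "mask") {
  if (inherits(m, "binary_mask")) m <- m$mask
  m <- as_volume3d(m, arg)
  if (!is.logical(m)) storage.mode(m) <- "logical"
  m
}

erode_cross1 <- function(m) {
  m & shift3(m, 1, 0, 0) & shift3(m, -1, 0, 0) &
    shift3(m, 0, 1, 0) & shift3(m, 0, -1, 0) &
    shift3(m, 0, 0, 1) & shift3(m, 0, 0, -1)
}

dilate_cross1 <- function(m) {
  m | shift3(m, 1, 0, 0) | shift3(m, -1, 0, 0) |
    shift3(m, 0, 1, 0) | shift3(m, 0, -1, 0) |
    shift3(m, 0, 0, 1) | shift3(m, 0, 0, -1)
}

#' Binary morphological opening in 3D
#'
#' Erosion followed by dilation with the same structuring element: the
#' 6-connected cross of radius 1 in voxel space, iterated `se_radius_vox`
#' times (radius r thus uses the octahedral ball of radius r). Opening is
#' anti-extensive (result is a subset of the input), idempotent and
#' monotone; with the default radius it removes single-voxel specks, the
#' minimal despeckling the noisier red channel needs. Voxels outside the
#' volume count as background.
#'
#' @param mask a `binary_mask` or logical array.
#' @param se_radius_vox structuring-element radius in voxels (>= 1).
#' @return A `binary_mask` with provenance `"opened"`.
#' @export
binary_opening <- function(mask, se_radius_vox = 1L) {
  if (!is_count(se_radius_vox) || se_radius_vox < 1L)
    stopf("se_radius_vox must be >= 1")
  m <- as_mask_array(mask)
  for (i in seq_len(se_radius_vox)) m <- erode_cross1(m)
  for (i in seq_len(se_radius_vox)) m <- dilate_cross1(m)
  src <- if (inherits(mask, "binary_mask")) mask$source_channel else "unknown"
  thr <- if (inherits(mask, "binary_mask")) mask$threshold else NULL
  new_binary_mask(m, src, "opened", thr)
}

#' Segment the green channel (single Otsu)
#'
#' The green channel's background is clean, so a single two-class Otsu cut
#' suffices: foreground is every voxel strictly above the threshold; no
#' morphological cleanup is applied.
#'
#' @param volume numeric array (the green channel).
#' @param bins histogram bins for [otsu_threshold()].
#' @return A `binary_mask` (provenance `"otsu"`) carrying its
#'   `threshold_result`.
#' @export
segment_green <- function(volume, bins = 256L) {
  vol <- as_volume3d(volume)
  thr <- otsu_threshold(vol, bins)
  new_binary_mask(vol > thr$thresholds, "green", "otsu", thr)
}

#' Segment the red channel (three-class multi-Otsu + opening)
#'
#' The red channel has a noisier, diffuse background, so two cuts are
#' needed: the lower class is true background, the middle class absorbs
#' diffuse cytosolic signal and background noise, and only the brightest
#' class (intensity above the upper threshold) is kept as foreground. The
#' binary image is then cleaned by a morphological opening. A threshold
#' must precede the opening — opening is defined on a binary image — so the
#' order here is threshold, binarize, open.
#'
#' @param volume numeric array (the red channel).
#' @param bins histogram bins for [multi_otsu_thresholds()].
#' @param open_radius structuring-element radius for [binary_opening()];
#'   set `open = FALSE` to skip the cleanup.
#' @param open apply the opening step (default TRUE).
#' @return A `binary_mask` (provenance `"opened"`, or `"multi_otsu"` when
#'   `open = FALSE`) carrying its `threshold_result`.
#' @export
segment_red <- function(volume, bins = 256L, open_radius = 1L, open = TRUE) {
  vol <- as_volume3d(volume)
  thr <- multi_otsu_thresholds(vol, 3L, bins)
  m <- new_binary_mask(vol > thr$thresholds[2], "red", "multi_otsu", thr)
  if (open) m <- binary_opening(m, open_radius) else m
}
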