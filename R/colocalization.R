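#' Masked Pearson correlation of two channels
#'
#' Standard Pearson correlation of the red and green intensities over the
#' voxels of an analysis region, the statistic used to score whether two
#' tagged enzymes co-vary in the same compartments. The region is typically
#' the overlap of the two channel foreground masks. Returns `NaN` when
#' either channel is constant over the region (the coefficient is undefined
#' there); an empty region is an error, distinct from the `NaN` case, so
#' callers can tell "nothing to analyze" from "degenerate intensities".
#'
#' @param red,green numeric arrays of identical shape.
#' @param region logical array or `binary_mask` selecting the voxels.
#' @return A single numeric in \[-1, 1\], or `NaN`.
#' @export
pearson_cc <- function(red, green, region) {
  red <- as_volume3d(red, "red")
  green <- as_volume3d(green, "green")
  reg <- as_mask_array(region, "region")
  if (!identical(dim(red), dim(green)) || !identical(dim(red), dim(reg)))
    stopf("red, green and region shapes must match")
  n <- sum(reg)
  if (n == 0L) stopf("empty analysis region")
  r <- red[reg]
  g <- green[reg]
  if (stats::var(r) == 0 || stats::var(g) == 0) return(NaN)
  stats::cor(r, g)
}

#' Manders split coefficients
#'
#' `m1` is the fraction of total red intensity (within the red mask) that
#' falls inside the green mask; `m2` is the symmetric quantity for green.
#' Unlike the Pearson coefficient these measure co-occurrence, not
#' co-variation.
#'
#' @param red,green numeric arrays of identical shape.
#' @param mask_red,mask_green logical arrays or `binary_mask` objects.
#' @return Named numeric `c(m1 = , m2 = )`, both in \[0, 1\].
#' @export
manders <- function(red, green, mask_red, mask_green) {
  red <- as_volume3d(red, "red")
  green <- as_volume3d(green, "green")
  mr <- as_mask_array(mask_red, "mask_red")
  mg <- as_mask_array(mask_green, "mask_green")
  if (!identical(dim(red), dim(mr)) || !identical(dim(green), dim(mg)))
    stopf("mask shapes must match their channels")
  tr <- sum(red[mr])
  tg <- sum(green[mg])
  if (tr <= 0 || tg <= 0)
    stopf("zero integrated intensity inside a channel mask")
  both <- mr & mg
  c(m1 = sum(red[both]) / tr, m2 = sum(green[both]) / tg)
}

build_region <- function(mask_red, mask_green, region_mode) {
  switch(region_mode,
    intersection = mask_red & mask_green,
    union = mask_red | mask_green,
    whole = array(TRUE, dim(mask_red)),
    stopf("unknown region_mode '%s'", region_mode)
  )
}

qc_failed_result <- function(image_id, t_index, region_mode, reason,
                             thresholds = list(), n_region = 0L) {
  structure(list(
    image_id = image_id, t_index = t_index, pcc = NaN,
    m1 = NaN, m2 = NaN, overlap_k = NaN, n_region_voxels = n_region,
    region_mode = region_mode, thresholds = thresholds,
    qc_fail = TRUE, qc_reason = reason
  ), class = "coloc_result")
}

#' Colocalization coefficients for one 3D image
#'
#' The per-image workflow: segment the green channel ([segment_green()]),
#' segment the red channel ([segment_red()]), build the analysis region
#' from the two masks (by default their intersection — the overlapping
#' voxels of the two channels), then compute the masked Pearson
#' coefficient, Manders `m1`/`m2`, and the mask overlap (Jaccard index).
#' Degenerate inputs (constant channels, empty region, zero-intensity
#' masks) yield a qc-flagged result rather than an error, so batch runs
#' over many images always complete.
#'
#' @param pair a 3D [channel_pair_volume()] (or a 4D pair with `t_index`).
#' @param region_mode `"intersection"` (default), `"union"`, or `"whole"`.
#' @param bins histogram bins for the thresholds.
#' @param open_radius,open red-channel opening parameters, see
#'   [segment_red()].
#' @param image_id identifier copied into results and CSV output.
#' @param t_index timepoint index recorded in the result (for 4D input,
#'   selects the frame).
#' @return An object of class `coloc_result`: `pcc`, `m1`, `m2`,
#'   `overlap_k`, `n_region_voxels`, `region_mode`, per-channel
#'   `thresholds`, `qc_fail` (+ `qc_reason` when flagged).
#' @export
coloc_image <- function(pair, region_mode = c("intersection", "union", "whole"),
                        bins = 256L, open_radius = 1L, open = TRUE,
                        image_id = "image", t_index = NULL) {
  stopifnot(inherits(pair, "channel_pair_volume"))
  region_mode <- match.arg(region_mode)
  if (length(dim(pair$red)) == 4L) {
    if (is.null(t_index)) stopf("4D pair: pass t_index or use coloc_timeseries()")
    pair <- get_frame(pair, t_index)
  }
  seg <- tryCatch(
    list(green = segment_green(pair$green, bins),
         red = segment_red(pair$red, bins, open_radius, open)),
    error = function(e) e
  )
  if (inherits(seg, "error"))
    return(qc_failed_result(image_id, t_index, region_mode,
                            conditionMessage(seg)))
  thresholds <- list(green = seg$green$threshold$thresholds,
                     red = seg$red$threshold$thresholds)
  mr <- seg$red$mask
  mg <- seg$green$mask
  region <- build_region(mr, mg, region_mode)
  n_region <- sum(region)
  if (n_region == 0L)
    return(qc_failed_result(image_id, t_index, region_mode,
                            "empty analysis region", thresholds))
  pcc <- pearson_cc(pair$red, pair$green, region)
  mm <- tryCatch(manders(pair$red, pair$green, mr, mg), error = function(e) e)
  if (inherits(mm, "error")) mm <- c(m1 = NaN, m2 = NaN)
  union_n <- sum(mr | mg)
  overlap_k <- if (union_n > 0) sum(mr & mg) / union_n else NaN
  structure(list(
    image_id = image_id, t_index = t_index, pcc = pcc,
    m1 = unname(mm["m1"]), m2 = unname(mm["m2"]), overlap_k = overlap_k,
    n_region_voxels = n_region, region_mode = region_mode,
    thresholds = thresholds, qc_fail = is.nan(pcc),
    qc_reason = if (is.nan(pcc)) "zero variance in region" else NA_character_
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> %s%s: pcc = %.4f, m1 = %.3f, m2 = %.3f, overlap = %.3f (%d voxels, %s)%s\n",
    x$image_id, if (!is.null(x$t_index)) sprintf(" t=%d", x$t_index) else "",
    x$pcc, x$m1, x$m2, x$overlap_k, x$n_region_voxels, x$region_mode,
    if (isTRUE(x$qc_fail)) sprintf(" [QC FAIL: %s]", x$qc_reason) else ""))
  invisible(x)
}

#' Colocalization over a 4D time-lapse
#'
#' Runs [coloc_image()] on every timepoint of a 4D pair and summarizes the
#' trend of the Pearson coefficient over time by the sign of its
#' least-squares slope (live-cell series where one channel bleaches show a
#' steady decrease). Qc-failed timepoints are kept in the series (with
#' `NaN`) and excluded from the trend fit.
#'
#' @param pair4d a 4D [channel_pair_volume()] with at least 2 timepoints.
#' @inheritParams coloc_image
#' @return An object of class `timeseries_result`: `results` (list of
#'   per-timepoint `coloc_result`), `table` (data frame), `slope`
#'   (pcc per frame), and `trend` (-1, 0 or +1).
#' @export
coloc_timeseries <- function(pair4d, region_mode = c("intersection", "union", "whole"),
                             bins = 256L, open_radius = 1L, open = TRUE,
                             image_id = "series") {
  stopifnot(inherits(pair4d, "channel_pair_volume"))
  region_mode <- match.arg(region_mode)
  if (length(dim(pair4d$red)) != 4L || dim(pair4d$red)[1] < 2L)
    stopf("coloc_timeseries needs a 4D pair with T >= 2")
  T_ <- dim(pair4d$red)[1]
  results <- lapply(seq_len(T_), function(t)
    coloc_image(get_frame(pair4d, t), region_mode, bins, open_radius, open,
                image_id = image_id, t_index = t))
  pcc <- vapply(results, function(r) r$pcc, numeric(1))
  tab <- data.frame(t = seq_len(T_), pcc = pcc,
                    m1 = vapply(results, function(r) r$m1, numeric(1)),
                    m2 = vapply(results, function(r) r$m2, numeric(1)),
                    overlap = vapply(results, function(r) r$overlap_k, numeric(1)),
                    qc_fail = vapply(results, function(r) isTRUE(r$qc_fail), logical(1)))
  ok <- !is.nan(pcc)
  slope <- if (sum(ok) >= 2L) {
    unname(stats::coef(stats::lm(pcc[ok] ~ seq_len(T_)[ok]))[2])
  } else NA_real_
  structure(list(results = results, table = tab, slope = slope,
                 trend = sign(slope %||% NA_real_)),
            class = "timeseries_result")
}

#' @export
print.timeseries_result <- function(x, ...) {
  cat(sprintf("<timeseries_result> %d timepoints, pcc slope %.4g per frame (trend %+d)\n",
              nrow(x$table), x$slope, as.integer(x$trend)))
  invisible(x)
}
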