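# Image-quality metrics on normalized envelope amplitudes: contrast (dB),
# SNR, and the generalized contrast-to-noise ratio (gCNR), computed from
# target and background ROI sample sets.

check_samples <- function(x, name) {
  if (!length(x)) stop(name, " samples are empty")
  if (any(!is.finite(x))) stop(name, " samples contain non-finite values")
  invisible(x)
}

#' Contrast in dB
#'
#' `20 * log10(mean(target) / mean(background))` on pre-log normalized
#' envelope amplitudes.
#'
#' @param target,background Numeric vectors of envelope amplitudes.
#' @return Contrast in dB.
#' @examples
#' contrast_db(c(0.8, 0.6), c(0.2, 0.2))  # 20*log10(3.5)
#' @export
contrast_db <- function(target, background) {
  check_samples(target, "target"); check_samples(background, "background")
  mb <- mean(background)
  if (mb == 0) stop("degenerate background: mean amplitude is zero")
  20 * log10(mean(target) / mb)
}

#' Signal-to-noise ratio
#'
#' `mean(target) / sd(background)`, with the sample (n - 1) standard
#' deviation convention.
#'
#' @inheritParams contrast_db
#' @return Unitless SNR.
#' @export
snr <- function(target, background) {
  check_samples(target, "target"); check_samples(background, "background")
  sb <- sd(background)
  if (!is.finite(sb) || sb == 0) {
    stop("degenerate background: standard deviation is zero")
  }
  mean(target) / sb
}

#' Generalized contrast-to-noise ratio (gCNR)
#'
#' One minus the overlap of the target and background amplitude histograms:
#' `1 - sum_k min(ht(x_k), hb(x_k))`, where `ht` and `hb` are
#' probability-mass histograms over `n_bins` shared equal-width bins
#' spanning `[0, 1]` (amplitude 1.0 falls in the last bin). Bounded in
#' `[0, 1]`: 0 for identical distributions, 1 for disjoint support.
#'
#' @inheritParams contrast_db
#' @param n_bins Number of histogram bins (default 256, >= 2).
#' @param range Support of the shared bins; default `c(0, 1)`, the natural
#'   support of envelope images normalized to their brightest pixel.
#' @return gCNR in `[0, 1]`.
#' @examples
#' gcnr(rep(0.8, 5), rep(0.2, 5))  # disjoint support -> 1
#' @export
gcnr <- function(target, background, n_bins = 256L, range = c(0, 1)) {
  check_samples(target, "target"); check_samples(background, "background")
  stopifnot(n_bins >= 2, length(range) == 2, range[1] < range[2])
  if (any(c(target, background) < range[1]) ||
      any(c(target, background) > range[2])) {
    stop("samples fall outside the histogram range")
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  bin <- function(x) {
    idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(idx, nbins = n_bins) / length(x)
  }
  1 - sum(pmin(bin(target), bin(background)))
}

#' Extract ROI samples from an envelope image
#'
#' @param envelope Numeric matrix (normalized envelope).
#' @param r A `pa_roi` fully inside the image.
#' @return Numeric vector of the ROI's pixel amplitudes.
#' @export
roi_samples <- function(envelope, r) {
  stopifnot(inherits(r, "pa_roi"))
  if (!roi_in_bounds(r, dim(envelope))) stop("ROI extends outside the image")
  as.vector(envelope[roi_rows(r), roi_cols(r)])
}

#' Contrast, SNR, and gCNR for one frame
#'
#' Extracts normalized-envelope samples from the target and background ROIs
#' of a beamformed image and computes all three image-quality metrics.
#'
#' @param image A `pa_image` from [beamform_frame()].
#' @param target_roi,background_roi `pa_roi` objects inside the image.
#' @param n_bins Histogram bins for [gcnr()].
#' @return One-row tibble: `frame_id`, `time_point_min`, `contrast_db`,
#'   `snr`, `gcnr`, and the ROI corner coordinates.
#' @export
compute_frame_metrics <- function(image, target_roi, background_roi,
                                  n_bins = 256L) {
  stopifnot(inherits(image, "pa_image"))
  tgt <- tryCatch(roi_samples(image$envelope, target_roi),
                  error = function(e) stop("frame ", image$frame_id, ": ",
                                           conditionMessage(e)))
  bg <- tryCatch(roi_samples(image$envelope, background_roi),
                 error = function(e) stop("frame ", image$frame_id, ": ",
                                          conditionMessage(e)))
  tibble::tibble(
    frame_id = image$frame_id,
    time_point_min = image$time_point_min,
    contrast_db = contrast_db(tgt, bg),
    snr = snr(tgt, bg),
    gcnr = gcnr(tgt, bg, n_bins = n_bins),
    target_row0 = target_roi$row0, target_col0 = target_roi$col0,
    background_row0 = background_roi$row0,
    background_col0 = background_roi$col0,
    roi_height_px = target_roi$height, roi_width_px = target_roi$width)
}
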