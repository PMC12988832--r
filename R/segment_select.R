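# Segmentation-driven frame retention: keep frames whose photoacoustic
# signal overlaps the segmented ureter lumen; drop stationary duplicates.

#' Mask-pair container
#'
#' Pairs a ureter-lumen mask (from B-mode segmentation) with a photoacoustic
#' signal mask on a common pixel grid.
#'
#' @param ureter_mask,signal_mask Logical (or 0/1) matrices of equal
#'   dimensions.
#' @param grid Optional [image_grid()] carried for downstream geometry.
#' @param frame_id Frame identifier.
#' @return A `pa_masks` object.
#' @export
mask_pair <- function(ureter_mask, signal_mask, grid = NULL,
                      frame_id = "frame-1") {
  ureter_mask <- as_binary_mask(ureter_mask)
  signal_mask <- as_binary_mask(signal_mask)
  if (!identical(dim(ureter_mask), dim(signal_mask))) {
    stop("ureter and signal masks must share dimensions")
  }
  structure(list(ureter_mask = ureter_mask, signal_mask = signal_mask,
                 grid = grid, frame_id = frame_id),
            class = "pa_masks")
}

as_binary_mask <- function(m) {
  stopifnot(is.matrix(m))
  if (is.logical(m)) return(m)
  if (!all(m %in% c(0, 1))) stop("mask must be strictly binary")
  m == 1
}

#' Frame retention test
#'
#' A frame is retained when its segmented photoacoustic signal spatially
#' overlaps the segmented ureter region: the pixelwise intersection of the
#' two masks is non-empty (at least `min_overlap` pixels).
#'
#' @param masks A `pa_masks` pair.
#' @param min_overlap Minimum shared pixel count; default 1.
#' @return One-row tibble: `frame_id`, `retained` (logical), `overlap_px`.
#' @examples
#' m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
#' retain_frame(mask_pair(m, m))
#' @export
retain_frame <- function(masks, min_overlap = 1L) {
  stopifnot(inherits(masks, "pa_masks"), min_overlap >= 1)
  if (!identical(dim(masks$ureter_mask), dim(masks$signal_mask))) {
    stop("mask dimensions differ")
  }
  ov <- sum(masks$ureter_mask & masks$signal_mask)
  tibble::tibble(frame_id = masks$frame_id,
                 retained = ov >= min_overlap,
                 overlap_px = as.integer(ov))
}

#' Flag stationary signal duplicates in a frame sequence
#'
#' A frame is a stationary duplicate when its signal mask is near-identical
#' to the previous retained (non-duplicate) frame's signal mask
#' (intersection-over-union above `iou_threshold`) and the envelope images
#' agree inside the mask union (Pearson correlation above `cor_threshold`).
#' Flagged frames are excluded from analysis sets. Frames listed in
#' `manual_exclude` are flagged unconditionally.
#'
#' @param masks_list List of `pa_masks`, in acquisition order (>= 1 frame;
#'   flagging needs >= 2).
#' @param envelopes List of envelope matrices matching `masks_list`.
#' @param iou_threshold Mask IoU above which frames are candidate
#'   duplicates; default 0.95.
#' @param cor_threshold Envelope correlation (inside the mask union) above
#'   which a candidate is confirmed; default 0.99.
#' @param manual_exclude Character vector of frame_ids to exclude by hand.
#' @return Tibble: `frame_id`, `duplicate` (logical), `iou`, `envelope_cor`
#'   (comparison against the previous kept frame; NA for the first frame).
#' @export
flag_stationary_duplicates <- function(masks_list, envelopes,
                                       iou_threshold = 0.95,
                                       cor_threshold = 0.99,
                                       manual_exclude = character()) {
  stopifnot(length(masks_list) == length(envelopes),
            length(masks_list) >= 1)
  dims <- lapply(masks_list, function(m) dim(m$signal_mask))
  if (length(unique(dims)) != 1) stop("frames must share a common grid")

  n <- length(masks_list)
  out <- tibble::tibble(
    frame_id = vapply(masks_list, `[[`, character(1), "frame_id"),
    duplicate = FALSE, iou = NA_real_, envelope_cor = NA_real_)
  ref <- NULL  # last kept frame
  for (i in seq_len(n)) {
    if (out$frame_id[i] %in% manual_exclude) {
      out$duplicate[i] <- TRUE
      next
    }
    cur_mask <- masks_list[[i]]$signal_mask
    if (!is.null(ref)) {
      un <- cur_mask | ref$mask
      iou <- if (sum(un) == 0) 0 else sum(cur_mask & ref$mask) / sum(un)
      out$iou[i] <- iou
      if (sum(un) >= 2) {
        a <- envelopes[[i]][un]; b <- ref$env[un]
        cc <- if (sd(a) == 0 || sd(b) == 0) {
          as.numeric(isTRUE(all.equal(a, b)))
        } else stats::cor(a, b)
        out$envelope_cor[i] <- cc
        if (iou > iou_threshold && cc > cor_threshold) {
          out$duplicate[i] <- TRUE
          next
        }
      }
    }
    ref <- list(mask = cur_mask, env = envelopes[[i]])
  }
  out
}
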