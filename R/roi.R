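# Constrained target-ROI placement: center a fixed-size rectangle on the
# brightest in-search-region pixel, then walk it by one-pixel directional
# offsets until it is entirely contained in the ureter mask; place the
# matched background ROI at the same depth near the right image edge.

#' Rectangular region of interest
#'
#' @param row0,col0 Top-left pixel (1-based).
#' @param height,width Extent in pixels (axial, lateral).
#' @param role `"target"` or `"background"`.
#' @return A `pa_roi` object.
#' @export
roi <- function(row0, col0, height, width, role = "target") {
  stopifnot(height >= 1, width >= 1)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width),
                 role = role),
            class = "pa_roi")
}

#' @export
print.pa_roi <- function(x, ...) {
  cat("<pa_roi> ", x$role, ": rows ", x$row0, "..", x$row0 + x$height - 1,
      ", cols ", x$col0, "..", x$col0 + x$width - 1, "\n", sep = "")
  invisible(x)
}

roi_rows <- function(r) r$row0:(r$row0 + r$height - 1)
roi_cols <- function(r) r$col0:(r$col0 + r$width - 1)

#' Convert a physical ROI size to pixels
#'
#' Default ROI is 3 mm (lateral) x 0.6 mm (axial), converted to whole pixels
#' by rounding on the supplied grid.
#'
#' @param grid An [image_grid()].
#' @param lateral_mm,axial_mm Physical ROI extent.
#' @return List with `height` (axial px) and `width` (lateral px).
#' @examples
#' roi_size_px(image_grid(acquisition_params()))
#' @export
roi_size_px <- function(grid, lateral_mm = 3, axial_mm = 0.6) {
  stopifnot(inherits(grid, "pa_grid"), lateral_mm > 0, axial_mm > 0)
  list(height = max(1L, as.integer(round(axial_mm / grid$dz))),
       width = max(1L, as.integer(round(lateral_mm / grid$dx))))
}

#' Brightest pixel within a search region
#'
#' Argmax of the envelope restricted to the mask, with ties broken by the
#' smallest row, then the smallest column.
#'
#' @param envelope Numeric matrix (normalized envelope image).
#' @param search_mask Logical matrix of the same dimensions, non-empty.
#' @return Integer vector `c(row, col)` (1-based).
#' @export
find_brightest_pixel <- function(envelope, search_mask) {
  search_mask <- as_binary_mask(search_mask)
  stopifnot(identical(dim(envelope), dim(search_mask)))
  if (!any(search_mask)) stop("no valid search region: search mask is empty")
  v <- envelope
  v[!search_mask] <- -Inf
  best <- max(v)
  hits <- which(v == best, arr.ind = TRUE)
  # column-major which() already orders by column; re-order row-first
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  c(row = unname(hits[1, 1]), col = unname(hits[1, 2]))
}

# top-left corner of an ROI centered on a pixel; for even extents the extra
# pixel goes toward the larger index
roi_center_origin <- function(pixel, height, width) {
  c(row0 = pixel[1] - floor((height - 1) / 2),
    col0 = pixel[2] - floor((width - 1) / 2))
}

roi_in_bounds <- function(r, dims) {
  r$row0 >= 1 && r$col0 >= 1 &&
    r$row0 + r$height - 1 <= dims[1] && r$col0 + r$width - 1 <= dims[2]
}

roi_contains <- function(r, pixel) {
  pixel[1] >= r$row0 && pixel[1] <= r$row0 + r$height - 1 &&
    pixel[2] >= r$col0 && pixel[2] <= r$col0 + r$width - 1
}

roi_mask_count <- function(r, mask) sum(mask[roi_rows(r), roi_cols(r)])

roi_fully_inside <- function(r, mask) {
  roi_mask_count(r, mask) == r$height * r$width
}

# any fully-contained position whose ROI still holds the bright pixel?
# (cumulative-sum integral image; exhaustive over all candidate origins)
feasible_positions_exist <- function(mask, pixel, height, width) {
  dims <- dim(mask)
  if (dims[1] < height || dims[2] < width) return(FALSE)
  cs <- apply(apply(mask, 2, cumsum), 1, cumsum)  # cs[j, i] = sum mask[1:i, 1:j]
  rect_sum <- function(r0, c0) {
    r1 <- r0 + height - 1; c1 <- c0 + width - 1
    cs[c1, r1] -
      (if (r0 > 1) cs[c1, r0 - 1] else 0) -
      (if (c0 > 1) cs[c0 - 1, r1] else 0) +
      (if (r0 > 1 && c0 > 1) cs[c0 - 1, r0 - 1] else 0)
  }
  r0s <- max(1, pixel[1] - height + 1):min(pixel[1], dims[1] - height + 1)
  c0s <- max(1, pixel[2] - width + 1):min(pixel[2], dims[2] - width + 1)
  if (length(r0s) < 1 || length(c0s) < 1 || any(r0s < 1) || any(c0s < 1)) {
    return(FALSE)
  }
  for (r0 in r0s) for (c0 in c0s) {
    if (rect_sum(r0, c0) == height * width) return(TRUE)
  }
  FALSE
}

#' Place the target ROI by constrained greedy search
#'
#' Starts with the ROI centered on the brightest photoacoustic pixel. While
#' the ROI is not entirely contained in the ureter mask, the eight one-pixel
#' offsets of the current position are evaluated in a fixed order -- left,
#' right (lateral); proximal (shallower), distal (deeper) (axial);
#' left-proximal, left-distal, right-proximal, right-distal (diagonal).
#' A candidate is admissible when (1) the ROI stays within the image
#' dimensions, (2) the brightest pixel remains inside the ROI, and (3) ROI
#' pixels intersect the ureter mask; the walk moves to the first admissible
#' candidate that strictly increases the count of ROI pixels inside the
#' mask, and stops at the first position entirely contained in the mask
#' (minimal displacement by first-found order).
#'
#' @param envelope Normalized envelope image (used only for bounds).
#' @param ureter_mask Logical matrix, same dimensions.
#' @param brightest Pixel `c(row, col)` from [find_brightest_pixel()]; must
#'   lie inside the ureter mask.
#' @param size List `height`/`width` in pixels, see [roi_size_px()].
#' @return A `pa_roi` with role `"target"` plus attribute `displacement_px`
#'   (Chebyshev displacement from the initial centered position). Errors
#'   with "no valid ROI" when no fully contained position holding the
#'   brightest pixel exists (verified exhaustively) or the walk stalls.
#' @export
place_target_roi <- function(envelope, ureter_mask, brightest, size) {
  ureter_mask <- as_binary_mask(ureter_mask)
  stopifnot(identical(dim(envelope), dim(ureter_mask)),
            length(brightest) == 2)
  if (!ureter_mask[brightest[1], brightest[2]]) {
    stop("brightest pixel lies outside the ureter mask")
  }
  dims <- dim(ureter_mask)
  h <- size$height; w <- size$width
  if (!feasible_positions_exist(ureter_mask, brightest, h, w)) {
    stop("no valid ROI: no fully contained position holds the brightest pixel")
  }
  org <- roi_center_origin(brightest, h, w)
  cur <- roi(org[1], org[2], h, w)
  # centered start may poke outside the image; clamp into bounds first
  cur$row0 <- min(max(cur$row0, 1L), dims[1] - h + 1L)
  cur$col0 <- min(max(cur$col0, 1L), dims[2] - w + 1L)
  start <- cur
  # offsets (drow, dcol): left, right, proximal, distal, then diagonals
  offsets <- rbind(c(0, -1), c(0, 1), c(-1, 0), c(1, 0),
                   c(-1, -1), c(1, -1), c(-1, 1), c(1, 1))
  max_iter <- prod(dims)
  iter <- 0L
  while (!roi_fully_inside(cur, ureter_mask)) {
    iter <- iter + 1L
    if (iter > max_iter) stop("no valid ROI: search did not terminate")
    cur_count <- roi_mask_count(cur, ureter_mask)
    moved <- FALSE
    for (k in seq_len(nrow(offsets))) {
      cand <- cur
      cand$row0 <- cur$row0 + offsets[k, 1]
      cand$col0 <- cur$col0 + offsets[k, 2]
      if (!roi_in_bounds(cand, dims)) next
      if (!roi_contains(cand, brightest)) next
      cnt <- roi_mask_count(cand, ureter_mask)
      if (cnt == 0) next
      if (cnt > cur_count) {
        cur <- cand
        moved <- TRUE
        break
      }
    }
    if (!moved) stop("no valid ROI: greedy walk stalled")
  }
  cur$role <- "target"
  attr(cur, "displacement_px") <- max(abs(cur$row0 - start$row0),
                                      abs(cur$col0 - start$col0))
  cur
}

#' Place the matched background ROI
#'
#' Background ROI of identical size at the same image depth (same rows) as
#' the target, with its right edge a fixed lateral distance (default
#' 0.54 mm) from the right edge of the image.
#'
#' @param target A `pa_roi` from [place_target_roi()].
#' @param dims Image dimensions `c(rows, cols)`.
#' @param grid [image_grid()] supplying the lateral pixel size.
#' @param margin_mm Lateral distance from the image's right edge; default
#'   0.54 mm (6 pixels at 0.09 mm pitch).
#' @return A `pa_roi` with role `"background"`.
#' @export
place_background_roi <- function(target, dims, grid, margin_mm = 0.54) {
  stopifnot(inherits(target, "pa_roi"), length(dims) == 2,
            inherits(grid, "pa_grid"))
  margin_px <- as.integer(round(margin_mm / grid$dx))
  col0 <- dims[2] - margin_px - target$width + 1L
  if (col0 < 1) stop("image too narrow for background ROI plus margin")
  bg <- roi(target$row0, col0, target$height, target$width,
            role = "background")
  if (bg$col0 <= target$col0 + target$width - 1 &&
      target$col0 <= bg$col0 + bg$width - 1) {
    warning("background ROI overlaps the target ROI")
  }
  bg
}

#' Summarize ROIs as a tibble
#'
#' @param rois List of `pa_roi` objects.
#' @param frame_id Frame identifier to tag rows with.
#' @return Tibble: `frame_id`, `roi_role`, `row0`, `col0`, `height_px`,
#'   `width_px`, `displacement_px`.
#' @export
roi_report <- function(rois, frame_id = "frame-1") {
  purrr::map_dfr(rois, function(r) {
    tibble::tibble(frame_id = frame_id, roi_role = r$role,
                   row0 = r$row0, col0 = r$col0,
                   height_px = r$height, width_px = r$width,
                   displacement_px = attr(r, "displacement_px") %||% NA_integer_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
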