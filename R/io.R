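# Plain-format I/O: channel frames as TSV matrices with a JSON metadata
# sidecar, masks as single-channel PNG (0 = background, 255 = mask),
# beamformed images as 32-bit float TIFF with a JSON grid sidecar.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read a channel-data frame
#'
#' The RF matrix is stored as a headerless TSV (one row per sample, one
#' column per element); acquisition parameters, the time-point label, and
#' the frame id go into a JSON sidecar of the same basename.
#'
#' @param frame A `pa_frame`.
#' @param path Output path (`.tsv`).
#' @return `path`, invisibly (`write`); a `pa_frame` (`read`).
#' @export
write_channel_frame <- function(frame, path) {
  stopifnot(inherits(frame, "pa_frame"))
  utils::write.table(frame$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  p <- frame$params
  meta <- list(
    params = list(n_elements = p$n_elements, pitch = p$pitch,
                  aperture_width = p$aperture_width,
                  center_frequency = p$center_frequency,
                  sampling_frequency = p$sampling_frequency,
                  speed_of_sound = p$speed_of_sound,
                  bandwidth = p$bandwidth, n_samples = p$n_samples),
    time_point_min = frame$time_point_min, frame_id = frame$frame_id)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_channel_frame
#' @export
read_channel_frame <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  p <- meta$params
  params <- acquisition_params(
    n_elements = p$n_elements, pitch = p$pitch,
    center_frequency = p$center_frequency,
    sampling_frequency = p$sampling_frequency,
    speed_of_sound = p$speed_of_sound, bandwidth = p$bandwidth,
    n_samples = p$n_samples, aperture_width = p$aperture_width)
  data <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(data) <- NULL
  if (ncol(data) != params$n_elements) {
    stop("channel data columns do not match the declared element count")
  }
  structure(list(data = data, params = params,
                 time_point_min = meta$time_point_min,
                 frame_id = meta$frame_id),
            class = "pa_frame")
}

#' Write / read a binary mask as PNG
#'
#' Single-channel 8-bit PNG, 0 = background, 255 = mask.
#'
#' @param mask Logical matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly (`write`); a logical matrix (`read`).
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' Write a beamformed image
#'
#' The normalized envelope (values in `[0, 1]`) is stored as a 32-bit float
#' TIFF; grid metadata, dynamic range, and labels go into a JSON sidecar.
#'
#' @param image A `pa_image`.
#' @param path Output `.tiff` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "pa_image"))
  tiff::writeTIFF(image$envelope, path, bits.per.sample = 32)
  meta <- list(frame_id = image$frame_id,
               time_point_min = image$time_point_min,
               dynamic_range = image$dynamic_range,
               grid = list(x = image$grid$x, z = image$grid$z,
                           dx = image$grid$dx, dz = image$grid$dz))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
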