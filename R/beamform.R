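# Delay-and-sum image formation: back-project channel samples along one-way
# geometric delays, sum across the aperture, envelope-detect along depth,
# normalize to the brightest pixel, and log-compress for display.

#' Delay-and-sum beamforming
#'
#' Reconstructs the RF image on the pixel grid. Pixel (x, z) is the sum over
#' elements e of the channel sample at the one-way delay
#' `sqrt(z^2 + (x - x_e)^2) / c` (a photoacoustic source emits at t = 0, so
#' no transmit delay applies). Samples are linearly interpolated; delays
#' outside the recorded window contribute zero; uniform (rectangular)
#' apodization over the full aperture.
#'
#' @param frame A `pa_frame` (see [simulate_channel_data()]).
#' @param grid An [image_grid()] derived from `frame$params`.
#' @return Numeric matrix (axial rows x lateral columns) of summed delayed
#'   samples.
#' @export
das_beamform <- function(frame, grid = image_grid(frame$params)) {
  stopifnot(inherits(frame, "pa_frame"), inherits(grid, "pa_grid"))
  p <- frame$params
  if (ncol(frame$data) != p$n_elements) {
    stop("channel data has ", ncol(frame$data), " columns but params declare ",
         p$n_elements, " elements")
  }
  if (any(!is.finite(frame$data))) stop("channel data contains non-finite samples")
  das_core(frame$data, element_positions(p), grid$x, grid$z,
           p$sampling_frequency, p$speed_of_sound)
}

# analytic signal of a real vector via the frequency-domain construction:
# zero the negative frequencies, double the positive ones
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Envelope detection
#'
#' Amplitude envelope of a beamformed RF image: per lateral line, the
#' magnitude of the analytic signal along the axial (depth) dimension.
#'
#' @param rf Numeric matrix of beamformed RF samples (axial rows x lateral
#'   columns), all finite.
#' @return Non-negative numeric matrix of the same dimensions.
#' @export
envelope_detect <- function(rf) {
  stopifnot(is.matrix(rf), all(is.finite(rf)))
  apply(rf, 2, function(col) Mod(analytic_signal(col)))
}

#' Normalize and log-compress an envelope image
#'
#' Divides the envelope by its brightest pixel and maps to decibels
#' (`20 * log10`), clipping below `-dynamic_range`.
#'
#' @param envelope Non-negative numeric matrix with a positive maximum.
#' @param dynamic_range Display dynamic range in dB (> 0).
#' @return List with `envelope` (normalized, max = 1) and `bmode_db`
#'   (values in `[-dynamic_range, 0]`).
#' @examples
#' normalize_log_compress(matrix(c(1, 0.1), 1), 30)$bmode_db
#' @export
normalize_log_compress <- function(envelope, dynamic_range = 30) {
  stopifnot(is.matrix(envelope) || is.numeric(envelope),
            all(envelope >= 0), dynamic_range > 0)
  m <- max(envelope)
  if (m == 0) stop("empty frame: envelope is identically zero")
  env <- envelope / m
  db <- 20 * log10(pmax(env, 10^(-dynamic_range / 20)))
  list(envelope = env, bmode_db = db)
}

# optional brick-wall FFT bandpass applied per channel line
bandpass_channels <- function(data, fs, band) {
  n <- nrow(data)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  keep <- f >= band[1] & f <= band[2]
  apply(data, 2, function(col) Re(fft(fft(col) * keep, inverse = TRUE) / n))
}

#' Beamform a channel-data frame into a B-mode image record
#'
#' Full image-formation chain: (optional) bandpass of the raw channels,
#' delay-and-sum, axial envelope detection, normalization to the brightest
#' pixel, and log compression at the requested dynamic range.
#'
#' @param frame A `pa_frame`.
#' @param dynamic_range Display dynamic range in dB.
#' @param grid Pixel grid; defaults to the acquisition-native grid.
#' @param bandpass `NULL` (default, off) or length-2 Hz band applied to the
#'   channel data before beamforming.
#' @return An object of class `pa_image`: list with `rf`, `envelope` (max 1),
#'   `bmode_db`, `grid`, `dynamic_range`, `time_point_min`, `frame_id`.
#' @examples
#' sc <- make_phantom(absorbers = data.frame(x = 0, z = 10, amplitude = 1))
#' img <- beamform_frame(simulate_channel_data(sc))
#' max(img$envelope)
#' @export
beamform_frame <- function(frame, dynamic_range = 30,
                           grid = image_grid(frame$params),
                           bandpass = NULL) {
  if (!is.null(bandpass)) {
    stopifnot(length(bandpass) == 2, bandpass[1] < bandpass[2])
    frame$data <- bandpass_channels(frame$data,
                                    frame$params$sampling_frequency, bandpass)
  }
  rf <- das_beamform(frame, grid)
  env <- envelope_detect(rf)
  nl <- normalize_log_compress(env, dynamic_range)
  structure(list(rf = rf, envelope = nl$envelope, bmode_db = nl$bmode_db,
                 grid = grid, dynamic_range = dynamic_range,
                 time_point_min = frame$time_point_min,
                 frame_id = frame$frame_id),
            class = "pa_image")
}

#' @export
print.pa_image <- function(x, ...) {
  cat("<pa_image> ", x$frame_id, ": ", nrow(x$envelope), " x ",
      ncol(x$envelope), " px, dynamic range ", x$dynamic_range, " dB\n",
      sep = "")
  invisible(x)
}

#' Plot a log-compressed photoacoustic image
#'
#' @param object A `pa_image`.
#' @param ... Unused.
#' @return A ggplot raster of `bmode_db` on the physical (mm) grid.
#' @export
autoplot.pa_image <- function(object, ...) {
  df <- tidyr::expand_grid(z = object$grid$z, x = object$grid$x)
  df$db <- as.vector(t(object$bmode_db))  # row-major expand_grid order
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$z, fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(-object$dynamic_range, 0),
                                 name = "dB") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Lateral (mm)", y = "Depth (mm)",
                  title = object$frame_id)
}
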