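#' Linear-array acquisition parameters
#'
#' Bundles the transducer and sampling constants that govern beamforming
#' geometry and delays. Defaults are those of a 256-element UHF linear array
#' (15--29 MHz bandwidth, 21.33 MHz center frequency) sampled at 96 MHz with
#' an assumed tissue speed of sound of 1538.5 m/s.
#'
#' The default number of samples per channel line covers a 20 mm one-way
#' imaging depth at the default sampling frequency.
#'
#' @param n_elements Number of receive elements.
#' @param pitch Element center-to-center spacing in mm.
#' @param center_frequency Transducer center frequency in Hz.
#' @param sampling_frequency Channel-data sampling frequency in Hz.
#' @param speed_of_sound Assumed speed of sound in m/s.
#' @param bandwidth Length-2 numeric, lower/upper -6 dB band edges in Hz.
#' @param n_samples Samples per channel line. Default covers 20 mm depth.
#' @param aperture_width Physical aperture in mm. Defaults to
#'   `n_elements * pitch`; must agree with it within 0.5 mm.
#'
#' @return An object of class `pa_params`: a named list of the validated
#'   acquisition constants.
#' @examples
#' p <- acquisition_params()
#' p$n_elements
#' @export
acquisition_params <- function(n_elements = 256L,
                               pitch = 0.09,
                               center_frequency = 21.33e6,
                               sampling_frequency = 96e6,
                               speed_of_sound = 1538.5,
                               bandwidth = c(15e6, 29e6),
                               n_samples = NULL,
                               aperture_width = NULL) {
  n_elements <- as.integer(n_elements)
  stopifnot(n_elements >= 1, pitch > 0, center_frequency > 0,
            sampling_frequency > 0, speed_of_sound > 0,
            length(bandwidth) == 2, bandwidth[1] < bandwidth[2])
  if (is.null(aperture_width)) aperture_width <- n_elements * pitch
  if (abs(n_elements * pitch - aperture_width) > 0.5) {
    stop("aperture_width inconsistent with n_elements * pitch (tolerance 0.5 mm)")
  }
  if (sampling_frequency <= 2 * bandwidth[2]) {
    stop("sampling_frequency must exceed twice the upper bandwidth edge")
  }
  if (is.null(n_samples)) {
    # one-way time of flight to 20 mm depth
    n_samples <- as.integer(ceiling(0.020 / speed_of_sound * sampling_frequency))
  }
  n_samples <- as.integer(n_samples)
  stopifnot(n_samples >= 2)
  structure(
    list(n_elements = n_elements, pitch = pitch,
         aperture_width = aperture_width,
         center_frequency = center_frequency,
         sampling_frequency = sampling_frequency,
         speed_of_sound = speed_of_sound,
         bandwidth = bandwidth, n_samples = n_samples),
    class = "pa_params"
  )
}

#' @export
print.pa_params <- function(x, ...) {
  cat("<pa_params> ", x$n_elements, " elements, pitch ", x$pitch, " mm, ",
      "fc ", x$center_frequency / 1e6, " MHz, fs ",
      x$sampling_frequency / 1e6, " MHz, c ", x$speed_of_sound, " m/s, ",
      x$n_samples, " samples\n", sep = "")
  invisible(x)
}

#' Element center lateral positions
#'
#' Lateral coordinates (mm) of the element centers, symmetric about 0:
#' `x_e = (e - (n_elements - 1) / 2) * pitch` for `e = 0, ..., n_elements - 1`.
#'
#' @param params A [acquisition_params()] object.
#' @return Numeric vector of length `n_elements`.
#' @export
element_positions <- function(params) {
  stopifnot(inherits(params, "pa_params"))
  (seq_len(params$n_elements) - 1 - (params$n_elements - 1) / 2) * params$pitch
}

#' Beamforming pixel grid
#'
#' The natural reconstruction grid for the channel data: one lateral column
#' per element center and axial rows at the one-way sample spacing
#' `z_j = j * c / fs` (j = 0, ..., n_samples - 1).
#'
#' @param params A [acquisition_params()] object.
#' @return An object of class `pa_grid` with fields `x` (lateral mm), `z`
#'   (axial mm), `dx`, `dz` (pixel dimensions mm).
#' @examples
#' g <- image_grid(acquisition_params())
#' g$dz  # axial pixel size in mm
#' @export
image_grid <- function(params) {
  stopifnot(inherits(params, "pa_params"))
  dz <- params$speed_of_sound / params$sampling_frequency * 1000  # mm
  structure(
    list(x = element_positions(params),
         z = (seq_len(params$n_samples) - 1) * dz,
         dx = params$pitch, dz = dz),
    class = "pa_grid"
  )
}

#' @export
print.pa_grid <- function(x, ...) {
  cat("<pa_grid> ", length(x$z), " x ", length(x$x), " px (axial x lateral), ",
      "dx ", signif(x$dx, 4), " mm, dz ", signif(x$dz, 4), " mm\n", sep = "")
  invisible(x)
}
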