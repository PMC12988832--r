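# Synthetic acquisition generator: a tube-shaped absorber (ureter lumen plus
# an adventitia lining) viewed by a linear array, with controllable amplitude
# statistics and additive channel noise. Stands in for in vivo acquisitions
# so every downstream stage is testable.

# evaluate expr under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Build a synthetic imaging phantom
#'
#' Constructs a deterministic scene containing a simulated ureter lumen
#' (an ellipse or rectangle filled with point absorbers), an optional
#' adventitia band of absorbers lining the lumen boundary, and any
#' explicitly supplied absorbers. All positions are in the imaging plane:
#' lateral `x` (mm, 0 at the aperture center) and depth `z` (mm, positive
#' into tissue).
#'
#' @param lumen_center Length-2 numeric `(x, z)` mm, or `NULL` for no lumen.
#' @param lumen_half_widths Length-2 numeric `(hx, hz)` mm half-widths.
#' @param lumen_shape `"ellipse"` or `"rect"`.
#' @param n_lumen Number of absorbers drawn uniformly inside the lumen.
#' @param lumen_amplitude Mean absorber amplitude inside the lumen (a.u.).
#' @param n_adventitia Number of absorbers lining the lumen boundary
#'   (ignored when there is no lumen).
#' @param adventitia_amplitude Mean amplitude of the adventitia absorbers.
#' @param absorbers Optional data frame with columns `x`, `z`, `amplitude`
#'   (and optionally `role`) of extra absorbers placed as given.
#' @param noise_sigma Standard deviation of additive Gaussian channel noise
#'   (a.u.); must be >= 0.
#' @param seed Integer RNG seed; the same configuration and seed always
#'   yield an identical scene.
#' @param params [acquisition_params()] defining the field of view used for
#'   validation: depths must lie in (0, max depth], lateral positions within
#'   the aperture extent plus a 50 percent margin.
#'
#' @return An object of class `pa_scene`: list with `absorbers` (tibble
#'   `x`, `z`, `amplitude`, `role`), `lumen` (NULL or list `center`,
#'   `half_widths`, `shape`), `noise_sigma`, `seed`, `params`.
#' @examples
#' sc <- make_phantom(lumen_center = c(0, 8), lumen_half_widths = c(2, 1),
#'                    n_lumen = 30, seed = 7)
#' nrow(sc$absorbers)
#' @export
make_phantom <- function(lumen_center = NULL,
                         lumen_half_widths = c(2, 1),
                         lumen_shape = c("ellipse", "rect"),
                         n_lumen = 30L,
                         lumen_amplitude = 1,
                         n_adventitia = 0L,
                         adventitia_amplitude = 1,
                         absorbers = NULL,
                         noise_sigma = 0,
                         seed = 1L,
                         params = acquisition_params()) {
  lumen_shape <- match.arg(lumen_shape)
  stopifnot(inherits(params, "pa_params"), noise_sigma >= 0)
  grid <- image_grid(params)
  z_max <- max(grid$z)
  x_lim <- params$aperture_width / 2 * 1.5  # aperture extent +- 50%

  lumen <- NULL
  pts <- list()
  if (!is.null(lumen_center)) {
    stopifnot(length(lumen_center) == 2, length(lumen_half_widths) == 2,
              all(lumen_half_widths > 0))
    lumen <- list(center = as.numeric(lumen_center),
                  half_widths = as.numeric(lumen_half_widths),
                  shape = lumen_shape)
    if (n_lumen > 0) {
      pts$lumen <- with_seed(seed, sample_in_region(lumen, n_lumen,
                                                    lumen_amplitude))
    }
    if (n_adventitia > 0) {
      pts$adventitia <- with_seed(seed + 1L,
        sample_on_boundary(lumen, n_adventitia, adventitia_amplitude))
    }
  }
  if (!is.null(absorbers)) {
    stopifnot(all(c("x", "z", "amplitude") %in% names(absorbers)))
    extra <- tibble::as_tibble(absorbers[, intersect(
      c("x", "z", "amplitude", "role"), names(absorbers))])
    if (!("role" %in% names(extra))) extra$role <- "extra"
    pts$extra <- extra
  }
  ab <- if (length(pts)) dplyr::bind_rows(pts) else
    tibble::tibble(x = numeric(), z = numeric(),
                   amplitude = numeric(), role = character())
  if (nrow(ab)) {
    if (any(ab$z <= 0) || any(ab$z > z_max)) {
      stop("absorber depths must lie in (0, ", signif(z_max, 4), "] mm")
    }
    if (any(abs(ab$x) > x_lim)) {
      stop("absorber lateral positions must lie within +-", signif(x_lim, 4),
           " mm of the aperture center")
    }
  }
  structure(list(absorbers = ab, lumen = lumen, noise_sigma = noise_sigma,
                 seed = as.integer(seed), params = params),
            class = "pa_scene")
}

# uniform points inside the lumen region, amplitudes ~ N(mean, 10% of mean)
sample_in_region <- function(lumen, n, amplitude) {
  c0 <- lumen$center; hw <- lumen$half_widths
  if (lumen$shape == "rect") {
    x <- runif(n, c0[1] - hw[1], c0[1] + hw[1])
    z <- runif(n, c0[2] - hw[2], c0[2] + hw[2])
  } else {
    # uniform in the unit disk, then scaled to the ellipse
    r <- sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    x <- c0[1] + hw[1] * r * cos(th)
    z <- c0[2] + hw[2] * r * sin(th)
  }
  tibble::tibble(x = x, z = z,
                 amplitude = pmax(rnorm(n, amplitude, 0.1 * amplitude), 0),
                 role = "lumen")
}

# points on (slightly outside) the lumen boundary: the adventitia lining
sample_on_boundary <- function(lumen, n, amplitude) {
  c0 <- lumen$center; hw <- lumen$half_widths
  th <- runif(n, 0, 2 * pi)
  scale <- runif(n, 1.02, 1.12)
  if (lumen$shape == "rect") {
    # project disk angles onto the rectangle boundary
    x <- c0[1] + hw[1] * scale * sign(cos(th)) *
      pmin(abs(cos(th)) / pmax(abs(cos(th)), abs(sin(th))), 1)
    z <- c0[2] + hw[2] * scale * sign(sin(th)) *
      pmin(abs(sin(th)) / pmax(abs(cos(th)), abs(sin(th))), 1)
  } else {
    x <- c0[1] + hw[1] * scale * cos(th)
    z <- c0[2] + hw[2] * scale * sin(th)
  }
  tibble::tibble(x = x, z = z,
                 amplitude = pmax(rnorm(n, amplitude, 0.1 * amplitude), 0),
                 role = "adventitia")
}

#' @export
print.pa_scene <- function(x, ...) {
  cat("<pa_scene> ", nrow(x$absorbers), " absorbers",
      if (!is.null(x$lumen)) paste0(", ", x$lumen$shape, " lumen at (",
        x$lumen$center[1], ", ", x$lumen$center[2], ") mm"),
      ", noise_sigma ", x$noise_sigma, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Gaussian envelope sigma such that the -6 dB spectral half-width of the
# pulse matches half the stated bandwidth
pulse_sigma_t <- function(params) {
  df <- diff(params$bandwidth) / 2
  sqrt(log(10^(6 / 20)) / (2 * pi^2)) / df
}

#' Simulate one frame of photoacoustic channel data
#'
#' Forward model: every absorber is an omnidirectional point source emitting
#' at t = 0 a Gaussian-windowed sinusoid at the transducer center frequency
#' whose -6 dB spectral extent matches the stated bandwidth. Element `e`
#' records the 1/r-weighted, time-of-flight-delayed sum over absorbers
#' (one-way, receive-only propagation; amplitude clamp at r_min = 1 mm),
#' plus zero-mean Gaussian noise of scale `noise_sigma`. Single scattering,
#' no attenuation, no element directivity: the simplest model for which
#' delay-and-sum beamforming is a consistent inverse.
#'
#' @param scene A [make_phantom()] scene.
#' @param params [acquisition_params()]; defaults to the scene's.
#' @param time_point_min Time-point label (minutes post-injection).
#' @param frame_id Frame identifier string.
#' @return An object of class `pa_frame`: list with `data` (n_samples x
#'   n_elements numeric matrix), `params`, `time_point_min`, `frame_id`.
#' @examples
#' sc <- make_phantom(absorbers = data.frame(x = 0, z = 10, amplitude = 1),
#'                    lumen_center = NULL, seed = 1)
#' fr <- simulate_channel_data(sc)
#' dim(fr$data)
#' @export
simulate_channel_data <- function(scene, params = scene$params,
                                  time_point_min = NA_real_,
                                  frame_id = "frame-1") {
  stopifnot(inherits(scene, "pa_scene"), inherits(params, "pa_params"))
  ab <- scene$absorbers
  ex <- element_positions(params)
  fs <- params$sampling_frequency
  c_ms <- params$speed_of_sound
  if (nrow(ab)) {
    r_max <- max(sqrt(outer(ab$z^2, rep(1, length(ex))) +
                        outer(ab$x, ex, `-`)^2))
    tof_max <- r_max / (c_ms * 1000)
    if (tof_max * fs > params$n_samples - 1) {
      stop("time of flight of the deepest absorber (", signif(tof_max * 1e6, 4),
           " us) exceeds the sampled window")
    }
    data <- channel_forward(ab$amplitude, ab$x, ab$z, ex,
                            params$n_samples, fs, c_ms,
                            params$center_frequency, pulse_sigma_t(params),
                            r_min = 1.0)
  } else {
    data <- matrix(0, params$n_samples, params$n_elements)
  }
  if (scene$noise_sigma > 0) {
    data <- data + with_seed(scene$seed + 7L,
      matrix(rnorm(length(data), 0, scene$noise_sigma), nrow(data)))
  }
  structure(list(data = data, params = params,
                 time_point_min = time_point_min, frame_id = frame_id),
            class = "pa_frame")
}

#' @export
print.pa_frame <- function(x, ...) {
  cat("<pa_frame> ", x$frame_id, ": ", nrow(x$data), " samples x ",
      ncol(x$data), " elements, t = ", x$time_point_min, " min\n", sep = "")
  invisible(x)
}

#' Ground-truth masks for a synthetic scene
#'
#' Rasterizes the scene onto the beamforming grid: the ureter (lumen) mask is
#' the filled lumen region; the photoacoustic signal mask is the footprint of
#' all absorber positions dilated by one resolution cell (one wavelength,
#' `c / f0`, at least one pixel in each dimension). These play the role of
#' the manual B-mode and photoacoustic segmentations of a real study.
#'
#' @param scene A [make_phantom()] scene.
#' @param grid An [image_grid()]; defaults to the scene's acquisition grid.
#' @param frame_id Frame identifier carried on the mask pair.
#' @param dilate_mm Dilation radius in mm; default one wavelength.
#' @return An object of class `pa_masks`: list with logical matrices
#'   `ureter_mask`, `signal_mask` (rows = axial, cols = lateral), `grid`,
#'   `frame_id`.
#' @export
make_truth_masks <- function(scene, grid = image_grid(scene$params),
                             frame_id = "frame-1", dilate_mm = NULL) {
  stopifnot(inherits(scene, "pa_scene"), inherits(grid, "pa_grid"))
  if (is.null(dilate_mm)) {
    dilate_mm <- scene$params$speed_of_sound /
      scene$params$center_frequency * 1000
  }
  nz <- length(grid$z); nx <- length(grid$x)
  ureter <- matrix(FALSE, nz, nx)
  if (!is.null(scene$lumen)) {
    lz <- scene$lumen; c0 <- lz$center; hw <- lz$half_widths
    X <- matrix(grid$x, nz, nx, byrow = TRUE)
    Z <- matrix(grid$z, nz, nx)
    ureter <- if (lz$shape == "rect") {
      abs(X - c0[1]) <= hw[1] & abs(Z - c0[2]) <= hw[2]
    } else {
      ((X - c0[1]) / hw[1])^2 + ((Z - c0[2]) / hw[2])^2 <= 1
    }
  }
  signal <- matrix(FALSE, nz, nx)
  ab <- scene$absorbers
  if (nrow(ab)) {
    rx <- max(1L, ceiling(dilate_mm / grid$dx))
    rz <- max(1L, ceiling(dilate_mm / grid$dz))
    for (k in seq_len(nrow(ab))) {
      ic <- which.min(abs(grid$x - ab$x[k]))
      ir <- which.min(abs(grid$z - ab$z[k]))
      rows <- max(1, ir - rz):min(nz, ir + rz)
      cols <- max(1, ic - rx):min(nx, ic + rx)
      # elliptical structuring element
      el <- outer((rows - ir) / rz, (cols - ic) / rx,
                  function(a, b) a^2 + b^2 <= 1)
      signal[rows, cols] <- signal[rows, cols] | el
    }
  }
  structure(list(ureter_mask = ureter, signal_mask = signal,
                 grid = grid, frame_id = frame_id),
            class = "pa_masks")
}

#' @export
print.pa_masks <- function(x, ...) {
  cat("<pa_masks> ", x$frame_id, ": ", nrow(x$ureter_mask), " x ",
      ncol(x$ureter_mask), " px; ureter ", sum(x$ureter_mask),
      " px, signal ", sum(x$signal_mask), " px\n", sep = "")
  invisible(x)
}

#' Default per-time-point sampling specification
#'
#' Group specification emulating the per-time-point image-quality samples of
#' a post-injection monitoring study: six time points (10, 20, 30, 60, 70,
#' 80 min) with 28, 43, 39, 64, 48, and 65 retained frames and metric
#' medians peaking 20--30 min after injection.
#'
#' @param metric One of `"contrast_db"`, `"snr"`, `"gcnr"`; sets defaults
#'   for the location/scale columns.
#' @return A tibble with columns `time_point_min`, `n`, `family`,
#'   `location` (the distribution median), `scale`.
#' @export
default_group_spec <- function(metric = c("contrast_db", "snr", "gcnr")) {
  metric <- match.arg(metric)
  loc <- switch(metric,
    contrast_db = c(3.46, 11.43, 9.0, 5.0, 3.5, 6.0),
    snr = c(2.84, 6.99, 6.0, 4.0, 2.9, 4.5),
    gcnr = c(0.27, 0.64, 0.58, 0.42, 0.28, 0.50))
  scl <- switch(metric, contrast_db = 2.0, snr = 1.2, gcnr = 0.08)
  tibble::tibble(
    time_point_min = c(10, 20, 30, 60, 70, 80),
    n = c(28L, 43L, 39L, 64L, 48L, 65L),
    family = "normal",
    location = loc,
    scale = scl)
}

#' Draw grouped metric samples from a specification
#'
#' Generates reproducible per-group samples for testing the group-comparison
#' stage without running the imaging chain. `location` is the distribution
#' median: the mean for `"normal"`, `exp(meanlog)` for `"lognormal"`.
#'
#' @param spec Data frame with columns `time_point_min`, `n`, `family`
#'   (`"normal"` or `"lognormal"`), `location`, `scale`; see
#'   [default_group_spec()]. Requires `n >= 3` and `scale >= 0` per group.
#' @param seed Integer seed; same spec and seed give identical samples.
#' @return A tibble with columns `time_point_min`, `value`.
#' @examples
#' head(sample_metric_groups(default_group_spec("gcnr"), seed = 1))
#' @export
sample_metric_groups <- function(spec, seed = 1L) {
  stopifnot(is.data.frame(spec),
            all(c("time_point_min", "n", "family", "location", "scale")
                %in% names(spec)))
  if (any(spec$n < 3)) stop("each group needs n >= 3")
  if (any(spec$scale < 0)) stop("scale must be >= 0")
  if (!all(spec$family %in% c("normal", "lognormal"))) {
    stop("family must be 'normal' or 'lognormal'")
  }
  with_seed(seed, {
    purrr::pmap_dfr(spec, function(time_point_min, n, family, location,
                                   scale, ...) {
      value <- switch(family,
        normal = rnorm(n, location, scale),
        lognormal = stats::rlnorm(n, log(location), scale))
      tibble::tibble(time_point_min = time_point_min, value = value)
    })
  })
}
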