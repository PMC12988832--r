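# Delay-and-sum image formation: the compiled path against a brute-force
# oracle, localization of point targets, envelope detection, and
# normalization / log compression.

test_that("DAS matches a brute-force per-pixel loop on toy instances", {
  set.seed(101)
  for (rep in 1:3) {
    p <- acquisition_params(n_elements = 8L, n_samples = 64L)
    g <- image_grid(p)
    data <- matrix(rnorm(p$n_samples * p$n_elements), p$n_samples)
    fr <- structure(list(data = data, params = p, time_point_min = NA,
                         frame_id = "toy"), class = "pa_frame")
    fast <- das_beamform(fr, g)
    slow <- das_brute(data, element_positions(p), g$x, g$z,
                      p$sampling_frequency, p$speed_of_sound)
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("DAS is linear and maps zero to zero", {
  p <- tiny_params()
  g <- image_grid(p)
  zero <- structure(list(data = matrix(0, p$n_samples, p$n_elements),
                         params = p, time_point_min = NA, frame_id = "z"),
                    class = "pa_frame")
  expect_true(all(das_beamform(zero, g) == 0))

  sc <- make_phantom(absorbers = data.frame(x = 0.2, z = 4, amplitude = 1),
                     seed = 2, params = p)
  fr <- simulate_channel_data(sc, p)
  rf1 <- das_beamform(fr, g)
  fr$data <- 3.5 * fr$data
  expect_equal(das_beamform(fr, g), 3.5 * rf1, tolerance = 1e-12)
})

test_that("DAS rejects malformed frames", {
  p <- tiny_params()
  g <- image_grid(p)
  bad <- structure(list(data = matrix(0, p$n_samples, p$n_elements - 1),
                        params = p, time_point_min = NA, frame_id = "b"),
                   class = "pa_frame")
  expect_error(das_beamform(bad, g), "columns")
  nf <- structure(list(data = matrix(NaN, p$n_samples, p$n_elements),
                       params = p, time_point_min = NA, frame_id = "n"),
                  class = "pa_frame")
  expect_error(das_beamform(nf, g), "non-finite")
})

test_that("a noise-free point target is localized on the grid", {
  p <- acquisition_params()
  g <- image_grid(p)
  # absorber on the grid column nearest the aperture center
  x0 <- g$x[which.min(abs(g$x))]
  z0 <- 10
  sc <- make_phantom(absorbers = data.frame(x = x0, z = z0, amplitude = 1),
                     seed = 1, params = p)
  img <- beamform_frame(simulate_channel_data(sc, p))
  pk <- which(img$envelope == max(img$envelope), arr.ind = TRUE)
  expect_lte(abs(g$z[pk[1]] - z0) / g$dz, 2)
  expect_lte(abs(g$x[pk[2]] - x0) / g$dx, 2)
})

test_that("translating an absorber by one pitch shifts the peak one column", {
  p <- acquisition_params(n_elements = 96L, n_samples = 768L)
  g <- image_grid(p)
  x0 <- g$x[40]; z0 <- 6
  peak_col <- function(x) {
    sc <- make_phantom(absorbers = data.frame(x = x, z = z0, amplitude = 1),
                       seed = 1, params = p)
    img <- beamform_frame(simulate_channel_data(sc, p))
    which(img$envelope == max(img$envelope), arr.ind = TRUE)[2]
  }
  expect_equal(peak_col(x0 + g$dx) - peak_col(x0), 1)
})

test_that("lateral resolution at 10 mm depth is physically sane", {
  p <- acquisition_params()
  g <- image_grid(p)
  x0 <- g$x[which.min(abs(g$x))]
  sc <- make_phantom(absorbers = data.frame(x = x0, z = 10, amplitude = 1),
                     seed = 1, params = p)
  img <- beamform_frame(simulate_channel_data(sc, p))
  pk <- which(img$envelope == max(img$envelope), arr.ind = TRUE)
  prof <- img$envelope[pk[1], ]
  # FWHM by linear interpolation around the peak
  above <- prof >= 0.5
  i1 <- min(which(above)); i2 <- max(which(above))
  interp_edge <- function(i, j) {
    g$x[j] + (0.5 - prof[j]) / (prof[i] - prof[j]) * (g$x[i] - g$x[j])
  }
  left <- if (i1 > 1) interp_edge(i1, i1 - 1) else g$x[i1]
  right <- if (i2 < length(prof)) interp_edge(i2, i2 + 1) else g$x[i2]
  fwhm <- right - left
  lambda <- p$speed_of_sound / p$center_frequency * 1000  # mm
  expect_gte(fwhm, lambda)
  expect_lte(fwhm, 20 * lambda)
})

test_that("envelope detection recovers amplitude of an RF tone", {
  p <- tiny_params()
  t <- (0:511) / p$sampling_frequency
  rf <- matrix(cos(2 * pi * p$center_frequency * t), ncol = 1)
  env <- envelope_detect(rf)
  interior <- env[50:462, 1]
  expect_true(all(abs(interior - 1) < 0.02))

  expect_true(all(envelope_detect(matrix(0, 64, 4)) == 0))
  x <- matrix(rnorm(256), 64, 4)
  expect_equal(envelope_detect(x), envelope_detect(-x), tolerance = 1e-12)
  expect_true(all(envelope_detect(x) >= 0))
})

test_that("normalization and log compression follow the display contract", {
  out <- normalize_log_compress(matrix(c(1, 0.1), 1), 30)
  expect_equal(out$bmode_db, matrix(c(0, -20), 1), tolerance = 1e-12)

  out2 <- normalize_log_compress(matrix(c(1, 1e-4), 1), 30)
  expect_equal(out2$bmode_db[2], -30)  # clipped

  set.seed(3)
  env <- matrix(runif(100), 10)
  out3 <- normalize_log_compress(env, 25)
  expect_equal(max(out3$envelope), 1)
  expect_equal(max(out3$bmode_db), 0)
  expect_true(all(out3$bmode_db >= -25))

  expect_error(normalize_log_compress(matrix(0, 3, 3), 30), "empty")
  expect_error(normalize_log_compress(matrix(1, 2, 2), -5))
})

test_that("the optional bandpass preserves in-band content", {
  p <- tiny_params()
  sc <- make_phantom(absorbers = data.frame(x = 0, z = 4, amplitude = 1),
                     seed = 1, params = p)
  fr <- simulate_channel_data(sc, p)
  img_off <- beamform_frame(fr)
  img_on <- beamform_frame(fr, bandpass = p$bandwidth)
  pk_off <- which(img_off$envelope == max(img_off$envelope), arr.ind = TRUE)
  pk_on <- which(img_on$envelope == max(img_on$envelope), arr.ind = TRUE)
  expect_lte(max(abs(pk_on - pk_off)), 2)
})
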