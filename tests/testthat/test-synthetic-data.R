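# Synthetic channel-data generator: scenes, forward model, truth masks,
# and grouped metric sampling.

test_that("phantom scenes are deterministic and geometrically valid", {
  # minimal scene: one explicit absorber, no lumen
  sc <- make_phantom(absorbers = data.frame(x = 0, z = 10, amplitude = 1),
                     noise_sigma = 0, seed = 1)
  expect_s3_class(sc, "pa_scene")
  expect_equal(nrow(sc$absorbers), 1)

  # lumen absorbers all fall inside the ellipse
  sc2 <- make_phantom(lumen_center = c(11.5, 8), lumen_half_widths = c(2, 1),
                      n_lumen = 30, seed = 7)
  ab <- sc2$absorbers
  expect_equal(nrow(ab), 30)
  inside <- ((ab$x - 11.5) / 2)^2 + ((ab$z - 8) / 1)^2 <= 1
  expect_true(all(inside))

  # same config, same seed -> identical scenes
  sc3 <- make_phantom(lumen_center = c(11.5, 8), lumen_half_widths = c(2, 1),
                      n_lumen = 30, seed = 7)
  expect_identical(sc2$absorbers, sc3$absorbers)

  # different seed -> different absorbers
  sc4 <- make_phantom(lumen_center = c(11.5, 8), lumen_half_widths = c(2, 1),
                      n_lumen = 30, seed = 8)
  expect_false(identical(sc2$absorbers, sc4$absorbers))
})

test_that("phantom construction rejects out-of-field absorbers", {
  expect_error(make_phantom(absorbers = data.frame(x = 0, z = -1,
                                                   amplitude = 1)),
               "depth")
  expect_error(make_phantom(absorbers = data.frame(x = 0, z = 0,
                                                   amplitude = 1)),
               "depth")
  # beyond lateral aperture extent +-50%
  expect_error(make_phantom(absorbers = data.frame(x = 30, z = 10,
                                                   amplitude = 1)),
               "lateral")
  expect_error(make_phantom(noise_sigma = -0.1))
})

test_that("channel simulation is deterministic, linear, and windowed", {
  p <- tiny_params()
  sc <- make_phantom(absorbers = data.frame(x = 0.2, z = 4, amplitude = 1),
                     seed = 3, params = p)
  f1 <- simulate_channel_data(sc, p)
  f2 <- simulate_channel_data(sc, p)
  expect_identical(f1$data, f2$data)

  # doubling every amplitude doubles the noise-free data exactly
  sc2 <- make_phantom(absorbers = data.frame(x = 0.2, z = 4, amplitude = 2),
                      seed = 3, params = p)
  expect_equal(simulate_channel_data(sc2, p)$data, 2 * f1$data,
               tolerance = 1e-14)

  # empty absorber list, zero noise -> all-zero channel data
  sc0 <- make_phantom(noise_sigma = 0, seed = 1, params = p)
  expect_true(all(simulate_channel_data(sc0, p)$data == 0))

  # time of flight beyond the sampled window errors
  p_short <- tiny_params(n_samples = 64L)
  sc3 <- make_phantom(absorbers = data.frame(x = 0, z = 7, amplitude = 1),
                      seed = 1, params = tiny_params())
  expect_error(simulate_channel_data(sc3, p_short), "window")
})

test_that("additive channel noise has the requested scale", {
  p <- tiny_params(n_elements = 8L, n_samples = 4096L)
  sc <- make_phantom(noise_sigma = 0.1, seed = 42, params = p)
  fr <- simulate_channel_data(sc, p)
  sds <- apply(fr$data, 2, sd)
  expect_true(all(abs(sds - 0.1) / 0.1 < 0.05))
})

test_that("single-absorber arrival times match analytic time of flight", {
  p <- tiny_params(n_elements = 16L, n_samples = 512L)
  z0 <- 4; x0 <- 0.1
  sc <- make_phantom(absorbers = data.frame(x = x0, z = z0, amplitude = 1),
                     seed = 1, params = p)
  fr <- simulate_channel_data(sc, p)
  env <- envelope_detect(fr$data)
  ex <- element_positions(p)
  for (e in seq_along(ex)) {
    r <- sqrt(z0^2 + (x0 - ex[e])^2)
    expected <- round(p$sampling_frequency * r / (p$speed_of_sound * 1000))
    got <- which.max(env[, e]) - 1  # 0-based sample index
    expect_lte(abs(got - expected), 1)
  }
})

test_that("truth masks rasterize the scene geometry", {
  p <- tiny_params(n_elements = 64L, n_samples = 512L)
  g <- image_grid(p)

  # no lumen -> empty ureter mask
  sc0 <- make_phantom(absorbers = data.frame(x = 0, z = 4, amplitude = 1),
                      seed = 1, params = p)
  mk0 <- make_truth_masks(sc0, g)
  expect_false(any(mk0$ureter_mask))

  # absorber at a pixel center is inside the signal mask
  x_px <- g$x[30]; z_px <- g$z[200]
  sc1 <- make_phantom(absorbers = data.frame(x = x_px, z = z_px,
                                             amplitude = 1),
                      seed = 1, params = p)
  mk1 <- make_truth_masks(sc1, g)
  expect_true(mk1$signal_mask[200, 30])

  # ellipse lumen pixel count approximates the analytic area within 10%
  hw <- c(1.5, 1.0)
  sc2 <- make_phantom(lumen_center = c(0, 4), lumen_half_widths = hw,
                      n_lumen = 5, seed = 1, params = p)
  mk2 <- make_truth_masks(sc2, g)
  area_px <- sum(mk2$ureter_mask) * g$dx * g$dz
  area_true <- pi * hw[1] * hw[2]
  expect_lt(abs(area_px - area_true) / area_true, 0.10)
})

test_that("metric-group sampling is reproducible and honors the spec", {
  spec <- default_group_spec("contrast_db")
  s1 <- sample_metric_groups(spec, seed = 5)
  s2 <- sample_metric_groups(spec, seed = 5)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), sum(spec$n))
  expect_equal(as.vector(table(factor(s1$time_point_min,
                                      levels = spec$time_point_min))),
               spec$n)

  # scale 0 -> constant samples at the stated location
  const <- sample_metric_groups(
    tibble::tibble(time_point_min = 10, n = 5L, family = "normal",
                   location = 3.3, scale = 0), seed = 1)
  expect_true(all(const$value == 3.3))

  # group medians track the specified medians (averaged over seeds to tame
  # sampling noise; groups with n >= 40 within 0.5 dB)
  meds <- sapply(1:20, function(s) {
    sm <- sample_metric_groups(spec, seed = s)
    tapply(sm$value, factor(sm$time_point_min, levels = spec$time_point_min),
           median)
  })
  big <- spec$n >= 40
  expect_true(all(abs(rowMeans(meds)[big] - spec$location[big]) < 0.5))

  expect_error(sample_metric_groups(
    tibble::tibble(time_point_min = 1, n = 2L, family = "normal",
                   location = 0, scale = 1)), "n >= 3")
  expect_error(sample_metric_groups(
    tibble::tibble(time_point_min = 1, n = 5L, family = "weird",
                   location = 0, scale = 1)), "family")
})

test_that("identically distributed groups reject at the nominal rate", {
  spec <- tibble::tibble(time_point_min = c(1, 2), n = 50L,
                         family = "normal", location = 0, scale = 1)
  rejects <- sapply(1:200, function(s) {
    sm <- sample_metric_groups(spec, seed = s)
    kruskal_wallis(sm, group = "time_point_min")$p_value < 0.05
  })
  expect_gt(mean(rejects), 0.01)
  expect_lt(mean(rejects), 0.10)
})
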