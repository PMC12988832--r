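# Shared fixtures and independent oracles, built in code at test time.

# small acquisition setup for fast simulations
tiny_params <- function(n_elements = 16L, n_samples = 512L, ...) {
  acquisition_params(n_elements = n_elements, n_samples = n_samples, ...)
}

# brute-force per-pixel, per-element DAS loop (independent of the compiled
# path): linear interpolation, zero outside the window, uniform apodization
das_brute <- function(data, elem_x, grid_x, grid_z, fs, c) {
  out <- matrix(0, length(grid_z), length(grid_x))
  for (ix in seq_along(grid_x)) {
    for (iz in seq_along(grid_z)) {
      acc <- 0
      for (e in seq_along(elem_x)) {
        r <- sqrt(grid_z[iz]^2 + (grid_x[ix] - elem_x[e])^2)
        s <- r / (c * 1000) * fs  # 0-based fractional sample
        s0 <- floor(s)
        if (s0 >= 0 && s0 < nrow(data) - 1) {
          fr <- s - s0
          acc <- acc + (1 - fr) * data[s0 + 1, e] + fr * data[s0 + 2, e]
        }
      }
      out[iz, ix] <- acc
    }
  }
  out
}

# exhaustive enumeration: every fully-in-mask ROI origin whose ROI contains
# the given pixel
roi_feasible_oracle <- function(mask, pixel, height, width) {
  dims <- dim(mask)
  hits <- list()
  for (r0 in seq_len(max(0, dims[1] - height + 1))) {
    for (c0 in seq_len(max(0, dims[2] - width + 1))) {
      rows <- r0:(r0 + height - 1); cols <- c0:(c0 + width - 1)
      if (pixel[1] %in% rows && pixel[2] %in% cols &&
          all(mask[rows, cols])) {
        hits[[length(hits) + 1]] <- c(r0, c0)
      }
    }
  }
  hits
}

# random blobby mask: union of a few random filled rectangles/ellipses
random_mask <- function(dims, n_blobs = 3) {
  m <- matrix(FALSE, dims[1], dims[2])
  for (b in seq_len(n_blobs)) {
    cr <- sample(dims[1], 1); cc <- sample(dims[2], 1)
    hr <- sample(2:8, 1); hc <- sample(2:8, 1)
    if (runif(1) < 0.5) {
      rows <- max(1, cr - hr):min(dims[1], cr + hr)
      cols <- max(1, cc - hc):min(dims[2], cc + hc)
      m[rows, cols] <- TRUE
    } else {
      for (i in max(1, cr - hr):min(dims[1], cr + hr)) {
        for (j in max(1, cc - hc):min(dims[2], cc + hc)) {
          if (((i - cr) / hr)^2 + ((j - cc) / hc)^2 <= 1) m[i, j] <- TRUE
        }
      }
    }
  }
  m
}

# tie-corrected Kruskal-Wallis H from first principles (rank arithmetic)
kw_brute <- function(groups) {
  v <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(v)
  rk <- rank(v)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(rk, g, function(r) length(r) * (mean(r) - (N + 1) / 2)^2))
  ties <- table(v)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# fast pipeline configuration used by the end-to-end tests
small_pipeline_config <- function(seed = 11L, out_dir = NULL,
                                  n_frames = 2L) {
  pipeline_config(
    n_frames = n_frames,
    lumen_center = c(-1.2, 5), lumen_half_widths = c(1.0, 0.6),
    n_lumen = 15L, n_adventitia = 20L,
    roi_lateral_mm = 1.2, roi_axial_mm = 0.4,
    jitter_mm = 0.15,
    params = acquisition_params(n_elements = 64L, n_samples = 576L),
    seed = seed, out_dir = out_dir)
}
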