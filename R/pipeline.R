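# End-to-end orchestration: simulate -> beamform -> select frames ->
# place ROIs -> metrics -> group statistics, with a reproducible manifest.

#' Pipeline configuration
#'
#' Describes a full synthetic monitoring run: per-time-point acquisition
#' counts and signal strengths, beamforming and ROI options, and
#' frame-selection thresholds. Defaults emulate a post-injection
#' monitoring study at 10/20/30/60/70/80 min with image quality peaking
#' 20--30 min after injection.
#'
#' @param time_points_min Time-point labels in minutes.
#' @param n_frames Frames simulated per time point.
#' @param signal_scale Per-time-point multiplier on absorber amplitudes
#'   (same length as `time_points_min`); shapes the time course of
#'   contrast.
#' @param lumen_center,lumen_half_widths Lumen geometry (mm).
#' @param n_lumen,n_adventitia Absorber counts.
#' @param noise_sigma Channel noise standard deviation (a.u.).
#' @param jitter_mm Frame-to-frame standard deviation of lumen center
#'   position (emulates freehand probe/fiber drift).
#' @param dynamic_range Display dynamic range in dB.
#' @param roi_lateral_mm,roi_axial_mm Target/background ROI size.
#' @param background_margin_mm Background ROI distance from the right
#'   image edge.
#' @param iou_threshold,cor_threshold Stationary-duplicate thresholds.
#' @param params [acquisition_params()] for the simulated system. The
#'   default extends the sampled window to 1536 samples so off-axis
#'   adventitia arrivals stay inside it.
#' @param seed Master seed; every stage derives its randomness from it.
#' @param out_dir Optional directory; when given, stage outputs are
#'   written there (CSV tables, JSON reports, manifest).
#' @return A `pa_config` list.
#' @export
pipeline_config <- function(time_points_min = c(10, 20, 30, 60, 70, 80),
                            n_frames = 4L,
                            signal_scale = c(1.0, 2.6, 2.3, 1.5, 1.0, 1.8),
                            lumen_center = c(-3, 8),
                            lumen_half_widths = c(2, 1),
                            n_lumen = 25L, n_adventitia = 35L,
                            noise_sigma = 0.004,
                            jitter_mm = 0.3,
                            dynamic_range = 30,
                            roi_lateral_mm = 3, roi_axial_mm = 0.6,
                            background_margin_mm = 0.54,
                            iou_threshold = 0.95, cor_threshold = 0.99,
                            params = acquisition_params(n_samples = 1536L),
                            seed = 1L, out_dir = NULL) {
  stopifnot(length(signal_scale) == length(time_points_min),
            n_frames >= 1, inherits(params, "pa_params"))
  structure(as.list(environment()), class = "pa_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> beamform -> select-frames -> place-roi -> metrics ->
#' stats on a synthetic monitoring run. Frames whose photoacoustic signal
#' does not overlap the ureter mask, stationary duplicates, and frames
#' where no valid ROI exists are excluded and logged with a reason.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pa_run`: list with `metrics` (per-frame
#'   metric tibble), `retention` (per-frame accounting with exclusion
#'   reasons), `rois`, `stats` (a `pa_comparison` per metric), `counts`
#'   (per-stage frame accounting), and `manifest`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(n_frames = 2,
#'                        params = acquisition_params(n_elements = 64,
#'                                                    n_samples = 640))
#' run <- run_pipeline(cfg)
#' head(run$metrics)
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pa_config"))
  grid <- image_grid(config$params)
  size <- roi_size_px(grid, config$roi_lateral_mm, config$roi_axial_mm)
  tp <- config$time_points_min

  frames <- list(); masks <- list(); images <- list()
  meta <- list()
  fidx <- 0L
  for (i in seq_along(tp)) {
    for (j in seq_len(config$n_frames)) {
      fidx <- fidx + 1L
      fseed <- config$seed + 1000L * i + j
      jit <- with_seed(fseed, rnorm(2, 0, config$jitter_mm))
      scene <- make_phantom(
        lumen_center = config$lumen_center + jit,
        lumen_half_widths = config$lumen_half_widths,
        n_lumen = config$n_lumen,
        lumen_amplitude = config$signal_scale[i],
        n_adventitia = config$n_adventitia,
        adventitia_amplitude = config$signal_scale[i],
        noise_sigma = config$noise_sigma,
        seed = fseed, params = config$params)
      id <- sprintf("t%03d-f%02d", tp[i], j)
      frames[[fidx]] <- simulate_channel_data(scene, time_point_min = tp[i],
                                              frame_id = id)
      masks[[fidx]] <- make_truth_masks(scene, grid, frame_id = id)
      images[[fidx]] <- beamform_frame(frames[[fidx]], config$dynamic_range,
                                       grid)
      meta[[fidx]] <- tibble::tibble(frame_id = id, time_point_min = tp[i])
    }
  }
  meta <- dplyr::bind_rows(meta)

  # frame selection: overlap retention, then stationary-duplicate exclusion
  retention <- purrr::map_dfr(masks, retain_frame)
  dup <- flag_stationary_duplicates(masks,
                                    lapply(images, `[[`, "envelope"),
                                    config$iou_threshold,
                                    config$cor_threshold)
  retention <- dplyr::left_join(meta, retention, by = "frame_id")
  retention$duplicate <- dup$duplicate
  retention$reason <- dplyr::case_when(
    !retention$retained ~ "no-signal-overlap",
    retention$duplicate ~ "stationary-duplicate",
    TRUE ~ NA_character_)

  rois <- list(); metrics <- list()
  for (k in seq_len(fidx)) {
    if (!is.na(retention$reason[k])) next
    img <- images[[k]]; mk <- masks[[k]]
    rec <- tryCatch({
      search <- mk$ureter_mask & mk$signal_mask
      bright <- find_brightest_pixel(img$envelope, search)
      tgt <- place_target_roi(img$envelope, mk$ureter_mask, bright, size)
      bg <- place_background_roi(tgt, dim(img$envelope), grid,
                                 config$background_margin_mm)
      rois[[length(rois) + 1L]] <- roi_report(list(tgt, bg), img$frame_id)
      compute_frame_metrics(img, tgt, bg)
    }, error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      retention$reason[k] <- paste0("roi-failed: ", rec)
    } else {
      metrics[[length(metrics) + 1L]] <- rec
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  rois <- dplyr::bind_rows(rois)

  stats <- list()
  if (nrow(metrics) &&
      length(unique(metrics$time_point_min)) >= 2 &&
      min(table(metrics$time_point_min)) >= 3) {
    for (m in c("contrast_db", "snr", "gcnr")) {
      stats[[m]] <- compare_groups(metrics, value = m,
                                   group = "time_point_min")
    }
  }

  counts <- dplyr::count(retention,
                         reason = dplyr::coalesce(.data$reason, "analyzed"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("paviq")),
    seed = config$seed,
    n_time_points = length(tp), n_frames_per_time = config$n_frames,
    frames_simulated = fidx,
    frames_analyzed = nrow(metrics),
    roi_px = size,
    config = config[!(names(config) %in% c("params", "out_dir"))])

  run <- structure(list(metrics = metrics, retention = retention,
                        rois = rois, stats = stats, counts = counts,
                        manifest = manifest),
                   class = "pa_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$metrics, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(run$retention, file.path(out_dir, "retention.csv"),
            row.names = FALSE)
  write.csv(run$rois, file.path(out_dir, "rois.csv"), row.names = FALSE)
  if (length(run$stats)) {
    report <- lapply(run$stats, function(s) {
      list(normality = s$normality, omnibus = s$omnibus,
           pairwise = s$pairwise)
    })
    jsonlite::write_json(report, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pa_run <- function(x, ...) {
  cat("<pa_run> ", x$manifest$frames_simulated, " frames simulated, ",
      x$manifest$frames_analyzed, " analyzed\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Overlay a photoacoustic image on its coregistered B-mode image
#'
#' Grayscale B-mode underlay with color-mapped photoacoustic signal drawn
#' wherever the photoacoustic image exceeds its display threshold
#' (`-pa_dynamic_range` dB).
#'
#' @param bmode,pa `pa_image` objects on the same grid.
#' @param bmode_dynamic_range,pa_dynamic_range Display dynamic ranges in dB
#'   for the underlay and overlay.
#' @return A ggplot object.
#' @export
render_overlay <- function(bmode, pa, bmode_dynamic_range = 45,
                           pa_dynamic_range = 18) {
  stopifnot(inherits(bmode, "pa_image"), inherits(pa, "pa_image"))
  if (!isTRUE(all.equal(bmode$grid$x, pa$grid$x)) ||
      !isTRUE(all.equal(bmode$grid$z, pa$grid$z))) {
    stop("B-mode and photoacoustic images must share the grid")
  }
  bdb <- pmax(20 * log10(pmax(bmode$envelope, 1e-12)),
              -bmode_dynamic_range)
  pdb <- 20 * log10(pmax(pa$envelope, 1e-12))
  df <- tidyr::expand_grid(z = bmode$grid$z, x = bmode$grid$x)
  df$bmode_db <- as.vector(t(bdb))
  df$pa_db <- as.vector(t(pdb))
  above <- df$pa_db > -pa_dynamic_range
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$z)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$bmode_db)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "B-mode dB") +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(x = "Lateral (mm)", y = "Depth (mm)")
  if (any(above)) {
    p <- p + ggplot2::geom_raster(
      data = df[above, ],
      ggplot2::aes(.data$x, .data$z, alpha = .data$pa_db),
      fill = "red", inherit.aes = FALSE) +
      ggplot2::scale_alpha_continuous(range = c(0.4, 1), name = "PA dB")
  }
  attr(p, "n_overlay_px") <- sum(above)
  p
}
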