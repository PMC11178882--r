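# End-to-end pipeline: simulate (optional) -> motion QC -> extract ->
# detect -> evaluate, with every threshold recorded and fully seeded
# reproducibility.

#' Run configuration
#'
#' All knobs of a pipeline run in one serialisable object: seeds,
#' acquisition settings, protocol choice and the thresholds applied at
#' each stage. A run is reproducible from (config, inputs) alone.
#'
#' @param seed master seed.
#' @param protocol_id protocol for the simulation stage (1-5).
#' @param frame_rate acquisition rate, Hz.
#' @param roi_shape c(rows, cols) of the simulated ROI, px.
#' @param pixel_size um per pixel.
#' @param power_density,spot_fwhm illumination settings.
#' @param f0 baseline photons per membrane pixel per frame at the
#'   reference power density.
#' @param snr_threshold spike-detection threshold (working default 5).
#' @param tolerance_ms event-matching tolerance.
#' @param motion_cor_threshold,motion_displacement_floor motion QC
#'   thresholds.
#' @param motion_sigmas 3D Gaussian QC smoothing sigmas (t, x, y).
#' @param run_qc,run_thermal stage toggles.
#' @param protocol_params extra parameters for [make_protocol()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1, protocol_id = 5, frame_rate = 500,
                       roi_shape = c(32, 32), pixel_size = 0.65,
                       power_density = 0.88, spot_fwhm = 12, f0 = 60,
                       snr_threshold = 5, tolerance_ms = 5,
                       motion_cor_threshold = 0.5,
                       motion_displacement_floor = 0.5,
                       motion_sigmas = c(1, 5, 5),
                       run_qc = TRUE, run_thermal = FALSE,
                       protocol_params = list()) {
  cfg <- as.list(environment())
  max_rows <- floor(266 * 1000 / frame_rate)
  if (roi_shape[1] > max_rows)
    stop("config invalid: ", roi_shape[1], " rows at ", frame_rate,
         " Hz exceeds the readout cap (266 rows at 1 kHz, ",
         max_rows, " at this rate)")
  structure(cfg, class = "run_config")
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 17
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%d", h)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on a (simulated) recording
#'
#' Simulates a single-cell recording under the configured protocol, runs
#' motion QC, extracts the weighted trace, detects events and evaluates
#' them against the generator's ground truth. Any stage failure aborts
#' with a stage-tagged error. With `out_dir` set, the trace, events,
#' metrics and motion report are written (CSV/JSON, plus the weights as a
#' 32-bit TIFF), each carrying provenance (config hash, seed, package
#' version).
#'
#' @param config a [run_config()].
#' @param movie optional pre-existing `sv_movie` plus `truth` list (as
#'   returned by [render_movie()]); when `NULL` the simulate stage runs.
#' @param out_dir optional output directory.
#' @return List with `movie`, `truth`, `motion`, `trace`, `weights`,
#'   `events`, `match`, `metrics`, `provenance`.
#' @export
run_pipeline <- function(config, movie = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  prov <- list(config_hash = config_hash(config), seed = config$seed,
               package_version =
                 as.character(utils::packageVersion("scanvolt")))

  sim <- stage("simulate", {
    if (is.null(movie)) {
      acq <- acquisition_config(frame_rate = config$frame_rate,
                                pixel_size = config$pixel_size,
                                roi_shape = config$roi_shape)
      fov <- config$roi_shape * config$pixel_size
      cell <- cell_model(x = fov[2] / 2, y = fov[1] / 2, f0 = config$f0)
      prot <- make_protocol(config$protocol_id,
                            params = config$protocol_params,
                            seed = config$seed)
      illum <- illumination_spec(spot_fwhm = config$spot_fwhm,
                                 power_density = config$power_density,
                                 reference_power_density = 0.88)
      render_movie(cell, prot, illum, acq, seed = config$seed)
    } else movie
  })

  motion <- if (isTRUE(config$run_qc)) stage("qc", {
    motion_check(sim$movie, sigmas = config$motion_sigmas,
                 cor_threshold = config$motion_cor_threshold,
                 displacement_floor = config$motion_displacement_floor)
  }) else NULL

  ext <- stage("extract", {
    d <- dim(sim$movie$counts)
    roi <- structure(list(counts = sim$movie$counts,
                          origin = c(row = 1, col = 1),
                          centroid_um = c(d[3], d[2]) *
                            sim$movie$pixel_size / 2,
                          pixel_size = sim$movie$pixel_size,
                          times_ms = sim$movie$times_ms,
                          frame_rate = sim$movie$frame_rate),
                     class = "sv_roi")
    mask <- initial_segment(roi)
    w <- pixel_weights(roi, mask)
    tr <- extract_trace(roi, w)
    epochs <- sim$truth$illumination_epochs_ms
    tr <- detrend_trace(tr, epochs_ms = epochs)
    base_n <- max(5, round(0.1 * sum(tr$time_ms >= epochs[1, 1] &
                                     tr$time_ms < epochs[1, 2])))
    first_ep <- which(tr$time_ms >= epochs[1, 1] &
                      tr$time_ms < epochs[1, 2])
    tr <- dff(tr, baseline = first_ep[seq_len(base_n)])
    list(roi = roi, mask = mask, weights = w, trace = tr)
  })

  det <- stage("detect", {
    detect_spikes(ext$trace$dff, rate = ext$trace$rate,
                  snr_threshold = config$snr_threshold)
  })

  ev <- stage("evaluate", {
    truth_ms <- sim$truth$spike_times_ms[[1]]
    if (length(truth_ms)) {
      m <- match_events(det, truth_ms, tolerance_ms = config$tolerance_ms)
      list(match = m, metrics = detection_metrics(m))
    } else list(match = NULL, metrics = NULL)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trace_csv(ext$trace, file.path(out_dir, "trace.csv"))
    utils::write.csv(det$events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    write_weights_tiff(ext$weights, file.path(out_dir, "weights.tif"))
    jsonlite::write_json(
      list(provenance = prov,
           thresholds = list(snr_threshold = config$snr_threshold,
                             tolerance_ms = config$tolerance_ms,
                             motion_cor_threshold =
                               config$motion_cor_threshold),
           motion = if (!is.null(motion))
             list(correlation = motion$correlation,
                  max_displacement = motion$max_displacement,
                  reject = motion$reject),
           metrics = ev$metrics,
           counts = if (!is.null(ev$match))
             list(tp = ev$match$tp, fp = ev$match$fp, fn = ev$match$fn,
                  tn = ev$match$tn)),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }

  list(movie = sim$movie, truth = sim$truth, motion = motion,
       trace = ext$trace, weights = ext$weights, events = det,
       match = ev$match, metrics = ev$metrics, provenance = prov)
}
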