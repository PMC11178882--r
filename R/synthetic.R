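# Synthetic scanless two-photon voltage-imaging recordings.
#
# The generator emulates camera-based recordings of a negative-going,
# soma-targeted genetically encoded voltage indicator: membrane-localised
# baseline fluorescence that scales quadratically with excitation power
# density, voltage transients of configurable sensitivity and kinetics,
# single-exponential photobleaching with partial dark recovery, and Poisson
# shot noise. Five stimulation protocols mirror the characterisation
# recordings (voltage steps, AP-like pulse trains, sub-threshold steps and
# random spiking), so every downstream stage can be tested against known
# ground truth.

# deterministic 31-bit sub-stream seed derived from a master seed and a
# stream name, so scene layout, spike times and shot noise draw from
# independent named streams
substream_seed <- function(seed, name) {
  h <- 17
  for (v in utf8ToInt(name)) h <- (h * 31 + v) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

#' Camera acquisition configuration
#'
#' @param frame_rate acquisition rate, Hz (100-1000 for the recordings
#'   modelled here).
#' @param exposure_ms per-frame exposure, ms; must not exceed the frame
#'   period. Default fills the frame period.
#' @param pixel_size pixel size at the sample plane, um.
#' @param roi_shape integer c(rows, cols) of the acquired region. The
#'   number of rows is limited by the camera readout: 266 rows at 1 kHz,
#'   scaling inversely with rate (532 at 500 Hz).
#' @param bit_depth sensor bit depth.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_rate = 500, exposure_ms = NULL,
                               pixel_size = 0.1625, roi_shape = c(64, 64),
                               bit_depth = 16) {
  stopifnot(frame_rate > 0, pixel_size > 0, length(roi_shape) == 2)
  period <- 1000 / frame_rate
  if (is.null(exposure_ms)) exposure_ms <- period
  if (exposure_ms > period + 1e-9)
    stop("exposure (", exposure_ms, " ms) exceeds the frame period (",
         signif(period, 4), " ms)")
  max_rows <- floor(266 * 1000 / frame_rate)
  if (roi_shape[1] > max_rows)
    stop("ROI has ", roi_shape[1], " rows but at ", frame_rate,
         " Hz at most ", max_rows,
         " rows can be read out (266 rows at 1 kHz)")
  structure(list(frame_rate = frame_rate, exposure_ms = exposure_ms,
                 pixel_size = pixel_size, roi_shape = as.integer(roi_shape),
                 bit_depth = bit_depth, max_rows = max_rows),
            class = "acquisition_config")
}

#' Model of a fluorescent cell
#'
#' @param x,y centroid, um.
#' @param soma_diameter soma diameter, um.
#' @param membrane_width width of the membrane annulus carrying the
#'   indicator, um.
#' @param f0 expected baseline photon count per membrane pixel per frame at
#'   the reference power density.
#' @param sensitivity fractional fluorescence decrease per 100 mV
#'   depolarisation (0.43 reproduces the weighted-mean characterisation).
#' @param tau_rise_ms,tau_decay_ms indicator response kinetics, ms.
#' @param cytosol_fraction relative brightness of the cell interior.
#' @return An object of class `cell_model`.
#' @export
cell_model <- function(x, y, soma_diameter = 12, membrane_width = 1,
                       f0 = 20, sensitivity = 0.43, tau_rise_ms = 1,
                       tau_decay_ms = 2, cytosol_fraction = 0.15) {
  stopifnot(soma_diameter > 0, f0 >= 0)
  if (sensitivity < 0 || sensitivity > 1)
    stop("sensitivity must lie in [0, 1]")
  structure(list(x = x, y = y, soma_diameter = soma_diameter,
                 membrane_width = membrane_width, f0 = f0,
                 sensitivity = sensitivity, tau_rise_ms = tau_rise_ms,
                 tau_decay_ms = tau_decay_ms,
                 cytosol_fraction = cytosol_fraction),
            class = "cell_model")
}

#' Illumination specification
#'
#' The power per target follows the convention
#' `power = power_density * pi * (fwhm/2)^2` (area of the FWHM disc), which
#' reproduces the printed pairings (0.88 mW um^-2 over a 12 um spot is
#' 100 mW per cell; 0.66 is 75 mW).
#'
#' @param spot_fwhm lateral FWHM of the excitation spot, um (12 or 17).
#' @param power_density average power density, mW um^-2.
#' @param reference_power_density power density at which `f0` of a
#'   [cell_model()] and the photobleaching calibration are defined.
#' @param wavelength nm.
#' @param schedule optional (on, off) illumination epochs in ms; `NULL`
#'   takes the epochs from the protocol.
#' @return An object of class `illumination_spec`.
#' @export
illumination_spec <- function(spot_fwhm = 12, power_density = 0.88,
                              reference_power_density = 0.88,
                              wavelength = 940, schedule = NULL) {
  stopifnot(spot_fwhm > 0, power_density >= 0, reference_power_density > 0)
  if (!is.null(schedule)) {
    schedule <- as.matrix(schedule)
    if (any(schedule[, 2] <= schedule[, 1]))
      stop("illumination epochs must have off > on")
  }
  structure(list(spot_fwhm = spot_fwhm, power_density = power_density,
                 reference_power_density = reference_power_density,
                 power_per_target = power_density * pi * (spot_fwhm / 2)^2,
                 wavelength = wavelength, schedule = schedule),
            class = "illumination_spec")
}

#' Photon flux of a power density
#'
#' Converts an average power density into a photon flux,
#' `flux = power_density / (h * c / lambda)`. At 1.33 mW um^-2 and 940 nm
#' this is 6.29e27 photons per second per square metre.
#'
#' @param power_density mW um^-2.
#' @param wavelength nm.
#' @return Photon flux, photons s^-1 m^-2.
#' @export
photon_flux <- function(power_density, wavelength) {
  h <- 6.62607015e-34
  c0 <- 299792458
  (power_density * 1e9) / (h * c0 / (wavelength * 1e-9))
}

#' Build a stimulation protocol
#'
#' Returns the command-voltage waveform (sampled at `fs` Hz, emulating the
#' electrophysiology digitiser), ground-truth spike times and illumination
#' epochs for one of the five recording protocols:
#'
#' 1. three 100 ms, 100 mV steps under 3 s continuous illumination
#'    (100 Hz acquisition);
#' 2. three 100 ms, 100 mV steps with 200 ms strobed illumination centred
#'    on each step and 2.5 s dark intervals;
#' 3. a 20 Hz train of ten 3 ms, 100 mV AP-like pulses in a 500 ms
#'    illumination window (1 kHz acquisition);
#' 4. six 20 ms sub-threshold steps from 0 to 2.5 mV in 0.5 mV increments,
#'    40 ms strobed illumination centred on each step, repeated over
#'    trials;
#' 5. a 30 s continuous recording with randomly timed AP-like events
#'    (seeded Poisson process with a refractory floor).
#'
#' @param protocol_id integer 1-5.
#' @param params named list overriding protocol parameters:
#'   `step_amplitude` (mV), `n_steps`, `step_ms`, `train_hz`, `pulse_ms`,
#'   `sub_amplitudes` (mV), `rate_hz` (protocol 5 spike rate),
#'   `duration_ms` (protocol 5), `n_repeats` (protocol 4).
#' @param seed integer seed (protocol 5 spike times).
#' @param fs waveform sampling rate, Hz (>= 10 kHz).
#' @return An object of class `protocol_spec`: list with `protocol_id`,
#'   `time_ms`, `waveform_mV` (depolarisation relative to holding),
#'   `holding_mV`, `spike_times_ms`, `illumination_epochs_ms` (matrix of
#'   on/off, ms), `duration_ms`, `n_repeats`, `fs`.
#' @export
make_protocol <- function(protocol_id, params = list(), seed = 1,
                          fs = 10000) {
  if (!protocol_id %in% 1:5) stop("unknown protocol id: ", protocol_id)
  if (fs < 10000) stop("waveform must be sampled at >= 10 kHz")
  p <- function(name, default) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  amp <- p("step_amplitude", 100)
  step_ms <- p("step_ms", 100)
  if (step_ms < 0) stop("negative durations are not allowed")
  dt <- 1000 / fs
  n_repeats <- 1L
  spike_times <- numeric(0)
  holding <- -55

  if (protocol_id == 1) {
    duration <- 3000
    onsets <- c(500, 1500, 2500)
    epochs <- matrix(c(0, duration), 1)
  } else if (protocol_id == 2) {
    onsets <- c(300, 2800, 5300)
    duration <- 5600
    epochs <- cbind(onsets - 50, onsets + 150)
  } else if (protocol_id == 3) {
    holding <- -75
    amp <- p("step_amplitude", 100)
    step_ms <- p("pulse_ms", 3)
    train_hz <- p("train_hz", 20)
    n_pulses <- p("n_steps", 10)
    isi <- 1000 / train_hz
    onsets <- 60 + isi * (seq_len(n_pulses) - 1)
    duration <- if (length(onsets)) max(600, max(onsets) + 60) else 600
    epochs <- matrix(c(50, 550), 1)
    spike_times <- onsets
  } else if (protocol_id == 4) {
    holding <- -75
    amps <- p("sub_amplitudes", seq(0, 2.5, by = 0.5))
    step_ms <- p("step_ms", 20)
    gap <- 30
    onsets <- 30 + (step_ms + gap) * (seq_along(amps) - 1)
    duration <- max(onsets) + step_ms + gap
    epochs <- cbind(onsets - 10, onsets + step_ms + 10)
    n_repeats <- as.integer(p("n_repeats", 50))
  } else {
    holding <- -75
    duration <- p("duration_ms", 30000)
    rate <- p("rate_hz", 0.9)
    step_ms <- p("pulse_ms", 3)
    set.seed(substream_seed(seed, "spikes"))
    n <- stats::rpois(1, rate * duration / 1000)
    st <- sort(stats::runif(n, 20, duration - 20))
    while (length(st) > 1 && any(diff(st) < 20)) {
      st <- st[c(TRUE, diff(st) >= 20)]
    }
    spike_times <- st
    onsets <- st
    amp <- p("step_amplitude", 100)
    epochs <- matrix(c(0, duration), 1)
  }

  time_ms <- seq(0, duration - dt, by = dt)
  wav <- numeric(length(time_ms))
  if (protocol_id == 4) {
    amps <- p("sub_amplitudes", seq(0, 2.5, by = 0.5))
    for (i in seq_along(onsets)) {
      sel <- time_ms >= onsets[i] & time_ms < onsets[i] + step_ms
      wav[sel] <- amps[i]
    }
  } else if (length(onsets)) {
    for (on in onsets) {
      sel <- time_ms >= on & time_ms < on + step_ms
      wav[sel] <- amp
    }
  }

  structure(list(protocol_id = protocol_id, time_ms = time_ms,
                 waveform_mV = wav, holding_mV = holding,
                 spike_times_ms = spike_times,
                 illumination_epochs_ms = epochs, duration_ms = duration,
                 n_repeats = n_repeats, fs = fs),
            class = "protocol_spec")
}

#' Ideal relative-fluorescence response to a command waveform
#'
#' Applies the linearised indicator response: relative fluorescence
#' `1 - s * dV / 100 mV` (negative-going), convolved with a unit-area
#' bi-exponential kinetic kernel (mono-exponential rise and decay). The
#' convolution preserves the time integral of the deviation from baseline.
#'
#' @param protocol a [protocol_spec][make_protocol].
#' @param cell a [cell_model()].
#' @return List with `time_ms` and `rel_f` (dimensionless, 1 at rest).
#' @export
voltage_to_fluorescence <- function(protocol, cell) {
  stopifnot(inherits(protocol, "protocol_spec"), inherits(cell, "cell_model"))
  if (cell$sensitivity < 0 || cell$sensitivity > 1)
    stop("sensitivity must lie in [0, 1]")
  dt <- 1000 / protocol$fs
  tr <- cell$tau_rise_ms
  td <- cell$tau_decay_ms
  tk <- seq(0, max(8 * td, 8 * tr), by = dt)
  k <- if (abs(td - tr) < 1e-9) {
    tk * exp(-tk / td)
  } else {
    exp(-tk / td) - exp(-tk / tr)
  }
  k <- k / sum(k)  # unit mass: steady state passes through unchanged
  # causal convolution: y[i] = sum_j k[j] * x[i - j + 1]
  dv <- stats::filter(c(rep(0, length(k) - 1), protocol$waveform_mV),
                      k, sides = 1)
  dv <- as.numeric(dv)[length(k) - 1 + seq_along(protocol$waveform_mV)]
  list(time_ms = protocol$time_ms,
       rel_f = 1 - cell$sensitivity * dv / 100)
}

# photobleaching state along a time grid (s): single-exponential decay
# towards a floor while illuminated (rate scaled linearly with power ratio),
# partial recovery towards `recovery_ceiling * value at previous epoch
# onset` while dark. Calibrated so 3 s of continuous illumination at the
# reference power leaves 0.80 of the initial fluorescence and a 2.5 s dark
# interval restores it to 0.97.
bleach_profile <- function(times_s, epochs_s, power_ratio = 1,
                           end_fraction = 0.80, floor = 0.70,
                           recovery_to = 0.97, tau_cal_s = 3,
                           dark_ref_s = 2.5) {
  tau_b <- tau_cal_s / log((1 - floor) / (end_fraction - floor))
  ceiling_rec <- 1 - (1 - recovery_to) / 2
  # dark time constant chosen so a dark_ref_s gap recovers end_fraction ->
  # recovery_to (given the ceiling)
  tau_r <- dark_ref_s /
    log((ceiling_rec - end_fraction) / (ceiling_rec - recovery_to))
  b <- numeric(length(times_s))
  state <- 1
  t_prev <- 0
  epoch_start_val <- 1
  for (i in seq_along(times_s)) {
    t <- times_s[i]
    # advance state from t_prev to t in (at most one) regime at a time
    while (t_prev < t - 1e-12) {
      in_ep <- which(epochs_s[, 1] <= t_prev + 1e-12 &
                     t_prev < epochs_s[, 2] - 1e-12)
      if (length(in_ep)) {
        t_end <- min(t, epochs_s[in_ep[1], 2])
        if (abs(t_prev - epochs_s[in_ep[1], 1]) < 1e-12)
          epoch_start_val <- state
        dtau <- (t_end - t_prev) * power_ratio / tau_b
        state <- floor + (state - floor) * exp(-dtau)
      } else {
        nxt <- epochs_s[epochs_s[, 1] > t_prev + 1e-12, 1]
        t_end <- if (length(nxt)) min(t, nxt[1]) else t
        ceil_i <- ceiling_rec * epoch_start_val
        if (state < ceil_i) {
          state <- ceil_i - (ceil_i - state) * exp(-(t_end - t_prev) / tau_r)
        }
      }
      t_prev <- t_end
    }
    b[i] <- state
  }
  b
}

#' Randomly placed, non-overlapping target positions
#'
#' Samples `n_targets` centroids uniformly over the field of excitation
#' with a hard-core minimum pairwise separation (dart throwing with bounded
#' retries).
#'
#' @param n_targets number of targets.
#' @param fov c(width, height) of the field, um.
#' @param min_separation minimum pairwise distance, um.
#' @param seed integer seed.
#' @param margin clearance from the field edge, um.
#' @param max_tries retry budget before declaring the packing infeasible.
#' @return data.frame with `cell_id`, `x_um`, `y_um`.
#' @export
make_multi_target_scene <- function(n_targets, fov = c(300, 300),
                                    min_separation = 20, seed = 1,
                                    margin = 10, max_tries = 20000) {
  stopifnot(n_targets >= 1, all(fov > 0), min_separation >= 0)
  set.seed(substream_seed(seed, "scene"))
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n_targets) {
    if (tries >= max_tries)
      stop("could not place ", n_targets, " targets with separation ",
           min_separation, " um in ", fov[1], " x ", fov[2],
           " um (infeasible packing)")
    p <- c(stats::runif(1, margin, fov[1] - margin),
           stats::runif(1, margin, fov[2] - margin))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >=
          min_separation) {
      pts <- rbind(pts, p)
    }
    tries <- tries + 1
  }
  data.frame(cell_id = seq_len(n_targets), x_um = pts[, 1], y_um = pts[, 2])
}

#' Render a synthetic voltage-imaging movie
#'
#' Forward model of a camera recording: for every pixel the expected photon
#' count is `background + F0 * relative fluorescence * bleach(t) *
#' illumination gate`, where `F0` is the membrane (or cytosol) baseline
#' scaled quadratically with power density, and the realised counts are
#' Poisson draws (16-bit clipped). Each cell is illuminated by a top-hat
#' spot of the configured FWHM centred on its soma. Bit-identical for a
#' fixed seed.
#'
#' @param cells a [cell_model()] or list of them; all centroids must lie
#'   inside the field of view.
#' @param protocol a [protocol_spec][make_protocol].
#' @param illum an [illumination_spec()].
#' @param acq an [acquisition_config()].
#' @param seed integer master seed; shot noise, speckle and any protocol
#'   randomness derive from named sub-streams.
#' @param background expected background photons per pixel per frame.
#' @param speckle_sdlog optional log-normal sd of a static multiplicative
#'   speckle gain field (0 disables; emulates holographic spots).
#' @return List with `movie` (class `sv_movie`: `counts` T x rows x cols,
#'   `times_ms`, plus the acquisition metadata) and `truth` (ground truth:
#'   per-cell spike times, command waveform, bleach/recovery fractions,
#'   per-cell membrane masks, expected baseline `f0_eff`, seed).
#' @export
render_movie <- function(cells, protocol, illum, acq, seed = 1,
                         background = 2, speckle_sdlog = 0) {
  if (inherits(cells, "cell_model")) cells <- list(cells)
  stopifnot(all(vapply(cells, inherits, TRUE, "cell_model")),
            inherits(protocol, "protocol_spec"),
            inherits(illum, "illumination_spec"),
            inherits(acq, "acquisition_config"))
  nr <- acq$roi_shape[1]
  nc <- acq$roi_shape[2]
  fov_x <- nc * acq$pixel_size
  fov_y <- nr * acq$pixel_size
  for (cl in cells) {
    if (cl$x < 0 || cl$x > fov_x || cl$y < 0 || cl$y > fov_y)
      stop("cell centroid (", cl$x, ", ", cl$y, ") outside the field of view")
  }
  n_frames <- floor(protocol$duration_ms * acq$frame_rate / 1000)
  if (n_frames <= 0) stop("non-positive frame count")
  t_frame <- (seq_len(n_frames) - 1) * 1000 / acq$frame_rate

  # pixel coordinate grids (um), pixel centres, row-major frames
  px_x <- (seq_len(nc) - 0.5) * acq$pixel_size
  px_y <- (seq_len(nr) - 0.5) * acq$pixel_size
  X <- matrix(px_x, nr, nc, byrow = TRUE)
  Y <- matrix(px_y, nr, nc)

  epochs <- if (!is.null(illum$schedule)) illum$schedule else
    protocol$illumination_epochs_ms
  power_ratio <- illum$power_density / illum$reference_power_density
  gain2 <- power_ratio^2   # two-photon: F0 quadratic in power density

  # temporal factors on the fine grid, averaged over each exposure window
  frame_average <- function(x_fine) {
    dt <- 1000 / protocol$fs
    idx_on <- pmin(length(x_fine),
                   pmax(1, floor(t_frame / dt) + 1))
    n_in <- max(1, round(acq$exposure_ms / dt))
    vapply(idx_on, function(i0)
      mean(x_fine[i0:min(length(x_fine), i0 + n_in - 1)]), numeric(1))
  }
  gate_fine <- rep(0, length(protocol$time_ms))
  for (i in seq_len(nrow(epochs))) {
    gate_fine[protocol$time_ms >= epochs[i, 1] &
              protocol$time_ms < epochs[i, 2]] <- 1
  }
  gate_t <- frame_average(gate_fine)
  bleach_t <- frame_average(
    bleach_profile(protocol$time_ms / 1000, epochs / 1000,
                   power_ratio = power_ratio))

  expected <- matrix(background, n_frames, nr * nc)
  masks <- vector("list", length(cells))
  for (ci in seq_along(cells)) {
    cl <- cells[[ci]]
    r_out <- cl$soma_diameter / 2
    r_in <- r_out - cl$membrane_width
    d <- sqrt((X - cl$x)^2 + (Y - cl$y)^2)
    annulus <- d <= r_out & d > r_in
    interior <- d <= r_in
    spot <- d <= illum$spot_fwhm / 2
    masks[[ci]] <- which(annulus)
    rel <- voltage_to_fluorescence(protocol, cl)$rel_f
    rel_t <- frame_average(rel)
    base <- matrix(0, nr, nc)
    base[annulus & spot] <- cl$f0 * gain2
    base[interior & spot] <- cl$f0 * gain2 * cl$cytosol_fraction
    if (speckle_sdlog > 0) {
      set.seed(substream_seed(seed, paste0("speckle", ci)))
      base <- base * matrix(stats::rlnorm(nr * nc, -speckle_sdlog^2 / 2,
                                          speckle_sdlog), nr, nc)
    }
    temporal <- rel_t * bleach_t * gate_t
    nz <- which(as.vector(base) > 0)
    if (length(nz)) {
      expected[, nz] <- expected[, nz] +
        tcrossprod(temporal, as.vector(base)[nz])
    }
  }

  set.seed(substream_seed(seed, "shot"))
  counts <- array(stats::rpois(length(expected), expected),
                  dim = c(n_frames, nr, nc))
  counts[counts > 2^acq$bit_depth - 1] <- 2^acq$bit_depth - 1

  movie <- structure(list(counts = counts, times_ms = t_frame,
                          frame_rate = acq$frame_rate,
                          pixel_size = acq$pixel_size,
                          exposure_ms = acq$exposure_ms,
                          bit_depth = acq$bit_depth),
                     class = "sv_movie")
  truth <- list(
    spike_times_ms = lapply(cells, function(cl) protocol$spike_times_ms),
    waveform_mV = protocol$waveform_mV,
    time_ms = protocol$time_ms,
    illumination_epochs_ms = epochs,
    bleach_end_fraction = 0.80, recovery_fraction = 0.97,
    membrane_masks = masks,
    f0_eff = vapply(cells, function(cl) cl$f0 * gain2, numeric(1)),
    background = background, cells = cells, seed = seed)
  list(movie = movie, truth = truth)
}

#' @export
print.sv_movie <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<sv_movie> %d frames of %d x %d px @ %g Hz (%.4g um/px)\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_size))
  invisible(x)
}
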