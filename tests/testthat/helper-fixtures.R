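# shared fixtures and independent oracles, built in code at test time

# wrap a T x h x w count array as an ROI object
as_roi <- function(counts, rate = 100, pixel_size = 0.65) {
  d <- dim(counts)
  structure(list(counts = counts, origin = c(row = 1, col = 1),
                 centroid_um = c(d[3], d[2]) * pixel_size / 2,
                 pixel_size = pixel_size,
                 times_ms = (seq_len(d[1]) - 1) * 1000 / rate,
                 frame_rate = rate),
            class = "sv_roi")
}

# ROI built from a frames x pixels matrix
mat_roi <- function(m, h, w, rate = 100, pixel_size = 0.65) {
  as_roi(array(m, c(nrow(m), h, w)), rate = rate, pixel_size = pixel_size)
}

# render a single-cell recording and return the movie as an ROI plus truth
render_recording <- function(protocol_id = 1, frame_rate = 100,
                             power_density = 0.88, f0 = 60,
                             background = 2, seed = 1, roi_px = 32,
                             pixel_size = 0.65, schedule = NULL,
                             protocol_params = list(), spot_fwhm = 12,
                             tau_decay_ms = 2) {
  acq <- acquisition_config(frame_rate = frame_rate,
                            pixel_size = pixel_size,
                            roi_shape = c(roi_px, roi_px))
  fov <- roi_px * pixel_size
  cell <- cell_model(x = fov / 2, y = fov / 2, f0 = f0,
                     tau_decay_ms = tau_decay_ms)
  prot <- make_protocol(protocol_id, params = protocol_params, seed = seed)
  illum <- illumination_spec(spot_fwhm = spot_fwhm,
                             power_density = power_density,
                             reference_power_density = 0.88,
                             schedule = schedule)
  sim <- render_movie(cell, prot, illum, acq, seed = seed,
                      background = background)
  list(roi = as_roi(sim$movie$counts, rate = frame_rate,
                    pixel_size = pixel_size),
       truth = sim$truth, protocol = prot, cell = cell, movie = sim$movie)
}

# SNR of the strobed voltage-step recording at one power density:
# render, weight, and for each illumination epoch remove the (linear,
# within-epoch) bleach trend from the baseline samples before measuring
# amplitude and noise
p2_snr <- function(power_density, seed) {
  rec <- render_recording(protocol_id = 2, frame_rate = 500,
                          power_density = power_density, f0 = 60,
                          seed = seed)
  mask <- initial_segment(rec$roi)
  w <- pixel_weights(rec$roi, mask)
  tr <- extract_trace(rec$roi, w)
  ep <- rec$protocol$illumination_epochs_ms
  amps <- c()
  resid <- c()
  for (i in seq_len(nrow(ep))) {
    idx <- which(tr$time_ms >= ep[i, 1] & tr$time_ms < ep[i, 2])
    rel_t <- tr$time_ms[idx] - ep[i, 1]
    y <- tr$raw[idx]
    base <- which(rel_t < 45 | (rel_t >= 165 & rel_t < 200))
    sig <- which(rel_t >= 60 & rel_t < 145)
    fit <- lm(y[base] ~ rel_t[base])
    pred <- coef(fit)[1] + coef(fit)[2] * rel_t
    dffv <- 100 * (pred - y) / mean(pred[base])
    amps <- c(amps, mean(dffv[sig]))
    resid <- c(resid, dffv[base])
  }
  mean(amps) / sd(resid)
}

# synthetic -%dF/F0 trace with unit-amplitude biexponential events at
# given times, scaled to `amp`, plus white noise
event_trace <- function(event_ms, rate, duration_ms, amp = 10,
                        noise_sd = 1, tau_r = 1, tau_d = 2, seed = 1) {
  set.seed(seed)
  n <- floor(duration_ms * rate / 1000)
  t_ms <- (seq_len(n) - 1) * 1000 / rate
  x <- rnorm(n, 0, noise_sd)
  tk <- seq(0, 8 * tau_d, by = 1000 / rate)
  k <- exp(-tk / tau_d) - exp(-tk / tau_r)
  k <- k / max(k)
  amp <- rep_len(amp, length(event_ms))
  for (e in seq_along(event_ms)) {
    i0 <- which.min(abs(t_ms - event_ms[e]))
    idx <- i0:min(n, i0 + length(k) - 1)
    x[idx] <- x[idx] + amp[e] * k[seq_along(idx)]
  }
  list(x = x, t_ms = t_ms, rate = rate)
}

# exhaustive maximum bipartite matching (Kuhn's augmenting paths) between
# detected and truth times within a tolerance: the optimal-assignment
# oracle for match_events
oracle_match_count <- function(detected, truth, tol) {
  adj <- lapply(seq_along(detected), function(i)
    which(abs(truth - detected[i]) <= tol))
  match_t <- rep(0L, length(truth))
  n <- 0L
  for (i in seq_along(detected)) {
    seen <- rep(FALSE, length(truth))
    aug <- function(i) {
      for (j in adj[[i]]) {
        if (!seen[j]) {
          seen[j] <<- TRUE
          if (match_t[j] == 0L || aug(match_t[j])) {
            match_t[j] <<- i
            return(TRUE)
          }
        }
      }
      FALSE
    }
    if (aug(i)) n <- n + 1L
  }
  n
}

# explicit finite-difference solver of the cylindrical heat equation with
# the same Gaussian-beam column source; independent oracle for the
# Green's-function quadrature
fd_heat_centre <- function(medium, spot, t_end = 0.1, hr = 5e-6,
                           hz = 10e-6, r_max = 400e-6, z_span = 1200e-6) {
  D <- medium$D
  rho_c <- medium$rho * medium$specific_heat
  h <- spot$depth * 1e-6
  nr <- round(r_max / hr)
  nz <- round(z_span / hz)
  r <- (seq_len(nr) - 0.5) * hr
  z <- h + (seq_len(nz) - nz / 2) * hz
  sigma0 <- spot$fwhm_lateral * 1e-6 / (2 * sqrt(2 * log(2)))
  sig <- scanvolt:::beam_sigma(z, h, sigma0, spot$wavelength * 1e-9)
  P <- spot$power * 1e-3
  Q <- outer(r, seq_along(z), function(ri, j)
    medium$mu_a * P * exp(-ri^2 / (2 * sig[j]^2)) / (2 * pi * sig[j]^2))
  # normalise the discrete radial mass of each slice to mu_a * P exactly
  mass <- colSums(Q * 2 * pi * r * hr)
  Q <- sweep(Q, 2, (medium$mu_a * P) / mass, "*")
  dt <- 0.45 * min(hr, hz)^2 / (4 * D)
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps
  Tm <- matrix(0, nr, nz)
  rp <- r + hr / 2
  rm <- r - hr / 2
  for (s in seq_len(nsteps)) {
    Tp <- rbind(Tm[-1, ], 0)
    Tmn <- rbind(Tm[1, ], Tm[-nr, ])   # rm[1] = 0: axis term vanishes
    lap_r <- (rp * (Tp - Tm) - rm * (Tm - Tmn)) / (r * hr^2)
    Tzp <- cbind(Tm[, -1], 0)
    Tzm <- cbind(0, Tm[, -nz])
    lap_z <- (Tzp - 2 * Tm + Tzm) / hz^2
    Tm <- Tm + dt * (D * (lap_r + lap_z) + Q / rho_c)
  }
  list(dT = Tm[1, nz / 2], r_um = r[1] * 1e6,
       dT_off = Tm[4, nz / 2], r_off_um = r[4] * 1e6)
}
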