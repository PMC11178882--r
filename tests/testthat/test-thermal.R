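# Green's-function heating model: closed-form limits, finite-difference
# oracle, boundary construction, strobing, multi-target superposition,
# scattering engine

test_that("medium constants are validated and self-consistent", {
  m <- thermal_medium()
  expect_equal(m$D, m$kappa / (m$rho * m$specific_heat))
  expect_error(thermal_medium(g = 1.2), "anisotropy")
  expect_error(thermal_medium(kappa = -1))
})

test_that("energy bookkeeping of the absorbed source closes", {
  m <- thermal_medium()
  sp <- heat_spot(depth = 300, power = 75, fwhm_lateral = 12)
  f <- absorbed_source_field(sp, m, z_max = 4000)
  # without scattering the whole column carries mu_a * P per metre
  expect_equal(absorbed_power(f), m$mu_a * 75e-3 * 4000e-6,
               tolerance = 1e-3)
  fs <- absorbed_source_field(sp, m, scattering = TRUE, z_max = 4000)
  expect_equal(absorbed_power(fs),
               m$mu_a * attr(fs, "power_in") * 4000e-6,
               tolerance = 1e-3)
  expect_error(heat_spot(fwhm_lateral = 0), "fwhm")
})

test_that("scattering power compensation implements both conventions", {
  expect_equal(scattering_power_factor(150, 166), exp(166 / 150))
  expect_equal(scattering_power_factor(150, 166,
                                       convention = "beer_lambert"),
               exp(150 / 166))
  expect_equal(scattering_power_factor(0, 166, "beer_lambert"), 1)
  expect_equal(scattering_power_factor(0, 166, "reference"), 1)
})

test_that("zero power gives zero temperature rise, and dT(0) = 0", {
  m <- thermal_medium()
  sp0 <- heat_spot(depth = 300, power = 0)
  expect_equal(peak_delta_T(sp0, m), 0)
  sp <- heat_spot(depth = 300, power = 75)
  expect_equal(delta_T(sp, m, data.frame(x = 0, y = 0, z = 300),
                       0)$dT[1, 1], 0)
})

test_that("steady state approaches the point-source conduction limit", {
  m <- thermal_medium()
  P_abs <- 1e-3
  f <- data.frame(z_lo = 1999e-6, z_hi = 2001e-6, q = P_abs / 2e-6,
                  sigma = 1e-6)
  attr(f, "x") <- 0; attr(f, "y") <- 0
  for (r_um in c(20, 50)) {
    num <- scanvolt:::.dT_column(f, m, r_um * 1e-6, 0, 2000e-6, 300,
                                 surface = FALSE, n_t = 400)
    ana <- P_abs / (4 * pi * m$kappa * r_um * 1e-6)
    expect_equal(num, ana, tolerance = 0.02)
  }
})

test_that("Green's function solution agrees with a finite-difference
           oracle", {
  m <- thermal_medium()
  sp <- heat_spot(depth = 600, power = 75, fwhm_lateral = 12)
  fd <- fd_heat_centre(m, sp, t_end = 0.1)
  gr <- delta_T(sp, m, data.frame(x = fd$r_um, y = 0, z = 600), 0.1,
                surface = FALSE)$dT[1, 1]
  expect_equal(fd$dT, gr, tolerance = 0.05)
  # and a few cells off-axis, where source discretisation matters less
  gr2 <- delta_T(sp, m, data.frame(x = fd$r_off_um, y = 0, z = 600), 0.1,
                 surface = FALSE)$dT[1, 1]
  expect_equal(fd$dT_off, gr2, tolerance = 0.05)
})

test_that("the method of images pins the surface at zero and bounds the
           interior", {
  m <- thermal_medium()
  sp <- heat_spot(depth = 300, power = 75)
  surf <- delta_T(sp, m, data.frame(x = c(0, 30, 100), y = 0,
                                    z = c(0, 0, 0)), 30)
  expect_true(all(abs(surf$dT) < 1e-9))

  q <- data.frame(x = c(0, 20, 50), y = c(0, 10, -30),
                  z = c(300, 200, 400))
  bounded <- delta_T(sp, m, q, 30, surface = TRUE)$dT
  infinite <- delta_T(sp, m, q, 30, surface = FALSE)$dT
  expect_true(all(bounded <= infinite + 1e-12))

  # deep source, short time: boundary is invisible
  deep <- heat_spot(depth = 2000, power = 75)
  qd <- data.frame(x = 0, y = 0, z = 2000)
  b <- delta_T(deep, m, qd, 0.1, surface = TRUE)$dT[1, 1]
  i <- delta_T(deep, m, qd, 0.1, surface = FALSE)$dT[1, 1]
  expect_equal(b, i, tolerance = 0.01)
})

test_that("temperature rise is linear in power and monotone in time", {
  m <- thermal_medium()
  p1 <- peak_delta_T(heat_spot(depth = 300, power = 75), m)
  p2 <- peak_delta_T(heat_spot(depth = 300, power = 150), m)
  expect_equal(p2, 2 * p1, tolerance = 1e-9)

  ts <- delta_T(heat_spot(depth = 300, power = 75), m,
                data.frame(x = 0, y = 0, z = 300),
                c(0.01, 0.1, 1, 10, 30))$dT[1, ]
  expect_true(all(diff(ts) > 0))
})

test_that("strobed schedules superpose and dissipate between pulses", {
  m <- thermal_medium()
  # 99% duty cycle over 10 s converges to continuous illumination
  on <- seq(0, 9, by = 1)
  sched <- cbind(on, on + 0.99)
  sp <- heat_spot(depth = 300, power = 75, schedule = sched)
  st <- strobed_delta_T(sp, m, times = 9.98)
  cw <- delta_T(heat_spot(depth = 300, power = 75), m,
                data.frame(x = 0, y = 0, z = 300), 9.98)$dT[1, 1]
  expect_equal(st$dT, cw, tolerance = 0.01)

  # 15 ms pulses at 5 Hz: residual before each pulse is a small fraction
  # of the per-pulse peak (negligible inter-pulse cross-talk)
  on5 <- seq(0, 0.8, by = 0.2)
  sp5 <- heat_spot(depth = 300, power = 2.5,
                   schedule = cbind(on5, on5 + 0.015))
  st5 <- strobed_delta_T(sp5, m)
  expect_true(all(st5$residual_at_onset <
                    0.1 * max(st5$epoch_peaks, na.rm = TRUE)))
  # monotone accumulation: the second epoch peaks at least as high
  expect_gte(st5$epoch_peaks[2], st5$epoch_peaks[1] - 1e-12)

  expect_error(heat_spot(schedule = rbind(c(0, 2), c(1, 3))),
               "non-overlapping")
  expect_error(strobed_delta_T(heat_spot(), m), "schedule")
})

test_that("multi-target scenes superpose linearly", {
  m <- thermal_medium()
  centres <- data.frame(x = rep(150, 3), y = rep(150, 3))
  multi <- multi_target_delta_T(centres, m, power_per_target = 10,
                                depth = 300, duration = 5)
  single <- multi_target_delta_T(centres[1, ], m, power_per_target = 10,
                                 depth = 300, duration = 5)
  expect_equal(multi$dT_centre, 3 * single$dT_centre, tolerance = 1e-9)
})

test_that("beam propagation reproduces free-space diffraction and the
           configured scattering length", {
  m <- thermal_medium()
  free <- bpm_scatter(m, depth = 150, w0 = 5, grid_n = 128,
                      screens = FALSE)
  # analytic Gaussian-beam intensity radius at depth
  k <- 2 * pi * 1.33 / (1.03e-3 * 1e3 * 1e-3)  # rad/um at 1030 nm
  zR <- pi * 5^2 * 1.33 / (1030e-3)
  w_an <- 5 * sqrt(1 + (150 / zR)^2)
  prof <- free$intensity[, 64]
  w_num <- 2 * sqrt(sum(prof * free$x_um^2) / sum(prof))
  expect_equal(w_num, w_an, tolerance = 0.01)

  b1 <- bpm_scatter(m, depth = 150, seed = 5)
  b2 <- bpm_scatter(m, depth = 150, seed = 5)
  expect_identical(b1$field, b2$field)
  expect_error(bpm_scatter(m, dx = 2), "coarse")

  # ensemble ballistic decay fits exp(-z / ell_s) with ell_s within 15%
  fr <- rowMeans(vapply(1:40, function(s)
    bpm_scatter(m, depth = 150, grid_n = 128, seed = s)$ballistic$fraction,
    numeric(30)))
  z <- seq(5, 150, by = 5)
  ls_fit <- -1 / coef(lm(log(fr) ~ z))[2]
  expect_equal(unname(ls_fit), 166, tolerance = 0.15)
})

test_that("the admissible target count shrinks with depth and power", {
  m <- thermal_medium()
  # monotonicity holds under the Beer-Lambert compensation; the
  # reference exp(ell_s/ell) form shrinks with depth by construction
  n_ref <- max_targets(150, 8.3, dT_limit = 4.2, medium = m, n_cap = 20,
                       seed = 3, inflation = "beer_lambert")
  n_deeper <- max_targets(250, 8.3, dT_limit = 4.2, medium = m,
                          n_cap = 20, seed = 3,
                          inflation = "beer_lambert")
  n_hotter <- max_targets(150, 16.6, dT_limit = 4.2, medium = m,
                          n_cap = 20, seed = 3,
                          inflation = "beer_lambert")
  expect_lte(n_deeper, n_ref)
  expect_lte(n_hotter, n_ref)
  # an unbounded budget caps at the configured maximum
  n_inf <- max_targets(150, 8.3, dT_limit = 1e6, medium = m, n_cap = 6,
                       seed = 3)
  expect_equal(as.integer(n_inf), 6L)
  expect_true(isTRUE(attr(n_inf, "capped")))
  expect_message(
    n0 <- max_targets(150, 8.3, dT_limit = 1e-4, medium = m, n_cap = 4,
                      seed = 3),
    "exceeds")
  expect_equal(n0, 0L)
})
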