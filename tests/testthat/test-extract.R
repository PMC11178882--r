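# trace extraction: cropping, segmentation, pixel weighting, detrending,
# -%dF/F0, SNR, photometrics, correlation image, SBR

test_that("ROI cropping is centred, clipped and coordinate-faithful", {
  rec <- render_recording(seed = 7)
  movie <- rec$movie
  roi <- crop_roi(movie, c(10.4, 10.4), 16)
  expect_equal(dim(roi$counts)[2:3], c(16, 16))
  # centre pixel of the crop maps back to the centroid pixel
  ctr_row <- roi$origin["row"] + 8
  expect_equal(unname(ctr_row), round(10.4 / 0.65 + 0.5))

  expect_warning(crop_roi(movie, c(2, 2), 16), "clipped")
  expect_error(crop_roi(movie, c(500, 500), 16), "outside")

  set.seed(1)
  for (k in 1:100) {
    i <- sample(16, 1); j <- sample(16, 1); t <- sample(300, 1)
    expect_identical(roi$counts[t, i, j],
                     movie$counts[t, roi$origin["row"] + i - 1,
                                  roi$origin["col"] + j - 1])
  }
})

test_that("segmentation finds the responsive membrane and rejects noise", {
  rec <- render_recording(seed = 8, f0 = 60)
  mask <- initial_segment(rec$roi)
  ann <- rec$truth$membrane_masks[[1]]
  expect_gte(mean(ann %in% which(mask)), 0.8)

  noise <- mat_roi(matrix(rpois(300 * 256, 5), 300, 256), 16, 16)
  expect_error(initial_segment(noise), "no responsive cell")

  short <- mat_roi(matrix(rpois(50 * 256, 5), 50, 256), 16, 16)
  expect_error(initial_segment(short), "100 frames")

  # two cells in one ROI separated via manual sub-region hints
  acq <- acquisition_config(frame_rate = 100, pixel_size = 0.65,
                            roi_shape = c(48, 48))
  cells <- list(cell_model(x = 8, y = 15.6, f0 = 60),
                cell_model(x = 23, y = 15.6, f0 = 60))
  sim <- render_movie(cells, make_protocol(1), illumination_spec(), acq,
                      seed = 9)
  roi2 <- as_roi(sim$movie$counts)
  half <- 48 * 24
  hints <- list(seq_len(half), half + seq_len(half))
  masks <- initial_segment(roi2, hints = hints)
  expect_length(masks, 2)
  expect_true(all(which(masks[[1]]) %in% hints[[1]]))
  expect_true(all(which(masks[[2]]) %in% hints[[2]]))
  expect_gt(sum(masks[[1]]), 0)
  expect_gt(sum(masks[[2]]), 0)
})

test_that("regression weights follow signal amplitude", {
  set.seed(21)
  Tn <- 400
  sig <- 100 + 10 * sin(seq_len(Tn) / 10)
  # all pixels identical signal + iid noise: near-uniform weights
  P <- matrix(rep(sig, 64), Tn, 64) + rnorm(Tn * 64, 0, 1)
  roi <- mat_roi(P, 8, 8)
  w <- pixel_weights(roi, rep(TRUE, 64))
  wv <- as.vector(w$weights)
  expect_lt(sd(wv) / mean(wv), 0.2)

  # half signal, half noise: weight mass concentrates on signal pixels
  P2 <- cbind(matrix(rep(sig, 32), Tn, 32) + rnorm(Tn * 32, 0, 1),
              matrix(rnorm(Tn * 32, 100, 1), Tn, 32))
  roi2 <- mat_roi(P2, 8, 8)
  w2 <- pixel_weights(roi2, rep(TRUE, 64))
  expect_gte(sum(as.vector(w2$weights)[1:32]), 0.95)
  # support shrinks strictly below the mask when noise pixels exist
  expect_lt(w2$n_pixels_used, 64)

  flat <- mat_roi(matrix(100, Tn, 64), 8, 8)
  expect_error(pixel_weights(flat, rep(TRUE, 64)), "degenerate")
  expect_error(pixel_weights(roi, rep(FALSE, 64)), "empty")
})

test_that("trace extraction is a weighted mean with the expected
           identities", {
  set.seed(3)
  P <- matrix(rpois(200 * 16, 50), 200, 16)
  roi <- mat_roi(P, 4, 4)
  uni <- matrix(1 / 16, 4, 4)
  expect_equal(extract_trace(roi, uni)$raw, rowMeans(P))
  delta <- matrix(0, 4, 4); delta[2, 3] <- 1
  expect_equal(extract_trace(roi, delta)$raw, P[, 4 * 2 + 2])
  # linearity in the movie
  roi2 <- mat_roi(P + 7, 4, 4)
  roiS <- mat_roi(P + (P + 7), 4, 4)
  wts <- matrix(runif(16), 4, 4); wts <- wts / sum(wts)
  expect_equal(extract_trace(roiS, wts)$raw,
               extract_trace(roi, wts)$raw + extract_trace(roi2, wts)$raw)
  expect_error(extract_trace(roi, wts * 2), "normalised")
})

test_that("detrending removes bleach but preserves step amplitudes", {
  t_ms <- seq(0, 2999, by = 10)
  mk <- function(y) structure(list(time_ms = t_ms, raw = y, rate = 100,
                                   detrended = NULL, f0 = NULL,
                                   dff = NULL), class = "sv_trace")
  const <- suppressWarnings(detrend_trace(mk(rep(50, 300))))
  expect_equal(const$detrended, rep(50, 300))

  # pure exponential decay: flat output, residual slope < 1%/s
  y <- 100 * exp(-t_ms / 1000 / 2)
  dt <- detrend_trace(mk(y))
  sl <- coef(lm(dt$detrended ~ I(t_ms / 1000)))[2]
  expect_lt(abs(sl), 0.01 * 100)

  # bleach to 0.80 with three 100 mV steps: amplitudes recovered to 2%
  prot <- make_protocol(1)
  rel <- voltage_to_fluorescence(prot, cell_model(0, 0))$rel_f
  rel_f <- rel[seq(1, length(rel), by = 100)]          # 100 Hz frames
  bleach <- 0.7 + 0.3 * exp(-(t_ms / 1000) / (3 / log(3)))
  tr <- detrend_trace(mk(100 * rel_f * bleach))
  tr <- dff(tr, baseline = 1:40)
  for (on in c(500, 1500, 2500)) {
    plateau <- mean(tr$dff[t_ms >= on + 20 & t_ms < on + 95])
    expect_equal(plateau, 43, tolerance = 0.02)
  }
})

test_that("-%dF/F0 arithmetic and the characterised step response", {
  t_ms <- seq(0, 999, by = 10)
  mk <- function(y) structure(list(time_ms = t_ms, raw = y, rate = 100,
                                   detrended = NULL, f0 = NULL,
                                   dff = NULL), class = "sv_trace")
  flat <- dff(mk(rep(80, 100)), baseline = 1:10)
  expect_equal(flat$dff, rep(0, 100))
  y <- rep(80, 100); y[51:60] <- 40
  half <- dff(mk(y), baseline = 1:10)
  expect_equal(half$dff[55], 50)
  expect_error(dff(mk(rep(0, 100)), baseline = 1:10), "F0")

  # rendered 100 mV steps with s = 0.43 plateau at 43 +/- 2 (shot noise)
  rec <- render_recording(seed = 15, f0 = 80, background = 0)
  mask <- initial_segment(rec$roi)
  w <- pixel_weights(rec$roi, mask)
  tr <- detrend_trace(extract_trace(rec$roi, w),
                      epochs_ms = rec$protocol$illumination_epochs_ms)
  tr <- dff(tr, baseline = 1:40)
  plateau <- mean(tr$dff[rec$roi$times_ms >= 520 &
                         rec$roi$times_ms < 595])
  expect_equal(plateau, 43, tolerance = 2 / 43)
})

test_that("weighted -%dF/F0 is at least the unweighted on mixed ROIs", {
  # ROI whose mask contains responsive and non-responsive pixels
  rec <- render_recording(seed = 16, f0 = 60)
  mask <- matrix(TRUE, 32, 32)   # the whole crop, noise pixels included
  w <- pixel_weights(rec$roi, mask)
  epochs <- rec$protocol$illumination_epochs_ms
  step <- rec$roi$times_ms >= 520 & rec$roi$times_ms < 595
  amp <- function(tr) {
    tr <- dff(detrend_trace(tr, epochs_ms = epochs), baseline = 1:40)
    mean(tr$dff[step])
  }
  a_w <- amp(extract_trace(rec$roi, w))
  a_u <- amp(extract_trace(rec$roi, pixels = mask))
  expect_gte(a_w, a_u)
  expect_lt(w$n_pixels_used, sum(mask))
})

test_that("snr follows its definition and guards its inputs", {
  x <- c(rep(0, 50), rep(5, 20))
  x[1:50] <- x[1:50] + rep(c(-1, 1), 25)   # baseline sd ~ 1
  s <- snr(x, signal = 51:70, baseline = 1:50)
  expect_equal(s, 5 / sd(x[1:50]), tolerance = 1e-10)
  expect_error(snr(rep(c(0, 5), each = 10), 11:20, 1:10), "noise-free")
  expect_error(snr(x, 1:10, 5:20), "disjoint")
})

test_that("photometric fractions are near one without bleach", {
  set.seed(5)
  tr <- structure(list(raw = rnorm(1000, 100, 1)), class = "sv_trace")
  expect_equal(photostability(tr, 1:1000), 1, tolerance = 0.01)
  expect_equal(photorecovery(tr, 1:500, 501:1000), 1, tolerance = 0.01)
  expect_error(photostability(tr, 1:10), "too short")
})

test_that("correlation image peaks on the cell with the spot-sized
           footprint", {
  rec <- render_recording(seed = 17, frame_rate = 500, f0 = 40)
  mask <- initial_segment(rec$roi)
  w <- pixel_weights(rec$roi, mask)
  ref <- extract_trace(rec$roi, w)$raw
  img <- correlation_image(rec$roi, ref)
  fwhm <- correlation_fwhm(img, rec$roi$pixel_size)
  expect_lt(abs(fwhm - 12), 3)
  # doubling the pixel size doubles the reported width
  expect_equal(correlation_fwhm(img, 2 * rec$roi$pixel_size), 2 * fwhm)

  set.seed(6)
  noise <- mat_roi(matrix(rpois(600 * 256, 20), 600, 256), 16, 16,
                   rate = 500)
  imgn <- correlation_image(noise, rnorm(600))
  expect_lt(quantile(abs(imgn), 0.95), 0.2)
  expect_error(correlation_image(noise, rep(1, 600)), "constant")
  few <- mat_roi(matrix(rpois(200 * 16, 20), 200, 16), 4, 4)
  expect_error(correlation_image(few, rnorm(200)), "500 frames")
})

test_that("SBR scales inversely with background crosstalk", {
  set.seed(31)
  Tn <- 300
  sig <- rep(0, Tn); sig[101:200] <- 30          # response amplitude
  base <- 100
  mk_counts <- function(g) {
    P <- cbind(
      matrix(rep(base + sig, 32), Tn, 32) + rnorm(Tn * 32),
      matrix(rep(base + g * sig, 32), Tn, 32) + rnorm(Tn * 32))
    mat_roi(P, 8, 8)
  }
  support <- c(rep(TRUE, 32), rep(FALSE, 32))
  bgm <- !support
  ratios <- vapply(c(0.1, 0.2, 0.4), function(g) {
    roi <- mk_counts(g)
    w <- pixel_weights(roi, support)
    sbr(roi, w, matrix(bgm, 8, 8), signal = 101:200,
        baseline = 1:100)$sbr
  }, numeric(1))
  expect_equal(ratios[1] / ratios[2], 2, tolerance = 0.1)
  expect_equal(ratios[2] / ratios[3], 2, tolerance = 0.1)

  # identical movies give identical SBR
  roi <- mk_counts(0.2)
  w <- pixel_weights(roi, support)
  s1 <- sbr(roi, w, matrix(bgm, 8, 8), 101:200, 1:100)$sbr
  s2 <- sbr(roi, w, matrix(bgm, 8, 8), 101:200, 1:100)$sbr
  expect_identical(s1, s2)

  # flat background: capped and flagged
  Pz <- cbind(matrix(rep(base + sig, 32), Tn, 32) + rnorm(Tn * 32),
              matrix(base, Tn, 32))
  roiz <- mat_roi(Pz, 8, 8)
  wz <- pixel_weights(roiz, support)
  expect_warning(res <- sbr(roiz, wz, matrix(bgm, 8, 8), 101:200, 1:100),
                 "capped")
  expect_true(res$capped)
})
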