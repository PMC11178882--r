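# Trace extraction: from a movie plus target centroids to weighted
# single-cell fluorescence traces and per-recording metrics (-%dF/F0, SNR,
# photostability, photorecovery, correlation image, SBR).
#
# The weighting follows the regression scheme used for camera-based voltage
# imaging: each pixel's trace is regressed against the mean trace of the
# segmented pixels and the non-negative slopes, renormalised, are the pixel
# weights. Pixels that do not co-vary with the cell get zero weight, which
# concentrates the support on the membrane annulus.

roi_matrix <- function(roi) {
  d <- dim(roi$counts)
  matrix(roi$counts, d[1], d[2] * d[3])
}

#' Crop a rectangular region of interest around a target centroid
#'
#' @param movie an `sv_movie` (or list with `counts` T x rows x cols and
#'   `pixel_size`, `times_ms`, `frame_rate`).
#' @param centroid c(x, y) in um, FOV coordinates.
#' @param size c(rows, cols) of the crop in pixels (scalar for square).
#' @return List of class `sv_roi`: `counts` (T x h x w), `origin` (1-based
#'   row/col of the crop's first pixel in the movie), `centroid_um`,
#'   `pixel_size`, `times_ms`, `frame_rate`. Crops are clipped at the movie
#'   border with a warning.
#' @export
crop_roi <- function(movie, centroid, size = 64) {
  d <- dim(movie$counts)
  if (length(size) == 1) size <- c(size, size)
  col_c <- round(centroid[1] / movie$pixel_size + 0.5)
  row_c <- round(centroid[2] / movie$pixel_size + 0.5)
  if (row_c < 1 || row_c > d[2] || col_c < 1 || col_c > d[3])
    stop("centroid lies outside the movie")
  r0 <- row_c - floor(size[1] / 2)
  c0 <- col_c - floor(size[2] / 2)
  r1 <- r0 + size[1] - 1
  c1 <- c0 + size[2] - 1
  if (r0 < 1 || c0 < 1 || r1 > d[2] || c1 > d[3]) {
    warning("crop clipped at the movie border")
    r0 <- max(r0, 1); c0 <- max(c0, 1)
    r1 <- min(r1, d[2]); c1 <- min(c1, d[3])
  }
  structure(list(counts = movie$counts[, r0:r1, c0:c1, drop = FALSE],
                 origin = c(row = r0, col = c0),
                 centroid_um = centroid, pixel_size = movie$pixel_size,
                 times_ms = movie$times_ms, frame_rate = movie$frame_rate),
            class = "sv_roi")
}

#' Initial segmentation of responsive pixels
#'
#' Scores every pixel by the Pearson correlation of its trace with the
#' ROI-mean trace and keeps pixels above an adaptive threshold (half the
#' top-percentile score, floored at the chance level for the trace length).
#' Errors with "no responsive cell" when no pixel rises above chance.
#'
#' @param roi an `sv_roi` with at least 100 frames.
#' @param hints optional list of pixel-index vectors (column-major within
#'   the ROI) restricting segmentation to manually identified sub-regions,
#'   e.g. when two cells share a crop; a list of masks is then returned.
#' @param floor_factor multiplier on the `1/sqrt(T)` chance level used as
#'   the significance floor.
#' @return Logical h x w mask (or list of masks when `hints` is given).
#' @export
initial_segment <- function(roi, hints = NULL, floor_factor = 4) {
  stopifnot(inherits(roi, "sv_roi"))
  P <- roi_matrix(roi)
  if (nrow(P) < 100) stop("need at least 100 frames to segment")
  seg_one <- function(cols) {
    ref <- rowMeans(P[, cols, drop = FALSE])
    if (stats::sd(ref) == 0) stop("no responsive cell (constant region)")
    r <- suppressWarnings(as.vector(stats::cor(P[, cols, drop = FALSE], ref)))
    r[is.na(r)] <- 0
    s0 <- floor_factor / sqrt(nrow(P))
    top <- stats::quantile(r, 0.99, names = FALSE)
    if (top < s0) stop("no responsive cell")
    keep <- r >= max(s0, top / 2)
    m <- rep(FALSE, ncol(P))
    m[cols[keep]] <- TRUE
    matrix(m, dim(roi$counts)[2], dim(roi$counts)[3])
  }
  if (is.null(hints)) seg_one(seq_len(ncol(P))) else lapply(hints, seg_one)
}

#' Regression-based pixel weights
#'
#' Regresses each pixel trace (ordinary least squares, intercept included)
#' on the mean trace of the segmented pixels; weights are the non-negative
#' slopes renormalised to unit sum. Pixels with non-positive slope are
#' excluded from the support.
#'
#' @param roi an `sv_roi`.
#' @param mask logical h x w segmentation mask (non-empty).
#' @return List of class `pixel_weights`: `weights` (h x w, sums to 1),
#'   `support` (logical h x w), `n_pixels_used`.
#' @export
pixel_weights <- function(roi, mask) {
  stopifnot(inherits(roi, "sv_roi"))
  mask <- as.logical(mask)
  if (!any(mask)) stop("segmentation mask is empty")
  P <- roi_matrix(roi)
  ref <- rowMeans(P[, mask, drop = FALSE])
  v <- stats::var(ref)
  if (v == 0) stop("degenerate (constant) reference trace")
  rc <- ref - mean(ref)
  slope <- rep(0, ncol(P))
  slope[mask] <- as.vector(crossprod(P[, mask, drop = FALSE], rc)) /
    sum(rc^2)
  w <- pmax(slope, 0)
  if (sum(w) == 0) stop("no pixel regresses positively on the reference")
  w <- w / sum(w)
  d <- dim(roi$counts)
  structure(list(weights = matrix(w, d[2], d[3]),
                 support = matrix(w > 0, d[2], d[3]),
                 n_pixels_used = sum(w > 0)),
            class = "pixel_weights")
}

#' Extract a fluorescence trace from an ROI
#'
#' Weighted sum of pixel traces. With `weights = NULL` the unweighted mean
#' over `pixels` (default: all pixels) is returned, which is the comparison
#' baseline for the weighting scheme.
#'
#' @param roi an `sv_roi`.
#' @param weights a [pixel_weights()] object, a numeric h x w matrix
#'   summing to 1, or `NULL`.
#' @param pixels logical mask for the unweighted variant.
#' @return Object of class `sv_trace`: list with `time_ms`, `raw`, `rate`;
#'   `detrended`, `f0` and `dff` are filled by [detrend_trace()] and
#'   [dff()].
#' @export
extract_trace <- function(roi, weights = NULL, pixels = NULL) {
  stopifnot(inherits(roi, "sv_roi"))
  P <- roi_matrix(roi)
  if (is.null(weights)) {
    sel <- if (is.null(pixels)) rep(TRUE, ncol(P)) else as.logical(pixels)
    tr <- rowMeans(P[, sel, drop = FALSE])
  } else {
    w <- if (inherits(weights, "pixel_weights")) weights$weights else weights
    w <- as.vector(w)
    if (abs(sum(w) - 1) > 1e-6) stop("weights must be normalised to sum 1")
    tr <- as.vector(P %*% w)
  }
  structure(list(time_ms = roi$times_ms, raw = tr, rate = roi$frame_rate,
                 detrended = NULL, f0 = NULL, dff = NULL),
            class = "sv_trace")
}

# robust bi-exponential-with-offset fit of a decaying baseline;
# returns fitted trend or NULL on failure. Fast transients (dips of a
# negative-going indicator) are iteratively down-weighted so they are not
# absorbed into the trend. A single exponential seeds the bi-exponential
# and stands in for it when the richer fit does not converge.
fit_biexp <- function(t_s, y) {
  span <- max(t_s) - min(t_s)
  if (span <= 0) return(NULL)
  dat <- data.frame(t = t_s - min(t_s), y = y)
  q <- stats::quantile(y, c(0.1, 0.9), names = FALSE)
  wts <- rep(1, length(y))
  robust_fit <- function(form, st, lower) {
    fit <- NULL
    for (it in 1:3) {
      fit <- tryCatch(
        minpack.lm::nlsLM(form, data = dat, start = st, weights = wts,
                          lower = lower,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      res <- dat$y - stats::predict(fit, newdata = dat)
      s <- max(stats::mad(res), 1e-12)
      wts <<- ifelse(res < -2.5 * s, 1e-3, 1)
      st <- as.list(stats::coef(fit))
    }
    fit
  }
  f1 <- robust_fit(y ~ c0 + a1 * exp(-t / t1),
                   list(c0 = q[1], a1 = max(q[2] - q[1], 1e-9),
                        t1 = span / 3),
                   lower = c(0, 0, span / 1000))
  if (is.null(f1)) return(NULL)
  cf <- stats::coef(f1)
  f2 <- robust_fit(y ~ c0 + a1 * exp(-t / t1) + a2 * exp(-t / t2),
                   list(c0 = cf[["c0"]], a1 = 0.8 * cf[["a1"]] + 1e-9,
                        t1 = cf[["t1"]], a2 = 0.2 * cf[["a1"]] + 1e-9,
                        t2 = cf[["t1"]] / 5),
                   lower = c(0, 0, span / 1000, 0, span / 1000))
  best <- if (!is.null(f2)) f2 else f1
  stats::predict(best, newdata = dat)
}

#' Remove the slow photobleaching trend from a trace
#'
#' Fits a bi-exponential-with-offset to the illuminated portion of the
#' trace (robustly, so fast voltage transients are not absorbed) and
#' divides it out, preserving step amplitudes. Falls back to a running
#' 20th-percentile baseline (1 s window) with a warning when the fit does
#' not converge. With several illumination epochs each epoch is detrended
#' independently. Samples outside the illumination epochs are left
#' untouched.
#'
#' @param trace an `sv_trace`.
#' @param epochs_ms optional (on, off) illumination epochs, ms; default one
#'   epoch spanning the trace.
#' @param method `"biexp"` or `"percentile"`.
#' @param window_s window of the running-percentile fallback, s.
#' @return The trace with `$detrended` filled (same scale as `raw` at the
#'   epoch start).
#' @export
detrend_trace <- function(trace, epochs_ms = NULL,
                          method = c("biexp", "percentile"),
                          window_s = 1) {
  stopifnot(inherits(trace, "sv_trace"))
  method <- match.arg(method)
  t_ms <- trace$time_ms
  if (is.null(epochs_ms))
    epochs_ms <- matrix(c(min(t_ms), max(t_ms) + 1), 1)
  epochs_ms <- as.matrix(epochs_ms)
  out <- trace$raw
  for (i in seq_len(nrow(epochs_ms))) {
    sel <- which(t_ms >= epochs_ms[i, 1] & t_ms < epochs_ms[i, 2])
    if (length(sel) < 10) next
    y <- trace$raw[sel]
    trend <- NULL
    if (method == "biexp") {
      trend <- fit_biexp(t_ms[sel] / 1000, y)
      if (is.null(trend)) {
        warning("bi-exponential detrend did not converge; ",
                "falling back to running percentile")
      }
    }
    if (is.null(trend)) {
      k <- max(5, round(window_s * trace$rate))
      if (k %% 2 == 0) k <- k + 1
      trend <- zoo::rollapply(y, width = k,
                              FUN = stats::quantile, probs = 0.2,
                              partial = TRUE, align = "center")
      # smooth the percentile track so steps are not imprinted
      trend <- stats::filter(trend, rep(1 / k, k), sides = 2)
      trend <- zoo::na.fill(zoo::zoo(as.numeric(trend)), "extend")
      trend <- as.numeric(trend)
    }
    if (any(trend <= 0)) trend <- pmax(trend, 1e-9)
    out[sel] <- y / (trend / trend[1])
  }
  trace$detrended <- out
  trace
}

#' Relative fluorescence change (-%dF/F0)
#'
#' `dff = 100 * (F0 - F) / F0` on the detrended trace, with `F0` the mean
#' over the baseline window; the sign convention makes depolarisations of a
#' negative-going indicator positive.
#'
#' @param trace an `sv_trace`; if not yet detrended the raw trace is used.
#' @param baseline frame indices of the baseline window.
#' @return The trace with `$f0` and `$dff` filled.
#' @export
dff <- function(trace, baseline) {
  stopifnot(inherits(trace, "sv_trace"))
  f <- if (!is.null(trace$detrended)) trace$detrended else trace$raw
  if (any(baseline < 1) || any(baseline > length(f)))
    stop("baseline window outside the trace")
  f0 <- mean(f[baseline])
  if (f0 <= 0) stop("non-positive baseline F0")
  trace$f0 <- f0
  trace$dff <- 100 * (f0 - f) / f0
  trace
}

#' Signal-to-noise ratio of a response
#'
#' Signal amplitude (mean over the signal window minus mean over the
#' baseline window, on the -%dF/F0 scale) divided by the standard deviation
#' of the baseline.
#'
#' @param x numeric -%dF/F0 trace (or an `sv_trace` with `$dff`).
#' @param signal,baseline disjoint, non-empty frame-index windows.
#' @return SNR (dimensionless).
#' @export
snr <- function(x, signal, baseline) {
  if (inherits(x, "sv_trace")) x <- x$dff
  if (!length(signal) || !length(baseline)) stop("empty window")
  if (length(intersect(signal, baseline))) stop("windows must be disjoint")
  s <- stats::sd(x[baseline])
  if (s == 0) stop("noise-free input (zero baseline variance)")
  (mean(x[signal]) - mean(x[baseline])) / s
}

#' Photostability over an illumination epoch
#'
#' Fraction of the initial fluorescence retained at the end of an epoch:
#' mean of the final 5% of illuminated samples over the mean of the first
#' 5%.
#'
#' @param trace an `sv_trace` (raw trace is used).
#' @param epoch frame indices of the illumination epoch (>= 20 samples).
#' @return Fraction in `[0, ~1]`.
#' @export
photostability <- function(trace, epoch) {
  f <- if (inherits(trace, "sv_trace")) trace$raw else trace
  if (length(epoch) < 20) stop("epoch too short (< 20 samples)")
  k <- max(1, round(0.05 * length(epoch)))
  mean(f[utils::tail(epoch, k)]) / mean(f[utils::head(epoch, k)])
}

#' Photorecovery across a dark interval
#'
#' Fluorescence at the start of an illumination epoch relative to the start
#' of the previous epoch (first 5% of samples of each).
#'
#' @param trace an `sv_trace` (raw trace is used).
#' @param epoch_prev,epoch_next frame indices of consecutive illumination
#'   epochs (>= 20 samples each).
#' @return Fraction in `[0, ~1]`.
#' @export
photorecovery <- function(trace, epoch_prev, epoch_next) {
  f <- if (inherits(trace, "sv_trace")) trace$raw else trace
  if (length(epoch_prev) < 20 || length(epoch_next) < 20)
    stop("epoch too short (< 20 samples)")
  k1 <- max(1, round(0.05 * length(epoch_prev)))
  k2 <- max(1, round(0.05 * length(epoch_next)))
  mean(f[utils::head(epoch_next, k2)]) / mean(f[utils::head(epoch_prev, k1)])
}

#' Correlation image of an ROI
#'
#' Pearson correlation of every pixel trace with a reference trace.
#'
#' @param roi an `sv_roi` with at least 500 frames.
#' @param ref reference trace (e.g. the weighted cell trace).
#' @return h x w matrix of correlations.
#' @export
correlation_image <- function(roi, ref) {
  stopifnot(inherits(roi, "sv_roi"))
  if (dim(roi$counts)[1] < 500)
    stop("need at least 500 frames for a correlation image")
  if (stats::sd(ref) == 0) stop("constant reference trace")
  P <- roi_matrix(roi)
  r <- suppressWarnings(as.vector(stats::cor(P, ref)))
  r[is.na(r)] <- 0
  matrix(r, dim(roi$counts)[2], dim(roi$counts)[3])
}

#' FWHM of the radially averaged correlation image
#'
#' Radially averages the correlation image about its (positive-weighted)
#' centroid and reports the full width at half of the central value, in um,
#' with linear interpolation at the half-maximum crossing.
#'
#' @param img correlation image (matrix).
#' @param pixel_size um per pixel.
#' @param centre optional c(row, col) centre; default the centroid of the
#'   positive part of the image.
#' @return FWHM in um (NA if the profile never falls below half maximum).
#' @export
correlation_fwhm <- function(img, pixel_size, centre = NULL) {
  pos <- pmax(img, 0)
  if (is.null(centre)) {
    rw <- row(img); cw <- col(img)
    centre <- c(sum(rw * pos) / sum(pos), sum(cw * pos) / sum(pos))
  }
  d <- sqrt((row(img) - centre[1])^2 + (col(img) - centre[2])^2)
  bins <- floor(d)
  prof <- tapply(as.vector(img), as.vector(bins), mean)
  rr <- as.numeric(names(prof)) + 0.5
  half <- prof[[1]] / 2
  below <- which(prof < half)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(rr[1] * 2 * pixel_size)
  r_half <- rr[i - 1] + (rr[i] - rr[i - 1]) *
    (prof[[i - 1]] - half) / (prof[[i - 1]] - prof[[i]])
  2 * r_half * pixel_size
}

#' Signal-to-background ratio
#'
#' Ratio of the response amplitude of the in-support (weighted) trace to
#' the response amplitude of the mean trace over a background region, both
#' measured as |mean over the signal window - mean over the baseline
#' window| of the raw counts. The definition is recorded in the result.
#'
#' @param roi an `sv_roi`.
#' @param weights a [pixel_weights()].
#' @param background logical h x w mask, disjoint from the support.
#' @param signal,baseline frame-index windows.
#' @return List with `sbr`, `capped` (TRUE when the background amplitude
#'   was below machine tolerance and the ratio was capped) and
#'   `definition`.
#' @export
sbr <- function(roi, weights, background, signal, baseline) {
  stopifnot(inherits(roi, "sv_roi"), inherits(weights, "pixel_weights"))
  background <- as.logical(background)
  if (!any(background)) stop("empty background region")
  if (any(background & as.vector(weights$support)))
    stop("background region overlaps the signal support")
  tr_sig <- extract_trace(roi, weights)$raw
  tr_bg <- extract_trace(roi, pixels = background)$raw
  amp <- function(x) abs(mean(x[signal]) - mean(x[baseline]))
  a_sig <- amp(tr_sig)
  a_bg <- amp(tr_bg)
  eps <- 1e-9 * max(a_sig, 1)
  capped <- a_bg < eps
  if (capped) warning("background amplitude ~ 0; SBR capped")
  list(sbr = a_sig / max(a_bg, eps), capped = capped,
       definition = paste("amplitude(weighted support trace) /",
                          "amplitude(mean background trace),",
                          "amplitude = |mean(signal) - mean(baseline)|"))
}
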