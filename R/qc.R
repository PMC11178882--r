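# Motion quality control.
#
# In vivo recordings are screened rather than corrected: the movie is
# smoothed with a 3D Gaussian kernel, the per-frame centre of mass is
# tracked on background-subtracted frames, and a recording is rejected when
# fluorescence-intensity changes correlate with centre-of-mass
# displacements (a displacement floor guards against rejecting static
# recordings on numerically tiny wobble).

# 1D Gaussian smoothing of matrix columns with edge replication; short
# axes go through a dense banded kernel matrix (one BLAS multiply), long
# axes through stats::filter
conv1_gauss <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- nrow(mat)
  if (n <= 1024) {
    K <- matrix(0, n, n)
    i <- seq_len(n)
    for (o in -r:r) {
      j <- pmin(pmax(i + o, 1), n)
      K[cbind(i, j)] <- K[cbind(i, j)] + k[o + r + 1]
    }
    return(K %*% mat)
  }
  pad <- rbind(mat[rep(1, r), , drop = FALSE], mat,
               mat[rep(n, r), , drop = FALSE])
  out <- stats::filter(pad, k, sides = 2)
  matrix(out[(r + 1):(r + n), ], n, ncol(mat))
}

gauss_smooth_3d <- function(a, sigmas) {
  d <- dim(a)
  m <- matrix(a, d[1], d[2] * d[3])
  m <- conv1_gauss(m, sigmas[1])                       # time
  a2 <- aperm(array(m, d), c(2, 1, 3))                 # rows first
  m2 <- conv1_gauss(matrix(a2, d[2], d[1] * d[3]), sigmas[2])
  a3 <- aperm(array(m2, c(d[2], d[1], d[3])), c(3, 2, 1))  # cols first
  m3 <- conv1_gauss(matrix(a3, d[3], d[1] * d[2]), sigmas[3])
  aperm(array(m3, c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Centre-of-mass motion check
#'
#' Smooths the movie with a 3D Gaussian kernel (default sigmas 1 frame and
#' 5 x 5 pixels), subtracts each frame's median value as background,
#' computes the
#' centre of mass of every frame and the Pearson correlation between
#' frame-to-frame centre-of-mass displacement and mean-intensity change.
#' The recording is flagged for rejection when that correlation exceeds
#' `cor_threshold` in magnitude and the displacement exceeds
#' `displacement_floor` pixels.
#'
#' @param movie an `sv_movie` (or array T x rows x cols) with >= 50 frames.
#' @param sigmas c(t, x, y) Gaussian sigmas in frames / pixels.
#' @param cor_threshold rejection threshold on |correlation|.
#' @param displacement_floor minimum peak displacement (px) for rejection.
#' @return Object of class `motion_report`: data.frame `com` (per-frame x,
#'   y in px), `displacement` and `intensity` series, `correlation`,
#'   `max_displacement`, `reject`, and the parameters used.
#' @export
motion_check <- function(movie, sigmas = c(1, 5, 5), cor_threshold = 0.5,
                         displacement_floor = 0.5) {
  a <- if (inherits(movie, "sv_movie")) movie$counts else movie
  d <- dim(a)
  if (is.null(d) || length(d) != 3) stop("movie must be a T x Y x X array")
  if (d[1] < 50) stop("need at least 50 frames for motion QC")
  if (all(a == 0)) stop("degenerate all-zero movie")
  sm <- gauss_smooth_3d(a, sigmas)
  n <- d[1]
  m <- matrix(sm, n, d[2] * d[3])
  # scalar median background per frame: removes the camera offset that
  # would otherwise pull the centre of mass towards the frame centre
  bg <- apply(m, 1, stats::median)
  rows <- as.vector(matrix(seq_len(d[2]), d[2], d[3]))
  cols <- as.vector(matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE))
  fg <- pmax(m - bg, 0)
  tot <- rowSums(fg)
  zero <- tot <= 0
  if (any(zero)) {
    fg[zero, ] <- m[zero, , drop = FALSE]
    tot[zero] <- rowSums(fg[zero, , drop = FALSE])
  }
  com <- cbind(as.vector(fg %*% cols), as.vector(fg %*% rows)) / tot
  intensity <- rowMeans(m)
  disp_step <- sqrt(diff(com[, 1])^2 + diff(com[, 2])^2)
  dint <- abs(diff(intensity))
  corr <- if (stats::sd(disp_step) == 0 || stats::sd(dint) == 0) 0 else
    stats::cor(disp_step, dint)
  ref <- c(stats::median(com[, 1]), stats::median(com[, 2]))
  max_disp <- max(sqrt((com[, 1] - ref[1])^2 + (com[, 2] - ref[2])^2))
  structure(list(
    com = data.frame(frame = seq_len(n), x_px = com[, 1], y_px = com[, 2]),
    displacement = disp_step, intensity = intensity,
    correlation = corr, max_displacement = max_disp,
    reject = abs(corr) > cor_threshold && max_disp > displacement_floor,
    sigmas = sigmas, cor_threshold = cor_threshold,
    displacement_floor = displacement_floor), class = "motion_report")
}

#' @export
print.motion_report <- function(x, ...) {
  cat(sprintf(
    "<motion_report> %d frames; |r(disp, dI)| = %.3f; max disp %.2f px; %s\n",
    nrow(x$com), abs(x$correlation), x$max_displacement,
    if (x$reject) "REJECT" else "pass"))
  invisible(x)
}
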