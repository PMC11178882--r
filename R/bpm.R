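# Beam propagation through scattering tissue.
#
# Split-step (angular spectrum) propagation with random phase screens.
# Screen statistics are tied to the macroscopic scattering properties: the
# phase variance accumulated per scattering length is 1 rad^2, so the
# ensemble ballistic power decays as exp(-z / ell_s), and the screen
# correlation length is set from the anisotropy g through the rms
# single-scattering angle of a Gaussian random phase screen.

#' Propagate a Gaussian beam through random phase screens
#'
#' Paraxial split-step propagation of a focused Gaussian beam (waist at
#' z = 0) through a stack of independent Gaussian random phase screens.
#' Each screen of thickness `step` carries phase variance `step / ell_s`
#' (so the expected ballistic power decays with the scattering length) and
#' a Gaussian correlation length `l_c = sqrt(2 / (1 - g)) / k`, which makes
#' the rms scattering angle per scattering length consistent with the
#' anisotropy. Fields are reproducible per seed.
#'
#' @param medium a [thermal_medium()] (uses `ell_s`, `g`).
#' @param depth propagation depth, um.
#' @param w0 beam waist (1/e^2 intensity radius), um.
#' @param wavelength nm.
#' @param grid_n grid points per axis.
#' @param dx grid spacing, um; must Nyquist-sample the screen correlation
#'   length (error if too coarse).
#' @param step screen spacing, um.
#' @param seed integer seed.
#' @param screens logical; `FALSE` propagates through free space (used to
#'   validate against the analytic Gaussian-beam solution).
#' @return List with `field` (complex grid at the final depth),
#'   `intensity`, `ballistic` (data.frame z_um / fraction: power remaining
#'   in the unscattered mode), `x_um` (grid coordinates), and the
#'   parameters.
#' @export
bpm_scatter <- function(medium, depth = 150, w0 = 5, wavelength = 1030,
                        grid_n = 128, dx = 0.25, step = 5, seed = 1,
                        screens = TRUE) {
  stopifnot(inherits(medium, "thermal_medium"), depth > 0, w0 > 0)
  n_med <- 1.33
  k <- 2 * pi * n_med / (wavelength * 1e-3)     # rad / um
  l_c <- sqrt(2 / (1 - medium$g)) / k           # um
  if (dx > l_c / 2)
    stop("grid too coarse: dx = ", dx, " um does not sample the screen ",
         "correlation length (", signif(l_c, 3), " um); need dx <= l_c/2")
  x <- (seq_len(grid_n) - grid_n / 2 - 0.5) * dx
  X <- matrix(x, grid_n, grid_n)
  Y <- t(X)
  E <- exp(-(X^2 + Y^2) / w0^2)                 # field, waist at z = 0
  E0 <- E

  fx <- c(seq(0, grid_n / 2 - 1), seq(-grid_n / 2, -1)) / (grid_n * dx)
  KX <- matrix(2 * pi * fx, grid_n, grid_n)
  KY <- t(KX)
  prop <- exp(-1i * (KX^2 + KY^2) * step / (2 * k))

  n_steps <- max(1, round(depth / step))
  sig_phi <- sqrt(step / (medium$ell_s))        # rad per screen
  # Fourier filter giving a Gaussian autocorrelation of 1/e radius l_c
  filt <- exp(-(KX^2 + KY^2) * l_c^2 / 8)
  set.seed(substream_seed(seed, "bpm"))

  free_E <- E0
  ball <- data.frame(z_um = numeric(n_steps), fraction = numeric(n_steps))
  for (s in seq_len(n_steps)) {
    if (screens) {
      noise <- matrix(stats::rnorm(grid_n^2), grid_n)
      phi <- Re(stats::fft(stats::fft(noise) * filt, inverse = TRUE)) /
        grid_n^2
      phi <- phi * sig_phi / stats::sd(phi)
      E <- E * exp(1i * phi)
    }
    E <- stats::fft(stats::fft(E) * prop, inverse = TRUE) / grid_n^2
    free_E <- stats::fft(stats::fft(free_E) * prop, inverse = TRUE) /
      grid_n^2
    ov <- abs(sum(Conj(free_E) * E))^2 /
      (sum(abs(free_E)^2) * sum(abs(E)^2))
    ball$z_um[s] <- s * step
    ball$fraction[s] <- ov
  }
  list(field = E, intensity = abs(E)^2, ballistic = ball, x_um = x,
       params = list(w0 = w0, wavelength = wavelength, dx = dx,
                     step = step, l_c = l_c, depth = depth,
                     seed = seed, screens = screens))
}
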