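#' Quantum/classical harmonic energy ratio
#'
#' The weighting function at the heart of generalized smoothed trajectory
#' analysis (GSTA): the ratio of the mean energy of a quantum harmonic
#' oscillator to that of the classical one at the same temperature,
#' \deqn{w(\nu) = \frac{\beta h \nu}{2}\,\coth\!\left(\frac{\beta h \nu}{2}\right),}
#' with \eqn{\beta = 1/k_B T}. It satisfies \eqn{w(0) = 1}, grows
#' monotonically with frequency, and approaches \eqn{\beta h\nu/2} (the
#' ratio of zero-point to thermal energy) at high frequency. A classical
#' trajectory filtered so that each Fourier component is amplified by
#' \eqn{\sqrt{w(\nu)}} acquires the quantum coordinate variance of every
#' harmonic mode.
#'
#' @param frequency vibrational wavenumber(s), cm^-1, >= 0.
#' @param temperature temperature, K, > 0.
#' @return dimensionless ratio(s), always >= 1.
#' @export
#' @examples
#' quantum_weight(3000, 300)   # a C-H stretch at room temperature: ~7.2
#' quantum_weight(0, 300)      # classical limit: exactly 1
quantum_weight <- function(frequency, temperature) {
  if (!is.numeric(temperature) || any(temperature <= 0)) {
    .stopf("temperature must be positive (K)")
  }
  if (any(frequency < 0)) .stopf("frequency must be non-negative (cm^-1)")
  x <- .mode_quantum_ev(frequency) / (2 * nuq_constants$kB_ev * temperature)
  .xcothx(x)
}

# x * coth(x), numerically safe: series below 1e-4, expm1 form in the body,
# asymptote x for large x (coth -> 1).
.xcothx <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-4
  big <- x > 350
  mid <- !small & !big
  out[small] <- 1 + x[small]^2 / 3        # x coth x = 1 + x^2/3 - x^4/45 + ...
  out[big] <- x[big]
  xm <- x[mid]
  em <- expm1(-2 * xm)
  out[mid] <- xm * (2 + em) / (-em)        # x (1+e^-2x)/(1-e^-2x)
  out
}

#' Build the GSTA convolution kernel
#'
#' Constructs the discrete, real, symmetric filter applied to a classical
#' trajectory to imprint quantum harmonic amplitudes. The taps are the
#' inverse discrete Fourier transform of \eqn{\sqrt{w(\nu_k)}} evaluated on
#' the window's frequency grid \eqn{\nu_k = k/(M\,dt)} (aliased
#' symmetrically about Nyquist), so the filter's amplitude response at any
#' grid-resolvable frequency is \eqn{\sqrt{w(\nu)}} and its DC gain is
#' exactly 1 (means are preserved). No taper is applied.
#'
#' @param window_frames odd window length in frames, >= 3. The window
#'   spans \code{(window_frames - 1) * dt} fs.
#' @param dt trajectory timestep, fs.
#' @param temperature temperature, K.
#' @return An object of class \code{"filter_kernel"}: list with
#'   \code{taps} (length \code{window_frames}, centered), \code{dt},
#'   \code{temperature}, \code{window_frames}.
#' @export
#' @examples
#' k <- build_gsta_kernel(241, dt = 0.5, temperature = 300)
#' sum(k$taps)  # 1: constant signals pass unchanged
build_gsta_kernel <- function(window_frames, dt, temperature) {
  if (window_frames < 3L || window_frames %% 2L == 0L) {
    .stopf("window_frames must be an odd integer >= 3 (a centered window)")
  }
  if (dt <= 0) .stopf("dt must be positive (fs)")
  m <- as.integer(window_frames)
  k <- seq_len(m) - 1L
  # frequency magnitude per DFT bin, folded about Nyquist, in cm^-1
  cyc_fs <- pmin(k, m - k) / (m * dt)                    # cycles per fs
  nu_cm <- cyc_fs * nuq_constants$h_ev_fs / nuq_constants$hc_ev_cm
  gain <- sqrt(quantum_weight(nu_cm, temperature))
  g <- Re(stats::fft(gain, inverse = TRUE)) / m
  # circularly shift so the center tap is at position (m+1)/2
  half <- (m - 1L) %/% 2L
  taps <- g[c((m - half + 1L):m, 1L:(m - half))]
  taps <- (taps + rev(taps)) / 2   # kill rounding-level asymmetry
  structure(
    list(taps = taps, dt = as.numeric(dt),
         temperature = as.numeric(temperature), window_frames = m),
    class = "filter_kernel"
  )
}

#' @export
print.filter_kernel <- function(x, ...) {
  cat(sprintf("<filter_kernel> %d taps (%.1f fs window), dt = %g fs, T = %g K\n",
              x$window_frames, (x$window_frames - 1) * x$dt, x$dt,
              x$temperature))
  invisible(x)
}

#' Frequency response of a GSTA kernel
#'
#' Evaluates the kernel's amplitude gain at arbitrary frequencies (cm^-1)
#' by direct summation of the tap phases. At grid-resolvable frequencies
#' this equals \eqn{\sqrt{w(\nu)}} up to discretization error.
#'
#' @param kernel a \code{\link{build_gsta_kernel}} result.
#' @param frequency wavenumbers, cm^-1.
#' @return numeric gains.
#' @export
kernel_gain <- function(kernel, frequency) {
  stopifnot(inherits(kernel, "filter_kernel"))
  half <- (kernel$window_frames - 1L) %/% 2L
  offs <- -half:half
  cyc_fs <- .omega_fs(frequency) / (2 * pi)
  vapply(cyc_fs, function(f) {
    sum(kernel$taps * cos(2 * pi * f * kernel$dt * offs))
  }, numeric(1))
}

#' Apply the GSTA filter to a trajectory
#'
#' Convolves every Cartesian component of every atom with the kernel taps
#' (a moving window centered on each frame). The half-window at each end
#' of the trajectory is discarded rather than padded, so the output has
#' \code{n_frames - (window - 1)} frames; elements and timestep are
#' preserved.
#'
#' @param traj a \code{\link{trajectory}} with at least
#'   \code{kernel$window_frames} frames and matching timestep.
#' @param kernel a \code{\link{build_gsta_kernel}} result.
#' @return The filtered (quantized) \code{\link{trajectory}}.
#' @export
apply_gsta <- function(traj, kernel) {
  stopifnot(inherits(traj, "trajectory"), inherits(kernel, "filter_kernel"))
  m <- kernel$window_frames
  nf <- n_frames(traj)
  if (nf < m) {
    .stopf("trajectory has %d frames; the %d-tap kernel needs at least %d",
           nf, m, m)
  }
  if (abs(traj$dt - kernel$dt) > 1e-9) {
    .stopf("trajectory dt (%g fs) does not match kernel dt (%g fs)",
           traj$dt, kernel$dt)
  }
  half <- (m - 1L) %/% 2L
  keep <- (half + 1L):(nf - half)
  na <- n_atoms(traj)
  out <- array(0, dim = c(length(keep), na, 3L))
  # stats::filter computes sum_j taps[j] * x[t + half + 1 - j]; taps are
  # symmetric so convolution and correlation coincide.
  for (a in seq_len(na)) {
    for (d in 1:3) {
      y <- stats::filter(traj$coords[, a, d], kernel$taps, sides = 2L)
      out[, a, d] <- y[keep]
    }
  }
  trajectory(traj$elements, out, traj$dt,
             provenance = c(traj$provenance,
                            sprintf("GSTA-filtered: %d-frame window, T = %g K",
                                    m, kernel$temperature)))
}
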