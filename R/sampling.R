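#' Wigner and classical coordinate widths of a harmonic mode
#'
#' \code{wigner_coordinate_sigma} gives the standard deviation of the
#' coordinate marginal of the harmonic-oscillator Wigner distribution,
#' \deqn{\sigma_W = \sqrt{\frac{\hbar}{2 m \omega}\coth\frac{\beta\hbar\omega}{2}},}
#' which at T = 0 reduces to the ground-state width and at high
#' temperature tends to the classical thermal width
#' \eqn{\sigma_{cl} = \sqrt{k_B T / m\omega^2}} returned by
#' \code{classical_coordinate_sigma}. The ratio of their variances is the
#' GSTA weighting function \code{\link{quantum_weight}}.
#'
#' @param frequency mode wavenumber, cm^-1, > 0.
#' @param reduced_mass effective mass of the mode, amu, > 0.
#' @param temperature K; \code{wigner_coordinate_sigma} accepts 0
#'   (zero-point width), the classical width requires T > 0.
#' @return standard deviation in Angstrom.
#' @export
#' @examples
#' wigner_coordinate_sigma(3000, 1, 0)     # ~0.075 A zero-point width
#' wigner_coordinate_sigma(3000, 1, 300) / classical_coordinate_sigma(3000, 1, 300)
wigner_coordinate_sigma <- function(frequency, reduced_mass, temperature) {
  if (any(frequency <= 0)) .stopf("frequency must be positive (cm^-1)")
  if (any(reduced_mass <= 0)) .stopf("reduced mass must be positive (amu)")
  if (any(temperature < 0)) .stopf("temperature must be >= 0 (K)")
  n <- max(length(frequency), length(reduced_mass), length(temperature))
  freq <- rep_len(frequency, n)
  mass <- rep_len(reduced_mass, n)
  temp <- rep_len(temperature, n)
  omega <- .omega_fs(freq)
  base <- .hbar_internal() / (2 * mass * omega)   # A^2
  cothf <- rep(1, n)                               # T = 0: ground state
  hot <- temp > 0
  if (any(hot)) {
    x <- .mode_quantum_ev(freq[hot]) / (2 * nuq_constants$kB_ev * temp[hot])
    cothf[hot] <- .xcothx(x) / x
  }
  sqrt(base * cothf)
}

#' @rdname wigner_coordinate_sigma
#' @export
classical_coordinate_sigma <- function(frequency, reduced_mass, temperature) {
  if (any(frequency <= 0)) .stopf("frequency must be positive (cm^-1)")
  if (any(reduced_mass <= 0)) .stopf("reduced mass must be positive (amu)")
  if (any(temperature <= 0)) .stopf("classical width requires T > 0 (K)")
  omega <- .omega_fs(frequency)
  sqrt(.kT_internal(temperature) / (reduced_mass * omega^2))
}

#' Quantum/classical vibrational amplitude ratio (lower estimate)
#'
#' The ratio \eqn{\sqrt{E_{ZPV}/E_{th}} = \sqrt{(h\nu/2)/(k_B T)}} of the
#' amplitude of a zero-point vibration to that of the classical thermal
#' one — a lower estimate of how much a quantized nuclear ensemble is wider
#' than the classical ensemble for a given internal degree of freedom. For
#' X-H stretching modes (~3000 cm^-1) at room temperature it falls in the
#' 2-3 range, which is why hydrogen stretches dominate quantum broadening
#' of absorption bands.
#'
#' @param frequency wavenumber, cm^-1, > 0.
#' @param temperature K, > 0.
#' @return dimensionless ratio.
#' @export
#' @examples
#' amplitude_ratio_lower_estimate(3000, 300)  # ~2.68
amplitude_ratio_lower_estimate <- function(frequency, temperature) {
  if (any(frequency <= 0)) .stopf("frequency must be positive (cm^-1)")
  if (any(temperature <= 0)) .stopf("temperature must be positive (K)")
  sqrt(.mode_quantum_ev(frequency) / 2 /
         (nuq_constants$kB_ev * temperature))
}

.sample_modes <- function(modes, sigmas, n, seed, origin, temperature) {
  nm <- length(modes$frequencies)
  q <- .with_seed(seed, {
    matrix(stats::rnorm(n * nm), n, nm)
  })
  q <- sweep(q, 2L, sigmas, `*`)              # n x modes, sqrt(amu) A
  dx <- q %*% modes$displacements             # n x 3N cartesian
  na <- nrow(modes$reference_geometry)
  ref <- as.vector(t(modes$reference_geometry))   # atom-major x y z
  configs <- array(0, dim = c(n, na, 3L))
  for (d in 1:3) {
    configs[, , d] <- sweep(dx[, seq(d, 3L * na, by = 3L), drop = FALSE],
                            2L, ref[seq(d, 3L * na, by = 3L)], `+`)
  }
  structure(
    list(configurations = configs, origin = origin,
         temperature = temperature, seed = seed,
         mode_coordinates = q, modes = modes),
    class = "mode_sample_set"
  )
}

#' Sample nuclear configurations from harmonic normal modes
#'
#' \code{sample_wigner} draws each mass-weighted mode coordinate from the
#' (thermal) harmonic Wigner coordinate marginal — a zero-mean Gaussian
#' with the \code{\link{wigner_coordinate_sigma}} width at unit
#' mass-weighted mass — so the ensemble carries zero-point motion;
#' \code{sample_classical} draws from the classical Boltzmann coordinate
#' marginal (variance \eqn{k_B T / \omega^2} in mass-weighted
#' coordinates). Mode coordinates are mapped to Cartesian displacements
#' through the displacement vectors and added to the reference geometry.
#'
#' @param modes a \code{\link{normal_modes}} object.
#' @param temperature K (\code{sample_wigner} accepts 0).
#' @param n number of configurations, >= 1.
#' @param seed integer RNG seed; identical seeds give identical samples.
#' @return An object of class \code{"mode_sample_set"}: list with
#'   \code{configurations} (n x atoms x 3, Angstrom), \code{origin},
#'   \code{temperature}, \code{seed}, plus the drawn
#'   \code{mode_coordinates} (n x modes, sqrt(amu) Angstrom).
#' @export
sample_wigner <- function(modes, temperature, n, seed = NULL) {
  stopifnot(inherits(modes, "normal_modes"))
  if (n <= 0) .stopf("n must be >= 1")
  if (temperature < 0) .stopf("temperature must be >= 0 (K)")
  sig <- wigner_coordinate_sigma(modes$frequencies, 1, temperature)
  .sample_modes(modes, sig, n, seed, "wigner", temperature)
}

#' @rdname sample_wigner
#' @export
sample_classical <- function(modes, temperature, n, seed = NULL) {
  stopifnot(inherits(modes, "normal_modes"))
  if (n <= 0) .stopf("n must be >= 1")
  if (temperature <= 0) .stopf("the classical sampler is undefined at T <= 0")
  sig <- classical_coordinate_sigma(modes$frequencies, 1, temperature)
  .sample_modes(modes, sig, n, seed, "classical", temperature)
}

#' @export
print.mode_sample_set <- function(x, ...) {
  cat(sprintf("<mode_sample_set> %d %s configurations at %g K\n",
              dim(x$configurations)[1], x$origin, x$temperature))
  invisible(x)
}

#' Harmonic potential-energy distribution of a sample set
#'
#' Evaluates the harmonic potential energy
#' \eqn{\sum_j \frac{1}{2}\omega_j^2 Q_j^2} of every sampled configuration
#' (projecting Cartesian displacements back onto the mass-weighted modes),
#' and summarizes the distribution by its mean, standard deviation, and a
#' moment-matched gamma law. For classical thermal sampling of M modes the
#' energy is exactly \eqn{\frac{k_B T}{2}\chi^2(M)}-distributed, i.e. a
#' gamma with shape M/2 and scale \eqn{k_B T}, which this diagnostic
#' recovers; zero-point sampling shifts the whole distribution up. The
#' reported "width" is a standard deviation (FWHM of a gamma has no simple
#' closed form).
#'
#' @param samples a \code{"mode_sample_set"}.
#' @param modes the \code{\link{normal_modes}} defining the harmonic
#'   surface (defaults to the set the samples were drawn from).
#' @return list with \code{mean_kcal}, \code{std_kcal} (kcal/mol),
#'   \code{gamma_shape}, \code{gamma_scale_kcal}, and the per-sample
#'   energies \code{energies_kcal}.
#' @export
potential_energy_distribution <- function(samples, modes = samples$modes) {
  stopifnot(inherits(samples, "mode_sample_set"),
            inherits(modes, "normal_modes"))
  n <- dim(samples$configurations)[1]
  if (n < 2L) .stopf("need at least 2 samples for a distribution")
  na <- nrow(modes$reference_geometry)
  # displacements, atom-major 3N
  dx <- matrix(0, n, 3L * na)
  for (d in 1:3) {
    dx[, seq(d, 3L * na, by = 3L)] <-
      sweep(samples$configurations[, , d, drop = FALSE][, , 1],
            2L, modes$reference_geometry[, d], `-`)
  }
  mw <- sweep(dx, 2L, rep(modes$masses, each = 3L), `*`)
  q <- mw %*% t(modes$displacements)        # n x modes mass-weighted coords
  omega2 <- .omega_fs(modes$frequencies)^2
  pe_internal <- 0.5 * (q^2 %*% omega2)[, 1]
  ev_to_kcal <- 23.060548
  pe <- pe_internal * nuq_constants$ev_per_internal * ev_to_kcal
  m <- mean(pe); s <- stats::sd(pe)
  list(mean_kcal = m, std_kcal = s,
       gamma_shape = m^2 / s^2, gamma_scale_kcal = s^2 / m,
       energies_kcal = pe)
}
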