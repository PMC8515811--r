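# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# Random normal-mode set with the requested wavenumbers: displacement
# vectors drawn as a random orthonormal frame in mass-weighted space.
make_mode_set <- function(freqs_cm, masses = NULL, seed = 1) {
  nm <- length(freqs_cm)
  na <- max(2L, ceiling((nm + 6L) / 3L))
  set.seed(seed)
  if (is.null(masses)) masses <- stats::runif(na, 1, 16)
  q <- qr.Q(qr(matrix(stats::rnorm(3L * na * nm), 3L * na, nm)))
  disp <- t(q) / rep(sqrt(masses), each = 3L)[col(t(q))]
  normal_modes(
    reference_geometry = matrix(stats::rnorm(3L * na), na, 3L),
    masses = masses,
    frequencies = sort(freqs_cm),
    displacements = disp
  )
}

# One-atom, one-mode oscillator along x (mass in amu).
make_1d_mode <- function(freq_cm, mass = 1) {
  normal_modes(
    reference_geometry = matrix(0, 1, 3),
    masses = mass,
    frequencies = freq_cm,
    displacements = matrix(c(1 / sqrt(mass), 0, 0), 1, 3)
  )
}

# Sticks whose strengths follow a smooth Gaussian envelope of the energy,
# with multiplicative noise — the generic shape of pooled TDDFT sticks.
make_envelope_sticks <- function(n, seed, center = 3, width = 0.3,
                                 noise = 0.2) {
  set.seed(seed)
  x <- stats::runif(n, center - 1, center + 1)
  y <- exp(-(x - center)^2 / (2 * width^2)) * (1 + noise * stats::rnorm(n))
  stick_table(seq_len(n), x, pmax(y, 0))
}

# Brute-force leave-one-out loss: refits the deleted-point kernel sum for
# every record; the independent oracle for loo_cv_loss().
brute_force_loo <- function(sticks, delta) {
  X <- sticks$energy; Y <- sticks$strength
  s <- vapply(X, function(x) sum(Y * stats::dnorm(x - X, sd = delta)),
              numeric(1))
  a <- sum(Y * s) / sum(s^2)
  sum(vapply(seq_along(X), function(i) {
    (Y[i] - a * sum(Y[-i] * stats::dnorm(X[i] - X[-i], sd = delta)))^2
  }, numeric(1)))
}

toy_dho <- function() {
  dho_model(vib_energy = 0.18, huang_rhys = 1.0, adiabatic_energy = 3.0,
            osc_strength = 1, reduced_mass = 1)
}
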