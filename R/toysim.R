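#' Toy chromophore and surface models
#'
#' Desk-scale model systems used to validate the spectral pipeline with
#' closed-form references.
#'
#' \code{dho_model} defines a displaced harmonic oscillator (DHO)
#' chromophore: two identical 1-D harmonic surfaces with vibrational
#' quantum \code{vib_energy} (eV), offset by the Huang-Rhys factor
#' \code{huang_rhys} in coordinate and by the adiabatic (0-0) energy
#' \code{adiabatic_energy} (eV); the transition carries a constant
#' (Condon) oscillator strength \code{osc_strength}. Its Franck-Condon
#' spectrum has closed-form moments (\code{\link{fc_dho_oracle}}).
#'
#' \code{morse_model} defines a 1-D Morse oscillator
#' \eqn{V(x) = D (1 - e^{-a (x - x_0)})^2}, the minimal anharmonic,
#' dissociative surface on which harmonic samplers can be stress-tested.
#'
#' \code{toy_md_config} collects Langevin-dynamics settings.
#'
#' @param vib_energy vibrational quantum of the DHO mode, eV, > 0.
#' @param huang_rhys Huang-Rhys factor S, dimensionless, >= 0.
#' @param adiabatic_energy 0-0 excitation energy, eV.
#' @param osc_strength Condon oscillator strength, >= 0.
#' @param reduced_mass effective mass of the mode, amu, > 0.
#' @return model objects of class \code{"dho_model"} / \code{"morse_model"}
#'   / \code{"toy_md_config"}.
#' @export
#' @examples
#' m <- dho_model(vib_energy = 0.18, huang_rhys = 1.0, adiabatic_energy = 3.0)
#' fc_dho_oracle(m, temperature = 0)$mean  # 3.18 eV vertical mean
dho_model <- function(vib_energy, huang_rhys, adiabatic_energy,
                      osc_strength = 1, reduced_mass = 1) {
  if (vib_energy <= 0) .stopf("vib_energy must be positive (eV)")
  if (huang_rhys < 0) .stopf("huang_rhys must be >= 0")
  if (osc_strength < 0) .stopf("osc_strength must be >= 0")
  if (reduced_mass <= 0) .stopf("reduced_mass must be positive (amu)")
  structure(list(vib_energy = vib_energy, huang_rhys = huang_rhys,
                 adiabatic_energy = adiabatic_energy,
                 osc_strength = osc_strength, reduced_mass = reduced_mass),
            class = "dho_model")
}

#' @rdname dho_model
#' @param well_depth Morse dissociation energy D, eV, > 0.
#' @param range_parameter Morse range a, 1/Angstrom, > 0.
#' @param equilibrium Morse minimum position, Angstrom.
#' @export
morse_model <- function(well_depth, range_parameter, equilibrium = 0,
                        reduced_mass = 1) {
  if (well_depth <= 0) .stopf("well_depth must be positive (eV)")
  if (range_parameter <= 0) .stopf("range_parameter must be positive (1/A)")
  if (reduced_mass <= 0) .stopf("reduced_mass must be positive (amu)")
  structure(list(well_depth = well_depth, range_parameter = range_parameter,
                 equilibrium = equilibrium, reduced_mass = reduced_mass),
            class = "morse_model")
}

#' @rdname dho_model
#' @param temperature thermostat temperature, K, >= 0.
#' @param dt integration timestep, fs, > 0.
#' @param steps number of steps, >= 1.
#' @param friction Langevin friction, 1/fs, >= 0 (0 = plain Verlet, no
#'   thermostat).
#' @param seed integer RNG seed.
#' @export
toy_md_config <- function(temperature = 300, dt = 0.5, steps = 1000L,
                          friction = 0.01, seed = 1L) {
  if (dt <= 0) .stopf("dt must be positive (fs)")
  if (steps < 1) .stopf("steps must be >= 1")
  if (friction < 0) .stopf("friction must be >= 0 (1/fs)")
  if (temperature < 0) .stopf("temperature must be >= 0 (K)")
  structure(list(temperature = temperature, dt = dt,
                 steps = as.integer(steps), friction = friction,
                 seed = as.integer(seed)),
            class = "toy_md_config")
}

# Harmonic angular frequency (fs^-1) of the Morse well curvature at its
# minimum: V''(x0) = 2 D a^2.
.morse_omega_fs <- function(model) {
  d_int <- model$well_depth / nuq_constants$ev_per_internal
  sqrt(2 * d_int * model$range_parameter^2 / model$reduced_mass)
}

.model_omega_fs <- function(model) {
  switch(class(model)[1],
    dho_model = model$vib_energy / nuq_constants$hbar_ev_fs,
    morse_model = .morse_omega_fs(model),
    normal_modes = max(.omega_fs(model$frequencies)),
    .stopf("unsupported model class '%s'", class(model)[1])
  )
}

#' Langevin dynamics on a toy surface
#'
#' Integrates BAOAB-discretized Langevin dynamics on the ground-state
#' surface of a \code{\link{dho_model}} (harmonic), a
#' \code{\link{morse_model}}, or the harmonic surface of a
#' \code{\link{normal_modes}} set (each mass-weighted mode integrated
#' independently and mapped back to Cartesian). Starts at the potential
#' minimum with Maxwell-Boltzmann velocities; coordinates are recorded at
#' every step, giving \code{steps + 1} frames. Runs are reproducible under
#' a fixed seed.
#'
#' The timestep must resolve the fastest vibrational period: a warning is
#' issued above period/10 and integration is refused above period/5.
#'
#' @param model the surface.
#' @param cfg a \code{\link{toy_md_config}}.
#' @return A \code{\link{trajectory}} (single dummy atom moving along x
#'   for the 1-D models; full Cartesian frames for normal-mode surfaces).
#' @export
simulate_langevin <- function(model, cfg) {
  stopifnot(inherits(cfg, "toy_md_config"))
  omega_max <- .model_omega_fs(model)
  period <- 2 * pi / omega_max
  if (cfg$dt > period / 5) {
    .stopf("dt = %g fs exceeds 1/5 of the fastest period (%g fs): refusing",
           cfg$dt, period)
  }
  if (cfg$dt > period / 10) {
    warning(sprintf("dt = %g fs is coarse for the fastest period (%g fs)",
                    cfg$dt, period), call. = FALSE)
  }
  if (inherits(model, "normal_modes")) {
    .langevin_modes(model, cfg)
  } else {
    .langevin_1d(model, cfg)
  }
}

# BAOAB update for nd independent degrees of freedom with force function
# f(x) (internal units). Returns (steps+1) x nd coordinate matrix.
.baoab <- function(x0, mass, force, cfg) {
  nd <- length(x0)
  kT <- .kT_internal(max(cfg$temperature, 0))
  c1 <- exp(-cfg$friction * cfg$dt)
  c2 <- sqrt((1 - c1^2) * kT / mass)
  .with_seed(cfg$seed, {
    v <- if (cfg$temperature > 0) {
      stats::rnorm(nd, 0, sqrt(kT / mass))
    } else rep(0, nd)
    noise <- matrix(stats::rnorm(cfg$steps * nd), cfg$steps, nd)
    out <- matrix(0, cfg$steps + 1L, nd)
    x <- x0
    out[1L, ] <- x
    f <- force(x)
    h <- cfg$dt
    for (s in seq_len(cfg$steps)) {
      v <- v + (h / 2) * f / mass
      x <- x + (h / 2) * v
      v <- c1 * v + c2 * noise[s, ]
      x <- x + (h / 2) * v
      f <- force(x)
      v <- v + (h / 2) * f / mass
      out[s + 1L, ] <- x
    }
    out
  })
}

.langevin_1d <- function(model, cfg) {
  m <- model$reduced_mass
  if (inherits(model, "dho_model")) {
    omega2 <- (model$vib_energy / nuq_constants$hbar_ev_fs)^2
    force <- function(x) -m * omega2 * x
    x0 <- 0
  } else {
    d_int <- model$well_depth / nuq_constants$ev_per_internal
    a <- model$range_parameter
    x_eq <- model$equilibrium
    force <- function(x) {
      e <- exp(-a * (x - x_eq))
      -2 * d_int * a * (1 - e) * e
    }
    x0 <- x_eq
  }
  xs <- .baoab(x0, m, force, cfg)
  coords <- array(0, dim = c(nrow(xs), 1L, 3L))
  coords[, 1L, 1L] <- xs[, 1L]
  trajectory("X", coords, cfg$dt,
             provenance = sprintf("Langevin %s, T = %g K, gamma = %g /fs, seed %d",
                                  class(model)[1], cfg$temperature,
                                  cfg$friction, cfg$seed))
}

.langevin_modes <- function(modes, cfg) {
  omega <- .omega_fs(modes$frequencies)
  force <- function(q) -omega^2 * q     # unit mass in mass-weighted coords
  qs <- .baoab(rep(0, length(omega)), 1, force, cfg)
  dx <- qs %*% modes$displacements      # frames x 3N
  na <- nrow(modes$reference_geometry)
  coords <- array(0, dim = c(nrow(qs), na, 3L))
  for (d in 1:3) {
    coords[, , d] <- sweep(dx[, seq(d, 3L * na, by = 3L), drop = FALSE],
                           2L, modes$reference_geometry[, d], `+`)
  }
  trajectory(modes$elements, coords, cfg$dt,
             provenance = sprintf("Langevin normal-mode surface, T = %g K, seed %d",
                                  cfg$temperature, cfg$seed))
}

#' Vertical excitation of the DHO chromophore
#'
#' Energy gap between the two DHO surfaces at nuclear coordinate x
#' (reflection/vertical approximation). The gap is linear in the
#' coordinate,
#' \deqn{E(x) = E_{00} + S\hbar\omega - m\omega^2 d\, x,}
#' with excited-state displacement \eqn{d = \sqrt{2 S \hbar/(m\omega)}};
#' the oscillator strength is constant (Condon approximation). At x = 0
#' this is the vertical energy \eqn{E_{00} + S\hbar\omega}.
#'
#' @param model a \code{\link{dho_model}}.
#' @param coordinate nuclear coordinate(s), Angstrom.
#' @return list with \code{energy} (eV, same length as
#'   \code{coordinate}) and \code{strength}.
#' @export
dho_vertical_excitation <- function(model, coordinate) {
  stopifnot(inherits(model, "dho_model"))
  omega <- model$vib_energy / nuq_constants$hbar_ev_fs
  m <- model$reduced_mass
  d <- sqrt(2 * model$huang_rhys * .hbar_internal() / (m * omega))
  slope_ev <- m * omega^2 * d * nuq_constants$ev_per_internal   # eV / A
  list(energy = model$adiabatic_energy +
         model$huang_rhys * model$vib_energy - slope_ev * coordinate,
       strength = rep(model$osc_strength, length(coordinate)))
}

#' Per-snapshot excitations along a trajectory
#'
#' Thins a 1-D trajectory to every \code{every}-th frame (starting from
#' the first) and evaluates the DHO vertical excitation at each selected
#' frame, producing the stick table consumed by the broadening stage.
#'
#' @param model a \code{\link{dho_model}}.
#' @param traj a single-atom \code{\link{trajectory}} whose x coordinate
#'   is the DHO mode.
#' @param every snapshot thinning stride in frames (default 100).
#' @return A \code{\link{stick_table}} with one record per snapshot.
#' @export
dho_excite_trajectory <- function(model, traj, every = 100L) {
  stopifnot(inherits(model, "dho_model"), inherits(traj, "trajectory"))
  if (n_atoms(traj) != 1L) {
    .stopf("DHO excitation expects a single-atom (1-D) trajectory")
  }
  sel <- seq(1L, n_frames(traj), by = as.integer(every))
  ex <- dho_vertical_excitation(model, traj$coords[sel, 1L, 1L])
  stick_table(seq_along(sel), ex$energy, ex$strength)
}

#' Exact Franck-Condon reference for the DHO chromophore
#'
#' Closed-form absorption line shape of the displaced harmonic
#' oscillator. At T = 0 the spectrum is the Poisson progression: lines at
#' \eqn{E_{00} + n\hbar\omega} with intensities \eqn{e^{-S} S^n / n!},
#' truncated once the cumulative intensity reaches \eqn{1 - 10^{-10}}. At
#' any temperature the exact first two moments are
#' \deqn{\langle E \rangle = E_{00} + S\hbar\omega, \qquad
#'   \mathrm{Var}(E) = S (\hbar\omega)^2 \coth(\beta\hbar\omega/2),}
#' the reference against which ensemble spectra (GSTA-filtered dynamics
#' or Wigner sampling) are judged: all three reproduce these moments
#' exactly for the DHO. Moments are computed in closed form, never from
#' the truncated sticks.
#'
#' @param model a \code{\link{dho_model}}.
#' @param temperature K, >= 0.
#' @return list with \code{mean} (eV), \code{std} (eV), and at T = 0 a
#'   \code{sticks} data frame (\code{n}, \code{energy}, \code{intensity};
#'   intensities scaled by the model's oscillator strength).
#' @export
fc_dho_oracle <- function(model, temperature = 0) {
  stopifnot(inherits(model, "dho_model"))
  if (temperature < 0) .stopf("temperature must be >= 0 (K)")
  s <- model$huang_rhys
  hw <- model$vib_energy
  cothf <- if (temperature == 0) 1 else {
    x <- hw / (2 * nuq_constants$kB_ev * temperature)
    .xcothx(x) / x
  }
  out <- list(mean = model$adiabatic_energy + s * hw,
              std = sqrt(s * hw^2 * cothf))
  if (temperature == 0) {
    nmax <- if (s == 0) 0L else {
      n <- stats::qpois(1 - 1e-10, s)
      while (stats::ppois(n, s) < 1 - 1e-10 && n < 10000L) n <- n + 1L
      if (stats::ppois(n, s) < 1 - 1e-10) {
        .stopf("FC progression truncation failed to reach 1 - 1e-10")
      }
      n
    }
    n <- 0:nmax
    out$sticks <- data.frame(
      n = n,
      energy = model$adiabatic_energy + n * hw,
      intensity = model$osc_strength * stats::dpois(n, s)
    )
  }
  out
}

#' Overextension of harmonic samples on a Morse surface
#'
#' Quantifies the failure mode of harmonic configurational sampling on a
#' dissociative potential: the Morse well is approximated by its harmonic
#' curvature at the minimum, displacements are drawn from the Wigner or
#' classical thermal marginal of that harmonic model, and the function
#' returns the fraction of samples stretched beyond \code{threshold} on
#' the dissociative (positive-displacement) side — configurations a
#' harmonic sampler happily produces but that sit far up the Morse
#' dissociation plateau. Because the Wigner marginal is wider than the
#' classical one at any temperature, its overextension fraction is always
#' at least as large.
#'
#' @param model a \code{\link{morse_model}}.
#' @param sampler \code{"wigner"} or \code{"classical"}.
#' @param threshold displacement threshold from the minimum, Angstrom.
#' @param temperature K.
#' @param n number of samples, >= 1.
#' @param seed RNG seed.
#' @return fraction in \[0, 1\].
#' @export
morse_overextension_fraction <- function(model, sampler = c("wigner", "classical"),
                                         threshold, temperature, n,
                                         seed = NULL) {
  stopifnot(inherits(model, "morse_model"))
  sampler <- match.arg(sampler)
  if (n <= 0) .stopf("n must be >= 1")
  omega <- .morse_omega_fs(model)
  freq_cm <- omega * nuq_constants$hbar_ev_fs / nuq_constants$hc_ev_cm
  sig <- if (sampler == "wigner") {
    wigner_coordinate_sigma(freq_cm, model$reduced_mass, temperature)
  } else {
    classical_coordinate_sigma(freq_cm, model$reduced_mass, temperature)
  }
  u <- .with_seed(seed, stats::rnorm(n, 0, sig))
  mean(u > threshold)
}
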