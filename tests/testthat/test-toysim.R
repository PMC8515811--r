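test_that("Langevin dynamics is still, deterministic, and thermalizes correctly", {
  model <- toy_dho()
  # T = 0, start at the minimum: nothing moves
  cfg0 <- toy_md_config(temperature = 0, dt = 0.5, steps = 200L,
                        friction = 0.05, seed = 1L)
  tr0 <- simulate_langevin(model, cfg0)
  expect_true(all(tr0$coords == 0))
  expect_equal(n_frames(tr0), 201L)   # initial frame + one per step

  cfg <- toy_md_config(temperature = 300, dt = 0.5, steps = 120000L,
                       friction = 0.05, seed = 5L)
  tr <- simulate_langevin(model, cfg)
  expect_identical(tr$coords, simulate_langevin(model, cfg)$coords)

  # equipartition: coordinate variance kBT/(m omega^2), mean PE kBT/2
  x <- tr$coords[, 1, 1]
  freq_cm <- model$vib_energy / nuq_constants$hc_ev_cm
  expect_equal(var(x), classical_coordinate_sigma(freq_cm, 1, 300)^2,
               tolerance = 0.05)
  omega <- model$vib_energy / nuq_constants$hbar_ev_fs
  pe <- 0.5 * omega^2 * x^2                   # internal units, m = 1
  kT <- nuq_constants$kB_ev * 300 / nuq_constants$ev_per_internal
  expect_equal(mean(pe), kT / 2, tolerance = 0.05)
})

test_that("timestep guards track the fastest vibrational period", {
  model <- toy_dho()                      # period ~23 fs
  expect_error(
    simulate_langevin(model, toy_md_config(300, dt = 6, steps = 10)),
    "refusing")
  expect_warning(
    simulate_langevin(model, toy_md_config(300, dt = 2.5, steps = 10,
                                           seed = 1)),
    "coarse")
  expect_error(toy_md_config(300, 0.5, 10, friction = -0.1), "friction")
})

test_that("the DHO gap is linear with the Franck-Condon mean and slope", {
  model <- toy_dho()
  vert <- model$adiabatic_energy + model$huang_rhys * model$vib_energy
  ex0 <- dho_vertical_excitation(model, 0)
  expect_equal(ex0$energy, vert)
  expect_equal(ex0$strength, model$osc_strength)

  flat <- dho_model(0.18, 0, 3.0)
  expect_equal(dho_vertical_excitation(flat, c(-1, 0, 2))$energy, rep(3.0, 3))

  # Gaussian propagation through the linear map: sampling the T = 0 ground
  # state reproduces the exact FC mean and sqrt(S)*hbar*omega width
  freq_cm <- model$vib_energy / nuq_constants$hc_ev_cm
  set.seed(42)
  x <- rnorm(50000, 0, wigner_coordinate_sigma(freq_cm, 1, 0))
  e <- dho_vertical_excitation(model, x)$energy
  expect_equal(mean(e), vert, tolerance = 0.005)
  expect_equal(sd(e), sqrt(model$huang_rhys) * model$vib_energy,
               tolerance = 0.02)
})

test_that("the Franck-Condon oracle matches brute-force Poisson summation", {
  m <- dho_model(vib_energy = 0.1, huang_rhys = 1, adiabatic_energy = 3.0)
  o <- fc_dho_oracle(m, 0)
  expect_equal(o$mean, 3.1)
  expect_equal(o$std, 0.1)
  # moments recomputed from the truncated progression itself
  stick_mean <- with(o$sticks, sum(energy * intensity) / sum(intensity))
  stick_var <- with(o$sticks, sum(intensity * (energy - stick_mean)^2) /
                      sum(intensity))
  expect_equal(stick_mean, o$mean, tolerance = 1e-8)
  expect_equal(sqrt(stick_var), o$std, tolerance = 1e-6)
  expect_gte(sum(dpois(o$sticks$n, 1)), 1 - 1e-10)

  # S = 0: a single line, zero width
  o0 <- fc_dho_oracle(dho_model(0.2, 0, 2.5), 0)
  expect_equal(nrow(o0$sticks), 1L)
  expect_equal(o0$sticks$energy, 2.5)
  expect_equal(o0$std, 0)

  # finite temperature widens the band by the coth factor
  o300 <- fc_dho_oracle(dho_model(0.15, 0.5, 3.0), 300)
  expect_equal(o300$std, 0.1064, tolerance = 1e-3)
  expect_gt(o300$std, fc_dho_oracle(dho_model(0.15, 0.5, 3.0), 0)$std)
})

test_that("harmonic samplers overstretch a Morse well, Wigner worst", {
  # shallow well: ~0.8 eV depth, ~1100 cm^-1 harmonic frequency
  m <- morse_model(well_depth = 0.8, range_parameter = 1.5, reduced_mass = 1)
  freq_cm <- nuqspec:::.morse_omega_fs(m) * nuq_constants$hbar_ev_fs /
    nuq_constants$hc_ev_cm
  expect_equal(morse_overextension_fraction(m, "wigner", Inf, 298.15, 1000,
                                            seed = 2), 0)
  thr <- 0.25
  fw <- morse_overextension_fraction(m, "wigner", thr, 298.15, 40000, seed = 3)
  fc <- morse_overextension_fraction(m, "classical", thr, 298.15, 40000,
                                     seed = 3)
  expect_gte(fw, fc)
  expect_gt(fw, 3 * max(fc, 1e-4))   # materially larger, not just >=
  # Gaussian tail integral as the analytic oracle
  expect_equal(fw, pnorm(thr, sd = wigner_coordinate_sigma(freq_cm, 1, 298.15),
                         lower.tail = FALSE), tolerance = 0.1)
  expect_equal(fc, pnorm(thr, sd = classical_coordinate_sigma(freq_cm, 1, 298.15),
                         lower.tail = FALSE), tolerance = 0.25)
})

test_that("excitation thinning selects every k-th frame from the start", {
  model <- toy_dho()
  cfg <- toy_md_config(300, 0.5, 1000L, 0.05, seed = 3L)
  tr <- simulate_langevin(model, cfg)
  st <- dho_excite_trajectory(model, tr, every = 100L)
  expect_equal(nrow(st), 11L)   # frames 1, 101, ..., 1001
  ex <- dho_vertical_excitation(model, tr$coords[1, 1, 1])
  expect_equal(st$energy[1], ex$energy)
})
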