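test_that("the kernel sum evaluates Gaussian peaks and conserves strength", {
  one <- stick_table(1L, 3.0, 1.0)
  peak <- 1 / (0.1 * sqrt(2 * pi))
  expect_equal(kernel_regression_estimate(one, 0.1, 3.0), peak)
  expect_equal(kernel_regression_estimate(one, 0.1, c(2.9, 3.1)),
               rep(peak * exp(-0.5), 2))
  # integral over a wide grid = sum of strengths
  st <- stick_table(c(1L, 1L, 2L), c(2.8, 3.1, 3.4), c(1, 0.2, 0.6))
  g <- seq(1.5, 4.7, by = 0.001)
  expect_equal(nuqspec:::.trapz(g, kernel_regression_estimate(st, 0.1, g)),
               sum(st$strength), tolerance = 1e-6)
  expect_error(kernel_regression_estimate(one, -0.1, 3), "positive")
})

test_that("broadening averages per snapshot and superposes cleanly", {
  one <- stick_table(1L, 3.0, 0.7)
  cv <- broaden_sticks(one, 0.05)
  expect_equal(nuqspec:::.trapz(cv$grid, cv$values), 0.7, tolerance = 1e-6)

  # duplicating every snapshot leaves the per-snapshot-average curve fixed
  st <- stick_table(c(1L, 1L, 2L), c(2.8, 3.1, 3.4), c(1, 0.2, 0.6))
  dup <- stick_table(c(st$snapshot, st$snapshot + 10L),
                     rep(st$energy, 2), rep(st$strength, 2))
  g <- seq(2, 4.2, by = 0.002)
  expect_equal(broaden_sticks(dup, 0.1, g)$values,
               broaden_sticks(st, 0.1, g)$values, tolerance = 1e-12)

  # two sticks 10 widths apart = two isolated Gaussians
  d <- 0.05
  far <- stick_table(c(1L, 1L), c(3.0, 3.0 + 10 * d), c(1, 0.5))
  g2 <- seq(2.6, 3.9, by = 0.001)
  iso <- dnorm(g2, 3.0, d) + 0.5 * dnorm(g2, 3.5, d)
  expect_equal(broaden_sticks(far, d, g2)$values, iso, tolerance = 1e-8)
  expect_error(broaden_sticks(st, 0), "positive")
})

test_that("the closed-form amplitude reproduces isolated-stick identities", {
  d <- 0.08
  one <- stick_table(1L, 3.0, 2.5)
  expect_equal(fit_amplitude(one, d)$a, d * sqrt(2 * pi), tolerance = 1e-12)
  # two sticks far apart: same identity regardless of strengths
  far <- stick_table(c(1L, 2L), c(2.0, 4.0), c(1.7, 0.3))
  expect_equal(fit_amplitude(far, d)$a, d * sqrt(2 * pi), tolerance = 1e-8)
  # scale invariance: a unchanged when all Y are rescaled
  st <- make_envelope_sticks(200, seed = 1)
  st2 <- stick_table(st$snapshot, st$energy, st$strength * 7.3)
  expect_equal(fit_amplitude(st2, d)$a, fit_amplitude(st, d)$a,
               tolerance = 1e-10)
  expect_error(fit_amplitude(stick_table(1L, 3, 0), d), "degenerate")
})

test_that("leave-one-out loss matches the brute-force per-record refit", {
  st <- make_envelope_sticks(60, seed = 4)
  for (d in c(0.02, 0.1, 0.4)) {
    expect_equal(loo_cv_loss(st, d), brute_force_loo(st, d),
                 tolerance = 1e-10)
  }
  # coincident pair: loss is exactly 1/2 for every width
  pair <- stick_table(c(1L, 2L), c(1.0, 1.0), c(1, 1))
  for (d in c(0.01, 0.1, 1)) expect_equal(loo_cv_loss(pair, d), 0.5)
  expect_error(loo_cv_loss(stick_table(1L, 3, 1), 0.1), "at least 2")
})

test_that("bandwidth optimization is self-consistent and flags degenerate scans", {
  st <- make_envelope_sticks(300, seed = 8)
  scan <- optimize_bandwidth(st, c(0.005, 0.5), 15)
  expect_false(scan$boundary_warning)
  expect_equal(scan$optimum, scan$deltas[which.min(scan$cv_losses)])
  expect_equal(loo_cv_loss(st, scan$optimum), min(scan$cv_losses),
               tolerance = 1e-12)
  # refinement actually beats every coarse neighbor
  expect_lte(min(scan$cv_losses), min(vapply(scan$deltas, function(d)
    loo_cv_loss(st, d), numeric(1))))

  pair <- stick_table(c(1L, 2L), c(1.0, 1.0), c(1, 1))
  expect_true(optimize_bandwidth(pair, c(0.01, 0.1), 10)$boundary_warning)

  # kernel-convention invariance: unit-height kernels rescale a by
  # delta*sqrt(2pi) but leave the CV loss (hence its argmin) unchanged
  unit_height_loo <- function(sticks, delta) {
    X <- sticks$energy; Y <- sticks$strength
    s <- vapply(X, function(x) sum(Y * exp(-(x - X)^2 / (2 * delta^2))),
                numeric(1))
    a <- sum(Y * s) / sum(s^2)
    s_loo <- s - Y
    sum((Y - a * s_loo)^2)
  }
  for (d in c(0.05, 0.15)) {
    expect_equal(unit_height_loo(st, d), loo_cv_loss(st, d),
                 tolerance = 1e-10)
  }
})

test_that("single-geometry spectra use the ensemble machinery with one snapshot", {
  st <- stick_table(rep(1L, 3), c(3.0, 3.3, 3.6), c(1, 0.4, 0.2))
  g <- seq(2.2, 4.4, by = 0.002)
  expect_equal(single_point_spectrum(st, 0.2, g)$values,
               broaden_sticks(st, 0.2, g)$values)
  expect_equal(formals(single_point_spectrum)$delta, 0.14)
  multi <- stick_table(c(1L, 2L), c(3, 3.2), c(1, 1))
  expect_error(single_point_spectrum(multi, 0.2, g), "one snapshot")

  # widening the kernel pulls the apparent maximum of a weak band toward a
  # stronger neighbor as the two merge (the blueshift seen when stronger
  # excitations sit next to an observed peak)
  two <- stick_table(rep(1L, 2), c(3.0, 3.6), c(0.45, 1))
  weak_peak_at <- function(d) {
    cv <- single_point_spectrum(two, d, g)
    win <- cv$grid >= 2.6 & cv$grid <= 3.3
    cv$grid[win][which.max(cv$values[win])]
  }
  expect_gt(weak_peak_at(0.18), weak_peak_at(0.08))
  # and once fully merged, the single maximum sits nearer the stronger stick
  merged <- single_point_spectrum(two, 0.35, g)
  mx <- merged$grid[which.max(merged$values)]
  expect_lt(abs(mx - 3.6), abs(mx - 3.0))
})

test_that("Marcus broadening follows sigma = sqrt(2 kB T Er)", {
  expect_equal(marcus_broadening(0, 300), 0)
  expect_equal(marcus_broadening(0.1, 300), 0.0719, tolerance = 1e-3)
  expect_equal(marcus_broadening(0.0174, 300), 0.030, tolerance = 1e-2)
  expect_error(marcus_broadening(-0.1, 300), "E_r")
})

test_that("axis conversion is exact, invertible, and optionally area-conserving", {
  g <- seq(1.6, 4.4, by = 0.01)
  cv <- spectrum_curve(g, dnorm(g, 3, 0.3), "energy-eV",
                       meta = list(delta = 0.05, snapshots = 1L))
  nm <- convert_axis(cv, "wavelength-nm")
  expect_equal(max(nm$grid), nuq_constants$ev_nm / 1.6)
  expect_equal(sort(nuq_constants$ev_nm / nm$grid), g, tolerance = 1e-12)
  expect_equal(nuq_constants$ev_nm / 4.2, 295.2, tolerance = 1e-3)
  expect_equal(nuq_constants$ev_nm / 1.0, 1239.84, tolerance = 1e-4)
  back <- convert_axis(nm, "energy-eV")
  expect_equal(back$grid, g, tolerance = 1e-9)
  expect_equal(back$values, cv$values, tolerance = 1e-9)
  # Jacobian mode conserves integrated area
  nmj <- convert_axis(cv, "wavelength-nm", jacobian = TRUE)
  expect_equal(nuqspec:::.trapz(nmj$grid, nmj$values),
               nuqspec:::.trapz(g, cv$values), tolerance = 1e-4)
  expect_error(convert_axis(spectrum_curve(c(-1, 1), c(0, 0), "energy-eV")),
               "positive")
})

test_that("window normalization yields unit area and is scale invariant", {
  g <- seq(250, 800, by = 0.5)
  cv <- spectrum_curve(g, dnorm(g, 420, 60), "wavelength-nm",
                       meta = list(delta = 0.1, snapshots = 5L))
  nrm <- normalize_window(cv, c(300, 700))
  expect_equal(nuqspec:::.window_area(nrm$grid, nrm$values, c(300, 700)), 1,
               tolerance = 1e-10)
  expect_equal(nrm$meta$normalization, "unit-area-window")
  scaled <- spectrum_curve(g, cv$values * 13, "wavelength-nm", meta = cv$meta)
  expect_equal(normalize_window(scaled, c(300, 700))$values, nrm$values,
               tolerance = 1e-12)
  outside <- spectrum_curve(seq(100, 200, 1), rep(1, 101), "wavelength-nm")
  expect_error(normalize_window(outside, c(300, 700)), "no area")
  expect_error(normalize_window(convert_axis(nrm, "energy-eV")), "wavelength")
})

test_that("spectra converge toward the full ensemble as snapshots accumulate", {
  set.seed(19)
  n <- 400
  x <- rnorm(n, 3.2, 0.2)
  st <- stick_table(seq_len(n), x, rep(1, n))
  cp <- convergence_profile(st, c(10, 50, 200, 400), delta = 0.05,
                            n_random = 6, seed = 2)
  expect_equal(cp$distance[4], 0, tolerance = 1e-12)
  expect_lt(cp$distance[3], cp$distance[1])
  # random-subset scatter concentrates with k
  expect_lt(mean(cp$random[3, ]), mean(cp$random[1, ]))
  expect_error(convergence_profile(st, 1000, 0.05), "subset sizes")
})

test_that("spectrum curves round-trip through their TSV format", {
  g <- seq(300, 700, by = 1)
  cv <- spectrum_curve(g, dnorm(g, 450, 40), "wavelength-nm",
                       meta = list(delta = 0.045, snapshots = 800L,
                                   normalization = "unit-area-window",
                                   window = c(300, 700)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_curve(cv, path)
  back <- read_spectrum_curve(path)
  expect_equal(back$grid, cv$grid)
  expect_equal(back$values, cv$values, tolerance = 1e-9)
  expect_equal(back$meta$delta, 0.045)
  expect_equal(back$meta$window, c(300, 700))
})
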