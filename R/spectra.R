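#' Spectrum curve container
#'
#' A continuous absorption curve on an energy (eV) or wavelength (nm)
#' axis, with the broadening metadata needed to reproduce it.
#'
#' @param grid strictly ascending axis values.
#' @param values non-negative intensities, same length as \code{grid}.
#' @param axis_kind \code{"energy-eV"} or \code{"wavelength-nm"}.
#' @param meta list: \code{delta} (eV), \code{snapshots},
#'   \code{normalization} (\code{"none"} or \code{"unit-area-window"}),
#'   \code{window} (nm interval or NULL).
#' @return object of class \code{"spectrum_curve"}.
#' @export
spectrum_curve <- function(grid, values,
                           axis_kind = c("energy-eV", "wavelength-nm"),
                           meta = list()) {
  axis_kind <- match.arg(axis_kind)
  grid <- as.numeric(grid); values <- as.numeric(values)
  if (length(grid) != length(values)) .stopf("grid/values length mismatch")
  if (is.unsorted(grid, strictly = TRUE)) .stopf("grid must be strictly ascending")
  if (!all(is.finite(values)) || any(values < -1e-12)) {
    .stopf("intensities must be finite and non-negative")
  }
  meta <- utils::modifyList(
    list(delta = NA_real_, snapshots = NA_integer_,
         normalization = "none", window = NULL), meta)
  structure(list(axis_kind = axis_kind, grid = grid,
                 values = pmax(values, 0), meta = meta),
            class = "spectrum_curve")
}

#' @export
print.spectrum_curve <- function(x, ...) {
  cat(sprintf("<spectrum_curve> %d points on %s axis [%g, %g], delta = %g eV, %s\n",
              length(x$grid), x$axis_kind, min(x$grid), max(x$grid),
              x$meta$delta, x$meta$normalization))
  invisible(x)
}

# sum_i Y_i K_delta(x - X_i) for each x; K is the unit-area Gaussian
# density of sd delta.
.kernel_sum <- function(X, Y, delta, x) {
  if (length(x) * length(X) <= 4e6) {
    colSums(Y * stats::dnorm(outer(X, x, "-"), sd = delta))
  } else {
    vapply(x, function(xi) sum(Y * stats::dnorm(xi - X, sd = delta)),
           numeric(1))
  }
}

#' Kernel-regression estimate of the stick envelope
#'
#' The raw Gaussian kernel sum
#' \eqn{\hat s(x) = \sum_i Y_i K_\Delta(x - X_i)}, where \eqn{K_\Delta}
#' is the unit-area Gaussian density with standard deviation
#' \eqn{\Delta} (eV). The integral of \eqn{\hat s} over all x equals
#' \eqn{\sum_i Y_i}.
#'
#' @param sticks a \code{\link{stick_table}}.
#' @param delta kernel width (standard deviation), eV, > 0.
#' @param x evaluation point(s), eV.
#' @return intensities at \code{x}.
#' @export
kernel_regression_estimate <- function(sticks, delta, x) {
  stopifnot(inherits(sticks, "stick_table"))
  if (delta <= 0) .stopf("delta must be positive (eV)")
  .kernel_sum(sticks$energy, sticks$strength, delta, x)
}

#' Broaden a stick table into a spectrum
#'
#' Gaussian broadening of pooled vertical excitations: each stick becomes
#' a unit-area Gaussian of standard deviation \code{delta} scaled by its
#' oscillator strength, and the sum is divided by the number of snapshots
#' so that ensembles of different sizes are directly comparable. The
#' curve integral therefore equals the per-snapshot mean total oscillator
#' strength at any \code{delta}.
#'
#' @param sticks a \code{\link{stick_table}}.
#' @param delta Gaussian standard deviation, eV, > 0.
#' @param grid ascending energy axis (eV); should cover
#'   \code{range(energy) + c(-5, 5) * delta} unless truncation is wanted.
#' @return a \code{\link{spectrum_curve}} on the energy axis.
#' @export
broaden_sticks <- function(sticks, delta, grid = NULL) {
  stopifnot(inherits(sticks, "stick_table"))
  if (delta <= 0) .stopf("delta must be positive (eV)")
  if (is.null(grid)) {
    grid <- seq(min(sticks$energy) - 5 * delta,
                max(sticks$energy) + 5 * delta, length.out = 2000L)
  }
  nsnap <- length(unique(sticks$snapshot))
  vals <- .kernel_sum(sticks$energy, sticks$strength, delta, grid) / nsnap
  spectrum_curve(grid, vals, "energy-eV",
                 meta = list(delta = delta, snapshots = nsnap))
}

#' Single-geometry spectrum
#'
#' Spectrum of one nuclear configuration: identical to
#' \code{\link{broaden_sticks}} restricted to a single snapshot, with the
#' kernel width supplied by the caller. The default width of 0.14 eV is
#' the empirical value typically needed for single-point spectra to mimic
#' ensemble broadening; it is a documented default, not a computed
#' optimum.
#'
#' @param sticks a \code{\link{stick_table}} containing exactly one
#'   snapshot id.
#' @param delta Gaussian standard deviation, eV (default 0.14).
#' @param grid ascending energy axis, eV.
#' @return a \code{\link{spectrum_curve}}.
#' @export
single_point_spectrum <- function(sticks, delta = 0.14, grid = NULL) {
  stopifnot(inherits(sticks, "stick_table"))
  if (length(unique(sticks$snapshot)) != 1L) {
    .stopf("single-point spectrum requires exactly one snapshot id")
  }
  broaden_sticks(sticks, delta, grid)
}

#' Optimal kernel amplitude for a given width
#'
#' With the kernel width fixed, the global amplitude a that best maps the
#' kernel sum back onto the stick strengths minimizes the mean squared
#' error \eqn{L(a;\Delta) = N^{-1}\sum_i (Y_i - a\,\hat s(X_i))^2}, which
#' has the closed form
#' \eqn{a(\Delta) = \sum_i Y_i \hat s(X_i) / \sum_i \hat s(X_i)^2}
#' (self-term included). With the unit-area kernel convention, a carries
#' the axis unit (eV); for a single isolated stick
#' \eqn{a = \Delta\sqrt{2\pi}} exactly.
#'
#' @param sticks a \code{\link{stick_table}} with at least one record and
#'   not all strengths zero.
#' @param delta kernel width, eV, > 0.
#' @return list with \code{a} (eV), \code{loss} (the minimized mean
#'   squared error).
#' @export
fit_amplitude <- function(sticks, delta) {
  stopifnot(inherits(sticks, "stick_table"))
  if (delta <= 0) .stopf("delta must be positive (eV)")
  if (all(sticks$strength == 0)) {
    .stopf("all oscillator strengths are zero: amplitude fit is degenerate")
  }
  s <- .kernel_sum(sticks$energy, sticks$strength, delta, sticks$energy)
  a <- sum(sticks$strength * s) / sum(s^2)
  n <- nrow(sticks)
  list(a = a, loss = mean((sticks$strength - a * s)^2))
}

#' Leave-one-out cross-validation loss for a kernel width
#'
#' How well each stick's strength is predicted by the kernel sum built
#' from all the other sticks:
#' \eqn{L_{cv}(\Delta) = \sum_i (Y_i - a(\Delta)\,\hat s_{-i}(X_i))^2},
#' where \eqn{\hat s_{-i}} omits record i and \eqn{a(\Delta)} is the
#' full-data amplitude of \code{\link{fit_amplitude}}. The leave-one-out
#' sum is computed by subtracting the self-term \eqn{Y_i K_\Delta(0)}
#' from the full kernel sum, which is algebraically identical to refitting
#' per left-out point.
#'
#' @param sticks a \code{\link{stick_table}} with at least 2 records.
#' @param delta kernel width, eV, > 0.
#' @return the loss (scalar).
#' @export
loo_cv_loss <- function(sticks, delta) {
  stopifnot(inherits(sticks, "stick_table"))
  if (nrow(sticks) < 2L) {
    .stopf("leave-one-out needs at least 2 records")
  }
  if (delta <= 0) .stopf("delta must be positive (eV)")
  X <- sticks$energy; Y <- sticks$strength
  s <- .kernel_sum(X, Y, delta, X)
  a <- sum(Y * s) / sum(s^2)
  s_loo <- s - Y * stats::dnorm(0, sd = delta)
  sum((Y - a * s_loo)^2)
}

#' Select the kernel width by leave-one-out cross-validation
#'
#' Evaluates \code{\link{loo_cv_loss}} on a log-spaced width grid over
#' \code{delta_range}, then refines the best interior bracket by
#' golden-section search to a relative tolerance of 1e-3. Ties are broken
#' toward the smaller width (less artificial smoothing). If the loss is
#' minimal at a grid boundary (including the flat degenerate case) the
#' result carries a \code{boundary_warning}: the range is probably wrong
#' for the data. The full scan is kept so the loss profile can be
#' plotted.
#'
#' @param sticks a \code{\link{stick_table}}, >= 2 records.
#' @param delta_range length-2 positive interval of widths, eV.
#' @param n_grid number of scan points, >= 10.
#' @return object of class \code{"bandwidth_scan"}: list with
#'   \code{deltas}, \code{cv_losses}, \code{optimum} (eV),
#'   \code{amplitude} (a at the optimum), \code{boundary_warning}.
#' @export
optimize_bandwidth <- function(sticks, delta_range = c(0.005, 0.5),
                               n_grid = 30L) {
  stopifnot(inherits(sticks, "stick_table"))
  if (nrow(sticks) < 2L) .stopf("bandwidth selection needs at least 2 records")
  if (length(delta_range) != 2L || any(delta_range <= 0) ||
      delta_range[1] >= delta_range[2]) {
    .stopf("delta_range must be an ascending positive interval (eV)")
  }
  if (n_grid < 10L) .stopf("n_grid must be >= 10")
  X <- sticks$energy; Y <- sticks$strength
  D <- if (length(X) <= 3000L) outer(X, X, "-") else NULL
  lcv <- function(delta) {
    s <- if (is.null(D)) {
      .kernel_sum(X, Y, delta, X)
    } else {
      as.vector(Y %*% stats::dnorm(D, sd = delta))
    }
    a <- sum(Y * s) / sum(s^2)
    s_loo <- s - Y * stats::dnorm(0, sd = delta)
    sum((Y - a * s_loo)^2)
  }
  deltas <- exp(seq(log(delta_range[1]), log(delta_range[2]),
                    length.out = n_grid))
  losses <- vapply(deltas, lcv, numeric(1))
  i <- which.min(losses)   # first minimum -> smaller delta on ties
  boundary <- i == 1L || i == n_grid ||
    diff(range(losses)) <= 1e-12 * max(abs(losses))
  best_delta <- deltas[i]
  if (!boundary) {
    opt <- stats::optimize(lcv, interval = c(deltas[i - 1L], deltas[i + 1L]),
                           tol = best_delta * 1e-3)
    if (opt$objective <= losses[i]) {
      best_delta <- opt$minimum
      deltas <- c(deltas, opt$minimum)
      losses <- c(losses, opt$objective)
      ord <- order(deltas)
      deltas <- deltas[ord]; losses <- losses[ord]
    }
  }
  structure(
    list(deltas = deltas, cv_losses = losses, optimum = best_delta,
         amplitude = fit_amplitude(sticks, best_delta)$a,
         boundary_warning = boundary),
    class = "bandwidth_scan"
  )
}

#' @export
print.bandwidth_scan <- function(x, ...) {
  cat(sprintf("<bandwidth_scan> %d widths in [%g, %g] eV; optimum %.4g eV%s\n",
              length(x$deltas), min(x$deltas), max(x$deltas), x$optimum,
              if (x$boundary_warning) " (BOUNDARY: range suspect)" else ""))
  invisible(x)
}

#' Marcus-theory solvent broadening
#'
#' Gaussian width of the solvent-induced inhomogeneous broadening from
#' the linear-response (Marcus) relation \eqn{\sigma^2 = 2 k_B T E_r},
#' where \eqn{E_r} is the solvent reorganization energy of the vertical
#' transition.
#'
#' @param reorganization_energy E_r, eV, >= 0.
#' @param temperature K, > 0.
#' @return sigma in eV.
#' @export
#' @examples
#' marcus_broadening(0.1, 300)  # ~0.072 eV
marcus_broadening <- function(reorganization_energy, temperature) {
  if (any(reorganization_energy < 0)) .stopf("E_r must be >= 0 (eV)")
  if (any(temperature <= 0)) .stopf("temperature must be positive (K)")
  sqrt(2 * nuq_constants$kB_ev * temperature * reorganization_energy)
}

#' Convert a spectrum between energy and wavelength axes
#'
#' Pointwise \eqn{\lambda\,[nm] = 1239.84198 / E\,[eV]}, with the grid
#' re-sorted ascending. By default intensities are re-plotted unchanged
#' (the usual presentation for area-normalized shapes); with
#' \code{jacobian = TRUE} they are multiplied by \eqn{|dE/d\lambda|} so
#' that integrated area is conserved.
#'
#' @param curve a \code{\link{spectrum_curve}}.
#' @param target \code{"energy-eV"} or \code{"wavelength-nm"}.
#' @param jacobian logical, default FALSE.
#' @return a \code{\link{spectrum_curve}} on the target axis.
#' @export
convert_axis <- function(curve, target = c("wavelength-nm", "energy-eV"),
                         jacobian = FALSE) {
  stopifnot(inherits(curve, "spectrum_curve"))
  target <- match.arg(target)
  if (identical(curve$axis_kind, target)) return(curve)
  if (any(curve$grid <= 0)) .stopf("axis values must be positive to convert")
  new_grid <- nuq_constants$ev_nm / curve$grid
  vals <- curve$values
  if (jacobian) {
    vals <- vals * nuq_constants$ev_nm / new_grid^2   # |dE/dlambda| or |dlambda/dE|^-1
  }
  ord <- order(new_grid)
  spectrum_curve(new_grid[ord], vals[ord], target, meta = curve$meta)
}

#' Normalize a spectrum to unit area in a wavelength window
#'
#' Scales the curve so the trapezoidal area inside the window (default
#' 300-700 nm) equals 1, the convention that makes spectra of different
#' ensembles and broadenings comparable by shape. The curve must be on
#' the wavelength axis and overlap the window with nonzero area.
#'
#' @param curve a \code{\link{spectrum_curve}} on the nm axis.
#' @param window length-2 nm interval, default \code{c(300, 700)}.
#' @return the rescaled \code{\link{spectrum_curve}}, with
#'   \code{normalization = "unit-area-window"} recorded.
#' @export
normalize_window <- function(curve, window = c(300, 700)) {
  stopifnot(inherits(curve, "spectrum_curve"))
  if (curve$axis_kind != "wavelength-nm") {
    .stopf("normalize_window expects a wavelength-nm curve; use convert_axis first")
  }
  area <- .window_area(curve$grid, curve$values, window)
  if (!is.finite(area) || area <= 0) {
    .stopf("curve has no area inside [%g, %g] nm", window[1], window[2])
  }
  spectrum_curve(curve$grid, curve$values / area, curve$axis_kind,
                 meta = utils::modifyList(curve$meta,
                   list(normalization = "unit-area-window",
                        window = window)))
}

# trapezoidal area of (x, y) restricted to [w1, w2], with linear
# interpolation at the window edges.
.window_area <- function(x, y, window) {
  lo <- max(window[1], min(x)); hi <- min(window[2], max(x))
  if (lo >= hi) return(0)
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, lo)$y, y[inside], stats::approx(x, y, hi)$y)
  .trapz(xs, ys)
}

#' Spectral convergence with the number of snapshots
#'
#' Rebuilds the broadened, area-normalized spectrum from the first k
#' snapshots for each requested k and reports its distance to the
#' full-ensemble spectrum — the standard check that enough configurations
#' have been sampled. Optionally repeats each k with random snapshot
#' subsets to show how the subset scatter concentrates as k grows.
#'
#' @param sticks a \code{\link{stick_table}}.
#' @param subset_sizes snapshot counts, each <= the number of snapshots.
#' @param delta kernel width, eV.
#' @param distance \code{"max-abs"} or \code{"L1"} between unit-area
#'   normalized curves on a common energy grid.
#' @param n_random random subsets per size (0 = none).
#' @param seed RNG seed for the random subsets.
#' @return list with \code{sizes}, \code{distance} (one per size, first-k
#'   subsets), and \code{random} (sizes x n_random matrix or NULL).
#' @export
convergence_profile <- function(sticks, subset_sizes, delta,
                                distance = c("max-abs", "L1"),
                                n_random = 0L, seed = NULL) {
  stopifnot(inherits(sticks, "stick_table"))
  distance <- match.arg(distance)
  snaps <- unique(sticks$snapshot)
  if (any(subset_sizes > length(snaps)) || any(subset_sizes < 1)) {
    .stopf("subset sizes must be in [1, %d] (available snapshots)",
           length(snaps))
  }
  grid <- seq(min(sticks$energy) - 5 * delta, max(sticks$energy) + 5 * delta,
              length.out = 1200L)
  norm_curve <- function(ids) {
    sub <- sticks[sticks$snapshot %in% ids, , drop = FALSE]
    v <- .kernel_sum(sub$energy, sub$strength, delta, grid) / length(ids)
    v / .trapz(grid, v)
  }
  dist_fn <- function(a, b) {
    if (distance == "max-abs") max(abs(a - b)) else .trapz(grid, abs(a - b))
  }
  full <- norm_curve(snaps)
  d_first <- vapply(subset_sizes, function(k) {
    dist_fn(norm_curve(snaps[seq_len(k)]), full)
  }, numeric(1))
  rand <- NULL
  if (n_random > 0L) {
    rand <- .with_seed(seed, {
      sapply(seq_len(n_random), function(r) {
        vapply(subset_sizes, function(k) {
          dist_fn(norm_curve(sample(snaps, k)), full)
        }, numeric(1))
      })
    })
    rand <- matrix(rand, nrow = length(subset_sizes))
  }
  list(sizes = as.integer(subset_sizes), distance = d_first, random = rand)
}

#' Write a spectrum curve as TSV
#'
#' Two columns (axis, intensity) with \code{#} header lines recording the
#' axis kind, kernel width, snapshot count and normalization, re-readable
#' by \code{\link{read_spectrum_curve}}.
#'
#' @param curve a \code{\link{spectrum_curve}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_spectrum_curve <- function(curve, path) {
  stopifnot(inherits(curve, "spectrum_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# axis_kind: %s", curve$axis_kind),
    sprintf("# delta_eV: %.10g", curve$meta$delta),
    sprintf("# snapshots: %d", curve$meta$snapshots),
    sprintf("# normalization: %s", curve$meta$normalization),
    if (!is.null(curve$meta$window)) {
      sprintf("# window_nm: %g %g", curve$meta$window[1], curve$meta$window[2])
    },
    "axis\tintensity"), con)
  writeLines(sprintf("%.10g\t%.10g", curve$grid, curve$values), con)
  invisible(path)
}

#' @rdname write_spectrum_curve
#' @export
read_spectrum_curve <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    h <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    if (length(h)) trimws(sub(paste0("^# ", key, ":"), "", h[1])) else NA
  }
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body[-1L], sep = "\t",
                          col.names = c("axis", "intensity"))
  window <- get("window_nm")
  meta <- list(
    delta = as.numeric(get("delta_eV")),
    snapshots = as.integer(get("snapshots")),
    normalization = if (is.na(get("normalization"))) "none" else get("normalization"),
    window = if (!is.na(window)) as.numeric(strsplit(window, " ")[[1]])
  )
  spectrum_curve(df$axis, df$intensity,
                 axis_kind = get("axis_kind"), meta = meta)
}
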