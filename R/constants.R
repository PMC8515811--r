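# Physical constants (CODATA 2018) in the package's working units:
# Angstrom, femtosecond, electronvolt, amu, Kelvin, cm^-1.

#' Physical constants used throughout nuqspec
#'
#' A named list of the conversion constants the package works with.
#' All internal unit conversions go through these values; nothing else
#' in the package hard-codes a physical constant.
#'
#' \describe{
#'   \item{hc_ev_cm}{Planck constant times speed of light, eV·cm. Multiplying
#'     a wavenumber in cm^-1 by this gives a photon/vibrational quantum in eV.}
#'   \item{kB_ev}{Boltzmann constant, eV/K.}
#'   \item{h_ev_fs}{Planck constant, eV·fs.}
#'   \item{hbar_ev_fs}{Reduced Planck constant, eV·fs.}
#'   \item{ev_nm}{Photon energy-wavelength product, eV·nm
#'     (lambda\[nm\] = ev_nm / E\[eV\]).}
#'   \item{ev_per_internal}{1 amu·Angstrom^2/fs^2 expressed in eV; converts the
#'     natural energy unit of (amu, Angstrom, fs) dynamics to eV.}
#' }
#' @export
#' @examples
#' nuq_constants$hc_ev_cm * 3000  # a 3000 cm^-1 quantum in eV
nuq_constants <- local({
  e_charge <- 1.602176634e-19   # C (exact)
  amu_kg   <- 1.66053906892e-27 # kg
  list(
    hc_ev_cm        = 1.23984198e-4,
    kB_ev           = 8.617333262e-5,
    h_ev_fs         = 4.135667696,
    hbar_ev_fs      = 4.135667696 / (2 * pi),
    ev_nm           = 1239.84198,
    ev_per_internal = amu_kg * 1e-20 / 1e-30 / e_charge
  )
})

# quantum of a mode in eV from its wavenumber in cm^-1
.mode_quantum_ev <- function(freq_cm) nuq_constants$hc_ev_cm * freq_cm

# angular frequency in fs^-1 from a wavenumber in cm^-1
.omega_fs <- function(freq_cm) .mode_quantum_ev(freq_cm) / nuq_constants$hbar_ev_fs

# hbar in internal units (amu * Angstrom^2 / fs)
.hbar_internal <- function() nuq_constants$hbar_ev_fs / nuq_constants$ev_per_internal

# kB*T in internal units (amu * Angstrom^2 / fs^2)
.kT_internal <- function(temperature) {
  nuq_constants$kB_ev * temperature / nuq_constants$ev_per_internal
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# trapezoidal integral of y over x (x ascending)
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
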