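#' Harmonic normal-mode set
#'
#' Reference geometry plus the harmonic vibrational analysis needed for
#' Wigner or classical-thermal configurational sampling: atomic masses,
#' mode wavenumbers, and Cartesian displacement vectors that are
#' orthonormal in mass-weighted coordinates.
#'
#' The displacement convention is the usual one for mass-weighted normal
#' coordinates: a configuration is \eqn{x = x_ref + \sum_j d_j Q_j}, where
#' \eqn{Q_j} is the mode coordinate in \eqn{\sqrt{amu}\cdot\AA} and the
#' mass-weighted vectors \eqn{\sqrt{m} \odot d_j} are orthonormal. For a
#' single atom of mass 1 amu moving along x this reduces to the textbook
#' 1-D oscillator with displacement (1, 0, 0).
#'
#' @param reference_geometry atoms x 3 matrix, Angstrom.
#' @param masses atomic masses, amu (one per atom, > 0).
#' @param frequencies mode wavenumbers in cm^-1, sorted ascending, all > 0
#'   (imaginary modes are not supported).
#' @param displacements modes x (3 atoms) matrix, or modes x atoms x 3
#'   array, of Cartesian displacement vectors (rows flattened atom-major:
#'   x1 y1 z1 x2 ...).
#' @param elements optional chemical symbols (defaults to "X").
#' @param tol orthonormality tolerance on the mass-weighted Gram matrix.
#' @return An object of class \code{"normal_modes"}.
#' @export
normal_modes <- function(reference_geometry, masses, frequencies,
                         displacements, elements = NULL, tol = 1e-6) {
  reference_geometry <- as.matrix(reference_geometry)
  if (ncol(reference_geometry) != 3L) .stopf("reference geometry must be atoms x 3")
  na <- nrow(reference_geometry)
  masses <- as.numeric(masses)
  if (length(masses) != na || any(!is.finite(masses) | masses <= 0)) {
    .stopf("need one positive mass per atom")
  }
  frequencies <- as.numeric(frequencies)
  if (any(!is.finite(frequencies) | frequencies <= 0)) {
    .stopf("mode frequencies must be positive (cm^-1); imaginary modes unsupported")
  }
  if (is.unsorted(frequencies)) .stopf("frequencies must be sorted ascending")
  nm <- length(frequencies)
  if (na > 1L && nm > 3L * na - 5L) {
    .stopf("%d modes exceeds the 3N-5 = %d internal degrees of freedom",
           nm, 3L * na - 5L)
  }
  if (length(dim(displacements)) == 3L) {
    # modes x atoms x 3 -> modes x 3N, atom-major (x1 y1 z1 x2 ...)
    displacements <- t(apply(displacements, 1L, function(m) as.vector(t(m))))
  }
  displacements <- as.matrix(displacements)
  if (nrow(displacements) != nm || ncol(displacements) != 3L * na) {
    .stopf("displacements must be %d x %d (modes x 3N, atom-major x y z)",
           nm, 3L * na)
  }
  sqm <- rep(sqrt(masses), each = 3L)   # length 3N, atom-major
  mw <- sweep(displacements, 2L, sqm, `*`)
  gram <- mw %*% t(mw)
  dev <- abs(gram - diag(nm))
  if (max(dev) > tol) {
    worst <- which(dev == max(dev), arr.ind = TRUE)[1, ]
    .stopf(paste0("mode displacements are not orthonormal in mass-weighted ",
                  "coordinates: worst overlap |<%d|%d> - delta| = %.3g"),
           worst[1], worst[2], max(dev))
  }
  if (is.null(elements)) elements <- rep("X", na)
  structure(
    list(reference_geometry = reference_geometry, masses = masses,
         frequencies = frequencies, displacements = displacements,
         elements = as.character(elements)),
    class = "normal_modes"
  )
}

#' @export
print.normal_modes <- function(x, ...) {
  cat(sprintf("<normal_modes> %d atoms, %d modes (%.1f - %.1f cm^-1)\n",
              nrow(x$reference_geometry), length(x$frequencies),
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Read a normal-mode file
#'
#' Parses the plain-text normal-mode format written by
#' \code{\link{write_normal_modes}}: keyword blocks \code{natoms},
#' \code{nmodes}, \code{elements}, \code{masses} (amu),
#' \code{frequencies_cm}, \code{reference_geometry} (Angstrom, one
#' \code{x y z} line per atom) and one \code{mode <i>} block per mode with
#' the Cartesian displacement vector. Mass-weighted orthonormality of the
#' displacements is verified to 1e-6 on read.
#'
#' @param path input file.
#' @return A \code{\link{normal_modes}} object.
#' @export
read_normal_modes <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kw <- function(name) {
    i <- which(startsWith(lines, name))
    if (!length(i)) .stopf("normal-mode file %s: missing '%s' block", path, name)
    i[1]
  }
  nums <- function(i, n) {
    out <- numeric(0)
    while (length(out) < n) {
      i <- i + 1L
      v <- suppressWarnings(as.numeric(strsplit(lines[i], "[[:space:]]+")[[1]]))
      if (anyNA(v)) .stopf("normal-mode file %s: non-numeric value near '%s'",
                           path, lines[i])
      out <- c(out, v)
    }
    out[seq_len(n)]
  }
  na <- as.integer(sub("^natoms[[:space:]]+", "", lines[kw("natoms")]))
  nm <- as.integer(sub("^nmodes[[:space:]]+", "", lines[kw("nmodes")]))
  el_i <- which(startsWith(lines, "elements"))
  elements <- if (length(el_i)) {
    strsplit(lines[el_i[1] + 1L], "[[:space:]]+")[[1]]
  }
  masses <- nums(kw("masses"), na)
  freqs <- nums(kw("frequencies_cm"), nm)
  geom <- matrix(nums(kw("reference_geometry"), 3L * na), na, 3L, byrow = TRUE)
  disp <- matrix(0, nm, 3L * na)
  for (j in seq_len(nm)) {
    i <- which(lines == sprintf("mode %d", j))
    if (!length(i)) .stopf("normal-mode file %s: missing 'mode %d' block", path, j)
    disp[j, ] <- nums(i[1], 3L * na)
  }
  normal_modes(geom, masses, freqs, disp, elements = elements)
}

#' Write a normal-mode file
#'
#' @param modes a \code{\link{normal_modes}} object.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_normal_modes <- function(modes, path) {
  stopifnot(inherits(modes, "normal_modes"))
  na <- nrow(modes$reference_geometry)
  nm <- length(modes$frequencies)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w(sprintf("natoms %d", na), sprintf("nmodes %d", nm))
  w("elements", paste(modes$elements, collapse = " "))
  w("masses", paste(sprintf("%.10g", modes$masses), collapse = " "))
  w("frequencies_cm", paste(sprintf("%.10g", modes$frequencies), collapse = " "))
  w("reference_geometry")
  for (a in seq_len(na)) {
    w(paste(sprintf("%16.10f", modes$reference_geometry[a, ]), collapse = " "))
  }
  for (j in seq_len(nm)) {
    w(sprintf("mode %d", j))
    row <- matrix(modes$displacements[j, ], na, 3L, byrow = TRUE)
    for (a in seq_len(na)) {
      w(paste(sprintf("%16.10f", row[a, ]), collapse = " "))
    }
  }
  invisible(path)
}
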