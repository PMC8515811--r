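#' Molecular trajectory
#'
#' Container for an ordered sequence of Cartesian snapshots with a fixed
#' timestep, the central data structure passed between the Langevin
#' simulators, the GSTA filter, and the excitation stage.
#'
#' @param elements character vector of chemical symbols, one per atom.
#' @param coords numeric array of dimension \code{frames x atoms x 3},
#'   Cartesian coordinates in Angstrom. A \code{frames x 3} matrix is
#'   accepted for a single atom, and a length-3n vector for a single frame.
#' @param dt timestep between consecutive frames, fs. Must be positive.
#' @param provenance free-text metadata carried along (character).
#'
#' @return An object of class \code{"trajectory"}: a list with fields
#'   \code{elements}, \code{coords}, \code{dt}, \code{provenance}.
#' @export
#' @examples
#' tr <- trajectory("H", matrix(rnorm(30), 10, 3), dt = 0.5)
#' n_frames(tr)
trajectory <- function(elements, coords, dt, provenance = character()) {
  elements <- as.character(elements)
  n_atoms <- length(elements)
  if (n_atoms < 1L) .stopf("a trajectory needs at least one atom")
  if (is.matrix(coords) && n_atoms == 1L && ncol(coords) == 3L) {
    coords <- array(coords, dim = c(nrow(coords), 1L, 3L))
  }
  if (is.null(dim(coords)) && length(coords) == 3L * n_atoms) {
    coords <- array(coords, dim = c(1L, n_atoms, 3L))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != n_atoms ||
      dim(coords)[3] != 3L) {
    .stopf("coords must be a frames x %d x 3 array", n_atoms)
  }
  if (dim(coords)[1] < 1L) .stopf("a trajectory needs at least one frame")
  if (!all(is.finite(coords))) .stopf("non-finite coordinate in trajectory")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    .stopf("dt must be a single positive number (fs)")
  }
  structure(
    list(elements = elements, coords = coords, dt = as.numeric(dt),
         provenance = as.character(provenance)),
    class = "trajectory"
  )
}

#' @rdname trajectory
#' @param traj a \code{trajectory}.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, dt = %g fs\n",
              n_frames(x), n_atoms(x), x$dt))
  if (length(x$provenance)) cat(" provenance:", x$provenance[1], "\n")
  invisible(x)
}

#' Read a multi-frame XYZ trajectory
#'
#' Parses concatenated-frame XYZ (atom-count line, comment line, then one
#' \code{symbol x y z} line per atom; coordinates in Angstrom). The XYZ
#' format carries no timestep, so \code{dt} must be supplied.
#'
#' All frames must list the same atoms in the same order; a frame that does
#' not is reported by its (1-based) frame number.
#'
#' @param path path to the XYZ file.
#' @param dt timestep between frames in fs.
#' @return A \code{\link{trajectory}}.
#' @export
read_xyz_trajectory <- function(path, dt) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) .stopf("empty XYZ file: %s", path)
  frames <- list()
  elements <- NULL
  i <- 1L
  frame_no <- 0L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) {
      .stopf("line %d of %s: expected an atom count, got '%s'",
             i, path, lines[i])
    }
    frame_no <- frame_no + 1L
    if (i + 1L + nat > length(lines)) {
      .stopf("frame %d of %s is truncated", frame_no, path)
    }
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad)) {
      .stopf("line %d of %s: malformed atom line", i + 1L + bad[1], path)
    }
    sym <- vapply(toks, `[[`, "", 1L)
    xyz <- vapply(toks, function(t) {
      v <- suppressWarnings(as.numeric(t[2:4]))
      v
    }, numeric(3))
    if (anyNA(xyz)) {
      bad <- which(apply(is.na(xyz), 2, any))[1]
      .stopf("line %d of %s: non-numeric coordinate", i + 1L + bad, path)
    }
    if (is.null(elements)) {
      elements <- sym
    } else if (length(sym) != length(elements) || any(sym != elements)) {
      .stopf("frame %d of %s: atom count or element order differs from frame 1",
             frame_no, path)
    }
    frames[[frame_no]] <- t(xyz)  # atoms x 3
    i <- i + 2L + nat
  }
  coords <- array(0, dim = c(length(frames), length(elements), 3L))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory(elements, coords, dt,
             provenance = sprintf("read from %s", path))
}

#' Write a multi-frame XYZ trajectory
#'
#' Writes plain extended-free XYZ (Angstrom, no lattice). Coordinates are
#' printed with 8 decimal places so a read/write round trip is lossless to
#' well below 1e-6 Angstrom. The timestep is not stored in the file.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param path output path.
#' @param comment comment-line text (recycled per frame); frame index
#'   appended.
#' @return invisibly, \code{path}.
#' @export
write_xyz_trajectory <- function(traj, path, comment = "nuqspec") {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj); na <- n_atoms(traj)
  if (nf < 1L) .stopf("refusing to write an empty trajectory")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(c(as.character(na), sprintf("%s frame %d", comment, f)), con)
    writeLines(sprintf("%-3s %16.8f %16.8f %16.8f", traj$elements,
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
  invisible(path)
}
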