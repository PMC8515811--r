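#' Stick-spectrum table
#'
#' Pooled per-snapshot vertical excitations: each record is one electronic
#' transition with its excitation energy (eV) and oscillator strength
#' (dimensionless), tagged by the snapshot it came from. This is the input
#' to all broadening and bandwidth-selection operations.
#'
#' @param snapshot integer snapshot ids.
#' @param energy excitation energies, eV; must be finite and positive.
#' @param strength oscillator strengths; finite and non-negative.
#' @return A \code{data.frame} of class \code{"stick_table"} with columns
#'   \code{snapshot}, \code{energy}, \code{strength}.
#' @export
#' @examples
#' stick_table(c(0, 0, 1), c(3.0, 3.5, 3.1), c(1.0, 0.2, 0.9))
stick_table <- function(snapshot, energy, strength) {
  snapshot <- as.integer(snapshot)
  energy <- as.numeric(energy)
  strength <- as.numeric(strength)
  n <- length(snapshot)
  if (n < 1L) .stopf("a stick table needs at least one record")
  if (length(energy) != n || length(strength) != n) {
    .stopf("snapshot, energy, strength must have equal length")
  }
  if (anyNA(snapshot)) .stopf("non-integer snapshot id")
  if (!all(is.finite(energy)) || any(energy <= 0)) {
    .stopf("excitation energies must be finite and positive (eV)")
  }
  if (!all(is.finite(strength)) || any(strength < 0)) {
    .stopf("oscillator strengths must be finite and non-negative")
  }
  structure(
    data.frame(snapshot = snapshot, energy = energy, strength = strength),
    class = c("stick_table", "data.frame")
  )
}

#' Read a stick-spectrum table
#'
#' Reads a tab- or comma-separated file with the header
#' \code{snapshot, energy_eV, osc_strength}. Lines starting with \code{#}
#' are comments. Record order is preserved.
#'
#' @param path input file.
#' @return A \code{\link{stick_table}}.
#' @export
read_stick_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) .stopf("stick table %s has no data rows", path)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  header <- trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]])
  want <- c("snapshot", "energy_eV", "osc_strength")
  idx <- match(want, header)
  if (anyNA(idx)) {
    .stopf("stick table %s is missing column(s): %s", path,
           paste(want[is.na(idx)], collapse = ", "))
  }
  df <- utils::read.table(text = lines[-1L], sep = sep,
                          col.names = header, check.names = FALSE)
  stick_table(df[[idx[1]]], df[[idx[2]]], df[[idx[3]]])
}

#' Write a stick-spectrum table
#'
#' Tab-separated with the canonical header, re-readable by
#' \code{\link{read_stick_table}}.
#'
#' @param sticks a \code{\link{stick_table}}.
#' @param path output path.
#' @param comments optional character vector written as leading
#'   \code{#}-prefixed lines (e.g. the RNG seed or pipeline parameters).
#' @return invisibly, \code{path}.
#' @export
write_stick_table <- function(sticks, path, comments = character()) {
  stopifnot(inherits(sticks, "stick_table"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines("snapshot\tenergy_eV\tosc_strength", con)
  writeLines(sprintf("%d\t%.10g\t%.10g", sticks$snapshot, sticks$energy,
                     sticks$strength), con)
  invisible(path)
}
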