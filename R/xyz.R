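# XYZ geometry I/O (angstrom) and fragment-map parsing.

#' Read an XYZ geometry file
#'
#' Standard XYZ: atom count, comment line, then `element x y z` in angstrom.
#'
#' @param file Path to the XYZ file.
#' @return Tibble with columns `element`, `x`, `y`, `z` (angstrom); the
#'   comment line is attached as attribute `comment`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (length(lines) < 2) abort("truncated XYZ file", class = "iqfpen_parse_error")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    abort("XYZ parse error: first line must be the atom count",
          class = "iqfpen_parse_error")
  }
  if (length(lines) < n + 2) {
    abort("XYZ parse error: fewer atom lines than declared",
          class = "iqfpen_parse_error")
  }
  rows <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  bad <- vapply(rows, length, integer(1)) < 4
  if (any(bad)) abort("XYZ parse error: malformed atom line", class = "iqfpen_parse_error")
  geom <- tibble(
    element = vapply(rows, `[[`, character(1), 1),
    x = as.numeric(vapply(rows, `[[`, character(1), 2)),
    y = as.numeric(vapply(rows, `[[`, character(1), 3)),
    z = as.numeric(vapply(rows, `[[`, character(1), 4))
  )
  if (!all(is.finite(as.matrix(geom[, 2:4])))) {
    abort("XYZ parse error: non-numeric coordinates", class = "iqfpen_parse_error")
  }
  attr(geom, "comment") <- lines[2]
  geom
}

#' Write an XYZ geometry file
#' @param geometry Tibble with `element`, `x`, `y`, `z` (angstrom).
#' @param file Output path.
#' @param comment Comment line.
#' @return The path, invisibly.
#' @export
write_xyz <- function(geometry, file, comment = "") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    as.character(nrow(geometry)), comment,
    sprintf("%-2s %16.8f %16.8f %16.8f",
            geometry$element, geometry$x, geometry$y, geometry$z)
  ), con)
  invisible(file)
}

#' Parse a fragment map string
#'
#' Fragment maps use the CLI syntax `"A=1-8,B=9-16"` with 1-based inclusive
#' atom-index ranges (comma-separated ranges or single indices per fragment).
#'
#' @param spec Fragment map string, or a character vector of per-atom labels
#'   (returned unchanged after validation).
#' @param n_atoms Total number of atoms.
#' @return Character vector of length `n_atoms` with labels `"A"`/`"B"`.
#' @export
parse_fragments <- function(spec, n_atoms) {
  if (length(spec) == n_atoms && !grepl("=", spec[1])) {
    frag <- as.character(spec)
  } else {
    stopifnot(length(spec) == 1)
    frag <- rep(NA_character_, n_atoms)
    parts <- strsplit(spec, ",(?=[A-Za-z]+=)", perl = TRUE)[[1]]
    for (p in parts) {
      kv <- strsplit(p, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) abort("malformed fragment map", class = "iqfpen_config_error")
      lab <- trimws(kv[1])
      for (rng in strsplit(kv[2], ",", fixed = TRUE)[[1]]) {
        ab <- as.integer(strsplit(rng, "-", fixed = TRUE)[[1]])
        idx <- if (length(ab) == 2) seq(ab[1], ab[2]) else ab
        if (any(is.na(idx)) || any(idx < 1) || any(idx > n_atoms)) {
          abort("fragment map indices out of range", class = "iqfpen_config_error")
        }
        frag[idx] <- lab
      }
    }
  }
  if (any(is.na(frag))) {
    abort("fragment map must label every atom", class = "iqfpen_config_error")
  }
  if (length(unique(frag)) != 2) {
    abort("exactly two fragments are required", class = "iqfpen_config_error")
  }
  frag
}
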