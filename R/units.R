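# Physical constants and element tables. Internal units are atomic units
# (bohr, hartree, e); geometry I/O is in angstrom, reports in kcal/mol.

#' Unit conversion constants
#'
#' Conversion factors used throughout the package: all internal arithmetic is
#' in atomic units (bohr, hartree, electron charge), geometry files are read
#' and written in angstrom, and energies are reported in kcal/mol alongside
#' hartree.
#'
#' @format A named list with elements `bohr_per_angstrom` and
#'   `kcalmol_per_hartree`.
#' @export
iqf_units <- list(
  bohr_per_angstrom = 1.8897259886,
  kcalmol_per_hartree = 627.509474
)

#' Convert hartree to kcal/mol
#' @param e Energy in hartree.
#' @return Energy in kcal/mol.
#' @export
hartree_to_kcal <- function(e) e * iqf_units$kcalmol_per_hartree

# Nuclear charges for the elements the promolecular model supports.
.element_z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Br = 35, Kr = 36
)

element_z <- function(symbol) {
  z <- .element_z[symbol]
  bad <- is.na(z)
  if (any(bad)) {
    abort(paste0(
      "unknown element symbol(s): ", paste(unique(symbol[bad]), collapse = ", ")
    ), class = "iqfpen_parameter_error")
  }
  unname(z)
}

# Bondi van der Waals radii (angstrom), used for ESP fitting surfaces.
.vdw_radii_angstrom <- c(
  H = 1.20, He = 1.40, Li = 1.82, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Ne = 1.54, Na = 2.27, Mg = 1.73, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75,
  Ar = 1.88, K = 2.75, Br = 1.85, Kr = 2.02
)

vdw_radius_bohr <- function(symbol) {
  r <- .vdw_radii_angstrom[symbol]
  bad <- is.na(r)
  if (any(bad)) {
    abort(paste0(
      "no van der Waals radius tabulated for: ",
      paste(unique(symbol[bad]), collapse = ", ")
    ), class = "iqfpen_parameter_error")
  }
  unname(r) * iqf_units$bohr_per_angstrom
}
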