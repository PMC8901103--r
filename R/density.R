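# Promolecular Gaussian densities: atom-centred spherical Gaussian electron
# clouds plus point nuclei.  Each primitive integrates to its population q
# (electrons); the density value is q (alpha/pi)^{3/2} exp(-alpha r^2).

#' Construct a Gaussian fragment density
#'
#' A fragment's charge distribution: point nuclei plus an electron density
#' expanded in atom-centred spherical Gaussian primitives. All coordinates are
#' in bohr; primitive populations are in electrons.
#'
#' @param nuclei Tibble with columns `element`, `Z`, `x`, `y`, `z` (bohr).
#' @param primitives Tibble with columns `atom` (owning nucleus index), `x`,
#'   `y`, `z` (centre, bohr), `alpha` (exponent, bohr^-2), `q` (population,
#'   electrons, non-negative).
#' @param label Fragment tag (e.g. `"A"`).
#' @return An object of class `gaussian_density`.
#' @export
gaussian_density <- function(nuclei, primitives, label = "fragment") {
  nuclei <- as_tibble(nuclei)
  primitives <- as_tibble(primitives)
  stopifnot(all(c("element", "Z", "x", "y", "z") %in% names(nuclei)))
  stopifnot(all(c("x", "y", "z", "alpha", "q") %in% names(primitives)))
  if (!"atom" %in% names(primitives)) primitives$atom <- NA_integer_
  if (any(nuclei$Z <= 0)) {
    abort("nuclear charges must be positive", class = "iqfpen_geometry_error")
  }
  if (any(primitives$alpha <= 0)) {
    abort("Gaussian exponents must be positive", class = "iqfpen_parameter_error")
  }
  if (any(primitives$q < 0)) {
    abort("primitive populations must be non-negative (density must be non-negative)",
          class = "iqfpen_parameter_error")
  }
  .check_distinct_nuclei(as.matrix(nuclei[, c("x", "y", "z")]))
  structure(
    list(nuclei = nuclei, prim = primitives, label = label),
    class = "gaussian_density"
  )
}

.check_distinct_nuclei <- function(R) {
  n <- nrow(R)
  if (n < 2) return(invisible(TRUE))
  d <- as.matrix(stats::dist(R))
  diag(d) <- Inf
  if (any(d <= 1e-6)) {
    abort("duplicate atoms: two nuclei closer than 1e-6 bohr",
          class = "iqfpen_geometry_error")
  }
  invisible(TRUE)
}

#' Default promolecular exponent table
#'
#' One spherical Gaussian primitive per atom with an element-keyed exponent
#' and a neutral population q = Z. Exponents are qualitative (they give atoms
#' realistic sizes on the bohr scale), not fitted to any wavefunction.
#'
#' @return Tibble with columns `element` and `alpha` (bohr^-2).
#' @export
promolecule_params <- function() {
  tibble(
    element = c("H", "He", "Li", "B", "C", "N", "O", "F", "Ne",
                "Na", "P", "S", "Cl", "Ar"),
    alpha = c(1.2, 1.6, 0.9, 1.8, 2.0, 2.2, 2.4, 2.6, 2.8,
              0.8, 1.4, 1.6, 1.8, 2.0)
  )
}

#' Build a promolecular density from an XYZ geometry
#'
#' Places one spherical Gaussian primitive (population Z, element-keyed
#' exponent) on every atom, so the fragment is neutral by construction.
#' Coordinates are converted from angstrom to bohr.
#'
#' @param geometry Tibble with columns `element`, `x`, `y`, `z` (angstrom),
#'   e.g. from [read_xyz()].
#' @param params Exponent table as from [promolecule_params()]; may carry an
#'   optional `q` column to override the neutral population.
#' @param label Fragment tag.
#' @return A [gaussian_density()] object.
#' @export
build_promolecule <- function(geometry, params = promolecule_params(),
                              label = "fragment") {
  geometry <- as_tibble(geometry)
  stopifnot(all(c("element", "x", "y", "z") %in% names(geometry)))
  if (!all(is.finite(as.matrix(geometry[, c("x", "y", "z")])))) {
    abort("non-finite coordinates in geometry", class = "iqfpen_geometry_error")
  }
  missing_el <- setdiff(unique(geometry$element), params$element)
  if (length(missing_el) > 0) {
    abort(paste0("no promolecular parameters for element(s): ",
                 paste(missing_el, collapse = ", ")),
          class = "iqfpen_parameter_error")
  }
  b <- iqf_units$bohr_per_angstrom
  Z <- element_z(geometry$element)
  nuc <- tibble(
    element = geometry$element, Z = Z,
    x = geometry$x * b, y = geometry$y * b, z = geometry$z * b
  )
  al <- params$alpha[match(geometry$element, params$element)]
  q <- if ("q" %in% names(params)) {
    qq <- params$q[match(geometry$element, params$element)]
    ifelse(is.na(qq), Z, qq)
  } else Z
  prim <- tibble(atom = seq_len(nrow(nuc)), x = nuc$x, y = nuc$y, z = nuc$z,
                 alpha = al, q = as.numeric(q))
  gaussian_density(nuc, prim, label = label)
}

#' Displace part of an atom's electron population
#'
#' Splits the population of the primitives owned by `atom`, moving a fraction
#' to a second primitive displaced by `offset`. This "polarized" synthetic mode
#' emulates a relaxed (non-promolecular) density so that intrafragment
#' electrostatic relaxation terms are nonzero without any quantum-chemistry
#' input.
#'
#' @param d A [gaussian_density()].
#' @param atom Index of the atom whose population is split.
#' @param fraction Fraction (0..1) of the population moved.
#' @param offset Length-3 displacement of the new primitive centre (bohr).
#' @param alpha Optional exponent of the displaced primitive (defaults to the
#'   parent primitive's).
#' @return A new `gaussian_density`.
#' @export
polarize_density <- function(d, atom, fraction, offset, alpha = NULL) {
  stopifnot(inherits(d, "gaussian_density"), fraction >= 0, fraction <= 1)
  idx <- which(d$prim$atom == atom)
  if (length(idx) == 0) abort("atom owns no primitives", class = "iqfpen_parameter_error")
  prim <- d$prim
  moved <- prim[idx, ]
  moved$q <- moved$q * fraction
  moved$x <- moved$x + offset[1]
  moved$y <- moved$y + offset[2]
  moved$z <- moved$z + offset[3]
  if (!is.null(alpha)) moved$alpha <- alpha
  prim$q[idx] <- prim$q[idx] * (1 - fraction)
  gaussian_density(d$nuclei, bind_rows(prim, moved), label = d$label)
}

#' Rigidly translate a density
#' @param d A density object.
#' @param shift Length-3 translation vector (bohr).
#' @return The translated density.
#' @export
translate_density <- function(d, shift) {
  UseMethod("translate_density")
}

#' @export
translate_density.gaussian_density <- function(d, shift) {
  d$nuclei$x <- d$nuclei$x + shift[1]
  d$nuclei$y <- d$nuclei$y + shift[2]
  d$nuclei$z <- d$nuclei$z + shift[3]
  d$prim$x <- d$prim$x + shift[1]
  d$prim$y <- d$prim$y + shift[2]
  d$prim$z <- d$prim$z + shift[3]
  d
}

# ---- generic evaluation interface -----------------------------------------

#' Evaluate an electron density at points
#' @param d A density object (`gaussian_density`, `complex_density`, or a
#'   wavefunction density from [read_wfx()] / [read_molden()]).
#' @param points n x 3 matrix of coordinates (bohr).
#' @return Numeric vector of density values (e/bohr^3, non-negative).
#' @export
density_eval <- function(d, points) UseMethod("density_eval")

#' Evaluate the density gradient at points
#' @inheritParams density_eval
#' @return n x 3 matrix of gradient values (e/bohr^4).
#' @export
density_grad <- function(d, points) UseMethod("density_grad")

#' Nuclei of a density
#' @param d A density object.
#' @return Tibble with columns `element`, `Z`, `x`, `y`, `z` (bohr).
#' @export
nuclei_of <- function(d) UseMethod("nuclei_of")

#' Nominal electron count of a density
#' @param d A density object.
#' @return Total electrons (sum of primitive populations or occupations).
#' @export
electron_count <- function(d) UseMethod("electron_count")

.as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (!all(is.finite(points))) abort("non-finite evaluation points",
                                     class = "iqfpen_geometry_error")
  points
}

#' @export
density_eval.gaussian_density <- function(d, points) {
  pts <- .as_points(points)
  v <- numeric(nrow(pts))
  for (p in seq_len(nrow(d$prim))) {
    dx <- pts[, 1] - d$prim$x[p]
    dy <- pts[, 2] - d$prim$y[p]
    dz <- pts[, 3] - d$prim$z[p]
    a <- d$prim$alpha[p]
    v <- v + d$prim$q[p] * (a / pi)^1.5 * exp(-a * (dx * dx + dy * dy + dz * dz))
  }
  v
}

#' @export
density_grad.gaussian_density <- function(d, points) {
  pts <- .as_points(points)
  g <- matrix(0, nrow(pts), 3)
  for (p in seq_len(nrow(d$prim))) {
    dx <- pts[, 1] - d$prim$x[p]
    dy <- pts[, 2] - d$prim$y[p]
    dz <- pts[, 3] - d$prim$z[p]
    a <- d$prim$alpha[p]
    rho <- d$prim$q[p] * (a / pi)^1.5 * exp(-a * (dx * dx + dy * dy + dz * dz))
    g[, 1] <- g[, 1] - 2 * a * dx * rho
    g[, 2] <- g[, 2] - 2 * a * dy * rho
    g[, 3] <- g[, 3] - 2 * a * dz * rho
  }
  g
}

#' @export
nuclei_of.gaussian_density <- function(d) d$nuclei

#' @export
electron_count.gaussian_density <- function(d) sum(d$prim$q)

#' Analytic potential of the electron cloud of a Gaussian density
#'
#' The Coulomb potential generated by the (positive) electron cloud alone:
#' per primitive q erf(sqrt(alpha) r)/r, with the closed-form limit
#' q sqrt(4 alpha / pi) at r = 0. The nuclear contribution is deliberately a
#' separate operation ([nuclear_potential()]); signs are applied by energy
#' assembly code.
#'
#' @param d A [gaussian_density()].
#' @param points n x 3 matrix (bohr).
#' @return Potential values (hartree/e).
#' @export
analytic_potential <- function(d, points) {
  stopifnot(inherits(d, "gaussian_density"))
  pts <- .as_points(points)
  v <- numeric(nrow(pts))
  for (p in seq_len(nrow(d$prim))) {
    dx <- pts[, 1] - d$prim$x[p]
    dy <- pts[, 2] - d$prim$y[p]
    dz <- pts[, 3] - d$prim$z[p]
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    a <- d$prim$alpha[p]
    small <- r < 1e-10
    vv <- numeric(length(r))
    vv[!small] <- pracma::erf(sqrt(a) * r[!small]) / r[!small]
    vv[small] <- sqrt(4 * a / pi)
    v <- v + d$prim$q[p] * vv
  }
  v
}

#' Coulomb potential of the point nuclei
#' @param d A density object with nuclei.
#' @param points n x 3 matrix (bohr).
#' @return Potential values (hartree/e); +Inf at a nucleus.
#' @export
nuclear_potential <- function(d, points) {
  nuc <- nuclei_of(d)
  pts <- .as_points(points)
  v <- numeric(nrow(pts))
  for (i in seq_len(nrow(nuc))) {
    r <- sqrt((pts[, 1] - nuc$x[i])^2 + (pts[, 2] - nuc$y[i])^2 +
                (pts[, 3] - nuc$z[i])^2)
    v <- v + nuc$Z[i] / r
  }
  v
}

#' Total electrostatic potential (nuclei minus electrons) of a density
#'
#' @param d A density object. For Gaussian densities the electron part is the
#'   closed-form erf potential; for wavefunction densities it is integrated
#'   numerically on a grid supplied via `grid`.
#' @param points n x 3 matrix (bohr).
#' @param grid Optional [build_grid()] result (required for non-Gaussian
#'   densities).
#' @return Potential values (hartree/e).
#' @export
esp_potential <- function(d, points, grid = NULL) {
  pts <- .as_points(points)
  if (inherits(d, "gaussian_density")) {
    return(nuclear_potential(d, pts) - analytic_potential(d, pts))
  }
  if (is.null(grid)) {
    abort("a quadrature grid is required to evaluate the ESP of a non-Gaussian density",
          class = "iqfpen_config_error")
  }
  rho <- density_eval(d, grid$pts)
  ve <- numeric(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    r <- sqrt((grid$pts[, 1] - pts[k, 1])^2 + (grid$pts[, 2] - pts[k, 2])^2 +
                (grid$pts[, 3] - pts[k, 3])^2)
    ve[k] <- sum(grid$w * rho / pmax(r, 1e-8))
  }
  nuclear_potential(d, pts) - ve
}

# ---- zeroth-order complex density -----------------------------------------

#' Zeroth-order (promolecular-sum) complex density
#'
#' Represents the unrelaxed complex density rho0 = sum of fragment densities
#' placed at the complex geometry. In `zeroth_order` mode the complex density
#' evaluates pointwise to the sum of the fragment densities.
#'
#' @param fragments List of density objects (one per fragment).
#' @param mode `"zeroth_order"` (the only mode with additivity guarantees) or
#'   `"relaxed"` (a single supplied density carrying a fragment map).
#' @return An object of class `complex_density`.
#' @export
complex_density <- function(fragments, mode = c("zeroth_order", "relaxed")) {
  mode <- match.arg(mode)
  stopifnot(length(fragments) >= 1)
  structure(list(fragments = fragments, mode = mode), class = "complex_density")
}

#' @export
density_eval.complex_density <- function(d, points) {
  pts <- .as_points(points)
  Reduce(`+`, lapply(d$fragments, density_eval, points = pts))
}

#' @export
density_grad.complex_density <- function(d, points) {
  pts <- .as_points(points)
  Reduce(`+`, lapply(d$fragments, density_grad, points = pts))
}

#' @export
nuclei_of.complex_density <- function(d) {
  bind_rows(lapply(d$fragments, nuclei_of))
}

#' @export
electron_count.complex_density <- function(d) {
  sum(vapply(d$fragments, electron_count, numeric(1)))
}

#' Merge two fragment densities into one zeroth-order Gaussian density
#'
#' Concatenates nuclei and primitives of two Gaussian fragments into a single
#' `gaussian_density` for rho0 = rhoA0 + rhoB0, recording the fragment label
#' of every atom in the `fragment` attribute.
#'
#' @param rhoA,rhoB [gaussian_density()] fragments.
#' @param labels Fragment labels (default `c("A", "B")`).
#' @return A `gaussian_density` with attribute `fragment` (character per atom).
#' @export
merge_fragments <- function(rhoA, rhoB, labels = c("A", "B")) {
  stopifnot(inherits(rhoA, "gaussian_density"), inherits(rhoB, "gaussian_density"))
  nuc <- bind_rows(rhoA$nuclei, rhoB$nuclei)
  primB <- rhoB$prim
  primB$atom <- primB$atom + nrow(rhoA$nuclei)
  prim <- bind_rows(rhoA$prim, primB)
  d <- gaussian_density(nuc, prim, label = paste0(labels[1], labels[2]))
  attr(d, "fragment") <- c(rep(labels[1], nrow(rhoA$nuclei)),
                           rep(labels[2], nrow(rhoB$nuclei)))
  d
}
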