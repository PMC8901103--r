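# Two-zone atom-centred quadrature grids: a beta-sphere interior (ascent-free,
# exclusively owned by its atom) and an outer shell region carrying Becke
# fuzzy-cell weights so that overlapping atomic shells integrate each region
# of space exactly once.

# Radial map r(q) = r0 q^2 / (1-q)^2 on q in (0, 1), truncated at r_max.
.radial_map <- function(q, r0) r0 * q^2 / (1 - q)^2
.radial_map_inv <- function(r, r0) { s <- sqrt(r / r0); s / (1 + s) }
.radial_map_deriv <- function(q, r0) r0 * 2 * q / (1 - q)^3

#' Atomic grid specification
#'
#' Quadrature parameters for the two-zone scheme: angular orders are Lebedev
#' point counts (mapped internally to product rules of the same polynomial
#' exactness degree), radial points are Gauss-Legendre nodes in a mapped
#' coordinate r = r0 q^2/(1-q)^2 truncated at `r_max`.
#'
#' @param beta_fraction Beta-sphere radius as a fraction of the distance from
#'   each nucleus to its nearest internuclear density saddle (default 0.60).
#' @param inner_angular,outer_angular Angular orders (valid Lebedev point
#'   counts; defaults 974 and 5810).
#' @param inner_radial,outer_radial Radial point counts (defaults 382, 512).
#' @param r_max Outer truncation radius in bohr (default 15).
#' @param r0 Radial map scale in bohr (default 1).
#' @return An object of class `atom_grid_spec`.
#' @export
atom_grid_spec <- function(beta_fraction = 0.60,
                           inner_angular = 974L, inner_radial = 382L,
                           outer_angular = 5810L, outer_radial = 512L,
                           r_max = 15, r0 = 1.0) {
  if (beta_fraction <= 0 || beta_fraction >= 1) {
    abort("beta_fraction must lie in (0, 1)", class = "iqfpen_config_error")
  }
  if (r_max <= 0) abort("r_max must be positive", class = "iqfpen_config_error")
  angular_degree_for_order(inner_angular)
  angular_degree_for_order(outer_angular)
  structure(list(
    beta_fraction = beta_fraction,
    inner_angular = as.integer(inner_angular),
    inner_radial = as.integer(inner_radial),
    outer_angular = as.integer(outer_angular),
    outer_radial = as.integer(outer_radial),
    r_max = r_max, r0 = r0
  ), class = "atom_grid_spec")
}

#' Named grid profiles
#'
#' `"production"` is the full-accuracy profile (974/382 inner, 5810/512 outer,
#' r_max 15 bohr); `"test"` is the reduced profile used by the test suite
#' (110/60 inner, 266/90 outer); `"coarse"` is a minimal profile for quick
#' exploratory runs.
#'
#' @param name One of `"production"`, `"standard"`, `"test"`, `"coarse"`.
#' @return An [atom_grid_spec()].
#' @export
grid_profile <- function(name = c("test", "production", "standard", "coarse")) {
  name <- match.arg(name)
  switch(name,
    production = atom_grid_spec(),
    standard = atom_grid_spec(inner_angular = 194L, inner_radial = 120L,
                              outer_angular = 434L, outer_radial = 160L),
    test = atom_grid_spec(inner_angular = 110L, inner_radial = 60L,
                          outer_angular = 266L, outer_radial = 90L),
    coarse = atom_grid_spec(inner_angular = 26L, inner_radial = 24L,
                            outer_angular = 50L, outer_radial = 36L)
  )
}

#' Beta-sphere radius of an atom
#'
#' The beta-sphere radius is `beta_fraction` times the distance from the
#' nucleus to its nearest internuclear density saddle, found by a 1-D search
#' of the density along each internuclear line and minimised over neighbours.
#' For an isolated atom (or when no bracketing minimum exists along any line)
#' a fallback radius is used and a warning is emitted.
#'
#' @param density A density object (typically rho0 of the complex).
#' @param atom Atom index.
#' @param beta_fraction Fraction of the saddle distance (default 0.60).
#' @param r_max Outer truncation radius (bohr), used for the isolated-atom
#'   fallback (0.2 r_max).
#' @return Radius in bohr.
#' @export
beta_radius <- function(density, atom, beta_fraction = 0.60, r_max = 15) {
  nuc <- nuclei_of(density)
  R <- as.matrix(nuc[, c("x", "y", "z")])
  n <- nrow(R)
  if (n < 2) {
    warn("isolated atom: beta-sphere radius set to 0.2 r_max")
    return(beta_fraction * r_max / 3)
  }
  ri <- R[atom, ]
  best <- Inf
  any_bracketed <- FALSE
  for (j in seq_len(n)) {
    if (j == atom) next
    rj <- R[j, ]
    L <- sqrt(sum((rj - ri)^2))
    f <- function(t) {
      p <- matrix(ri + t * (rj - ri), 1, 3)
      density_eval(density, p)
    }
    opt <- optimize(f, interval = c(0.02, 0.98), tol = 1e-9)
    bracketed <- opt$objective < min(f(0.02), f(0.98)) &&
      opt$minimum > 0.025 && opt$minimum < 0.975
    if (bracketed) {
      any_bracketed <- TRUE
      best <- min(best, opt$minimum * L)
    } else {
      best <- min(best, 0.5 * L)
    }
  }
  if (!any_bracketed) {
    warn("no internuclear density saddle bracketed; falling back to half the nearest-neighbour distance")
  }
  beta_fraction * best
}

# Becke fuzzy-cell weight of `owner` at `pts` (standard k = 3 iterated
# polynomial switching, no atomic size adjustment).
.becke_weight <- function(pts, R, owner) {
  n <- nrow(pts)
  m <- nrow(R)
  if (m == 1) return(rep(1, n))
  d <- matrix(0, n, m)
  for (j in seq_len(m)) {
    d[, j] <- sqrt((pts[, 1] - R[j, 1])^2 + (pts[, 2] - R[j, 2])^2 +
                     (pts[, 3] - R[j, 3])^2)
  }
  P <- matrix(1, n, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      Rij <- sqrt(sum((R[i, ] - R[j, ])^2))
      mu <- (d[, i] - d[, j]) / Rij
      f <- mu
      for (k in 1:3) f <- 1.5 * f - 0.5 * f^3
      P[, i] <- P[, i] * 0.5 * (1 - f)
    }
  }
  P[, owner] / rowSums(P)
}

#' Build a molecular quadrature grid
#'
#' Per atom: an inner product grid (radial Gauss-Legendre in the mapped
#' coordinate on (0, beta), angular rule of order `inner_angular`) covering
#' the beta-sphere, and an outer grid from the beta radius to `r_max` with the
#' outer orders. All points carry smooth Becke fuzzy-cell weights so that the
#' overlapping atomic shells integrate every region of space exactly once;
#' the beta-spheres' role is topological (their interiors are pre-assigned to
#' their basin without gradient ascent).
#'
#' @param density Density object providing the nuclei (and the saddle
#'   positions for [beta_radius()]).
#' @param spec An [atom_grid_spec()].
#' @return An object of class `molecular_grid` with fields `pts` (n x 3),
#'   `w` (final weights, bohr^3), `atom`, `zone` (1 inner / 2 outer),
#'   `becke`, and per-atom shell structure in `atoms`.
#' @export
build_grid <- function(density, spec = grid_profile("test")) {
  stopifnot(inherits(spec, "atom_grid_spec"))
  nuc <- nuclei_of(density)
  R <- as.matrix(nuc[, c("x", "y", "z")])
  natom <- nrow(R)
  betas <- vapply(seq_len(natom), function(i) {
    beta_radius(density, i, spec$beta_fraction, spec$r_max)
  }, numeric(1))

  ang_in <- angular_quadrature(spec$inner_angular)
  ang_out <- angular_quadrature(spec$outer_angular)

  atoms <- vector("list", natom)
  pts_list <- list(); w_quad_list <- list(); atom_list <- list()
  zone_list <- list(); offset <- 0L

  for (i in seq_len(natom)) {
    beta <- min(betas[i], 0.95 * spec$r_max)
    qb <- .radial_map_inv(beta, spec$r0)
    qm <- .radial_map_inv(spec$r_max, spec$r0)

    gl_in <- pracma::gaussLegendre(spec$inner_radial, 0, qb)
    r_in <- .radial_map(gl_in$x, spec$r0)
    wr_in <- gl_in$w * .radial_map_deriv(gl_in$x, spec$r0) * r_in^2

    gl_out <- pracma::gaussLegendre(spec$outer_radial, qb, qm)
    r_out <- .radial_map(gl_out$x, spec$r0)
    wr_out <- gl_out$w * .radial_map_deriv(gl_out$x, spec$r0) * r_out^2

    mk_zone <- function(r, wr, ang) {
      m <- ang$n
      nr <- length(r)
      u <- ang$u[rep(seq_len(m), times = nr), , drop = FALSE]
      rad <- rep(r, each = m)
      pts <- u * rad
      pts[, 1] <- pts[, 1] + R[i, 1]
      pts[, 2] <- pts[, 2] + R[i, 2]
      pts[, 3] <- pts[, 3] + R[i, 3]
      w <- rep(wr, each = m) * rep(ang$w, times = nr)
      list(pts = pts, w = w, m = m, nr = nr)
    }
    zi <- mk_zone(r_in, wr_in, ang_in)
    zo <- mk_zone(r_out, wr_out, ang_out)

    atoms[[i]] <- list(
      center = R[i, ], beta = beta,
      inner = list(r = r_in, wr = wr_in, ang = ang_in,
                   offset = offset, n = length(zi$w)),
      outer = list(r = r_out, wr = wr_out, ang = ang_out,
                   offset = offset + length(zi$w), n = length(zo$w))
    )
    pts_list[[i]] <- rbind(zi$pts, zo$pts)
    w_quad_list[[i]] <- c(zi$w, zo$w)
    atom_list[[i]] <- rep(i, length(zi$w) + length(zo$w))
    zone_list[[i]] <- c(rep(1L, length(zi$w)), rep(2L, length(zo$w)))
    offset <- offset + length(zi$w) + length(zo$w)
  }

  pts <- do.call(rbind, pts_list)
  w_quad <- unlist(w_quad_list)
  atom <- unlist(atom_list)
  zone <- unlist(zone_list)

  # smooth Becke partition-of-unity over the whole grid (inner zones too):
  # overlapping atomic shells then integrate every region of space exactly
  # once without any sharp cut, and the beta-spheres keep their topological
  # role (ascent-free basin pre-assignment) rather than a quadrature one
  becke <- rep(1, length(w_quad))
  if (natom > 1) {
    for (i in seq_len(natom)) {
      sel <- which(atom == i)
      becke[sel] <- .becke_weight(pts[sel, , drop = FALSE], R, owner = i)
    }
  }

  structure(list(
    pts = pts, w = w_quad * becke, w_quad = w_quad, becke = becke,
    atom = atom, zone = zone, n = length(w_quad),
    atoms = atoms, nuclei = nuc, spec = spec
  ), class = "molecular_grid")
}

#' @export
print.molecular_grid <- function(x, ...) {
  cat(sprintf(
    "<molecular_grid> %d atoms, %d points (%d inner / %d outer), r_max %.1f bohr\n",
    length(x$atoms), x$n, sum(x$zone == 1L), sum(x$zone == 2L), x$spec$r_max
  ))
  invisible(x)
}

#' Weighted integration over a molecular grid
#'
#' @param grid A [build_grid()] result.
#' @param values Numeric vector of integrand values aligned with `grid$pts`.
#' @param mask Optional logical vector restricting the sum (e.g. a basin or
#'   zone membership mask).
#' @return The weighted sum (scalar).
#' @export
grid_integrate <- function(grid, values, mask = NULL) {
  if (length(values) != grid$n) {
    abort("values not aligned with grid points", class = "iqfpen_config_error")
  }
  if (is.null(mask)) return(sum(grid$w * values))
  if (length(mask) != grid$n) {
    abort("mask not aligned with grid points", class = "iqfpen_config_error")
  }
  sum(grid$w[mask] * values[mask])
}

#' Export a grid as a plain-text table
#' @param grid A [build_grid()] result.
#' @param partition Optional [assign_basins()] result adding the owner basin.
#' @return Tibble with columns `x`, `y`, `z`, `w`, `owner`, `zone`.
#' @export
grid_table <- function(grid, partition = NULL) {
  tibble(
    x = grid$pts[, 1], y = grid$pts[, 2], z = grid$pts[, 3],
    w = grid$w,
    owner = if (is.null(partition)) grid$atom else partition$basin,
    zone = ifelse(grid$zone == 1L, "inner", "outer")
  )
}
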