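# QTAIM basin assignment: every quadrature point is traced uphill along the
# density gradient until it is captured by an attractor (a nucleus).  Points
# inside an atom's beta-sphere are pre-assigned to that atom (beta-spheres
# are ascent-free by construction).

#' Partition a grid into QTAIM attraction basins
#'
#' Assigns every grid point to the attraction basin of the density gradient
#' field by fixed-step gradient ascent (initial step 0.1 bohr, halved whenever
#' the density would decrease; capture radius 0.3 bohr around an attractor;
#' at most 500 steps). Inner-zone (beta-sphere) points are pre-assigned to
#' their own atom. Points where the density is below `rho_floor` are assigned
#' to the nearest attractor without ascent: at those densities the gradient
#' field is numerical noise and the weighted contribution is negligible.
#'
#' Trajectories that exhaust the step budget are assigned to the nearest
#' attractor and counted in `n_fallback` (with a warning). A trajectory that
#' converges to a density maximum with no nucleus within the capture radius
#' signals a non-nuclear attractor, which is unsupported and raises an error.
#'
#' @param density Density object whose gradient defines the basins (for the
#'   zeroth-order analysis this is rho0 = rhoA0 + rhoB0).
#' @param grid A [build_grid()] result built on the same nuclei.
#' @param fragmentation Optional per-atom fragment labels (character vector or
#'   `"A=..,B=.."` string, see [parse_fragments()]).
#' @param capture Capture radius around an attractor (bohr).
#' @param step0 Initial ascent step (bohr).
#' @param max_steps Maximum ascent steps per point.
#' @param rho_floor Density below which points are assigned by proximity.
#' @return An object of class `basin_partition`: `attractors` (matrix),
#'   `basin` (integer per grid point), `atom_basin` (atom -> basin map),
#'   `fragment` (per-atom labels or NULL), `n_fallback`.
#' @export
assign_basins <- function(density, grid, fragmentation = NULL,
                          capture = 0.3, step0 = 0.1, max_steps = 500L,
                          rho_floor = 1e-10) {
  nuc <- nuclei_of(density)
  A <- as.matrix(nuc[, c("x", "y", "z")])
  natom <- nrow(A)
  if (!is.null(fragmentation)) {
    fragmentation <- parse_fragments(fragmentation, natom)
  }

  basin <- integer(grid$n)
  basin[grid$zone == 1L] <- grid$atom[grid$zone == 1L]
  # any point inside an atom's beta-sphere belongs to that basin (the
  # beta-spheres are disjoint and lie strictly inside their basins)
  for (j in seq_len(natom)) {
    dj <- sqrt((grid$pts[, 1] - A[j, 1])^2 + (grid$pts[, 2] - A[j, 2])^2 +
                 (grid$pts[, 3] - A[j, 3])^2)
    basin[dj < grid$atoms[[j]]$beta] <- j
  }

  nearest <- function(pts) {
    d2 <- matrix(0, nrow(pts), natom)
    for (j in seq_len(natom)) {
      d2[, j] <- (pts[, 1] - A[j, 1])^2 + (pts[, 2] - A[j, 2])^2 +
        (pts[, 3] - A[j, 3])^2
    }
    list(which = max.col(-d2), dist = sqrt(d2[cbind(seq_len(nrow(pts)), max.col(-d2))]))
  }

  out_sel <- which(basin == 0L & grid$w > 0)
  n_fallback <- 0L
  if (length(out_sel) > 0) {
    x <- grid$pts[out_sel, , drop = FALSE]
    rho <- density_eval(density, x)
    res <- integer(length(out_sel))

    low <- rho < rho_floor
    if (any(low)) res[low] <- nearest(x[low, , drop = FALSE])$which

    active <- which(!low)
    if (length(active) > 0) {
      xa <- x[active, , drop = FALSE]
      ra <- rho[active]
      h <- rep(step0, length(active))
      assigned <- integer(length(active))
      it <- 0L
      while (length(ra) > 0 && it < max_steps) {
        it <- it + 1L
        nr <- nearest(xa)
        cap <- nr$dist < capture
        if (any(cap)) {
          assigned[assigned == 0L][cap] <- nr$which[cap]
          keep <- !cap
          xa <- xa[keep, , drop = FALSE]; ra <- ra[keep]; h <- h[keep]
          if (nrow(xa) == 0) break
        }
        g <- density_grad(density, xa)
        gn <- sqrt(rowSums(g^2))
        zero_g <- gn < 1e-300
        gn[zero_g] <- 1
        xt <- xa + (g / gn) * h
        rt <- density_eval(density, xt)
        ok <- rt > ra & !zero_g
        xa[ok, ] <- xt[ok, ]
        ra[ok] <- rt[ok]
        h[!ok] <- h[!ok] / 2
        stalled <- h < 1e-4 | zero_g
        if (any(stalled)) {
          nr2 <- nearest(xa[stalled, , drop = FALSE])
          g2 <- sqrt(rowSums(density_grad(density, xa[stalled, , drop = FALSE])^2))
          nna <- ra[stalled] > 1e-6 & g2 < 1e-8 & nr2$dist > capture
          if (any(nna)) {
            abort("gradient ascent converged to a non-nuclear attractor; only nuclear attractors are supported",
                  class = "iqfpen_nna_error")
          }
          assigned[assigned == 0L][stalled] <- nr2$which
          n_fallback <- n_fallback + sum(stalled)
          keep <- !stalled
          xa <- xa[keep, , drop = FALSE]; ra <- ra[keep]; h <- h[keep]
        }
      }
      if (length(ra) > 0) {
        nr <- nearest(xa)
        assigned[assigned == 0L] <- nr$which
        n_fallback <- n_fallback + length(ra)
      }
      res[active] <- assigned
    }
    basin[out_sel] <- res
  }
  # zero-weight outer points (inside a foreign beta-sphere): assign by
  # proximity so that every point has an owner; they carry no weight.
  rest <- which(basin == 0L)
  if (length(rest) > 0) basin[rest] <- nearest(grid$pts[rest, , drop = FALSE])$which

  if (n_fallback > 0) {
    warn(sprintf("%d ascent trajectories exceeded the step budget; assigned to nearest attractor", n_fallback))
  }
  structure(list(
    attractors = A, basin = basin, atom_basin = seq_len(natom),
    fragment = fragmentation, n_fallback = n_fallback,
    density_label = if (!is.null(density$label)) density$label else "density"
  ), class = "basin_partition")
}

#' @export
print.basin_partition <- function(x, ...) {
  cat(sprintf("<basin_partition> %d basins over %d points (%d fallback)\n",
              nrow(x$attractors), length(x$basin), x$n_fallback))
  invisible(x)
}

# Basin ids belonging to one fragment label.
fragment_basins <- function(partition, label) {
  if (is.null(partition$fragment)) {
    abort("partition carries no fragment map", class = "iqfpen_config_error")
  }
  which(partition$fragment == label)
}

#' Integrate a density over a basin
#'
#' Computes the electron population of `density` inside one or more basins of
#' the partition. The integrated density may differ from the density that
#' defined the basins — e.g. integrating rhoB0 over the basins of fragment A
#' gives the mutual charge-penetration electron count.
#'
#' @param partition A [assign_basins()] result.
#' @param density Density to integrate.
#' @param grid The grid the partition was built on.
#' @param basins Integer basin ids (default: all).
#' @return Electrons (scalar).
#' @export
basin_population <- function(partition, density, grid, basins = NULL) {
  if (is.null(basins)) basins <- partition$atom_basin
  if (!all(basins %in% partition$atom_basin)) {
    abort("unknown basin id", class = "iqfpen_config_error")
  }
  mask <- partition$basin %in% basins
  rho <- density_eval(density, grid$pts)
  grid_integrate(grid, rho, mask)
}

#' QTAIM basin multipoles
#'
#' Real-solid-harmonic multipoles Q_lm (Racah / GDMA normalisation, traceless
#' quadrupoles) of the total charge density (point nucleus minus electron
#' density) of each basin, origin at the basin's nucleus. The monopole is
#' Q00 = Z - N(basin).
#'
#' @param partition A [assign_basins()] result.
#' @param density Density whose electrons are integrated.
#' @param grid The grid the partition was built on.
#' @param l_max Maximum multipole rank (default 2).
#' @return A `multipole_set`: tibble of sites with columns `element`, `x`,
#'   `y`, `z` (bohr) and `Q00`, `Q10`, `Q11c`, ... through `l_max`.
#' @export
basin_multipoles <- function(partition, density, grid, l_max = 2L) {
  stopifnot(l_max >= 0)
  nuc <- grid$nuclei
  rho <- density_eval(density, grid$pts)
  labels <- lm_labels(l_max)
  Q <- matrix(0, nrow(nuc), length(labels), dimnames = list(NULL, labels))
  for (i in partition$atom_basin) {
    mask <- partition$basin == i & grid$w > 0
    rel <- sweep(grid$pts[mask, , drop = FALSE], 2,
                 partition$attractors[i, ], `-`)
    Rlm <- real_solid_harm(l_max, rel)
    Q[i, ] <- -colSums(grid$w[mask] * rho[mask] * Rlm)
    Q[i, 1] <- Q[i, 1] + nuc$Z[i]
  }
  multipole_set(tibble(
    site = seq_len(nrow(nuc)), element = nuc$element,
    x = nuc$x, y = nuc$y, z = nuc$z
  ) |> cbind(as_tibble(Q)), l_max = l_max)
}
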