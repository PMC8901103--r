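# Coulomb energies between basin-restricted density pieces via one-centre
# Laplace (spherical-harmonic) expansion of the restricted potentials.
#
# A restricted piece's density is projected onto real spherical harmonics on
# the radial shells of the basin's own atomic grid; the potential follows
# from the two cumulative radial integrals
#   V(r) = sum_lm 4pi/(2l+1) Y_lm(rhat)
#          [ r^-(l+1) int_0^r s^(l+2) f_lm ds + r^l int_r^inf s^(1-l) f_lm ds ].
# Cumulative integrals use natural-cubic-spline quadrature on the shared
# radial mesh (the ~1e-4 relative error of a trapezoid rule on the reduced
# mesh would dominate every stated energy tolerance).

# Radii below which the l >= 1 radial profiles are zeroed: there the true
# profiles scale as r^l and are far below projection round-off, while the
# s^(1-l) weight would amplify that round-off catastrophically.
.expansion_r_cut <- 0.05

# Cumulative integral of the natural spline of (x, y); Simpson with the
# spline midpoint is exact for the cubic pieces.
.spline_cum <- function(x, y) {
  sp <- splinefun(x, y, method = "natural")
  n <- length(x)
  h <- diff(x)
  mid <- (x[-n] + x[-1]) / 2
  seg <- (h / 6) * (y[-n] + 4 * sp(mid) + y[-1])
  c(0, cumsum(seg))
}

#' Define a basin-restricted density piece
#'
#' @param density Density object (e.g. a fragment density rhoA0).
#' @param region Integer basin ids the piece is restricted to.
#' @param include_nuclei Whether the density's nuclei lying inside the region
#'   belong to the piece (tails penetrating a partner basin carry no nuclei).
#' @return An object of class `restricted_piece`.
#' @export
restricted_piece <- function(density, region, include_nuclei = TRUE) {
  structure(list(density = density, region = as.integer(region),
                 include_nuclei = isTRUE(include_nuclei)),
            class = "restricted_piece")
}

#' Laplace expansion of a basin-restricted density
#'
#' Projects the density, masked to one basin, onto real spherical harmonics
#' on the radial shells of that basin's atomic grid (expansion centre = the
#' basin nucleus).
#'
#' @param density Density to restrict.
#' @param basin Basin id (= atom index); also the expansion centre.
#' @param grid The [build_grid()] result.
#' @param partition The [assign_basins()] partition defining the mask.
#' @param l_max Expansion order (default 10).
#' @param rho Optional precomputed density values at all grid points.
#' @return An object of class `radial_expansion` with the radial mesh `r`,
#'   profile matrix `f` (mesh x (l_max+1)^2) and precomputed cumulative
#'   integrals.
#' @export
expand_piece <- function(density, basin, grid, partition, l_max = 10L,
                         rho = NULL) {
  if (l_max < 0) abort("l_max must be >= 0", class = "iqfpen_config_error")
  l_max <- as.integer(l_max)
  at <- grid$atoms[[basin]]
  if (is.null(rho)) rho <- density_eval(density, grid$pts)

  project_zone <- function(zone) {
    m <- zone$ang$n
    nr <- length(zone$r)
    idx <- zone$offset + seq_len(m * nr)
    vals <- rho[idx] * (partition$basin[idx] == basin)
    M <- matrix(vals, m, nr)
    Y <- real_sph_harm(l_max, zone$ang$u)
    t(M) %*% (zone$ang$w * Y)   # nr x nlm
  }
  f_in <- project_zone(at$inner)
  f_out <- project_zone(at$outer)
  r <- c(at$inner$r, at$outer$r)
  f <- rbind(f_in, f_out)

  if (l_max >= 1) {
    small <- r < .expansion_r_cut
    if (any(small)) f[small, -1] <- 0
  }

  nlm <- n_lm(l_max)
  M <- length(r)
  C1 <- matrix(0, M, nlm)
  C2 <- matrix(0, M, nlm)
  for (k in seq_len(nlm)) {
    l <- floor(sqrt(k - 1))
    C1[, k] <- .spline_cum(r, r^(l + 2) * f[, k])
    C2[, k] <- .spline_cum(r, r^(1 - l) * f[, k])
  }
  structure(list(
    center = at$center, r = r, f = f, l_max = l_max,
    C1 = C1, C2 = C2, labels = lm_labels(l_max, prefix = "f")
  ), class = "radial_expansion")
}

#' Electron count carried by a radial expansion
#'
#' Integrates the monopole channel: N = sqrt(4 pi) int r^2 f_00 dr.
#' @param expansion A [expand_piece()] result.
#' @return Electrons.
#' @export
expansion_electron_count <- function(expansion) {
  sqrt(4 * pi) * tail(expansion$C1[, 1], 1)
}

#' Potential of a restricted density piece
#'
#' Evaluates the Laplace-expansion Coulomb potential of the (positive)
#' restricted electron cloud at arbitrary points. Beyond the radial mesh the
#' potential reduces to the multipole form sum_lm 4pi/(2l+1) Q~_lm Y_lm /
#' r^(l+1).
#'
#' @param expansion A [expand_piece()] result.
#' @param points n x 3 matrix (bohr).
#' @return Potential values (hartree/e).
#' @export
restricted_potential <- function(expansion, points) {
  pts <- .as_points(points)
  n <- nrow(pts)
  V <- numeric(n)
  rmesh <- expansion$r
  M <- length(rmesh)
  chunk <- 40000L
  nlm <- n_lm(expansion$l_max)
  # spline interpolants of the cumulative integrals
  sp1 <- lapply(seq_len(nlm), function(k) splinefun(rmesh, expansion$C1[, k], method = "natural"))
  sp2 <- lapply(seq_len(nlm), function(k) splinefun(rmesh, expansion$C2[, k], method = "natural"))
  tot1 <- expansion$C1[M, ]
  tot2 <- expansion$C2[M, ]

  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    rel <- sweep(pts[s:e, , drop = FALSE], 2, expansion$center, `-`)
    r <- sqrt(rowSums(rel^2))
    u <- rel / ifelse(r > 1e-300, r, 1)
    if (any(r <= 1e-300)) {
      u[r <= 1e-300, ] <- matrix(c(0, 0, 1), sum(r <= 1e-300), 3, byrow = TRUE)
    }
    Y <- real_sph_harm(expansion$l_max, u)
    rc <- pmin(pmax(r, rmesh[1]), rmesh[M])
    v <- numeric(length(r))
    rl <- rep(1, length(r))           # r^l
    rlp1 <- pmax(r, 1e-300)           # r^(l+1)
    tiny <- r < .expansion_r_cut      # r^-(l+1) branch ill-conditioned there
    for (l in 0:expansion$l_max) {
      pref <- 4 * pi / (2 * l + 1)
      cols <- (l^2 + 1L):((l + 1L)^2)
      for (k in cols) {
        I1 <- sp1[[k]](rc)
        I2 <- tot2[k] - sp2[[k]](rc)
        I2[r >= rmesh[M]] <- 0
        I1[r >= rmesh[M]] <- tot1[k]
        t1 <- I1 / rlp1
        if (l >= 1) t1[tiny] <- 0     # true contribution ~ r^(l+2), below noise
        v <- v + pref * Y[, k] * (t1 + rl * I2)
      }
      rl <- rl * r
      rlp1 <- pmax(rlp1 * r, 1e-300)
    }
    V[s:e] <- v
  }
  V
}

# Expansions of one density restricted to each basin in `basins`.
.basin_expansions <- function(density, basins, grid, partition, l_max, rho = NULL) {
  if (is.null(rho)) rho <- density_eval(density, grid$pts)
  setNames(
    lapply(basins, function(b) expand_piece(density, b, grid, partition, l_max, rho = rho)),
    as.character(basins)
  )
}

# Summed potential of a list of expansions at points.
.group_potential <- function(expansions, points) {
  Reduce(`+`, lapply(expansions, restricted_potential, points = points))
}

# Map a density's nuclei onto partition basins (attractor within `tol`).
.nuclei_basins <- function(density, partition, tol = 0.3) {
  nuc <- nuclei_of(density)
  A <- partition$attractors
  idx <- integer(nrow(nuc))
  for (i in seq_len(nrow(nuc))) {
    d <- sqrt((A[, 1] - nuc$x[i])^2 + (A[, 2] - nuc$y[i])^2 + (A[, 3] - nuc$z[i])^2)
    j <- which.min(d)
    if (d[j] > tol) {
      abort("a nucleus does not coincide with any basin attractor",
            class = "iqfpen_geometry_error")
    }
    idx[i] <- j
  }
  idx
}

#' Coulomb energy between two restricted density pieces
#'
#' Electron-electron energy via the Laplace-expansion potential of piece 1
#' integrated against piece 2's density on the grid, plus the nuclear cross
#' terms (each counted once) and the internuclear term for nuclei belonging
#' to both pieces. When the two pieces are identical (same density, same
#' region) the electron-electron term carries the 1/2 self-energy factor, the
#' electron-nucleus term is counted once and nuclear self-interaction is
#' excluded.
#'
#' @param p1,p2 [restricted_piece()] objects on the same partition.
#' @param grid The [build_grid()] result.
#' @param partition The [assign_basins()] partition.
#' @param l_max Expansion order (default 10).
#' @return List with `total`, `ee`, `en`, `nn` (hartree).
#' @export
piece_piece_energy <- function(p1, p2, grid, partition, l_max = 10L) {
  if (!all(p1$region %in% partition$atom_basin) ||
      !all(p2$region %in% partition$atom_basin)) {
    abort("piece region references unknown basins", class = "iqfpen_config_error")
  }
  self <- identical(p1$density, p2$density) && setequal(p1$region, p2$region) &&
    p1$include_nuclei == p2$include_nuclei
  whole1 <- setequal(p1$region, partition$atom_basin)
  whole2 <- setequal(p2$region, partition$atom_basin)
  gauss1 <- inherits(p1$density, "gaussian_density")
  gauss2 <- inherits(p2$density, "gaussian_density")

  # potential of piece 1's electrons: analytic for an unrestricted Gaussian
  # piece, otherwise the per-basin Laplace expansions
  exps1 <- NULL
  if (whole1 && gauss1) {
    pot1 <- function(pts) analytic_potential(p1$density, pts)
  } else {
    exps1 <- .basin_expansions(p1$density, p1$region, grid, partition, l_max)
    pot1 <- function(pts) .group_potential(exps1, pts)
  }

  if (whole2 && gauss2) {
    # one-centre integration: each atom's own primitives on its own complete
    # shell set (full product weights, no fuzzy partition, no mask)
    ee <- 0
    ab <- .nuclei_basins(p2$density, partition)
    for (ia in seq_len(nrow(p2$density$nuclei))) {
      prm <- p2$density$prim[p2$density$prim$atom == ia, , drop = FALSE]
      if (nrow(prm) == 0) next
      da <- p2$density
      da$prim <- prm
      b <- ab[ia]
      at <- grid$atoms[[b]]
      idx <- c(at$inner$offset + seq_len(at$inner$n),
               at$outer$offset + seq_len(at$outer$n))
      ee <- ee + sum(grid$w_quad[idx] * density_eval(da, grid$pts[idx, , drop = FALSE]) *
                       pot1(grid$pts[idx, , drop = FALSE]))
    }
  } else {
    rho2 <- density_eval(p2$density, grid$pts)
    mask2 <- partition$basin %in% p2$region & grid$w > 0
    ee <- sum(grid$w[mask2] * rho2[mask2] * pot1(grid$pts[mask2, , drop = FALSE]))
  }

  nuc_b1 <- .nuclei_basins(p1$density, partition)
  nuc_b2 <- .nuclei_basins(p2$density, partition)
  nuc1 <- nuclei_of(p1$density)[p1$include_nuclei & nuc_b1 %in% p1$region, , drop = FALSE]
  nuc2 <- nuclei_of(p2$density)[p2$include_nuclei & nuc_b2 %in% p2$region, , drop = FALSE]

  if (self) {
    ee <- 0.5 * ee
    en <- if (nrow(nuc1) > 0) {
      -sum(nuc1$Z * pot1(as.matrix(nuc1[, c("x", "y", "z")])))
    } else 0
    nn <- 0
  } else {
    en <- 0
    if (nrow(nuc2) > 0) {
      en <- en - sum(nuc2$Z * pot1(as.matrix(nuc2[, c("x", "y", "z")])))
    }
    if (nrow(nuc1) > 0) {
      pot2 <- if (whole2 && gauss2) {
        function(pts) analytic_potential(p2$density, pts)
      } else {
        exps2 <- .basin_expansions(p2$density, p2$region, grid, partition, l_max)
        function(pts) .group_potential(exps2, pts)
      }
      en <- en - sum(nuc1$Z * pot2(as.matrix(nuc1[, c("x", "y", "z")])))
    }
    nn <- 0
    if (nrow(nuc1) > 0 && nrow(nuc2) > 0) {
      for (i in seq_len(nrow(nuc1))) {
        d <- sqrt((nuc2$x - nuc1$x[i])^2 + (nuc2$y - nuc1$y[i])^2 +
                    (nuc2$z - nuc1$z[i])^2)
        if (any(d < 1e-6)) {
          abort("pieces share a nucleus; use identical pieces for self-energies",
                class = "iqfpen_config_error")
        }
        nn <- nn + sum(nuc1$Z[i] * nuc2$Z / d)
      }
    }
  }
  list(total = ee + en + nn, ee = ee, en = en, nn = nn)
}

#' Electrostatic energy of a density decomposed over basin pairs
#'
#' Computes the total electrostatic energy of a density (electrons plus
#' nuclei, excluding infinite nuclear self-terms) and its decomposition into
#' intra-basin self terms (with the 1/2 electron-electron factor) and
#' inter-basin pair interaction terms.
#'
#' @param density Density whose energy is decomposed.
#' @param grid The [build_grid()] result.
#' @param partition The [assign_basins()] partition (built on this density
#'   for a QTAIM analysis, but any partition of the same nuclei is accepted).
#' @param l_max Expansion order (default 10).
#' @return List with `energy` (hartree), `self` (per-basin vector), `pair`
#'   (symmetric matrix: full pair interaction energies off-diagonal, self
#'   terms on the diagonal) and `table` (tibble basin_i, basin_j, E_hartree,
#'   E_kcalmol for i <= j).
#' @export
total_electrostatic_energy <- function(density, grid, partition, l_max = 10L) {
  nb <- length(partition$atom_basin)
  rho <- density_eval(density, grid$pts)
  live <- grid$w > 0

  gauss <- inherits(density, "gaussian_density") && !anyNA(density$prim$atom)
  Vb <- matrix(0, grid$n, nb)
  if (gauss) {
    # Accurate route: the restricted potential of basin I is written as the
    # closed-form potential of atom I's own primitives minus atom I's tails
    # into foreign basins plus the foreign tails inside basin I; only the
    # small tail pieces need Laplace expansions, so the large electron-
    # nuclear cancellations in the pair energies are formed from analytic
    # quantities.
    ab <- .nuclei_basins(density, partition)
    atom_dens <- lapply(seq_len(nb), function(b) {
      da <- density
      da$prim <- density$prim[ab[density$prim$atom] == b, , drop = FALSE]
      da
    })
    # tail expansions: density of atom a restricted to basin K != a
    tails <- vector("list", nb)
    for (a in seq_len(nb)) {
      rho_a <- density_eval(atom_dens[[a]], grid$pts)
      tails[[a]] <- lapply(seq_len(nb), function(K) {
        if (K == a) return(NULL)
        expand_piece(atom_dens[[a]], K, grid, partition, l_max, rho = rho_a)
      })
    }
    lp <- grid$pts[live, , drop = FALSE]
    for (b in seq_len(nb)) {
      v <- analytic_potential(atom_dens[[b]], lp)
      for (K in seq_len(nb)) {
        if (K == b) next
        v <- v - restricted_potential(tails[[b]][[K]], lp)   # own tail out
        v <- v + restricted_potential(tails[[K]][[b]], lp)   # foreign tail in
      }
      Vb[live, b] <- v
    }
  } else {
    exps <- .basin_expansions(density, partition$atom_basin, grid, partition,
                              l_max, rho = rho)
    for (b in seq_len(nb)) {
      Vb[live, b] <- restricted_potential(exps[[b]], grid$pts[live, , drop = FALSE])
    }
  }
  nuc <- nuclei_of(density)
  nuc_pts <- as.matrix(nuc[, c("x", "y", "z")])
  Vn <- matrix(0, nrow(nuc), nb)
  for (b in seq_len(nb)) {
    if (gauss) {
      v <- analytic_potential(atom_dens[[b]], nuc_pts)
      for (K in seq_len(nb)) {
        if (K == b) next
        v <- v - restricted_potential(tails[[b]][[K]], nuc_pts)
        v <- v + restricted_potential(tails[[K]][[b]], nuc_pts)
      }
      Vn[, b] <- v
    } else {
      Vn[, b] <- restricted_potential(exps[[b]], nuc_pts)
    }
  }

  nuc_basin <- .nuclei_basins(density, partition)

  pair <- matrix(0, nb, nb)
  selfv <- numeric(nb)
  for (i in seq_len(nb)) {
    mask_i <- partition$basin == i & live
    selfv[i] <- 0.5 * sum(grid$w[mask_i] * rho[mask_i] * Vb[mask_i, i]) -
      sum(nuc$Z[nuc_basin == i] * Vn[nuc_basin == i, i])
    pair[i, i] <- selfv[i]
    if (i < nb) {
      for (j in (i + 1L):nb) {
        mask_j <- partition$basin == j & live
        ee <- 0.5 * (sum(grid$w[mask_j] * rho[mask_j] * Vb[mask_j, i]) +
                       sum(grid$w[mask_i] * rho[mask_i] * Vb[mask_i, j]))
        en <- -sum(nuc$Z[nuc_basin == j] * Vn[nuc_basin == j, i]) -
          sum(nuc$Z[nuc_basin == i] * Vn[nuc_basin == i, j])
        nn <- 0
        ni <- which(nuc_basin == i)
        nj <- which(nuc_basin == j)
        for (a in ni) {
          d <- sqrt((nuc$x[nj] - nuc$x[a])^2 + (nuc$y[nj] - nuc$y[a])^2 +
                      (nuc$z[nj] - nuc$z[a])^2)
          nn <- nn + sum(nuc$Z[a] * nuc$Z[nj] / d)
        }
        pair[i, j] <- pair[j, i] <- ee + en + nn
      }
    }
  }
  energy <- sum(selfv) + sum(pair[upper.tri(pair)])
  tab <- tibble(
    basin_i = rep(seq_len(nb), times = nb),
    basin_j = rep(seq_len(nb), each = nb)
  ) |>
    filter(.data$basin_i <= .data$basin_j) |>
    mutate(E_hartree = pair[cbind(.data$basin_i, .data$basin_j)],
           E_kcalmol = hartree_to_kcal(.data$E_hartree))
  list(energy = energy, self = selfv, pair = pair, table = tab)
}
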