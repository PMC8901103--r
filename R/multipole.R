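# Distributed point-multipole electrostatics (l_max <= 2): spherical-tensor
# site multipoles (Racah-normalised real solid harmonics, traceless
# Buckingham quadrupoles) and Cartesian interaction tensors through rank 4.

#' Construct a multipole set
#'
#' @param sites Tibble with columns `element`, `x`, `y`, `z` (bohr) and the
#'   multipole columns `Q00`, and for l >= 1 `Q10`, `Q11c`, `Q11s`, and for
#'   l = 2 `Q20`, `Q21c`, `Q21s`, `Q22c`, `Q22s` (units e, e bohr, e bohr^2).
#' @param l_max Maximum rank present (0, 1 or 2 for interactions).
#' @return An object of class `multipole_set` (a tibble subclass).
#' @export
multipole_set <- function(sites, l_max = 2L) {
  sites <- as_tibble(sites)
  need <- c("x", "y", "z", lm_labels(min(l_max, 2L)))
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols) > 0) {
    abort(paste0("multipole set lacks columns: ", paste(missing_cols, collapse = ", ")),
          class = "iqfpen_config_error")
  }
  structure(sites, l_max = as.integer(l_max),
            convention = "real spherical harmonics (Racah), traceless quadrupole",
            class = c("multipole_set", class(sites)))
}

# Spherical components -> Cartesian charge / dipole / traceless quadrupole.
.site_cartesian <- function(set, i, l_max) {
  q <- set$Q00[i]
  mu <- c(0, 0, 0)
  Th <- matrix(0, 3, 3)
  if (l_max >= 1 && "Q10" %in% names(set)) {
    mu <- c(set$Q11c[i], set$Q11s[i], set$Q10[i])
  }
  if (l_max >= 2 && "Q20" %in% names(set)) {
    q20 <- set$Q20[i]; q21c <- set$Q21c[i]; q21s <- set$Q21s[i]
    q22c <- set$Q22c[i]; q22s <- set$Q22s[i]
    s3 <- sqrt(3)
    Th[1, 1] <- (s3 * q22c - q20) / 2
    Th[2, 2] <- -(s3 * q22c + q20) / 2
    Th[3, 3] <- q20
    Th[1, 2] <- Th[2, 1] <- s3 * q22s / 2
    Th[1, 3] <- Th[3, 1] <- s3 * q21c / 2
    Th[2, 3] <- Th[3, 2] <- s3 * q21s / 2
  }
  list(q = q, mu = mu, Th = Th)
}

# Interaction tensors T^(n) = grad^n (1/R) evaluated at R = r2 - r1.
.t_tensors <- function(Rv, l_max) {
  R2 <- sum(Rv^2); Rn <- sqrt(R2)
  I3 <- diag(3)
  T0 <- 1 / Rn
  T1 <- -Rv / Rn^3
  T2 <- (3 * outer(Rv, Rv) - R2 * I3) / Rn^5
  T3 <- NULL; T4 <- NULL
  if (l_max >= 1) {
    T3 <- array(0, c(3, 3, 3))
    for (a in 1:3) for (b in 1:3) for (cc in 1:3) {
      T3[a, b, cc] <- (-15 * Rv[a] * Rv[b] * Rv[cc] +
        3 * R2 * (Rv[a] * (b == cc) + Rv[b] * (a == cc) + Rv[cc] * (a == b))) / Rn^7
    }
  }
  if (l_max >= 2) {
    T4 <- array(0, c(3, 3, 3, 3))
    for (a in 1:3) for (b in 1:3) for (cc in 1:3) for (dd in 1:3) {
      T4[a, b, cc, dd] <- (105 * Rv[a] * Rv[b] * Rv[cc] * Rv[dd] -
        15 * R2 * (Rv[a] * Rv[b] * (cc == dd) + Rv[a] * Rv[cc] * (b == dd) +
                     Rv[a] * Rv[dd] * (b == cc) + Rv[b] * Rv[cc] * (a == dd) +
                     Rv[b] * Rv[dd] * (a == cc) + Rv[cc] * Rv[dd] * (a == b)) +
        3 * R2^2 * ((a == b) * (cc == dd) + (a == cc) * (b == dd) +
                      (a == dd) * (b == cc))) / Rn^9
    }
  }
  list(T0 = T0, T1 = T1, T2 = T2, T3 = T3, T4 = T4)
}

# Energy between two sites with moments through l_max (all l1, l2 <= l_max).
.pair_energy <- function(m1, m2, Rv, l_max) {
  tt <- .t_tensors(Rv, l_max)
  # potential of site 1 and its derivatives at site 2
  phi <- m1$q * tt$T0
  gphi <- m1$q * tt$T1
  hphi <- m1$q * tt$T2
  if (l_max >= 1) {
    phi <- phi - sum(m1$mu * tt$T1)
    gphi <- gphi - as.vector(tt$T2 %*% m1$mu)
    hphi <- hphi - apply(tt$T3, c(1, 2), function(v) sum(v * m1$mu))
  }
  if (l_max >= 2) {
    phi <- phi + sum(m1$Th * tt$T2) / 3
    gphi <- gphi + apply(tt$T3, 1, function(m) sum(m * m1$Th)) / 3
    hphi <- hphi + apply(tt$T4, c(1, 2), function(m) sum(m * m1$Th)) / 3
  }
  e <- m2$q * phi
  if (l_max >= 1) e <- e + sum(m2$mu * gphi)
  if (l_max >= 2) e <- e + sum(m2$Th * hphi) / 3
  e
}

#' Multipole-multipole interaction energy
#'
#' Interaction between two disjoint multipole sets via Cartesian interaction
#' tensors, keeping all terms with l1 <= l_max and l2 <= l_max (through
#' quadrupole-quadrupole at l_max = 2).
#'
#' @param setA,setB [multipole_set()] objects.
#' @param l_max Truncation rank (0, 1 or 2); defaults to the sets' rank.
#' @return List with `energy` (hartree) and `pairs`, a tibble of per-site-pair
#'   energies (`site_a`, `site_b`, `energy`).
#' @export
mtp_interaction <- function(setA, setB, l_max = NULL) {
  if (is.null(l_max)) l_max <- min(attr(setA, "l_max"), attr(setB, "l_max"))
  l_max <- as.integer(l_max)
  if (!l_max %in% 0:2) abort("l_max must be 0, 1 or 2", class = "iqfpen_config_error")
  na <- nrow(setA); nb <- nrow(setB)
  out <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    m1 <- .site_cartesian(setA, i, l_max)
    p1 <- c(setA$x[i], setA$y[i], setA$z[i])
    for (j in seq_len(nb)) {
      p2 <- c(setB$x[j], setB$y[j], setB$z[j])
      Rv <- p2 - p1
      if (sqrt(sum(Rv^2)) < 1e-3) {
        abort("coincident sites across multipole sets", class = "iqfpen_geometry_error")
      }
      m2 <- .site_cartesian(setB, j, l_max)
      out[i, j] <- .pair_energy(m1, m2, Rv, l_max)
    }
  }
  pairs <- tibble(
    site_a = rep(seq_len(na), times = nb),
    site_b = rep(seq_len(nb), each = na),
    energy = as.vector(out)
  )
  list(energy = sum(out), pairs = pairs, matrix = out, l_max = l_max)
}

#' Analytic distributed multipoles of a promolecular fragment
#'
#' For spherical Gaussian primitives the traceless solid-harmonic moments are
#' closed-form: a primitive of population q displaced by d from its site
#' contributes -q R_lm(d) (the spherical spread integrates to zero against any
#' harmonic polynomial). Nuclei contribute +Z to the monopole of their site.
#' These multipoles are exact for the promolecular model, so multipole-
#' truncation behaviour can be studied free of quadrature noise.
#'
#' @param d A [gaussian_density()].
#' @param l_max Maximum rank (default 2).
#' @return A [multipole_set()].
#' @export
promol_multipoles <- function(d, l_max = 2L) {
  stopifnot(inherits(d, "gaussian_density"))
  nuc <- d$nuclei
  labels <- lm_labels(l_max)
  Q <- matrix(0, nrow(nuc), length(labels), dimnames = list(NULL, labels))
  Q[, 1] <- nuc$Z
  for (p in seq_len(nrow(d$prim))) {
    i <- d$prim$atom[p]
    if (is.na(i)) {
      abort("promolecular multipoles need primitives assigned to atoms",
            class = "iqfpen_config_error")
    }
    dvec <- c(d$prim$x[p] - nuc$x[i], d$prim$y[p] - nuc$y[i],
              d$prim$z[p] - nuc$z[i])
    Q[i, ] <- Q[i, ] - d$prim$q[p] * real_solid_harm(l_max, matrix(dvec, 1, 3))[1, ]
  }
  multipole_set(as_tibble(cbind(tibble(
    site = seq_len(nrow(nuc)), element = nuc$element,
    x = nuc$x, y = nuc$y, z = nuc$z
  ), as_tibble(Q))), l_max = l_max)
}

#' ESP fitting surface
#'
#' Deterministic quasi-uniform points on scaled van der Waals shells
#' (golden-spiral layout), excluding points that fall inside any atom's
#' sphere at the same scale.
#'
#' @param density Density object (provides nuclei and elements).
#' @param shells Shell scale factors of the vdW radii (default 1.4, 1.6,
#'   1.8, 2.0).
#' @param points_per_shell Spiral points per atom per shell (default 120).
#' @return n x 3 matrix of points (bohr).
#' @export
esp_grid <- function(density, shells = c(1.4, 1.6, 1.8, 2.0),
                     points_per_shell = 120L) {
  nuc <- nuclei_of(density)
  rv <- vdw_radius_bohr(nuc$element)
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(points_per_shell)
  zs <- 1 - (2 * k - 1) / points_per_shell
  th <- golden * (k - 1)
  su <- sqrt(pmax(0, 1 - zs^2))
  u <- cbind(su * cos(th), su * sin(th), zs)
  out <- list()
  for (s in shells) {
    for (i in seq_len(nrow(nuc))) {
      p <- u * (s * rv[i])
      p[, 1] <- p[, 1] + nuc$x[i]
      p[, 2] <- p[, 2] + nuc$y[i]
      p[, 3] <- p[, 3] + nuc$z[i]
      keep <- rep(TRUE, nrow(p))
      for (j in seq_len(nrow(nuc))) {
        if (j == i) {
          next
        }
        dj <- sqrt((p[, 1] - nuc$x[j])^2 + (p[, 2] - nuc$y[j])^2 +
                     (p[, 3] - nuc$z[j])^2)
        keep <- keep & dj >= s * rv[j] * (1 - 1e-12)
      }
      out[[length(out) + 1L]] <- p[keep, , drop = FALSE]
    }
  }
  do.call(rbind, out)
}

#' Fit atomic point charges to the electrostatic potential
#'
#' Plain constrained least squares: minimises the squared ESP residual over
#' the fitting points subject to the total-charge constraint via a single
#' Lagrange multiplier. (No hyperbolic restraint is applied.)
#'
#' @param density Density object; the reference ESP is its exact potential
#'   (nuclei minus electron cloud).
#' @param points Fitting points (n x 3, bohr), e.g. from [esp_grid()].
#' @param total_charge Constraint value (default: the density's net charge).
#' @param grid Optional quadrature grid for non-Gaussian densities.
#' @return A [multipole_set()] with `l_max = 0` and attributes `rms`
#'   (hartree/e residual) and `lagrange`.
#' @export
fit_charges <- function(density, points, total_charge = NULL, grid = NULL) {
  nuc <- nuclei_of(density)
  m <- nrow(nuc)
  pts <- .as_points(points)
  if (nrow(pts) < m) {
    abort("need at least as many ESP points as atoms", class = "iqfpen_config_error")
  }
  if (is.null(total_charge)) {
    total_charge <- sum(nuc$Z) - electron_count(density)
  }
  v <- esp_potential(density, pts, grid = grid)
  A <- matrix(0, nrow(pts), m)
  for (i in seq_len(m)) {
    A[, i] <- 1 / sqrt((pts[, 1] - nuc$x[i])^2 + (pts[, 2] - nuc$y[i])^2 +
                         (pts[, 3] - nuc$z[i])^2)
  }
  AtA <- crossprod(A)
  if (qr(AtA)$rank < m) {
    abort("rank-deficient ESP design matrix; add more shells or points",
          class = "iqfpen_fit_error")
  }
  K <- rbind(cbind(2 * AtA, rep(1, m)), c(rep(1, m), 0))
  rhs <- c(2 * crossprod(A, v), total_charge)
  sol <- solve(K, rhs)
  qfit <- sol[seq_len(m)]
  resid <- A %*% qfit - v
  out <- multipole_set(tibble(
    site = seq_len(m), element = nuc$element,
    x = nuc$x, y = nuc$y, z = nuc$z, Q00 = qfit
  ), l_max = 0L)
  attr(out, "rms") <- sqrt(mean(resid^2))
  attr(out, "lagrange") <- sol[m + 1]
  out
}

#' Compare two atom-pair interaction-energy matrices
#'
#' Produces the per-pair difference table (sorted by absolute difference) and
#' the summary statistics used for model-versus-reference comparisons: the
#' coefficient of determination R^2 (squared Pearson correlation), Spearman's
#' rank correlation rho, and the root-mean-square difference.
#'
#' @param reference,model Numeric matrices of matching shape (atom-pair
#'   energies, hartree), or tibbles with columns `site_a`, `site_b`, `energy`.
#' @return List with `pairs` (tibble sorted by `abs_diff` descending) and
#'   `stats` (one-row tibble: `r_squared`, `spearman_rho`, `rms`).
#' @export
atom_pair_compare <- function(reference, model) {
  to_tbl <- function(x, val) {
    if (is.matrix(x)) {
      tibble(site_a = rep(seq_len(nrow(x)), ncol(x)),
             site_b = rep(seq_len(ncol(x)), each = nrow(x)),
             "{val}" := as.vector(x))
    } else {
      tb <- as_tibble(x)[, c("site_a", "site_b", "energy")]
      names(tb)[3] <- val
      tb
    }
  }
  ref <- to_tbl(reference, "reference")
  mod <- to_tbl(model, "model")
  if (nrow(ref) != nrow(mod)) {
    abort("pair matrices have mismatched shapes", class = "iqfpen_config_error")
  }
  tab <- left_join(ref, mod, by = c("site_a", "site_b"))
  if (any(is.na(tab$model))) {
    abort("pair matrices have mismatched atom indexing", class = "iqfpen_config_error")
  }
  tab <- tab |>
    mutate(diff = .data$model - .data$reference,
           abs_diff = abs(.data$diff)) |>
    arrange(desc(.data$abs_diff))
  degenerate <- nrow(tab) < 2 || sd(tab$reference) == 0 || sd(tab$model) == 0
  r2 <- if (degenerate) {
    as.numeric(all(tab$abs_diff < .Machine$double.eps^0.5))
  } else {
    cor(tab$reference, tab$model)^2
  }
  rho <- if (degenerate) NA_real_ else {
    suppressWarnings(cor(tab$reference, tab$model, method = "spearman"))
  }
  stats <- tibble(
    r_squared = r2,
    spearman_rho = rho,
    rms = sqrt(mean(tab$diff^2))
  )
  list(pairs = tab, stats = stats)
}
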