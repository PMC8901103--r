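# Real spherical harmonics, regular solid harmonics and angular quadrature.
#
# Real, orthonormal spherical harmonics are generated with the standard
# stable three-term recursion on fully normalised associated Legendre
# functions (no Condon-Shortley phase).  Column ordering follows the GDMA
# convention: for each l, m = 0, then (1c, 1s), (2c, 2s), ...

# Number of real (l, m) components through l = lmax.
n_lm <- function(lmax) (lmax + 1L)^2

# Column labels "Q00", "Q10", "Q11c", "Q11s", ...
lm_labels <- function(lmax, prefix = "Q") {
  out <- character(0)
  for (l in 0:lmax) {
    out <- c(out, paste0(prefix, l, "0"))
    if (l > 0) {
      for (m in seq_len(l)) {
        out <- c(out, paste0(prefix, l, m, "c"), paste0(prefix, l, m, "s"))
      }
    }
  }
  out
}

# Index of component (l, m, kind) in the flattened ordering above.
lm_index <- function(l, m, kind = c("c", "s")) {
  kind <- match.arg(kind)
  base <- l^2 + 1L
  if (m == 0L) return(base)
  base + 2L * (m - 1L) + 1L + (kind == "s")
}

# Real orthonormal spherical harmonics at unit vectors `u` (n x 3).
# Returns an n x (lmax+1)^2 matrix.  Points at the origin get u = z-hat.
real_sph_harm <- function(lmax, u) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 3)
  n <- nrow(u)
  ct <- u[, 3]
  ct <- pmin(1, pmax(-1, ct))
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- atan2(u[, 2], u[, 1])

  Y <- matrix(0, n, n_lm(lmax))
  # pbar[[m+1]] holds fully normalised P~_lm including the sqrt((2l+1)/4pi)
  # factor; recursion over l for each m.
  pmm <- rep(sqrt(1 / (4 * pi)), n)  # P~_00
  for (m in 0:lmax) {
    if (m > 0) pmm <- pmm * st * sqrt((2 * m + 1) / (2 * m))
    # attach l = m
    if (m == 0) {
      Y[, lm_index(m, 0L)] <- pmm
    } else {
      Y[, lm_index(m, m, "c")] <- sqrt(2) * pmm * cos(m * phi)
      Y[, lm_index(m, m, "s")] <- sqrt(2) * pmm * sin(m * phi)
    }
    if (m < lmax) {
      plm_prev <- pmm                       # l = m
      plm <- pmm * ct * sqrt(2 * m + 3)     # l = m + 1
      for (l in (m + 1L):lmax) {
        if (l > m + 1L) {
          a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
          b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
          plm_new <- a * (ct * plm - b * plm_prev)
          plm_prev <- plm
          plm <- plm_new
        }
        if (m == 0) {
          Y[, lm_index(l, 0L)] <- plm
        } else {
          Y[, lm_index(l, m, "c")] <- sqrt(2) * plm * cos(m * phi)
          Y[, lm_index(l, m, "s")] <- sqrt(2) * plm * sin(m * phi)
        }
      }
    }
  }
  Y
}

# Racah-normalised real regular solid harmonics R_lm(r) at points `pts`
# (n x 3, bohr): R_00 = 1, R_10 = z, R_11c = x, R_20 = (3z^2 - r^2)/2, ...
# R_lm = sqrt(4pi/(2l+1)) r^l Y_lm.
real_solid_harm <- function(lmax, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  r <- sqrt(rowSums(pts^2))
  u <- pts / ifelse(r > 1e-300, r, 1)
  if (any(r <= 1e-300)) {
    u[r <= 1e-300, ] <- matrix(c(0, 0, 1), sum(r <= 1e-300), 3, byrow = TRUE)
  }
  Y <- real_sph_harm(lmax, u)
  out <- Y
  for (l in 0:lmax) {
    cols <- (l^2 + 1L):((l + 1L)^2)
    out[, cols] <- Y[, cols] * (r^l) * sqrt(4 * pi / (2 * l + 1))
  }
  out
}

# Lebedev angular orders (point counts) and their polynomial exactness
# degrees; requested orders are mapped to a product Gauss-Legendre x
# trapezoid rule of at least the same degree.
.lebedev_orders <- c(
  6, 14, 26, 38, 50, 74, 86, 110, 146, 170, 194, 230, 266, 302, 350, 434,
  590, 770, 974, 1202, 1454, 1730, 2030, 2354, 2702, 3074, 3470, 3890,
  4334, 4802, 5294, 5810
)
.lebedev_degrees <- c(
  3, 5, 7, 9, 11, 13, 15, 17, 19, 21, 23, 25, 27, 29, 31, 35,
  41, 47, 53, 59, 65, 71, 77, 83, 89, 95, 101, 107, 113, 119, 125, 131
)

angular_degree_for_order <- function(order) {
  i <- match(order, .lebedev_orders)
  if (is.na(i)) {
    abort(paste0(
      "invalid angular order ", order, "; valid orders are: ",
      paste(.lebedev_orders, collapse = ", ")
    ), class = "iqfpen_config_error")
  }
  .lebedev_degrees[i]
}

# Spherical product quadrature exact for spherical harmonics through `degree`.
# Returns list(u = n x 3 unit vectors, w = weights summing to 4*pi).
angular_quadrature <- function(order) {
  degree <- angular_degree_for_order(order)
  nt <- ceiling((degree + 1) / 2)
  np <- degree + 1L
  gl <- pracma::gaussLegendre(nt, -1, 1)
  ct <- gl$x
  wt <- gl$w
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- 2 * pi * (seq_len(np) - 0.5) / np
  u <- cbind(
    as.vector(outer(st, cos(phi))),
    as.vector(outer(st, sin(phi))),
    rep(ct, times = np)
  )
  w <- rep(wt, times = np) * (2 * pi / np)
  list(u = u, w = w, degree = degree, n = nrow(u))
}
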