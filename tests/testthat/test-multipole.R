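# Distributed multipole electrostatics, ESP fitting and pair comparison.

mk_site <- function(x, y, z, ...) {
  q <- list(...)
  base <- list(site = 1, element = "C", x = x, y = y, z = z,
               Q00 = 0, Q10 = 0, Q11c = 0, Q11s = 0,
               Q20 = 0, Q21c = 0, Q21s = 0, Q22c = 0, Q22s = 0)
  base[names(q)] <- q
  multipole_set(tibble::as_tibble(base), l_max = 2L)
}

test_that("charge, dipole and quadrupole interactions match textbook values", {
  # +1 / -1 charges at 2 bohr
  e <- mtp_interaction(mk_site(0, 0, 0, Q00 = 1), mk_site(0, 0, 2, Q00 = -1))
  expect_equal(e$energy, -0.5, tolerance = 1e-14)

  # co-aligned collinear unit dipoles at 10 bohr: -2 mu^2 / R^3
  e <- mtp_interaction(mk_site(0, 0, 0, Q10 = 1), mk_site(0, 0, 10, Q10 = 1))
  expect_equal(e$energy, -0.002, tolerance = 1e-14)

  # +1 charge and radially-outward unit dipole at 5 bohr: -1/25
  e <- mtp_interaction(mk_site(0, 0, 0, Q00 = 1), mk_site(0, 0, 5, Q10 = 1))
  expect_equal(e$energy, -0.04, tolerance = 1e-14)

  # charge against an axial quadrupole on axis: q Theta / R^3
  e <- mtp_interaction(mk_site(0, 0, 0, Q00 = 1), mk_site(0, 0, 4, Q20 = 0.7))
  expect_equal(e$energy, 0.7 / 64, tolerance = 1e-12)

  # coincident sites are rejected
  expect_error(mtp_interaction(mk_site(0, 0, 0, Q00 = 1),
                               mk_site(0, 0, 1e-5, Q00 = 1)),
               class = "iqfpen_geometry_error")
})

test_that("tensor interactions agree with exact point-charge arrays", {
  # linear quadrupole (+s, -2s, +s at +-d): Q20 = 3 s d^2... realized exactly;
  # all odd moments vanish by symmetry, so the multipole value is accurate to
  # the hexadecapole term.
  d <- 0.05; s <- 4
  th <- 2 * s * d^2            # Buckingham Theta_zz of the array
  a1 <- list(pos = rbind(c(0, 0, d), c(0, 0, 0), c(0, 0, -d)), q = c(s, -2 * s, s))
  a2 <- list(pos = rbind(c(0, 0, 8 + d), c(0, 0, 8), c(0, 0, 8 - d)), q = c(s, -2 * s, s))
  exact <- 0
  for (i in 1:3) for (j in 1:3) {
    exact <- exact + a1$q[i] * a2$q[j] / sqrt(sum((a1$pos[i, ] - a2$pos[j, ])^2))
  }
  e <- mtp_interaction(mk_site(0, 0, 0, Q20 = th), mk_site(0, 0, 8, Q20 = th))
  expect_lt(abs(e$energy - exact), 1e-8)
  # coaxial quadrupole-quadrupole closed form: 6 Theta1 Theta2 / R^5
  expect_equal(e$energy, 6 * th * th / 8^5, tolerance = 1e-10)

  # dipole-quadrupole: charges (+s at +d, -s at -d) vs the array
  b1 <- list(pos = rbind(c(0, 0, d), c(0, 0, -d)), q = c(s, -s))
  mu <- 2 * s * d
  exact <- 0
  for (i in 1:2) for (j in 1:3) {
    exact <- exact + b1$q[i] * a2$q[j] / sqrt(sum((b1$pos[i, ] - a2$pos[j, ])^2))
  }
  e <- mtp_interaction(mk_site(0, 0, 0, Q10 = mu), mk_site(0, 0, 8, Q20 = th))
  expect_lt(abs(e$energy - exact), 1e-8)
})

test_that("promolecular multipoles are exact displaced-Gaussian moments", {
  d <- polarize_density(h_cloud(alpha = 1, q = 1), 1, 0.3, c(0.2, 0, 0.5))
  m <- promol_multipoles(d, l_max = 2)
  expect_equal(m$Q00[1], 0)                        # neutral
  expect_equal(m$Q11c[1], -0.3 * 0.2, tolerance = 1e-14)
  expect_equal(m$Q10[1], -0.3 * 0.5, tolerance = 1e-14)
  # quadrupole of the displaced spherical cloud: -q R_2m(d)
  expect_equal(m$Q20[1], -0.3 * (3 * 0.5^2 - (0.2^2 + 0.5^2)) / 2,
               tolerance = 1e-14)
})

test_that("ESP grids are deterministic shells with exclusion", {
  d <- h_cloud(alpha = 1, q = 1)
  pts <- esp_grid(d, shells = 1.4, points_per_shell = 50)
  r <- sqrt(rowSums(pts^2))
  expect_equal(max(abs(r - 1.4 * vdw_radius_bohr("H"))), 0, tolerance = 1e-12)

  dimer <- merge_fragments(h_cloud(z = 0), h_cloud(z = 2))
  pts2 <- esp_grid(dimer, shells = c(1.4, 2.0), points_per_shell = 60)
  for (z0 in c(0, 2)) {
    dist <- sqrt(pts2[, 1]^2 + pts2[, 2]^2 + (pts2[, 3] - z0)^2)
    expect_true(all(dist >= 1.4 * vdw_radius_bohr("H") - 1e-9))
  }
  expect_identical(pts2, esp_grid(dimer, shells = c(1.4, 2.0), points_per_shell = 60))
})

test_that("constrained ESP fits recover known charges", {
  # neutral spherical atom: zero charge
  d <- h_cloud(alpha = 1, q = 1)
  fit <- fit_charges(d, esp_grid(d))
  expect_equal(fit$Q00[1], 0, tolerance = 1e-3)

  # two nearly point-like +0.5 / -0.5 sites
  nuc <- tibble::tibble(element = c("H", "H"), Z = c(1, 1),
                        x = 0, y = 0, z = c(0, 3))
  prim <- tibble::tibble(atom = 1:2, x = 0, y = 0, z = c(0, 3),
                         alpha = 40, q = c(0.5, 1.5))
  d2 <- gaussian_density(nuc, prim)
  fit2 <- fit_charges(d2, esp_grid(d2))
  expect_equal(fit2$Q00, c(0.5, -0.5), tolerance = 1e-3)
  expect_equal(sum(fit2$Q00), 0, tolerance = 1e-12)   # Lagrange constraint

  # fitting surface confined to the bisector plane cannot resolve the sites
  theta <- seq(0, 2 * pi, length.out = 21)[-21]
  plane <- cbind(3 * cos(theta), 3 * sin(theta), 1.5)
  expect_error(fit_charges(d2, plane), class = "iqfpen_fit_error")
})

test_that("pair comparison reports sorted differences and summary statistics", {
  ref <- matrix(c(-1, 0.2, 0.2, -0.5), 2, 2)
  cmp <- atom_pair_compare(ref, ref)
  expect_equal(cmp$stats$r_squared, 1)
  expect_equal(cmp$stats$rms, 0)

  mod <- ref; mod[1, 2] <- mod[1, 2] + 0.3
  cmp2 <- atom_pair_compare(ref, mod)
  expect_equal(cmp2$pairs$site_a[1], 1)
  expect_equal(cmp2$pairs$site_b[1], 2)
  expect_equal(cmp2$pairs$abs_diff[1], 0.3)
  expect_error(atom_pair_compare(ref, matrix(0, 3, 3)),
               class = "iqfpen_config_error")
})

test_that("QTAIM basin multipoles reproduce exact pair energies at long range", {
  # dipolar single-atom fragments far apart: the dividing surface passes
  # through near-vacuum, so the basin-pair energy is pure multipolar physics
  A <- polarize_density(
    gaussian_density(tibble::tibble(element = "Ne", Z = 10, x = 0, y = 0, z = 0),
                     tibble::tibble(atom = 1L, x = 0, y = 0, z = 0,
                                    alpha = 0.8, q = 10)),
    1, 0.05, c(0, 0, 0.4)
  )
  B <- translate_density(A, c(0, 0, 12))
  sys <- pair_system("dipolar_far", A, B)
  M <- total_electrostatic_energy(sys$rho0, sys$grid, sys$part, l_max = 10)
  mset <- basin_multipoles(sys$part, sys$rho0, sys$grid, l_max = 2)
  mm <- mtp_interaction(multipole_set(mset[1, ], 2L),
                        multipole_set(mset[2, ], 2L))
  cmp <- atom_pair_compare(M$pair[1, 2, drop = FALSE], mm$matrix)
  expect_lt(cmp$stats$rms, 1e-4)
  # and both agree with the closed-form fragment-fragment interaction
  expect_equal(mm$energy, zeroth_order_interaction(A, B), tolerance = 1e-2)
})

test_that("truncation error shrinks with multipole order at long range", {
  d <- make_toy_dimer("hb")
  for (f in c(3, 4)) {
    B <- translate_density(d$rhoB, (f - 1) * d$R_eq * d$axis)
    e0 <- zeroth_order_interaction(d$rhoA, B)
    errs <- vapply(0:2, function(l) {
      abs(e0 - mtp_interaction(promol_multipoles(d$rhoA, 2),
                               promol_multipoles(B, 2), l_max = l)$energy)
    }, numeric(1))
    expect_true(all(diff(errs) < 0))
  }
})
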