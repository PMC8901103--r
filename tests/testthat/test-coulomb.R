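# Laplace expansions, restricted potentials and basin-pair Coulomb energies.

test_that("a spherical whole-space piece is purely monopolar", {
  d <- h_cloud(alpha = 1.2, q = 1)
  g <- suppressWarnings(build_grid(d, test_spec()))
  p <- assign_basins(d, g)
  ex <- expand_piece(d, 1, g, p, l_max = 6)
  expect_lt(max(abs(ex$f[, -1])), 1e-10)
  expect_equal(expansion_electron_count(ex), 1, tolerance = 1e-3)

  # far field: q / r (absolute agreement)
  expect_lt(abs(restricted_potential(ex, matrix(c(0, 0, 12), 1, 3)) - 1 / 12),
            1e-6)
  # at the expansion centre: matches the closed-form erf limit
  expect_equal(restricted_potential(ex, matrix(0, 1, 3)),
               analytic_potential(d, matrix(0, 1, 3)), tolerance = 1e-4)

  # zero density -> zero potential
  d0 <- h_cloud(alpha = 1.2, q = 0)
  ex0 <- expand_piece(d0, 1, g, p, l_max = 6)
  pts <- cbind(0, 0, seq(0.2, 8, length.out = 10))
  expect_equal(max(abs(restricted_potential(ex0, pts))), 0, tolerance = 1e-14)
})

test_that("a half-space restriction excites the dipole channel toward the kept half", {
  sys <- homo_system()
  # rhoA restricted to basin 1 (the z < mid half): l=1 z-component negative
  ex <- expand_piece(sys$rhoA, 1, sys$grid, sys$part, l_max = 4)
  outer_r <- ex$r > 2.5
  f10 <- ex$f[outer_r, lm_index(1, 0)]
  expect_true(any(abs(f10) > 1e-8))
  expect_true(all(f10[abs(f10) > 1e-8] < 0))
})

test_that("whole-space Gaussian pieces reproduce the erf Coulomb integral", {
  A <- h_cloud(alpha = 1, q = 1, z = 0)
  B <- h_cloud(alpha = 1, q = 1, z = 2)
  sys <- pair_system("erfpair", A, B)
  pa <- restricted_piece(A, 1:2, include_nuclei = FALSE)
  pb <- restricted_piece(B, 1:2, include_nuclei = FALSE)
  e <- piece_piece_energy(pa, pb, sys$grid, sys$part, l_max = 10)
  expect_equal(e$ee, pracma::erf(sqrt(0.5) * 2) / 2, tolerance = 1e-6)
  expect_equal(e$en, 0)
  expect_equal(e$nn, 0)
})

test_that("nuclear cross terms are bare point-Coulomb energies", {
  A <- h_cloud(alpha = 3, z = 0)
  B <- h_cloud(alpha = 3, z = 1.0)
  sys <- pair_system("nn1", A, B)
  pa <- restricted_piece(bare_nucleus(0), 1, include_nuclei = TRUE)
  pb <- restricted_piece(bare_nucleus(1.0), 2, include_nuclei = TRUE)
  e <- piece_piece_energy(pa, pb, sys$grid, sys$part, l_max = 4)
  expect_equal(e$total, 1.0, tolerance = 1e-12)
  expect_equal(e$ee, 0, tolerance = 1e-14)
})

test_that("far-separated neutral pieces interact negligibly", {
  A <- h_cloud(alpha = 1.2, z = 0)
  B <- h_cloud(alpha = 1.2, z = 50)
  sys <- pair_system("far50", A, B)
  e <- piece_piece_energy(restricted_piece(A, 1:2), restricted_piece(B, 1:2),
                          sys$grid, sys$part, l_max = 6)
  expect_lt(abs(e$total), 1e-6)
})

test_that("piece energies are bilinear in the density", {
  A <- h_cloud(alpha = 1.0, q = 1, z = 0)
  A2 <- polarize_density(A, 1, 0.4, c(0, 0, 0.3))   # two primitives, same total
  B <- h_cloud(alpha = 0.8, q = 2, z = 3)
  sys <- pair_system("bilin", A2, B, coarse_spec())
  pb <- restricted_piece(B, 1:2, include_nuclei = FALSE)
  whole <- piece_piece_energy(restricted_piece(A2, 1:2, include_nuclei = FALSE),
                              pb, sys$grid, sys$part, l_max = 8)
  # split A2 into its two primitives
  part1 <- A2; part1$prim <- A2$prim[1, ]
  part2 <- A2; part2$prim <- A2$prim[2, ]
  e1 <- piece_piece_energy(restricted_piece(part1, 1:2, include_nuclei = FALSE),
                           pb, sys$grid, sys$part, l_max = 8)
  e2 <- piece_piece_energy(restricted_piece(part2, 1:2, include_nuclei = FALSE),
                           pb, sys$grid, sys$part, l_max = 8)
  expect_equal(whole$ee, e1$ee + e2$ee, tolerance = 1e-10)
})

test_that("the basin-pair matrix is symmetric, closed and oracle-consistent", {
  sys <- homo_system()
  M <- total_electrostatic_energy(sys$rho0, sys$grid, sys$part, l_max = 10)
  expect_equal(M$pair[1, 2], M$pair[2, 1])
  expect_equal(M$pair[1, 1], M$pair[2, 2], tolerance = 1e-8)
  expect_equal(M$energy, sum(diag(M$pair)) + sum(M$pair[upper.tri(M$pair)]),
               tolerance = 1e-12)
  # total against the closed-form self-energy of the merged density
  expect_equal(M$energy, iqfpen:::.self_energy_analytic(sys$rho0),
               tolerance = 1e-4)

  # brute-force O(N^2) double-grid oracle for the inter-basin term
  gc_ <- build_grid(sys$rho0, coarse_spec())
  pc <- assign_basins(sys$rho0, gc_, fragmentation = attr(sys$rho0, "fragment"))
  rho <- density_eval(sys$rho0, gc_$pts)
  m1 <- pc$basin == 1 & gc_$w > 0
  m2 <- pc$basin == 2 & gc_$w > 0
  P1 <- gc_$pts[m1, ]; P2 <- gc_$pts[m2, ]
  w1 <- gc_$w[m1] * rho[m1]; w2 <- gc_$w[m2] * rho[m2]
  ee <- 0
  for (k in seq(1, nrow(P1), by = 2000)) {
    idx <- k:min(nrow(P1), k + 1999)
    D <- sqrt(outer(P1[idx, 1], P2[, 1], "-")^2 +
                outer(P1[idx, 2], P2[, 2], "-")^2 +
                outer(P1[idx, 3], P2[, 3], "-")^2)
    ee <- ee + sum((w1[idx] %o% w2) / D)
  }
  nuc <- sys$rho0$nuclei
  en <- -nuc$Z[2] * sum(w1 / sqrt((P1[, 1] - nuc$x[2])^2 +
                                    (P1[, 2] - nuc$y[2])^2 +
                                    (P1[, 3] - nuc$z[2])^2)) -
    nuc$Z[1] * sum(w2 / sqrt((P2[, 1] - nuc$x[1])^2 +
                               (P2[, 2] - nuc$y[1])^2 +
                               (P2[, 3] - nuc$z[1])^2))
  nn <- nuc$Z[1] * nuc$Z[2] / abs(nuc$z[2] - nuc$z[1])
  expect_equal(M$pair[1, 2], ee + en + nn, tolerance = 1e-3)
})

test_that("energies are converged in the expansion order", {
  sys <- homo_system()
  M10 <- total_electrostatic_energy(sys$rho0, sys$grid, sys$part, l_max = 10)
  M14 <- total_electrostatic_energy(sys$rho0, sys$grid, sys$part, l_max = 14)
  expect_lt(abs(M10$energy - M14$energy), 1e-4)
  expect_lt(max(abs(M10$pair - M14$pair)), 1e-4)
})

test_that("an isolated fragment decomposed over a foreign partition keeps its energy", {
  sys <- homo_system()
  MA <- total_electrostatic_energy(sys$rhoA, sys$grid, sys$part, l_max = 10)
  expect_equal(MA$energy, iqfpen:::.self_energy_analytic(sys$rhoA),
               tolerance = 1e-4)
})
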