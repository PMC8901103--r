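# Zeroth-order interaction, the four-term decomposition and the relaxed
# intra/inter split.

test_that("zeroth-order interaction has the right limits", {
  # two neutral atoms far apart: fully screened
  e_far <- zeroth_order_interaction(h_cloud(alpha = 1.2, z = 0),
                                    h_cloud(alpha = 1.2, z = 50))
  expect_lt(abs(e_far), 1e-8)

  # two bare +1 nuclei at 2 bohr: point Coulomb
  expect_equal(zeroth_order_interaction(bare_nucleus(0), bare_nucleus(2)),
               0.5, tolerance = 1e-14)

  # overlapping nuclei across fragments are rejected
  expect_error(zeroth_order_interaction(h_cloud(z = 0), h_cloud(z = 0.01)),
               class = "iqfpen_geometry_error")
})

test_that("the four-term decomposition closes onto the zeroth-order energy", {
  d <- make_toy_dimer("hb")
  dec <- cached("hb_eq_dec", cp_decomposition(d$rhoA, d$rhoB, spec = test_spec()))
  expect_equal(dec$E0_ele,
               dec$E_inter_AB + dec$E_intra_A + dec$E_intra_B + dec$E_tail_tail,
               tolerance = 1e-12)
  expect_equal(dec$E0_ele, zeroth_order_interaction(d$rhoA, d$rhoB),
               tolerance = 1e-10)
  expect_equal(dec$E_pen_iqf,
               dec$E_intra_A + dec$E_intra_B + dec$E_tail_tail,
               tolerance = 1e-14)
  # component sums reassemble each term
  expect_equal(dec$E_intra_A,
               sum(dec$components$intra_A), tolerance = 1e-12)
  expect_equal(dec$E_inter_AB, sum(dec$components$inter), tolerance = 1e-10)
})

test_that("penetration terms vanish at three times the equilibrium distance", {
  d <- make_toy_dimer("hb", separation = 3 * 4.9)
  dec <- cp_decomposition(d$rhoA, d$rhoB, spec = test_spec())
  expect_lt(abs(dec$E_pen_iqf), 1e-5)
  expect_lt(abs(dec$E0_ele - dec$E_inter_AB), 1e-5)
  expect_lt(abs(dec$E_intra_A), 1e-5)
  expect_lt(abs(dec$E_tail_tail), 1e-5)
})

test_that("a symmetric homodimer has equal intrafragment terms", {
  sys <- homo_system()
  dec <- cached("homo_eq_dec", {
    cp_decomposition(sys$rhoA, sys$rhoB, grid = sys$grid, partition = sys$part)
  })
  expect_equal(dec$E_intra_A, dec$E_intra_B, tolerance = 1e-6)
  expect_equal(dec$q_pen_into_A, dec$q_pen_into_B, tolerance = 1e-4)
  expect_gte(dec$E_tail_tail, -1e-10)
})

test_that("relabelling A and B swaps the intrafragment terms only", {
  d <- make_toy_dimer("mixed")
  dec <- cached("mixed_eq_dec", cp_decomposition(d$rhoA, d$rhoB, spec = test_spec()))
  swap <- cp_decomposition(d$rhoB, d$rhoA, spec = test_spec())
  expect_equal(swap$E_pen_iqf, dec$E_pen_iqf, tolerance = 1e-7)
  expect_equal(swap$E_intra_A, dec$E_intra_B, tolerance = 1e-7)
  expect_equal(swap$E_intra_B, dec$E_intra_A, tolerance = 1e-7)
  expect_equal(swap$E0_ele, dec$E0_ele, tolerance = 1e-10)
})

test_that("attraction beats repulsion inside the donor fragment at contact", {
  d <- make_toy_dimer("hb", separation = 0.9 * 4.9)
  dec <- cached("hb_09_dec", cp_decomposition(d$rhoA, d$rhoB, spec = test_spec()))
  expect_lt(dec$E_intra_A, 0)
  expect_gt(abs(dec$components$intra_A[["en"]]),
            abs(dec$components$intra_A[["ee"]]))
})

test_that("the relaxed split is consistent with the zeroth-order bookkeeping", {
  sys <- homo_system()
  dec <- cached("homo_eq_dec", {
    cp_decomposition(sys$rhoA, sys$rhoB, grid = sys$grid, partition = sys$part)
  })
  rep0 <- relaxed_iqf(complex_density(list(sys$rhoA, sys$rhoB)),
                      sys$rhoA, sys$rhoB, sys$grid, sys$part)
  expect_equal(rep0$mode, "zeroth_order")
  expect_equal(rep0$dE_ele, dec$E0_ele, tolerance = 1e-6)
  expect_equal(rep0$dE_ele, rep0$dE_A + rep0$dE_B + rep0$E_inter,
               tolerance = 1e-12)
  expect_equal(rep0$dE_A, rep0$dE_B, tolerance = 1e-6)
})

test_that("synthetic polarization moves the intrafragment energy", {
  sys <- homo_system()
  rep0 <- relaxed_iqf(complex_density(list(sys$rhoA, sys$rhoB)),
                      sys$rhoA, sys$rhoB, sys$grid, sys$part)
  rhoAp <- polarize_density(sys$rhoA, 1, 0.15, c(0, 0, 0.5))
  rho0p <- merge_fragments(rhoAp, sys$rhoB)
  gp <- build_grid(rho0p, test_spec())
  pp <- assign_basins(rho0p, gp, fragmentation = attr(rho0p, "fragment"))
  repp <- relaxed_iqf(complex_density(list(rhoAp, sys$rhoB)),
                      sys$rhoA, sys$rhoB, gp, pp)
  # the polarized fragment's own term changes strongly, the partner's only
  # through basin-shape effects
  expect_gt(abs(repp$dE_A - rep0$dE_A), 1e-3)
  expect_lt(abs(repp$dE_B - rep0$dE_B), 0.2 * abs(repp$dE_A - rep0$dE_A))

  # electron-count mismatch guard
  expect_error(
    relaxed_iqf(complex_density(list(sys$rhoA, sys$rhoB)),
                polarize_density(sys$rhoA, 1, 0, c(0, 0, 0)),
                h_cloud(alpha = 0.7, q = 1.5, z = 4.2),
                sys$grid, sys$part),
    class = "iqfpen_config_error"
  )
})

test_that("far-separated unpolarized fragments have a null report", {
  A <- h_cloud(alpha = 1.2, z = 0)
  B <- h_cloud(alpha = 1.2, z = 50)
  sys <- pair_system("far50", A, B)
  rep0 <- relaxed_iqf(complex_density(list(A, B)), A, B, sys$grid, sys$part)
  expect_lt(abs(rep0$dE_A), 1e-6)
  expect_lt(abs(rep0$dE_B), 1e-6)
  expect_lt(abs(rep0$E_inter), 1e-6)
})

test_that("multipole-reference penetration is definitional and vanishes for point charges", {
  e <- multipolar_penetration(-0.5, -0.45, l_max = 2)
  expect_equal(as.numeric(e), -0.05)
  expect_equal(attr(e, "l_max"), 2L)

  # point-charge-only system: the multipole expansion is exact
  A <- bare_nucleus(0); B <- bare_nucleus(3)
  e0 <- zeroth_order_interaction(A, B)
  mm <- mtp_interaction(promol_multipoles(A), promol_multipoles(B))
  expect_equal(as.numeric(multipolar_penetration(e0, mm$energy)), 0,
               tolerance = 1e-14)
})
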