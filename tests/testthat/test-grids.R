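# Two-zone quadrature grids: beta radii, conservation, masked integration
# and convergence behaviour.

test_that("beta radius finds the internuclear saddle", {
  # symmetric pair of identical compact H clouds, bond 1.4 bohr: saddle at
  # the midpoint, radius 0.6 x 0.7 bohr
  h2 <- merge_fragments(h_cloud(alpha = 2.5, z = 0), h_cloud(alpha = 2.5, z = 1.4))
  expect_equal(beta_radius(h2, 1), 0.42, tolerance = 1e-3)
  expect_equal(beta_radius(h2, 2), 0.42, tolerance = 1e-3)

  # asymmetric pair: dense 1-D scan oracle for the density minimum
  hf <- merge_fragments(h_cloud(alpha = 2.0, q = 9, z = 0, element = "F", Z = 9),
                        h_cloud(alpha = 2.5, q = 1, z = 1.7))
  t <- seq(0.02, 0.98, length.out = 4001)
  rho_line <- density_eval(hf, cbind(0, 0, t * 1.7))
  t_saddle <- t[which.min(rho_line)]
  expect_equal(beta_radius(hf, 1), 0.6 * t_saddle * 1.7, tolerance = 1e-3)

  # strongly overlapped diffuse pair has no bracketed internuclear minimum:
  # fall back to half the nearest-neighbour distance, with a warning
  blob <- merge_fragments(h_cloud(alpha = 1.2, z = 0), h_cloud(alpha = 1.2, z = 1.4))
  expect_warning(bb <- beta_radius(blob, 1), "saddle")
  expect_equal(bb, 0.6 * 0.7, tolerance = 1e-6)

  # isolated atom: fallback with a warning
  expect_warning(b <- beta_radius(h_cloud(), 1), "isolated")
  expect_gt(b, 0)
})

test_that("grids conserve electron counts", {
  g1 <- suppressWarnings(build_grid(h_cloud(alpha = 1, q = 1), test_spec()))
  expect_equal(grid_integrate(g1, density_eval(h_cloud(alpha = 1, q = 1), g1$pts)),
               1, tolerance = 1e-3)

  sys <- homo_system()
  n <- grid_integrate(sys$grid, density_eval(sys$rho0, sys$grid$pts))
  expect_equal(n, electron_count(sys$rho0), tolerance = 1e-3)
})

test_that("the inner zone integrates the beta-sphere volume", {
  sys <- homo_system()
  inner1 <- sys$grid$zone == 1L & sys$grid$atom == 1L
  vol <- grid_integrate(sys$grid, rep(1, sys$grid$n), inner1)
  beta <- sys$grid$atoms[[1]]$beta
  expect_equal(vol, 4 / 3 * pi * beta^3, tolerance = 0.005 * 4 / 3 * pi * beta^3)
})

test_that("masked integrals recover the closed-form partial Gaussian charge", {
  d <- h_cloud(alpha = 1.3, q = 1)
  g <- suppressWarnings(build_grid(d, test_spec()))
  beta <- g$atoms[[1]]$beta
  r <- sqrt(rowSums(g$pts^2))
  got <- grid_integrate(g, density_eval(d, g$pts), r < beta)
  expect_equal(got, stats::pgamma(1.3 * beta^2, 1.5), tolerance = 1e-3)

  expect_equal(grid_integrate(g, rep(0, g$n)), 0)
  expect_equal(grid_integrate(g, rep(1, g$n), rep(FALSE, g$n)), 0)
  expect_error(grid_integrate(g, 1:3), class = "iqfpen_config_error")
})

test_that("basin-masked integrals add up to the unmasked integral", {
  sys <- homo_system()
  rho <- density_eval(sys$rho0, sys$grid$pts)
  parts <- vapply(1:2, function(b) {
    grid_integrate(sys$grid, rho, sys$part$basin == b)
  }, numeric(1))
  expect_equal(sum(parts), grid_integrate(sys$grid, rho), tolerance = 1e-12)
})

test_that("invalid angular orders are rejected with the valid list", {
  expect_error(atom_grid_spec(inner_angular = 100L), "valid orders")
  expect_error(atom_grid_spec(beta_fraction = 1.2), class = "iqfpen_config_error")
  expect_error(angular_quadrature(123), class = "iqfpen_config_error")
})

test_that("radial resolution converges and halving it degrades the integral", {
  steep <- h_cloud(alpha = 6, q = 1)
  mk <- function(nr_in, nr_out) {
    suppressWarnings(build_grid(steep, atom_grid_spec(
      inner_angular = 26L, inner_radial = nr_in,
      outer_angular = 50L, outer_radial = nr_out, r_max = 15
    )))
  }
  n_of <- function(g) grid_integrate(g, density_eval(steep, g$pts))
  err_full <- abs(n_of(mk(24L, 36L)) - 1)
  err_half <- abs(n_of(mk(12L, 18L)) - 1)
  expect_gt(err_half, 10 * err_full)

  # doubling both radial and angular orders moves the count by < 1e-4 e
  sys <- homo_system()
  n_test <- grid_integrate(sys$grid, density_eval(sys$rho0, sys$grid$pts))
  g2 <- build_grid(sys$rho0, atom_grid_spec(
    inner_angular = 230L, inner_radial = 120L,
    outer_angular = 590L, outer_radial = 180L, r_max = 15
  ))
  n_dbl <- grid_integrate(g2, density_eval(sys$rho0, g2$pts))
  expect_lt(abs(n_dbl - n_test), 1e-4)
  expect_lt(abs(n_test - electron_count(sys$rho0)), 1e-4)
})

test_that("grid tables export points with owners and zones", {
  sys <- homo_system()
  tab <- grid_table(sys$grid, sys$part)
  expect_equal(nrow(tab), sys$grid$n)
  expect_setequal(unique(tab$zone), c("inner", "outer"))
  expect_setequal(unique(tab$owner), c(1L, 2L))
})
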