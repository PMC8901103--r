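# Shared fixtures and a session cache for expensive objects (grids, basin
# partitions, the preset x scan-factor sweep used by the acceptance tests).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

test_spec <- function() grid_profile("test")
coarse_spec <- function() grid_profile("coarse")

# single spherical 1-electron Gaussian "atom" on an H nucleus
h_cloud <- function(alpha = 1, q = 1, z = 0, element = "H", Z = 1) {
  gaussian_density(
    tibble::tibble(element = element, Z = Z, x = 0, y = 0, z = z),
    tibble::tibble(atom = 1L, x = 0, y = 0, z = z, alpha = alpha, q = q),
    label = paste0(element, z)
  )
}

# electron-free fragment (point nucleus only)
bare_nucleus <- function(z = 0, Z = 1, element = "H") {
  gaussian_density(
    tibble::tibble(element = element, Z = Z, x = 0, y = 0, z = z),
    tibble::tibble(atom = integer(0), x = numeric(0), y = numeric(0),
                   z = numeric(0), alpha = numeric(0), q = numeric(0)),
    label = "bare"
  )
}

# two-centre grid + rho0-basin partition for a fragment pair, cached by tag
pair_system <- function(tag, rhoA, rhoB, spec = test_spec()) {
  cached(paste0("pair_", tag), {
    rho0 <- merge_fragments(rhoA, rhoB)
    grid <- build_grid(rho0, spec)
    part <- assign_basins(rho0, grid, fragmentation = attr(rho0, "fragment"))
    list(rho0 = rho0, grid = grid, part = part, rhoA = rhoA, rhoB = rhoB)
  })
}

homo_system <- function() {
  d <- make_toy_dimer("homo")
  pair_system("homo", d$rhoA, d$rhoB)
}

# ---- acceptance sweep: every preset at the eight scan factors -------------
# Stores per-geometry summaries only (grids are dropped to bound memory).

acceptance_sweep <- function() {
  cached("acceptance_sweep", {
    rows <- list()
    for (preset in toy_presets()) {
      d <- make_toy_dimer(preset)
      sc <- run_scan(d, scan_spec(), spec = test_spec(), l_max = 10L)
      decs <- attr(sc, "decompositions")
      for (i in seq_along(decs)) {
        dec <- decs[[i]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          preset = preset,
          factor = sc$factor[i],
          E0_ele = dec$E0_ele,
          E_inter_AB = dec$E_inter_AB,
          E_intra_A = dec$E_intra_A,
          E_intra_B = dec$E_intra_B,
          E_tail_tail = dec$E_tail_tail,
          E_pen_iqf = dec$E_pen_iqf,
          E0_exact = dec$E0_exact,
          closure = dec$E0_ele -
            (dec$E_inter_AB + dec$E_intra_A + dec$E_intra_B + dec$E_tail_tail),
          intra_A_ee = dec$components$intra_A[["ee"]],
          intra_A_en = dec$components$intra_A[["en"]],
          q_pen_into_A = dec$q_pen_into_A,
          q_pen_into_B = dec$q_pen_into_B,
          pop_A_in_A = dec$pop_A_in_A,
          pop_B_in_B = dec$pop_B_in_B,
          pop_total = sum(dec$basin_populations),
          N_A = dec$N_A,
          N_B = dec$N_B,
          E_mtp_l0 = dec$E_mtp[["l0"]],
          E_mtp_l2 = dec$E_mtp[["l2"]],
          E_pen_mtp_l2 = dec$E_pen_mtp[["l2"]]
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

# tiny wavefunction fixture writers (synthetic files)

write_wfx_h_atom <- function(path) {
  a <- c(3.42525091, 0.62391373, 0.16885540)
  c0 <- c(0.15432897, 0.53532814, 0.44463454)
  cc <- c0 * (2 * a / pi)^0.75
  writeLines(c(
    "<Number of Nuclei>", "1", "</Number of Nuclei>",
    "<Number of Primitives>", "3", "</Number of Primitives>",
    "<Number of Occupied Molecular Orbitals>", "1",
    "</Number of Occupied Molecular Orbitals>",
    "<Atomic Numbers>", "1", "</Atomic Numbers>",
    "<Nuclear Cartesian Coordinates>", "0.0 0.0 0.0",
    "</Nuclear Cartesian Coordinates>",
    "<Primitive Centers>", "1 1 1", "</Primitive Centers>",
    "<Primitive Types>", "1 1 1", "</Primitive Types>",
    "<Primitive Exponents>", paste(sprintf("%.10f", a), collapse = " "),
    "</Primitive Exponents>",
    "<Molecular Orbital Occupation Numbers>", "1.0",
    "</Molecular Orbital Occupation Numbers>",
    "<Molecular Orbital Primitive Coefficients>",
    "<MO Number>", "1", "</MO Number>",
    paste(sprintf("%.12f", cc), collapse = " "),
    "</Molecular Orbital Primitive Coefficients>"
  ), path)
  path
}

write_molden_h2 <- function(path) {
  a <- c(3.42525091, 0.62391373, 0.16885540)
  c0 <- c(0.15432897, 0.53532814, 0.44463454)
  writeLines(c(
    "[Molden Format]",
    "[Atoms] AU",
    "H 1 1 0.0 0.0 0.0",
    "H 2 1 0.0 0.0 1.4",
    "[GTO]",
    " 1 0", "  s 3 1.00", sprintf("   %.8f %.8f", a, c0), "",
    " 2 0", "  s 3 1.00", sprintf("   %.8f %.8f", a, c0), "",
    "[MO]",
    " Sym= A1", " Ene= -0.58", " Spin= Alpha", " Occup= 2.0",
    "   1 0.54893", "   2 0.54893"
  ), path)
  path
}
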