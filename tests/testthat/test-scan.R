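# Toy presets, the distance-scan driver and reporting.

test_that("presets are deterministic and physically typed", {
  d1 <- make_toy_dimer("hb", seed = 5, jitter = 0.05)
  d2 <- make_toy_dimer("hb", seed = 5, jitter = 0.05)
  expect_identical(d1$geometry, d2$geometry)
  d3 <- make_toy_dimer("hb", seed = 6, jitter = 0.05)
  expect_false(identical(d1$geometry, d3$geometry))

  # polar preset binds electrostatically; apolar preset is weak
  hb <- make_toy_dimer("hb")
  expect_lt(zeroth_order_interaction(hb$rhoA, hb$rhoB), 0)
  disp <- make_toy_dimer("disp")
  expect_lt(abs(hartree_to_kcal(zeroth_order_interaction(disp$rhoA, disp$rhoB))), 2)

  expect_error(make_toy_dimer("nope"), class = "iqfpen_config_error")
  expect_error(make_toy_dimer("hb", separation = 0.3),
               class = "iqfpen_geometry_error")
  expect_error(make_toy_dimer("hb", jitter = 0.1), class = "iqfpen_config_error")
})

test_that("scan specifications are validated", {
  expect_silent(scan_spec())
  expect_error(scan_spec(c(1.0, 0.9)), class = "iqfpen_config_error")
  expect_error(scan_spec(c(0.9, 1.1)), class = "iqfpen_config_error")
  expect_error(scan_spec(c(-1, 1)), class = "iqfpen_config_error")
})

test_that("the scan driver produces closed rows that converge with distance", {
  sweep <- acceptance_sweep()
  homo <- sweep[sweep$preset == "homo", ]
  expect_equal(nrow(homo), 8)
  expect_true(all(abs(homo$closure) < 1e-6))
  # E_inter approaches E0 with increasing separation
  gap <- abs(homo$E0_ele - homo$E_inter_AB)
  expect_true(all(diff(gap) < 1e-9))
  # far-limit row
  expect_lt(abs(homo$E_pen_iqf[homo$factor == 2]), 1e-5)

  # hb: electrostatic binding reinforced upon shortening
  hb <- sweep[sweep$preset == "hb", ]
  expect_lt(hb$E0_ele[hb$factor == 0.9], hb$E0_ele[hb$factor == 1.5])
})

test_that("scan output serialises to the documented CSV and JSON forms", {
  d <- make_toy_dimer("homo")
  sc <- cached("homo_scan_small", {
    run_scan(d, scan_spec(c(1.0, 2.0)), spec = coarse_spec())
  })
  f <- withr::local_tempfile(fileext = ".csv")
  write_scan_csv(sc, f)
  tab <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(names(tab),
               c("factor", "E0_ele", "E_inter_AB", "E_intra_A", "E_intra_B",
                 "E_tail_tail", "E_pen_iqf", "E_mtp_q", "E_mtp_l2",
                 "E_pen_mtp_l2"))
  expect_equal(nrow(tab), 2)

  rep1 <- cp_report(attr(sc, "decompositions")[[1]], "homo", 1.0)
  expect_equal(rep1$E0_ele$kcalmol, hartree_to_kcal(rep1$E0_ele$hartree))
  expect_lt(abs(rep1$closure_residual_hartree), 1e-6)

  gl <- glance(sc)
  expect_equal(gl$label, "homo")
  p <- ggplot2::ggplot_build(autoplot(sc))
  expect_gt(length(p$data), 0)
})

test_that("tidy and glance summarise decompositions", {
  d <- make_toy_dimer("homo")
  dec <- cached("homo_coarse_dec", {
    cp_decomposition(d$rhoA, d$rhoB, spec = coarse_spec())
  })
  td <- tidy(dec)
  expect_equal(td$term[1], "E0_ele")
  expect_equal(td$kcalmol, hartree_to_kcal(td$hartree))
  gl <- glance(dec)
  expect_equal(gl$closure_residual_hartree, 0, tolerance = 1e-12)
})

test_that("the command line drives decompose and scan end to end", {
  dir <- withr::local_tempdir()
  d <- make_toy_dimer("homo")
  xyz <- file.path(dir, "homo.xyz")
  write_xyz(d$geometry, xyz, comment = "homodimer fixture")
  cfg <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(
    grid = list(profile = "coarse"),
    promolecule = list(elements = list(He = list(alpha = 0.7))),
    lmax = 8
  ), cfg)

  out <- file.path(dir, "run1")
  status <- suppressMessages(cli_main(c(
    "decompose", "--xyz", xyz, "--frag", "A=1,B=2",
    "--config", cfg, "--out", out
  )))
  expect_equal(status, 0L)
  rep <- jsonlite::read_json(paste0(out, "_decompose.json"))
  expect_lt(abs(rep$closure_residual_hartree), 1e-6)

  # determinism: identical bytes on a re-run
  out2 <- file.path(dir, "run2")
  suppressMessages(cli_main(c("decompose", "--xyz", xyz, "--frag", "A=1,B=2",
                              "--config", cfg, "--out", out2)))
  expect_identical(readLines(paste0(out, "_decompose.json")),
                   readLines(paste0(out2, "_decompose.json")))

  # scan with the default eight factors
  outs <- file.path(dir, "scan")
  status <- suppressMessages(cli_main(c(
    "scan", "--xyz", xyz, "--frag", "A=1,B=2", "--config", cfg, "--out", outs
  )))
  expect_equal(status, 0L)
  tab <- readr::read_csv(paste0(outs, "_scan.csv"), show_col_types = FALSE)
  expect_equal(nrow(tab), 8)

  # usage errors exit 2
  expect_equal(suppressMessages(cli_main(c("decompose", "--xyz", xyz))), 2L)
  expect_equal(suppressMessages(cli_main(character(0))), 2L)
  # runtime errors exit 1
  expect_equal(suppressWarnings(suppressMessages(cli_main(c(
    "decompose", "--xyz", file.path(dir, "missing.xyz"), "--frag", "A=1,B=2"
  )))), 1L)
})

test_that("fit-charges and compare-pairs subcommands run", {
  dir <- withr::local_tempdir()
  d <- make_toy_dimer("homo")
  xyz <- file.path(dir, "homo.xyz")
  write_xyz(d$geometry, xyz)
  cfg <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(grid = list(profile = "coarse"), lmax = 8), cfg)

  out <- file.path(dir, "fc")
  expect_equal(suppressMessages(cli_main(c(
    "fit-charges", "--xyz", xyz, "--config", cfg, "--out", out
  ))), 0L)
  ch <- readr::read_csv(paste0(out, "_charges.csv"), show_col_types = FALSE)
  expect_equal(nrow(ch), 2)
  expect_equal(sum(ch$Q00), 0, tolerance = 1e-10)

  out2 <- file.path(dir, "cp")
  expect_equal(suppressMessages(cli_main(c(
    "compare-pairs", "--xyz", xyz, "--frag", "A=1,B=2",
    "--config", cfg, "--out", out2
  ))), 0L)
  expect_true(file.exists(paste0(out2, "_pairs.csv")))
})
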