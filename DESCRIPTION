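Package: iqfpen
Title: Fragment-Resolved Electrostatics and Charge Penetration from Quantum
    Chemical Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the electrostatic interaction of a two-fragment
    molecular complex into atomic, fragment, intra- and inter-fragment terms
    from continuous charge densities, following the interacting-quantum-
    fragments (IQF) partitioning of QTAIM attraction basins. Builds synthetic
    promolecular Gaussian densities or reads wfx/molden wavefunction files,
    integrates them on two-zone (beta-sphere plus Becke-weighted outer shell)
    atomic quadrature grids, computes basin-restricted Coulomb energies via
    one-centre Laplace expansions, and evaluates the charge-penetration energy
    both as the multipole-reference difference and as the basin-resolved
    four-term IQF decomposition. Point-charge and distributed-multipole
    comparators (ESP-fitted charges, QTAIM basin multipoles up to quadrupole)
    and a rigid distance-scan driver with CSV/JSON reporting are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
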