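# Distance-scan driver: fragment B is rigidly translated along the fragment
# centroid axis to a list of R_AB/R_eq factors; each geometry is decomposed
# with the basin machinery and compared with the multipolar models.

#' Scan specification
#'
#' @param factors R_AB/R_eq multipliers, sorted ascending; must contain 1.0.
#'   Default follows the eight-point convention of scaled-separation
#'   benchmark sets: 0.90, 0.95, 1.00, 1.05, 1.10, 1.25, 1.50, 2.00.
#' @param mtp_lmax Multipole truncation orders reported alongside (default
#'   0 and 2).
#' @return An object of class `scan_spec`.
#' @export
scan_spec <- function(factors = c(0.90, 0.95, 1.00, 1.05, 1.10, 1.25, 1.50, 2.00),
                      mtp_lmax = c(0L, 2L)) {
  if (any(factors <= 0)) abort("scan factors must be positive", class = "iqfpen_config_error")
  if (is.unsorted(factors)) abort("scan factors must be sorted ascending", class = "iqfpen_config_error")
  if (!any(abs(factors - 1) < 1e-12)) {
    abort("scan factors must include 1.0 (the equilibrium geometry)",
          class = "iqfpen_config_error")
  }
  structure(list(factors = factors, mtp_lmax = as.integer(mtp_lmax)),
            class = "scan_spec")
}

#' Decompose one dimer geometry
#'
#' Runs the full pipeline for a single geometry: zeroth-order density, grid,
#' basin partition, four-term decomposition, analytic distributed multipoles
#' and the multipole-reference penetration energy.
#'
#' @param dimer A [make_toy_dimer()] result, or any list with `rhoA`, `rhoB`.
#' @param spec Grid profile ([atom_grid_spec()]).
#' @param l_max Laplace expansion order.
#' @param mtp_lmax Multipole truncation orders to report.
#' @param keep_grid Keep the quadrature grid and partition in the returned
#'   object (set `FALSE` in sweeps to bound memory).
#' @return A `cp_decomposition` with multipolar comparator fields `E_mtp`
#'   (named by order) and `E_pen_mtp` attached.
#' @export
decompose_dimer <- function(dimer, spec = grid_profile("test"), l_max = 10L,
                            mtp_lmax = c(0L, 2L), keep_grid = TRUE) {
  dec <- cp_decomposition(dimer$rhoA, dimer$rhoB, spec = spec, l_max = l_max)
  if (!keep_grid) dec$grid <- dec$partition <- NULL
  mA <- promol_multipoles(dimer$rhoA, l_max = max(mtp_lmax))
  mB <- promol_multipoles(dimer$rhoB, l_max = max(mtp_lmax))
  emtp <- vapply(mtp_lmax, function(l) mtp_interaction(mA, mB, l_max = l)$energy,
                 numeric(1))
  names(emtp) <- paste0("l", mtp_lmax)
  dec$E_mtp <- emtp
  e0 <- if (is.na(dec$E0_exact)) dec$E0_ele else dec$E0_exact
  dec$E_pen_mtp <- vapply(emtp, function(e) as.numeric(multipolar_penetration(e0, e)),
                          numeric(1))
  dec
}

#' Rigid distance scan of a two-fragment complex
#'
#' Translates fragment B along the fragment-centroid axis so that the
#' centroid separation equals `factor * R_eq` for every factor, and computes
#' the zeroth-order decomposition and the multipolar comparators at each
#' geometry.
#'
#' @param dimer A [make_toy_dimer()] result (fields `rhoA`, `rhoB`, `R_eq`,
#'   `axis`).
#' @param scan A [scan_spec()].
#' @param spec Grid profile.
#' @param l_max Laplace expansion order.
#' @return An `iqf_scan`: a tibble with one row per factor (energies in
#'   kcal/mol in the spec's column set, plus `*_hartree` duplicates and the
#'   mutual penetration charges), with the per-factor `cp_decomposition`
#'   objects in attribute `decompositions`.
#' @export
run_scan <- function(dimer, scan = scan_spec(), spec = grid_profile("test"),
                     l_max = 10L) {
  if (sqrt(sum(dimer$axis^2)) < 1e-8) {
    abort("fragment centroids coincide; no displacement axis", class = "iqfpen_geometry_error")
  }
  decs <- vector("list", length(scan$factors))
  rows <- vector("list", length(scan$factors))
  for (i in seq_along(scan$factors)) {
    f <- scan$factors[i]
    shift <- (f - 1) * dimer$R_eq * dimer$axis
    geom <- dimer
    geom$rhoB <- translate_density(dimer$rhoB, shift)
    dec <- decompose_dimer(geom, spec = spec, l_max = l_max,
                           mtp_lmax = scan$mtp_lmax, keep_grid = FALSE)
    decs[[i]] <- dec
    k <- hartree_to_kcal
    rows[[i]] <- tibble(
      factor = f,
      E0_ele = k(dec$E0_ele),
      E_inter_AB = k(dec$E_inter_AB),
      E_intra_A = k(dec$E_intra_A),
      E_intra_B = k(dec$E_intra_B),
      E_tail_tail = k(dec$E_tail_tail),
      E_pen_iqf = k(dec$E_pen_iqf),
      E_mtp_q = k(dec$E_mtp[["l0"]]),
      E_mtp_l2 = if ("l2" %in% names(dec$E_mtp)) k(dec$E_mtp[["l2"]]) else NA_real_,
      E_pen_mtp_l2 = if ("l2" %in% names(dec$E_pen_mtp)) k(dec$E_pen_mtp[["l2"]]) else NA_real_,
      E0_ele_hartree = dec$E0_ele,
      E_inter_AB_hartree = dec$E_inter_AB,
      E_pen_iqf_hartree = dec$E_pen_iqf,
      E0_exact_hartree = dec$E0_exact,
      q_pen_into_A = dec$q_pen_into_A,
      q_pen_into_B = dec$q_pen_into_B
    )
  }
  out <- bind_rows(rows)
  attr(out, "decompositions") <- decs
  attr(out, "label") <- dimer$label
  class(out) <- c("iqf_scan", class(out))
  out
}

#' @export
glance.iqf_scan <- function(x, ...) {
  eq <- which.min(abs(x$factor - 1))
  tibble(
    label = attr(x, "label"),
    E0_ele_eq_kcal = x$E0_ele[eq],
    E_pen_iqf_eq_kcal = x$E_pen_iqf[eq],
    E_inter_AB_eq_kcal = x$E_inter_AB[eq],
    max_closure_residual_hartree = max(vapply(
      attr(x, "decompositions"),
      function(d) abs(d$E0_ele - (d$E_inter_AB + d$E_intra_A + d$E_intra_B + d$E_tail_tail)),
      numeric(1)
    ))
  )
}

#' Plot the scan curves
#'
#' Energy terms (kcal/mol) versus R_AB/R_eq, one line per descriptor, in the
#' style of distance-dependence analyses of electrostatic decompositions.
#'
#' @param object An `iqf_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iqf_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("factor", "E0_ele", "E_inter_AB", "E_pen_iqf",
                          "E_mtp_q", "E_mtp_l2")],
    -"factor", names_to = "term", values_to = "kcalmol"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$factor, y = .data$kcalmol,
                                     colour = .data$term)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(R[AB] / R[eq]), y = "energy (kcal/mol)",
                  colour = NULL,
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' Write a scan table to CSV
#'
#' Emits the spec'd column set `factor, E0_ele, E_inter_AB, E_intra_A,
#' E_intra_B, E_tail_tail, E_pen_iqf, E_mtp_q, E_mtp_l2, E_pen_mtp_l2`
#' (kcal/mol).
#'
#' @param x An `iqf_scan`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_scan_csv <- function(x, file) {
  cols <- c("factor", "E0_ele", "E_inter_AB", "E_intra_A", "E_intra_B",
            "E_tail_tail", "E_pen_iqf", "E_mtp_q", "E_mtp_l2", "E_pen_mtp_l2")
  readr::write_csv(as_tibble(x)[, cols], file)
  invisible(file)
}

#' JSON report for a decomposition
#'
#' @param dec A `cp_decomposition` (typically from [decompose_dimer()], so
#'   that the multipolar fields are present).
#' @param geometry_id Identifier string.
#' @param R_over_Req Relative separation of this geometry.
#' @return A list ready for `jsonlite::write_json` with energies in both
#'   hartree and kcal/mol.
#' @export
cp_report <- function(dec, geometry_id = "geometry", R_over_Req = 1.0) {
  k <- hartree_to_kcal
  both <- function(h) list(hartree = h, kcalmol = k(h))
  list(
    geometry_id = geometry_id,
    R_over_Req = R_over_Req,
    E0_ele = both(dec$E0_ele),
    E_inter_AB = both(dec$E_inter_AB),
    E_intra_A = both(dec$E_intra_A),
    E_intra_B = both(dec$E_intra_B),
    E_tail_tail = both(dec$E_tail_tail),
    E_pen_IQF = both(dec$E_pen_iqf),
    E_mtp = if (!is.null(dec$E_mtp)) lapply(as.list(dec$E_mtp), both) else NULL,
    E_pen_mtp = if (!is.null(dec$E_pen_mtp)) lapply(as.list(dec$E_pen_mtp), both) else NULL,
    q_pen_A = dec$q_pen_into_A,
    q_pen_B = dec$q_pen_into_B,
    closure_residual_hartree =
      dec$E0_ele - (dec$E_inter_AB + dec$E_intra_A + dec$E_intra_B + dec$E_tail_tail)
  )
}
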