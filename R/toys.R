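# Synthetic two-fragment fixtures mirroring the three interaction classes of
# noncovalent benchmark sets (hydrogen-bonded / polar, dispersion / apolar,
# mixed). Polar fragments are OH-like diatomics whose valence clouds are
# displaced along the bond, so the sites carry dipoles and the fragment a
# bond dipole; apolar fragments are single diffuse closed-shell atoms. The
# exponents are chosen so that the equilibrium mutual charge-penetration
# electron counts fall in the few-hundredths-of-an-electron range typical of
# real noncovalent dimers, and all presets are neutral.

#' Toy dimer specification
#'
#' A fragment is a list with `nuclei` (tibble: `element`, `Z`, `x`, `y`, `z`
#' in bohr) and `prim` (tibble: `atom`, `x`, `y`, `z`, `alpha`, `q`) —
#' exactly the tables a [gaussian_density()] is built from. Fragment B is
#' placed along +z so that the fragment-centroid separation equals
#' `separation`.
#'
#' @param fragment_a,fragment_b Fragment lists (see above).
#' @param separation Centroid-centroid equilibrium separation (bohr).
#' @param seed Optional seed controlling the (optional) coordinate jitter.
#' @param jitter Amplitude (bohr) of uniform random displacement applied to
#'   every atom (0 = rigid preset).
#' @param label Fixture tag.
#' @return An object of class `toy_dimer_spec`.
#' @export
toy_dimer_spec <- function(fragment_a, fragment_b, separation,
                           seed = NULL, jitter = 0, label = "toy") {
  stopifnot(separation > 0, jitter >= 0)
  chk <- function(fr) {
    stopifnot(is.list(fr), all(c("nuclei", "prim") %in% names(fr)))
    fr$nuclei <- as_tibble(fr$nuclei)
    fr$prim <- as_tibble(fr$prim)
    fr
  }
  structure(list(fragment_a = chk(fragment_a), fragment_b = chk(fragment_b),
                 separation = separation, seed = seed, jitter = jitter,
                 label = label), class = "toy_dimer_spec")
}

# OH-like polar diatomic: O at z = 0, H at z = +1.8 pointing toward the
# partner; the O valence cloud is displaced toward H and the H cloud toward
# O, giving nonzero site dipoles. qH sets the donor-H electron population
# (site charge +1 - qH); the fragment is neutral.
.polar_fragment <- function(qH = 0.35) {
  list(
    nuclei = tibble(element = c("O", "H"), Z = c(8, 1),
                    x = 0, y = 0, z = c(0, 1.8)),
    prim = tibble(atom = c(1L, 1L, 2L), x = 0, y = 0,
                  z = c(0, 0.35, 1.6),
                  alpha = c(1.0, 0.75, 0.9),
                  q = c(9 - qH - 0.8, 0.8, qH))
  )
}

.atom_fragment <- function(element, Z, alpha) {
  list(
    nuclei = tibble(element = element, Z = Z, x = 0, y = 0, z = 0),
    prim = tibble(atom = 1L, x = 0, y = 0, z = 0, alpha = alpha, q = Z)
  )
}

.toy_presets <- function() {
  list(
    # head-to-tail polar diatomics, A's H pointing at B's O (H-bond-like)
    hb = list(a = .polar_fragment(0.35), b = .polar_fragment(0.35),
              separation = 4.9),
    # two diffuse closed-shell atoms at contact (dispersion-like: small
    # electrostatics, penetration-dominated)
    disp = list(a = .atom_fragment("Ne", 10, 0.8),
                b = .atom_fragment("Ne", 10, 0.8), separation = 5.0),
    # polar diatomic against a closed-shell atom (mixed)
    mixed = list(a = .polar_fragment(0.35),
                 b = .atom_fragment("Ne", 10, 0.8), separation = 5.4),
    # symmetric apolar homodimer
    homo = list(a = .atom_fragment("He", 2, 0.7),
                b = .atom_fragment("He", 2, 0.7), separation = 4.2),
    # strongly polar variant (nearly naked donor proton)
    polar2 = list(a = .polar_fragment(0.20), b = .polar_fragment(0.20),
                  separation = 4.8)
  )
}

#' Toy dimer preset names
#' @return Character vector of preset names.
#' @export
toy_presets <- function() names(.toy_presets())

#' Build a synthetic two-fragment dimer
#'
#' Instantiates a preset (or an explicit [toy_dimer_spec()]) into two
#' [gaussian_density()] fragments at the complex geometry, fragment B
#' displaced along +z by the equilibrium separation. With a `seed` and a
#' nonzero `jitter` the atomic positions receive a deterministic uniform
#' displacement (the same seed always yields the same geometry).
#'
#' @param preset Preset name (see [toy_presets()]) or a [toy_dimer_spec()].
#' @param separation Optional override of the preset separation (bohr).
#' @param seed,jitter Optional jitter controls (see [toy_dimer_spec()]).
#' @return List with `rhoA`, `rhoB` ([gaussian_density()]), `R_eq` (bohr),
#'   `axis` (unit vector A->B), `geometry` (tibble, angstrom, with
#'   `fragment`), `label`.
#' @export
make_toy_dimer <- function(preset = "hb", separation = NULL, seed = NULL,
                           jitter = 0) {
  if (inherits(preset, "toy_dimer_spec")) {
    spec <- preset
  } else {
    presets <- .toy_presets()
    if (!is.character(preset) || !preset %in% names(presets)) {
      abort(paste0("unknown preset; available: ",
                   paste(names(presets), collapse = ", ")),
            class = "iqfpen_config_error")
    }
    p <- presets[[preset]]
    spec <- toy_dimer_spec(p$a, p$b,
                           separation = if (is.null(separation)) p$separation else separation,
                           seed = seed, jitter = jitter, label = preset)
  }
  if (!is.null(separation)) spec$separation <- separation
  if (!is.null(seed)) spec$seed <- seed
  if (jitter > 0) spec$jitter <- jitter

  fa <- spec$fragment_a
  fb <- spec$fragment_b
  # shift fragment B so the nuclear-centroid separation equals `separation`
  dz <- mean(fa$nuclei$z) - mean(fb$nuclei$z) + spec$separation
  fb$nuclei$z <- fb$nuclei$z + dz
  fb$prim$z <- fb$prim$z + dz

  if (spec$jitter > 0) {
    if (is.null(spec$seed)) {
      abort("jitter requires a seed for reproducibility", class = "iqfpen_config_error")
    }
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(spec$seed)
    jit <- function(fr) {
      for (i in seq_len(nrow(fr$nuclei))) {
        dd <- stats::runif(3, -spec$jitter, spec$jitter)
        sel <- fr$prim$atom == i
        fr$nuclei$x[i] <- fr$nuclei$x[i] + dd[1]
        fr$nuclei$y[i] <- fr$nuclei$y[i] + dd[2]
        fr$nuclei$z[i] <- fr$nuclei$z[i] + dd[3]
        fr$prim$x[sel] <- fr$prim$x[sel] + dd[1]
        fr$prim$y[sel] <- fr$prim$y[sel] + dd[2]
        fr$prim$z[sel] <- fr$prim$z[sel] + dd[3]
      }
      fr
    }
    fa <- jit(fa); fb <- jit(fb)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  rhoA <- gaussian_density(fa$nuclei, fa$prim, label = "A")
  rhoB <- gaussian_density(fb$nuclei, fb$prim, label = "B")
  for (i in seq_len(nrow(fa$nuclei))) {
    d <- sqrt((fb$nuclei$x - fa$nuclei$x[i])^2 +
                (fb$nuclei$y - fa$nuclei$y[i])^2 +
                (fb$nuclei$z - fa$nuclei$z[i])^2)
    if (any(d < 0.5)) {
      abort("fragments have overlapping nuclei", class = "iqfpen_geometry_error")
    }
  }
  ca <- c(mean(fa$nuclei$x), mean(fa$nuclei$y), mean(fa$nuclei$z))
  cb <- c(mean(fb$nuclei$x), mean(fb$nuclei$y), mean(fb$nuclei$z))
  axis <- (cb - ca) / sqrt(sum((cb - ca)^2))
  ang <- 1 / iqf_units$bohr_per_angstrom
  geometry <- tibble(
    element = c(fa$nuclei$element, fb$nuclei$element),
    x = c(fa$nuclei$x, fb$nuclei$x) * ang,
    y = c(fa$nuclei$y, fb$nuclei$y) * ang,
    z = c(fa$nuclei$z, fb$nuclei$z) * ang,
    fragment = c(rep("A", nrow(fa$nuclei)), rep("B", nrow(fb$nuclei)))
  )
  list(rhoA = rhoA, rhoB = rhoB, R_eq = sqrt(sum((cb - ca)^2)), axis = axis,
       geometry = geometry, label = spec$label)
}
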