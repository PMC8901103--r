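# Wavefunction-density adapters: wfx and molden files are parsed into a
# common primitive representation (unnormalised Cartesian Gaussians with
# per-MO coefficients), evaluable for density and gradient on arbitrary
# points behind the same interface as the promolecular model.

# Cartesian powers for the supported primitive types (wfx ordering):
# 1 s; 2-4 px py pz; 5-10 dxx dyy dzz dxy dxz dyz.
.prim_powers <- rbind(
  c(0, 0, 0),
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(2, 0, 0), c(0, 2, 0), c(0, 0, 2), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)
)

.z_symbol <- function(z) {
  syms <- names(.element_z)[match(z, .element_z)]
  if (any(is.na(syms))) abort("unsupported atomic number", class = "iqfpen_parse_error")
  syms
}

.wfn_density <- function(nuclei, centers, types, alphas, occ, coef, label) {
  if (any(types < 1 | types > 10)) {
    abort("unsupported primitive type (only s, p and d Cartesian primitives, types 1-10, are supported)",
          class = "iqfpen_parse_error")
  }
  structure(list(
    nuclei = nuclei, centers = centers, types = as.integer(types),
    alphas = alphas, occ = occ, coef = coef, label = label
  ), class = "wfn_density")
}

# Primitive value matrix (n points x n prim) and optionally gradients.
.wfn_prim_values <- function(d, pts, grad = FALSE) {
  n <- nrow(pts)
  np <- length(d$alphas)
  G <- matrix(0, n, np)
  Gx <- if (grad) matrix(0, n, np)
  Gy <- if (grad) matrix(0, n, np)
  Gz <- if (grad) matrix(0, n, np)
  for (p in seq_len(np)) {
    dx <- pts[, 1] - d$centers[p, 1]
    dy <- pts[, 2] - d$centers[p, 2]
    dz <- pts[, 3] - d$centers[p, 3]
    a <- d$alphas[p]
    pw <- .prim_powers[d$types[p], ]
    ex <- exp(-a * (dx * dx + dy * dy + dz * dz))
    poly <- dx^pw[1] * dy^pw[2] * dz^pw[3]
    G[, p] <- poly * ex
    if (grad) {
      dpx <- if (pw[1] > 0) pw[1] * dx^(pw[1] - 1) * dy^pw[2] * dz^pw[3] else 0
      dpy <- if (pw[2] > 0) pw[2] * dx^pw[1] * dy^(pw[2] - 1) * dz^pw[3] else 0
      dpz <- if (pw[3] > 0) pw[3] * dx^pw[1] * dy^pw[2] * dz^(pw[3] - 1) else 0
      Gx[, p] <- (dpx - 2 * a * dx * poly) * ex
      Gy[, p] <- (dpy - 2 * a * dy * poly) * ex
      Gz[, p] <- (dpz - 2 * a * dz * poly) * ex
    }
  }
  if (grad) list(G = G, Gx = Gx, Gy = Gy, Gz = Gz) else list(G = G)
}

#' @export
density_eval.wfn_density <- function(d, points) {
  pts <- .as_points(points)
  pv <- .wfn_prim_values(d, pts)
  phi <- pv$G %*% t(d$coef)          # n x nmo
  as.vector((phi^2) %*% d$occ)
}

#' @export
density_grad.wfn_density <- function(d, points) {
  pts <- .as_points(points)
  pv <- .wfn_prim_values(d, pts, grad = TRUE)
  phi <- pv$G %*% t(d$coef)
  gx <- pv$Gx %*% t(d$coef)
  gy <- pv$Gy %*% t(d$coef)
  gz <- pv$Gz %*% t(d$coef)
  cbind(
    2 * (phi * gx) %*% d$occ,
    2 * (phi * gy) %*% d$occ,
    2 * (phi * gz) %*% d$occ
  )
}

#' @export
nuclei_of.wfn_density <- function(d) d$nuclei

#' @export
electron_count.wfn_density <- function(d) sum(d$occ)

# Extract a <Tag> ... </Tag> block from wfx lines.
.wfx_block <- function(lines, tag, required = TRUE) {
  open <- which(trimws(lines) == paste0("<", tag, ">"))
  close <- which(trimws(lines) == paste0("</", tag, ">"))
  if (length(open) != 1 || length(close) != 1 || close <= open) {
    if (required) {
      abort(paste0("wfx parse error: missing or malformed record <", tag, ">"),
            class = "iqfpen_parse_error")
    }
    return(NULL)
  }
  lines[(open + 1):(close - 1)]
}

.wfx_numbers <- function(block) {
  as.numeric(unlist(strsplit(trimws(paste(block, collapse = " ")), "\\s+")))
}

#' Read a wfx wavefunction file
#'
#' Parses the AIM wfx dialect: nuclei, unnormalised Cartesian primitives
#' (types 1-10: s, p, d) and occupied molecular orbitals with per-primitive
#' coefficients. The resulting object supports [density_eval()],
#' [density_grad()], [nuclei_of()] and [electron_count()] like any other
#' density, so it can drive grids, basins and Coulomb machinery directly.
#'
#' @param file Path to the wfx file.
#' @return An object of class `wfn_density`.
#' @export
read_wfx <- function(file) {
  lines <- readLines(file, warn = FALSE)
  nnuc <- as.integer(.wfx_numbers(.wfx_block(lines, "Number of Nuclei")))
  nprim <- as.integer(.wfx_numbers(.wfx_block(lines, "Number of Primitives")))
  nmo <- as.integer(.wfx_numbers(.wfx_block(lines, "Number of Occupied Molecular Orbitals")))
  if (any(is.na(c(nnuc, nprim, nmo)))) {
    abort("wfx parse error: malformed count record", class = "iqfpen_parse_error")
  }
  z <- as.integer(.wfx_numbers(.wfx_block(lines, "Atomic Numbers")))
  xyz <- .wfx_numbers(.wfx_block(lines, "Nuclear Cartesian Coordinates"))
  if (length(z) != nnuc || length(xyz) != 3 * nnuc) {
    abort("wfx parse error: nuclear records inconsistent with <Number of Nuclei>",
          class = "iqfpen_parse_error")
  }
  R <- matrix(xyz, ncol = 3, byrow = TRUE)
  nuc <- tibble(element = .z_symbol(z), Z = as.numeric(z),
                x = R[, 1], y = R[, 2], z = R[, 3])
  cent_idx <- as.integer(.wfx_numbers(.wfx_block(lines, "Primitive Centers")))
  types <- as.integer(.wfx_numbers(.wfx_block(lines, "Primitive Types")))
  alphas <- .wfx_numbers(.wfx_block(lines, "Primitive Exponents"))
  if (length(cent_idx) != nprim || length(types) != nprim || length(alphas) != nprim) {
    abort("wfx parse error: primitive records inconsistent with <Number of Primitives>",
          class = "iqfpen_parse_error")
  }
  occ <- .wfx_numbers(.wfx_block(lines, "Molecular Orbital Occupation Numbers"))
  coef_block <- .wfx_block(lines, "Molecular Orbital Primitive Coefficients")
  # drop <MO Number> ... </MO Number> groups (markers plus the index line)
  in_marker <- FALSE
  keep <- logical(length(coef_block))
  for (k in seq_along(coef_block)) {
    t1 <- trimws(coef_block[k])
    if (t1 == "<MO Number>") { in_marker <- TRUE; next }
    if (t1 == "</MO Number>") { in_marker <- FALSE; next }
    keep[k] <- !in_marker
  }
  cvals <- .wfx_numbers(coef_block[keep])
  if (length(cvals) != nmo * nprim) {
    abort("wfx parse error: <Molecular Orbital Primitive Coefficients> length mismatch",
          class = "iqfpen_parse_error")
  }
  coef <- matrix(cvals, nrow = nmo, byrow = TRUE)
  .wfn_density(nuc, R[cent_idx, , drop = FALSE], types, alphas, occ, coef,
               label = basename(file))
}

#' Read a molden wavefunction file
#'
#' Supports the common molden dialect with `[Atoms]` (Angs or AU), `[GTO]`
#' with s and p contracted shells (coefficients referring to normalised
#' primitives; contracted functions are renormalised), and `[MO]` blocks with
#' occupations. Higher shells raise an explicit parse error.
#'
#' @param file Path to the molden file.
#' @return An object of class `wfn_density`.
#' @export
read_molden <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lt <- tolower(trimws(lines))
  sec <- function(name) {
    i <- grep(paste0("^\\[", name, "\\]"), lt)
    if (length(i) != 1) {
      abort(paste0("molden parse error: missing section [", name, "]"),
            class = "iqfpen_parse_error")
    }
    i
  }
  ia <- sec("atoms")
  unit <- if (grepl("angs", lt[ia])) "angs" else "au"
  ends <- grep("^\\[", lt)
  nxt <- function(i) { j <- ends[ends > i]; if (length(j) == 0) length(lines) + 1L else min(j) }

  atom_lines <- lines[(ia + 1):(nxt(ia) - 1)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  at <- strsplit(trimws(atom_lines), "\\s+")
  b <- if (unit == "angs") iqf_units$bohr_per_angstrom else 1
  nuc <- tibble(
    element = vapply(at, `[[`, character(1), 1),
    Z = as.numeric(vapply(at, `[[`, character(1), 3)),
    x = as.numeric(vapply(at, `[[`, character(1), 4)) * b,
    y = as.numeric(vapply(at, `[[`, character(1), 5)) * b,
    z = as.numeric(vapply(at, `[[`, character(1), 6)) * b
  )

  ig <- sec("gto")
  gto_lines <- lines[(ig + 1):(nxt(ig) - 1)]
  shells <- list()  # per shell: atom, type, exps, coefs
  i <- 1
  cur_atom <- NA_integer_
  while (i <= length(gto_lines)) {
    ln <- trimws(gto_lines[i])
    if (!nzchar(ln)) { i <- i + 1; next }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) <= 2 && !is.na(suppressWarnings(as.integer(tok[1])))) {
      cur_atom <- as.integer(tok[1]); i <- i + 1; next
    }
    stype <- tolower(tok[1])
    if (!stype %in% c("s", "p")) {
      abort(paste0("molden parse error: unsupported shell type '", stype,
                   "' in [GTO] (only s and p shells are supported)"),
            class = "iqfpen_parse_error")
    }
    nprim <- as.integer(tok[2])
    ex <- numeric(nprim); cf <- numeric(nprim)
    for (k in seq_len(nprim)) {
      pt <- strsplit(gsub("[dD]", "e", trimws(gto_lines[i + k])), "\\s+")[[1]]
      ex[k] <- as.numeric(pt[1]); cf[k] <- as.numeric(pt[2])
    }
    shells[[length(shells) + 1L]] <- list(atom = cur_atom, type = stype,
                                          exps = ex, coefs = cf)
    i <- i + nprim + 1
  }
  if (length(shells) == 0) {
    abort("molden parse error: empty [GTO] section", class = "iqfpen_parse_error")
  }

  # expand contracted, renormalised AOs into unnormalised-primitive columns
  centers <- NULL; types <- integer(0); alphas <- numeric(0)
  ao_prim <- list()  # per AO: index range into primitive list + coefficients
  add_ao <- function(atom, type_id, exps, coefs) {
    R <- as.numeric(nuc[atom, c("x", "y", "z")])
    idx <- length(alphas) + seq_along(exps)
    centers <<- rbind(centers, matrix(R, length(exps), 3, byrow = TRUE))
    types <<- c(types, rep(type_id, length(exps)))
    alphas <<- c(alphas, exps)
    ao_prim[[length(ao_prim) + 1L]] <<- list(idx = idx, c = coefs)
  }
  for (sh in shells) {
    a <- sh$exps; c0 <- sh$coefs
    if (sh$type == "s") {
      Np <- (2 * a / pi)^0.75
      cc <- c0 * Np
      S <- outer(a, a, function(ai, aj) (pi / (ai + aj))^1.5)
      nrm <- sqrt(as.numeric(t(cc) %*% S %*% cc))
      add_ao(sh$atom, 1L, a, cc / nrm)
    } else {
      Np <- (2 * a / pi)^0.75 * 2 * sqrt(a)
      cc <- c0 * Np
      S <- outer(a, a, function(ai, aj) (pi / (ai + aj))^1.5 / (2 * (ai + aj)))
      nrm <- sqrt(as.numeric(t(cc) %*% S %*% cc))
      for (tp in 2:4) add_ao(sh$atom, tp, a, cc / nrm)
    }
  }
  nao <- length(ao_prim)

  im <- sec("mo")
  mo_lines <- lines[(im + 1):length(lines)]
  occ <- numeric(0)
  coef_rows <- list()
  cur <- NULL; cur_occ <- 0
  flush_mo <- function() {
    if (!is.null(cur)) {
      occ <<- c(occ, cur_occ)
      coef_rows[[length(coef_rows) + 1L]] <<- cur
    }
  }
  for (ln in mo_lines) {
    t1 <- trimws(ln)
    if (!nzchar(t1)) next
    if (grepl("^(Sym|Ene|Spin)\\s*=", t1, ignore.case = TRUE)) {
      if (grepl("^Sym", t1, ignore.case = TRUE)) { flush_mo(); cur <- numeric(nao); cur_occ <- 0 }
      next
    }
    if (grepl("^Occup\\s*=", t1, ignore.case = TRUE)) {
      if (is.null(cur)) cur <- numeric(nao)
      cur_occ <- as.numeric(sub("^Occup\\s*=\\s*", "", t1, ignore.case = TRUE))
      next
    }
    tok <- strsplit(t1, "\\s+")[[1]]
    if (length(tok) == 2) {
      if (is.null(cur)) cur <- numeric(nao)
      cur[as.integer(tok[1])] <- as.numeric(tok[2])
    }
  }
  flush_mo()
  if (length(occ) == 0) {
    abort("molden parse error: no molecular orbitals in [MO]", class = "iqfpen_parse_error")
  }
  keep <- occ > 1e-12
  occ <- occ[keep]
  coef_rows <- coef_rows[keep]
  nmo <- length(occ)
  coef <- matrix(0, nmo, length(alphas))
  for (k in seq_len(nmo)) {
    for (a in seq_len(nao)) {
      ap <- ao_prim[[a]]
      coef[k, ap$idx] <- coef[k, ap$idx] + coef_rows[[k]][a] * ap$c
    }
  }
  .wfn_density(nuc, centers, types, alphas, occ, coef, label = basename(file))
}
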