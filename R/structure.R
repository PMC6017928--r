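# Per-element van der Waals radii (angstrom). A compact, documented set
# close to the values protein-structure viewers use; unknown elements fall
# back to 1.8 A with a warning.
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98,
  Se = 1.90, Fe = 1.40, Zn = 1.39, Mg = 1.73, Ca = 1.74, Mn = 1.40
)

#' Van der Waals radius lookup
#'
#' @param element Character vector of element symbols.
#' @return Radii in angstrom; unknown elements get 1.8 A with a warning.
#' @export
vdw_radius <- function(element) {
  el <- gsub("\\s", "", element)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
  r <- unname(VDW_RADII[el])
  if (anyNA(r)) {
    warn(paste0("Unknown element(s) ", paste(unique(el[is.na(r)]), collapse = ", "),
                "; using 1.8 A."))
    r[is.na(r)] <- 1.8
  }
  r
}

#' Read a protein structure into an atom table
#'
#' Thin wrapper over bio3d's PDB/mmCIF readers returning a tidy atom
#' tibble. The first model is used; for alternate locations the
#' highest-occupancy copy of each atom is kept; waters and hetero atoms
#' are excluded by default; hydrogens are excluded by default (the crystal
#' structures this is aimed at lack them).
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param include_hetero Keep non-water HETATM records?
#' @param include_hydrogens Keep hydrogen atoms?
#' @return A tibble with columns `element`, `chain`, `resno`, `resid`,
#'   `atom_name`, `x`, `y`, `z`, `radius`.
#' @export
read_structure <- function(path, include_hetero = FALSE,
                           include_hydrogens = FALSE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("Package bio3d is required to read structure files.")
  }
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path) else
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE))
  at <- as_tibble(pdb$atom)
  if (nrow(at) == 0) abort("No atom records in file.")
  if (!include_hetero) {
    at <- at[at$type == "ATOM", , drop = FALSE]
  } else {
    at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  }
  if (nrow(at) == 0) abort("No usable ATOM records after filtering.")
  # altloc: keep the highest-occupancy copy of each atom position
  at$o[is.na(at$o)] <- 1
  at <- at |>
    dplyr::arrange(dplyr::desc(.data$o)) |>
    dplyr::distinct(.data$chain, .data$resno, .data$insert, .data$elety,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$chain, .data$resno)
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == "")) {
    el <- substr(gsub("[0-9']", "", at$elety), 1, 1)  # fall back to atom name
  }
  out <- tibble(
    element = el, chain = at$chain, resno = at$resno, resid = at$resid,
    atom_name = at$elety, x = at$x, y = at$y, z = at$z
  )
  if (!include_hydrogens) out <- out[!(out$element %in% c("H", "D")), ]
  if (nrow(out) == 0) abort("No atoms left after hydrogen filtering.")
  if (!all(is.finite(out$x + out$y + out$z))) abort("Non-finite coordinates.")
  out$radius <- vdw_radius(out$element)
  out
}

# Deterministic quasi-uniform point set on the unit sphere (Fibonacci /
# golden-spiral lattice). No RNG, so areas are bit-stable across runs.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

check_atoms <- function(atoms) {
  atoms <- as_tibble(atoms)
  req <- c("x", "y", "z", "radius")
  if (!all(req %in% names(atoms))) {
    abort("Atom table needs columns x, y, z, radius.")
  }
  if (nrow(atoms) == 0) abort("Atom table is empty.")
  if (any(atoms$radius <= 0)) abort("All radii must be positive.")
  if (!all(is.finite(as.matrix(atoms[req])))) abort("Non-finite atom data.")
  atoms
}

# neighbour list under expanded radii: j is a neighbour of i when
# d(i,j) < R_i + R_j, with R = r + probe. Chunked O(N^2), no RNG.
expanded_neighbours <- function(xyz, R) {
  n <- nrow(xyz)
  out <- vector("list", n)
  chunk <- 512L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    idx <- s:e
    d2 <- outer(rowSums(xyz[idx, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[idx, , drop = FALSE] %*% t(xyz)
    lim <- outer(R[idx], R, "+")^2
    hit <- d2 < lim
    for (k in seq_along(idx)) {
      nb <- which(hit[k, ])
      out[[idx[k]]] <- nb[nb != idx[k]]
    }
  }
  out
}

#' Solvent-accessible surface area (Lee-Richards/Shrake-Rupley style)
#'
#' Computes per-atom accessible surface area by deterministic sampling: a
#' Fibonacci lattice of `n_points` test points is placed on each atom's
#' probe-expanded sphere (radius + probe) and points falling inside any
#' neighbour's expanded sphere are occluded. Each surviving point
#' contributes `4 pi R^2 / n_points`.
#'
#' @param atoms Atom tibble with columns `x`, `y`, `z`, `radius` (e.g. from
#'   [read_structure()] or [gen_toy_dimer()]).
#' @param probe Probe (solvent) radius, angstrom; 1.4 for water.
#' @param n_points Sample points per atom.
#' @return The atom tibble with an `asa` column (A^2) appended; the total
#'   area is `sum(result$asa)` and is also stored in attribute `"total"`.
#' @export
#' @examples
#' a <- tibble::tibble(x = 0, y = 0, z = 0, radius = 1.7)
#' sum(sasa(a)$asa)              # ~ 4*pi*(1.7+1.4)^2
sasa <- function(atoms, probe = 1.4, n_points = 960L) {
  atoms <- check_atoms(atoms)
  if (probe <= 0) abort("`probe` must be positive.")
  n_points <- as.integer(n_points)
  if (n_points < 1L) abort("`n_points` must be positive.")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  R <- atoms$radius + probe
  nb <- expanded_neighbours(xyz, R)
  pts0 <- fibonacci_sphere(n_points)
  area <- numeric(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    Ri <- R[i]
    js <- nb[[i]]
    if (length(js) == 0) {
      area[i] <- 4 * pi * Ri^2
      next
    }
    pts <- pts0 * Ri
    pts[, 1] <- pts[, 1] + xyz[i, 1]
    pts[, 2] <- pts[, 2] + xyz[i, 2]
    pts[, 3] <- pts[, 3] + xyz[i, 3]
    free <- rep(TRUE, n_points)
    for (j in js) {
      dx <- pts[, 1] - xyz[j, 1]
      dy <- pts[, 2] - xyz[j, 2]
      dz <- pts[, 3] - xyz[j, 3]
      free <- free & (dx * dx + dy * dy + dz * dz >= R[j]^2)
      if (!any(free)) break
    }
    area[i] <- 4 * pi * Ri^2 * sum(free) / n_points
  }
  atoms$asa <- area
  attr(atoms, "total") <- sum(area)
  atoms
}

#' Buried area from the three surface areas
#'
#' The interface area buried on dimerisation, from the monomer and complex
#' accessible areas: `(asa_A + asa_B - asa_AB) / 2`.
#'
#' @param asa_A,asa_B,asa_AB Accessible surface areas (A^2) of chain A
#'   alone, chain B alone, and the AB complex.
#' @return Buried area in A^2.
#' @export
#' @examples
#' buried_area(13200, 13200, 17200)
buried_area <- function(asa_A, asa_B, asa_AB) {
  (asa_A + asa_B - asa_AB) / 2
}

#' @rdname buried_area
#' @param buried Buried area, A^2.
#' @param asa Monomer accessible area, A^2.
#' @return `buried_fraction()`: the buried percentage, 100 * buried / asa.
#' @export
buried_fraction <- function(buried, asa) 100 * buried / asa

#' Buried dimer-interface report
#'
#' Computes the accessible surface area of chain A alone, chain B alone
#' and the AB complex, then the buried interface area
#' `(ASA_A + ASA_B - ASA_AB) / 2` and the percentage of the chain-A
#' monomer surface it represents.
#'
#' @param atoms Atom tibble with a `chain` column.
#' @param chain_a,chain_b Chain identifiers.
#' @inheritParams sasa
#' @return A one-row tibble: `asa_A`, `asa_B`, `asa_AB`, `buried`,
#'   `buried_fraction_A` (%), `probe`, `n_points`.
#' @export
buried_interface <- function(atoms, chain_a = "A", chain_b = "B",
                             probe = 1.4, n_points = 960L) {
  atoms <- check_atoms(atoms)
  if (!"chain" %in% names(atoms)) abort("Atom table needs a chain column.")
  A <- atoms[atoms$chain == chain_a, ]
  B <- atoms[atoms$chain == chain_b, ]
  if (nrow(A) == 0) abort(paste0("Chain ", chain_a, " not present."))
  if (nrow(B) == 0) abort(paste0("Chain ", chain_b, " not present."))
  asa_A <- sum(sasa(A, probe, n_points)$asa)
  asa_B <- sum(sasa(B, probe, n_points)$asa)
  asa_AB <- sum(sasa(dplyr::bind_rows(A, B), probe, n_points)$asa)
  b <- buried_area(asa_A, asa_B, asa_AB)
  tibble(asa_A = asa_A, asa_B = asa_B, asa_AB = asa_AB, buried = b,
         buried_fraction_A = buried_fraction(b, asa_A),
         probe = probe, n_points = as.integer(n_points))
}

#' CPK molecular volume by grid integration
#'
#' Volume of the union of van der Waals spheres, integrated on a
#' deterministic cubic grid over the bounding box: each grid cell whose
#' centre lies inside at least one sphere contributes `spacing^3`.
#'
#' @param atoms Atom tibble with `x`, `y`, `z`, `radius`.
#' @param spacing Grid spacing in angstrom; 0.2 gives ~1% accuracy for
#'   small molecules.
#' @return Volume in A^3.
#' @export
#' @examples
#' cpk_volume(tibble::tibble(x = 0, y = 0, z = 0, radius = 1.7))
cpk_volume <- function(atoms, spacing = 0.2) {
  atoms <- check_atoms(atoms)
  if (spacing <= 0) abort("`spacing` must be positive.")
  rmax <- max(atoms$radius)
  gx <- seq(min(atoms$x) - rmax, max(atoms$x) + rmax, by = spacing)
  gy <- seq(min(atoms$y) - rmax, max(atoms$y) + rmax, by = spacing)
  gz <- seq(min(atoms$z) - rmax, max(atoms$z) + rmax, by = spacing)
  inside <- array(FALSE, dim = c(length(gx), length(gy), length(gz)))
  for (i in seq_len(nrow(atoms))) {
    r <- atoms$radius[i]
    ix <- which(abs(gx - atoms$x[i]) <= r)
    iy <- which(abs(gy - atoms$y[i]) <= r)
    iz <- which(abs(gz - atoms$z[i]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - atoms$x[i])^2
    dy2 <- (gy[iy] - atoms$y[i])^2
    dz2 <- (gz[iz] - atoms$z[i])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    inside[ix, iy, iz] <- inside[ix, iy, iz] | (d2 <= r^2)
  }
  sum(inside) * spacing^3
}

#' Write an atom table as a minimal PDB file
#'
#' Serialises a toy or derived atom set as standard fixed-width ATOM
#' records so external tools can read it. One model, occupancy 1, B 0.
#'
#' @param atoms Atom tibble (columns `element`, `chain`, `x`, `y`, `z`;
#'   `resno`, `resid`, `atom_name` optional).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  atoms <- as_tibble(atoms)
  n <- nrow(atoms)
  pick <- function(col, default) {
    if (col %in% names(atoms)) atoms[[col]] else default
  }
  resno <- pick("resno", seq_len(n))
  resid <- pick("resid", rep("UNK", n))
  name <- pick("atom_name", atoms$element)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n), substr(name, 1, 4), substr(resid, 1, 3), atoms$chain,
    resno, atoms$x, atoms$y, atoms$z, 1, 0, atoms$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
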