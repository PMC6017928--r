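#' Reference redox couple for the isodesmic thermodynamic cycle
#'
#' Relative reduction potentials are computed against a reference
#' nitroaromatic whose experimental one-electron reduction potential is
#' known. The default is nitrobenzene, E°' = -0.486 V vs NHE at pH 7.
#'
#' @param compound_id Identifier of the reference compound in the energy
#'   table.
#' @param E0_ref Experimental reduction potential of the reference couple,
#'   in V vs NHE.
#' @param n_electrons Number of electrons transferred (1 for the
#'   nitroaromatic/radical-anion couple).
#' @return A list of class `reference_couple`.
#' @export
#' @examples
#' reference_couple()
reference_couple <- function(compound_id = "nitrobenzene",
                             E0_ref = -0.486,
                             n_electrons = 1L) {
  stopifnot(is.character(compound_id), length(compound_id) == 1)
  if (!is.finite(E0_ref)) abort("`E0_ref` must be finite.")
  n_electrons <- as.integer(n_electrons)
  if (n_electrons < 1L) abort("`n_electrons` must be >= 1.")
  structure(
    list(compound_id = compound_id, E0_ref = E0_ref,
         n_electrons = n_electrons),
    class = "reference_couple"
  )
}

#' @export
print.reference_couple <- function(x, ...) {
  cat("<reference_couple> ", x$compound_id,
      sprintf(": E0 = %.3f V vs NHE, n = %d\n", x$E0_ref, x$n_electrons))
  invisible(x)
}

# Accept a few spellings for the redox state column and normalise to
# "oxidized" / "reduced_anion".
normalise_state <- function(state) {
  s <- tolower(as.character(state))
  out <- dplyr::case_when(
    s %in% c("oxidized", "oxidised", "ox") ~ "oxidized",
    s %in% c("reduced_anion", "reduced", "red", "anion") ~ "reduced_anion",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) {
    bad <- unique(s[is.na(out)])
    abort(paste0("Unknown redox state(s): ", paste(bad, collapse = ", "),
                 ". Use 'oxidized'/'ox' or 'reduced_anion'/'red'."))
  }
  out
}

# Pull G for one (compound, state); several conformer rows may be supplied,
# in which case the lowest-energy one is retained.
lookup_G <- function(energies, compound_id, state) {
  rows <- energies[energies$compound_id == compound_id &
                     energies$state == state, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(sprintf("No free-energy record for (%s, %s).", compound_id, state))
  }
  min(rows$G_hartree)
}

#' Free energy of the isodesmic electron-exchange reaction
#'
#' Computes the free-energy change of the electron-transfer reaction
#' ArNO2 + Ref^-. -> ArNO2^-. + Ref from the four species free energies:
#' dG = G(reduced, compound) + G(oxidized, reference)
#'    - G(oxidized, compound) - G(reduced, reference).
#' Because the reaction is isodesmic, systematic errors in the electronic
#' structure method largely cancel.
#'
#' If several records share a (compound, state) pair they are taken to be
#' alternative conformers and the lowest-energy one is retained.
#'
#' @param energies Data frame with columns `compound_id`, `state`
#'   (`"oxidized"`/`"ox"` or `"reduced_anion"`/`"red"`) and `G_hartree`.
#' @param compound_id Compound whose reduction is being computed.
#' @param reference A [reference_couple()].
#' @return Reaction free energy in hartree (length-1 numeric).
#' @export
#' @examples
#' en <- tibble::tribble(
#'   ~compound_id, ~state, ~G_hartree,
#'   "ArNO2", "ox",  -436.000,
#'   "ArNO2", "red", -436.100,
#'   "nitrobenzene", "ox",  -436.500,
#'   "nitrobenzene", "red", -436.580
#' )
#' reaction_free_energy(en, "ArNO2")  # -0.020 hartree
reaction_free_energy <- function(energies, compound_id,
                                 reference = reference_couple()) {
  energies <- as_tibble(energies)
  req <- c("compound_id", "state", "G_hartree")
  if (!all(req %in% names(energies))) {
    abort("`energies` needs columns compound_id, state, G_hartree.")
  }
  if (!all(is.finite(energies$G_hartree))) {
    abort("All free energies must be finite.")
  }
  energies$state <- normalise_state(energies$state)
  g_red_c <- lookup_G(energies, compound_id, "reduced_anion")
  g_ox_c <- lookup_G(energies, compound_id, "oxidized")
  g_red_r <- lookup_G(energies, reference$compound_id, "reduced_anion")
  g_ox_r <- lookup_G(energies, reference$compound_id, "oxidized")
  (g_red_c + g_ox_r) - (g_ox_c + g_red_r)
}

#' Convert an exchange free energy to a reduction potential
#'
#' Applies E° = -dG°/nF to the isodesmic exchange reaction and anchors the
#' result to the reference couple: for a one-electron couple, a free-energy
#' difference expressed in eV per electron is numerically a potential in
#' volts (the Faraday constant cancels), so
#' `E_comp = -dG * 27.2114 + E0_ref` with `dG` in hartree.
#'
#' @param dG Reaction free energy (hartree); vectorised.
#' @param reference A [reference_couple()]; must be one-electron.
#' @return Computed potential(s) in V on the raw computed scale.
#' @export
#' @examples
#' potential_from_dg(0)        # -0.486 V: the reference itself
#' potential_from_dg(-0.020)   # +0.0582 V
potential_from_dg <- function(dG, reference = reference_couple()) {
  if (!all(is.finite(dG))) abort("`dG` must be finite.")
  if (reference$n_electrons != 1L) {
    abort("The thermodynamic cycle is defined for a one-electron couple.")
  }
  -dG * HARTREE_EV + reference$E0_ref
}

#' Computed potentials for every compound in an energy table
#'
#' Convenience wrapper running [reaction_free_energy()] and
#' [potential_from_dg()] for each non-reference compound with both redox
#' states present.
#'
#' @inheritParams reaction_free_energy
#' @return A tibble with columns `compound_id`, `dG_hartree`, `E_comp`.
#' @export
compute_potentials <- function(energies, reference = reference_couple()) {
  energies <- as_tibble(energies)
  energies$state <- normalise_state(energies$state)
  ids <- setdiff(unique(energies$compound_id), reference$compound_id)
  purrr::map_dfr(ids, function(id) {
    dg <- reaction_free_energy(energies, id, reference)
    tibble(compound_id = id, dG_hartree = dg,
           E_comp = potential_from_dg(dg, reference))
  })
}

#' Fit the empirical computed-to-experimental potential calibration
#'
#' Gas-phase computed potentials are mapped onto the aqueous experimental
#' scale by a linear calibration in the form `Comp = slope * (Exp + offset)`,
#' fitted by ordinary least squares of `E_comp` on `E_exp` and
#' re-parameterised (`offset = intercept / slope`). The inverse map
#' `Calc = Comp / slope - offset` gives calibrated potentials; `mad_after`
#' is the mean absolute deviation of those calibrated values from
#' experiment, on the volt scale.
#'
#' @param pairs Data frame with columns `E_exp` and `E_comp` (V).
#' @return An object of class `redox_calibration` with fields `slope`,
#'   `offset`, `r_squared`, `mad_after`, `n_points` and the underlying `lm`
#'   fit.
#' @seealso [apply_calibration()], [calibration_model()]
#' @export
#' @examples
#' pr <- gen_calibration_pairs(n = 12, noise = 0, seed = 1)
#' fit_calibration(pr)
fit_calibration <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (!all(c("E_exp", "E_comp") %in% names(pairs))) {
    abort("`pairs` needs columns E_exp and E_comp.")
  }
  pairs <- tidyr::drop_na(pairs, "E_exp", "E_comp")
  if (nrow(pairs) < 2) abort("Need at least 2 calibration pairs.")
  if (stats::var(pairs$E_exp) <= .Machine$double.eps) {
    abort("Degenerate calibration set: all E_exp are equal.")
  }
  fit <- lm(E_comp ~ E_exp, data = pairs)
  s <- unname(coef(fit)[2])
  b <- unname(coef(fit)[1]) / s
  r2 <- suppressWarnings(summary(fit)$r.squared)
  mad_after <- mean(abs(pairs$E_comp / s - b - pairs$E_exp))
  structure(
    list(slope = s, offset = b, r_squared = r2, mad_after = mad_after,
         n_points = nrow(pairs), fit = fit, data = pairs),
    class = "redox_calibration"
  )
}

#' Build a calibration model directly from known constants
#'
#' @param slope,offset Constants of the map `Comp = slope * (Exp + offset)`.
#' @return A `redox_calibration` with no fit diagnostics.
#' @export
#' @examples
#' calibration_model(4.67, 0.379)
calibration_model <- function(slope, offset) {
  if (!is.finite(slope) || slope == 0) abort("`slope` must be finite and nonzero.")
  structure(
    list(slope = slope, offset = offset, r_squared = NA_real_,
         mad_after = NA_real_, n_points = 0L, fit = NULL, data = NULL),
    class = "redox_calibration"
  )
}

#' Apply the inverse calibration map to computed potentials
#'
#' `E_cal = E_comp / slope - offset`. Given a data frame with an `E_comp`
#' column, returns it with an `E_cal` column appended; given a numeric
#' vector, returns a numeric vector.
#'
#' @param E_comp Numeric vector of computed potentials (V), or a data frame
#'   containing an `E_comp` column.
#' @param model A `redox_calibration`.
#' @return Calibrated potential(s) in V (vector, or augmented tibble).
#' @export
#' @examples
#' apply_calibration(-0.4997, calibration_model(4.67, 0.379))  # -0.486 V
apply_calibration <- function(E_comp, model) {
  if (!inherits(model, "redox_calibration")) {
    abort("`model` must be a redox_calibration.")
  }
  if (model$slope == 0) abort("Calibration slope must be nonzero.")
  if (is.data.frame(E_comp)) {
    E_comp <- as_tibble(E_comp)
    if (!"E_comp" %in% names(E_comp)) abort("Data frame lacks an E_comp column.")
    E_comp$E_cal <- E_comp$E_comp / model$slope - model$offset
    return(E_comp)
  }
  E_comp / model$slope - model$offset
}

#' @export
print.redox_calibration <- function(x, ...) {
  cat("<redox_calibration>  Comp = slope * (Exp + offset)\n")
  cat(sprintf("  slope: %.4g   offset: %.4g V\n", x$slope, x$offset))
  if (x$n_points > 0) {
    cat(sprintf("  n = %d, R^2 = %.4f, MAD after calibration = %.4f V\n",
                x$n_points, x$r_squared, x$mad_after))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.redox_calibration <- function(x, ...) {
  tibble(term = c("slope", "offset"),
         estimate = c(x$slope, x$offset))
}

#' @exportS3Method generics::glance
glance.redox_calibration <- function(x, ...) {
  tibble(r.squared = x$r_squared, mad_after = x$mad_after,
         nobs = x$n_points)
}

#' @exportS3Method ggplot2::autoplot
autoplot.redox_calibration <- function(object, ...) {
  if (is.null(object$data)) abort("No data stored in this calibration model.")
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$E_exp, y = .data$E_comp)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$slope * object$offset,
                         linetype = 2) +
    ggplot2::labs(x = "Experimental E° (V vs NHE)",
                  y = "Computed potential (V, raw scale)",
                  title = "Computed-vs-experimental potential calibration")
}

#' Assemble a tidy compound-property table
#'
#' Collects per-compound descriptors (calibrated potential, pi-system size,
#' CPK volume, logP, amine outcome) into one tibble keyed by compound, the
#' layout used to explore which substrates yield full reduction to the
#' amine. Missing descriptors become explicit `NA`s.
#'
#' The pi-system size convention is the count of atoms bearing conjugated
#' p-orbitals: aromatic ring atoms plus directly conjugated substituent
#' atoms (nitro N and O, carbonyl C and O, ...). Nitrobenzene counts 6 ring
#' atoms + 3 nitro atoms = 9 under this rule; users may supply any
#' consistent convention.
#'
#' @param compounds Data frame with column `compound_id` and any of `name`,
#'   `sigma_para`, `pi_system_size`, `volume`, `logP`, `E0_c`,
#'   `amine_observed` (`"yes"`, `"no"` or `"unknown"`).
#' @return A tibble with one row per compound and the full column set.
#' @export
assemble_compound_table <- function(compounds) {
  cols <- c("compound_id", "name", "sigma_para", "pi_system_size",
            "volume", "logP", "E0_c", "amine_observed")
  template <- tibble(
    compound_id = character(), name = character(), sigma_para = numeric(),
    pi_system_size = numeric(), volume = numeric(), logP = numeric(),
    E0_c = numeric(), amine_observed = character()
  )
  if (is.null(compounds) || nrow(as_tibble(compounds)) == 0) return(template)
  compounds <- as_tibble(compounds)
  if (!"compound_id" %in% names(compounds)) {
    abort("`compounds` needs a compound_id column.")
  }
  if (anyDuplicated(compounds$compound_id)) {
    dup <- unique(compounds$compound_id[duplicated(compounds$compound_id)])
    abort(paste0("Duplicate compound_id: ", paste(dup, collapse = ", ")))
  }
  if ("amine_observed" %in% names(compounds)) {
    ok <- compounds$amine_observed %in% c("yes", "no", "unknown", NA)
    if (!all(ok)) abort("amine_observed must be yes/no/unknown.")
  }
  if ("volume" %in% names(compounds) &&
      any(compounds$volume <= 0, na.rm = TRUE)) {
    abort("CPK volumes must be positive where given.")
  }
  out <- dplyr::bind_rows(template, compounds[intersect(cols, names(compounds))])
  out[cols]
}

#' Scatter of amine outcome in potential / pi-system space
#'
#' @param compounds Output of [assemble_compound_table()].
#' @return A ggplot object.
#' @export
plot_compound_space <- function(compounds) {
  ggplot2::ggplot(compounds,
                  ggplot2::aes(x = .data$pi_system_size, y = .data$E0_c,
                               colour = .data$amine_observed)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "Size of the conjugated π system (atoms)",
                  y = "Calibrated E°c (V vs NHE)",
                  colour = "Amine formed")
}
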