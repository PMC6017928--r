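# Seeded synthetic datasets with the statistical structure each analysis
# stage assumes. Every generator is a pure function of its arguments:
# withr::with_seed gives each one an independent RNG stream and leaves the
# caller's RNG state untouched, so a fixed seed is byte-reproducible.

#' Synthetic computed-vs-experimental calibration pairs
#'
#' Experimental potentials drawn uniformly on `exp_range`; computed values
#' follow the linear map `E_comp = slope * (E_exp + offset)` with additive
#' Gaussian scatter. The default slope/offset (4.67, 0.379 V) and noise
#' (0.02 V) mirror the scale of a gas-phase small-basis computation
#' calibrated against aqueous measurements.
#'
#' @param n Number of pairs.
#' @param slope,offset Generating calibration constants.
#' @param noise Gaussian s.d. on `E_comp`, V.
#' @param exp_range Range of experimental potentials, V.
#' @param seed Integer seed.
#' @return A tibble with columns `E_exp`, `E_comp`.
#' @export
gen_calibration_pairs <- function(n = 12, slope = 4.67, offset = 0.379,
                                  noise = 0.02, exp_range = c(-0.6, -0.2),
                                  seed = 1) {
  if (n < 1) abort("`n` must be >= 1.")
  if (slope == 0) abort("`slope` must be nonzero.")
  withr::with_seed(seed, {
    E_exp <- runif(n, exp_range[1], exp_range[2])
    tibble(E_exp = E_exp,
           E_comp = slope * (E_exp + offset) + rnorm(n, 0, noise))
  })
}

#' Synthetic Michaelis-Menten initial-rate data
#'
#' Velocities follow v = kcat E0 S / (KM + S) with mean-one multiplicative
#' lognormal noise (rates are strictly positive). The default substrate
#' grid is 8 log-spaced concentrations over 0.013-0.5 mM, the working
#' range of an NADH co-substrate assay.
#'
#' @param kcat Turnover number, s^-1.
#' @param KM Michaelis constant, M.
#' @param E0 Enzyme concentration, M.
#' @param S_grid Substrate concentrations, M.
#' @param noise Relative noise (sdlog of the lognormal factor).
#' @param seed Integer seed.
#' @return A tibble with columns `substrate_conc`, `velocity`,
#'   `enzyme_conc`.
#' @export
gen_mm_rates <- function(kcat = 10, KM = 1e-4, E0 = 1e-7,
                         S_grid = NULL, noise = 0.05, seed = 1) {
  if (is.null(S_grid)) {
    S_grid <- exp(seq(log(1.3e-5), log(5e-4), length.out = 8))
  }
  if (length(S_grid) == 0 || all(S_grid == 0)) {
    abort("`S_grid` must contain nonzero concentrations.")
  }
  if (kcat <= 0 || KM <= 0 || E0 <= 0) abort("Parameters must be positive.")
  withr::with_seed(seed, {
    v <- kcat * E0 * S_grid / (KM + S_grid)
    if (noise > 0) {
      v <- v * stats::rlnorm(length(S_grid), meanlog = -noise^2 / 2,
                             sdlog = noise)
    }
    tibble(substrate_conc = S_grid, velocity = v, enzyme_conc = E0)
  })
}

#' Synthetic Hammett substituent series
#'
#' Rates follow the linear free-energy relationship
#' Yi = Y0 * 10^(rho * sigma_i), with mean-one multiplicative lognormal
#' noise. The parent compound (sigma = 0) is always included.
#'
#' @param rho Generating reaction constant.
#' @param sigma Substituent constants; a parent 0 is appended if missing.
#' @param Y0 Parent rate quantity.
#' @param noise Relative noise (sdlog).
#' @param seed Integer seed.
#' @return A tibble with columns `compound_id`, `sigma`, `Y`,
#'   `is_parent`.
#' @export
gen_hammett_series <- function(rho = 3.1,
                               sigma = c(-0.27, -0.17, 0, 0.06, 0.23,
                                         0.45, 0.54, 0.66, 0.78),
                               Y0 = 1, noise = 0.1, seed = 1) {
  if (length(sigma) == 0) abort("`sigma` must be non-empty.")
  if (Y0 <= 0) abort("`Y0` must be positive.")
  if (!any(sigma == 0)) sigma <- c(0, sigma)
  sigma <- sort(sigma)
  withr::with_seed(seed, {
    Y <- Y0 * 10^(rho * sigma)
    if (noise > 0) {
      Y <- Y * stats::rlnorm(length(sigma), meanlog = -noise^2 / 2,
                             sdlog = noise)
    }
    tibble(compound_id = sprintf("cmpd_%02d", seq_along(sigma)),
           sigma = sigma, Y = Y, is_parent = sigma == 0)
  })
}

#' Synthetic dye-referenced equilibrium titration
#'
#' Sweeps the solution potential over a grid bracketing both midpoints; at
#' each potential the oxidized fraction of the dye and of the enzyme
#' follows its Nernst equation, then fractions are converted to the two
#' recorded absorbances: A521 from the oxidized dye alone, A454 as the
#' dye's small spillover plus the enzyme flavin band interpolated between
#' its endpoint absorbances. Optional additive Gaussian noise (scaled by
#' the oxidized-enzyme endpoint absorbance) emulates spectrophotometer
#' error. Fully-oxidized and fully-reduced endpoints are included.
#'
#' @param E0_e Enzyme midpoint potential, V vs NHE.
#' @param n_e Electrons of the enzyme couple.
#' @param dye A [dye_spec()]; carries the dye midpoint, electron count,
#'   extinctions and total concentration.
#' @param A454_enz_ox,A454_enz_red Enzyme-only endpoint absorbances at
#'   454 nm, AU.
#' @param n Number of titration points (including endpoints).
#' @param noise Relative additive noise (fraction of `A454_enz_ox`).
#' @param potential_range Potential sweep, V; default brackets both
#'   midpoints by 80 mV.
#' @param pathlength Optical pathlength, cm.
#' @param seed Integer seed.
#' @return A tibble with columns `potential`, `A454`, `A521`, with the
#'   dye-corrected enzyme endpoints in attributes `A454_fully_ox` and
#'   `A454_fully_red`.
#' @export
gen_titration_series <- function(E0_e = -0.190, n_e = 2L,
                                 dye = phenosafranine(18),
                                 A454_enz_ox = 0.50, A454_enz_red = 0.05,
                                 n = 81, noise = 0,
                                 potential_range = NULL,
                                 pathlength = 1, seed = 1) {
  if (n < 3) abort("`n` must be >= 3.")
  if (is.null(potential_range)) {
    potential_range <- range(E0_e, dye$E0_d) + c(-0.08, 0.08)
  }
  if (diff(potential_range) <= 0) {
    abort("`potential_range` must have positive width.")
  }
  E <- seq(potential_range[2], potential_range[1], length.out = n)
  frac_ox <- function(E, E0, ne) {
    r <- 10^(ne * (E - E0) / NERNST_V)  # ox/red ratio
    r / (1 + r)
  }
  f_d <- frac_ox(E, dye$E0_d, dye$n_d)
  f_e <- frac_ox(E, E0_e, n_e)
  D_ox <- dye$total_conc * f_d
  A521 <- dye$eps_521 / 1000 * D_ox * pathlength
  A454 <- dye$eps_454 / 1000 * D_ox * pathlength +
    A454_enz_red + f_e * (A454_enz_ox - A454_enz_red)
  out <- withr::with_seed(seed, {
    if (noise > 0) {
      sdev <- noise * A454_enz_ox
      A521 <- pmax(A521 + rnorm(n, 0, sdev), 0)
      A454 <- pmax(A454 + rnorm(n, 0, sdev), 0)
    }
    tibble(potential = E, A454 = A454, A521 = A521)
  })
  attr(out, "A454_fully_ox") <- A454_enz_ox
  attr(out, "A454_fully_red") <- A454_enz_red
  out
}

#' Toy two-chain atom cluster for surface-area tests
#'
#' Builds a random carbon-sphere cluster, mirrors it through the plane
#' between the two chains, and places the copies (chains A and B) at the
#' requested centroid separation. Useful for exercising the
#' buried-interface machinery without real coordinates.
#'
#' @param n_atoms_per_chain Atoms per chain.
#' @param separation Centroid separation along x, angstrom.
#' @param spread Gaussian s.d. of atom positions about each centroid.
#' @param seed Integer seed.
#' @return An atom tibble compatible with [sasa()] and
#'   [buried_interface()].
#' @export
gen_toy_dimer <- function(n_atoms_per_chain = 30, separation = 8,
                          spread = 3, seed = 1) {
  if (n_atoms_per_chain < 1) abort("Need at least one atom per chain.")
  withr::with_seed(seed, {
    a <- matrix(rnorm(3 * n_atoms_per_chain, 0, spread), ncol = 3)
    b <- a
    b[, 1] <- -b[, 1]               # mirror image
    a[, 1] <- a[, 1] - separation / 2
    b[, 1] <- b[, 1] + separation / 2
    xyz <- rbind(a, b)
    tibble(
      element = "C",
      chain = rep(c("A", "B"), each = n_atoms_per_chain),
      resno = rep(seq_len(n_atoms_per_chain), 2),
      resid = "UNK",
      atom_name = "C",
      x = round(xyz[, 1], 3), y = round(xyz[, 2], 3),
      z = round(xyz[, 3], 3),
      radius = unname(VDW_RADII["C"])
    )
  })
}
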