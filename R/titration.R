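#' Reference-dye specification for equilibrium redox titrations
#'
#' Describes the two-electron indicator dye whose spectral signature tracks
#' the solution potential. Defaults are those of phenosafranine:
#' E° = -0.252 V vs NHE, n = 2, extinction coefficients 44.7 mM^-1 cm^-1 at
#' 521 nm (oxidized dye only) and 9.85 mM^-1 cm^-1 at 454 nm (its small
#' spillover at the flavin wavelength).
#'
#' @param name Dye name.
#' @param E0_d Dye midpoint potential, V vs NHE.
#' @param n_d Electrons taken up by the dye.
#' @param eps_521,eps_454 Extinction coefficients of the oxidized dye,
#'   mM^-1 cm^-1.
#' @param total_conc Total dye concentration, uM.
#' @return A list of class `dye_spec`.
#' @export
#' @examples
#' dye_spec()             # phenosafranine at 18 uM
#' phenosafranine(25)
dye_spec <- function(name = "phenosafranine", E0_d = -0.252, n_d = 2L,
                     eps_521 = 44.7, eps_454 = 9.85, total_conc = 18) {
  if (eps_521 <= 0 || eps_454 <= 0) abort("Extinction coefficients must be positive.")
  n_d <- as.integer(n_d)
  if (n_d < 1L) abort("`n_d` must be >= 1.")
  if (total_conc <= 0) abort("`total_conc` must be positive.")
  structure(
    list(name = name, E0_d = E0_d, n_d = n_d, eps_521 = eps_521,
         eps_454 = eps_454, total_conc = total_conc),
    class = "dye_spec"
  )
}

#' @rdname dye_spec
#' @export
phenosafranine <- function(total_conc = 18) dye_spec(total_conc = total_conc)

#' @export
print.dye_spec <- function(x, ...) {
  cat(sprintf("<dye_spec> %s: E0 = %.3f V, n = %d, %g uM\n",
              x$name, x$E0_d, x$n_d, x$total_conc))
  cat(sprintf("  eps521 = %g, eps454 = %g mM^-1 cm^-1\n",
              x$eps_521, x$eps_454))
  invisible(x)
}

#' Oxidized/reduced dye concentrations from A521
#'
#' The 521 nm band belongs to the oxidized dye alone, so Beer-Lambert gives
#' its concentration directly: `D_ox = A521 / (eps_521 * pathlength)` (in
#' uM, with eps in mM^-1 cm^-1 the mM->uM factor of 1000 applies), and
#' `D_red = total - D_ox`. Values are clipped to [0, total] to absorb noise
#' at the endpoints.
#'
#' @param A521 Absorbance(s) at 521 nm, AU; vectorised.
#' @param spec A [dye_spec()].
#' @param pathlength Optical pathlength, cm.
#' @return A tibble with columns `D_ox`, `D_red` in uM.
#' @export
#' @examples
#' dye_fractions(0.8046, phenosafranine(18))  # fully oxidized: D_ox = 18
dye_fractions <- function(A521, spec = dye_spec(), pathlength = 1) {
  if (any(A521 < -1e-6)) abort("Absorbances must be nonnegative.")
  a_max <- spec$eps_521 * spec$total_conc / 1000 * pathlength
  if (any(A521 > a_max * 1.05)) {
    warn("Some A521 values exceed the fully-oxidized dye absorbance by >5%.")
  }
  D_ox <- pmin(pmax(A521 / (spec$eps_521 / 1000 * pathlength), 0),
               spec$total_conc)
  tibble(D_ox = D_ox, D_red = spec$total_conc - D_ox)
}

#' Enzyme oxidized/reduced fractions from dye-corrected A454
#'
#' The flavin band at 454 nm contains a small contribution from the
#' oxidized dye, removed using its 454 nm extinction coefficient; the
#' remaining enzyme absorbance is converted to a fraction oxidized by
#' normalising between the fully-oxidized and fully-reduced enzyme
#' endpoint absorbances (already dye-corrected), clipped to [0, 1].
#'
#' @param A454 Absorbance(s) at 454 nm, AU; vectorised.
#' @param D_ox Oxidized dye concentration(s), uM (from [dye_fractions()]).
#' @param A454_fully_ox,A454_fully_red Dye-corrected enzyme absorbances at
#'   the titration endpoints, AU.
#' @param spec A [dye_spec()].
#' @param pathlength Optical pathlength, cm.
#' @return A tibble with columns `E_ox`, `E_red` (fractions).
#' @export
enzyme_fractions <- function(A454, D_ox, A454_fully_ox, A454_fully_red,
                             spec = dye_spec(), pathlength = 1) {
  if (A454_fully_ox == A454_fully_red) {
    abort("Endpoint absorbances must be distinct.")
  }
  A_enz <- A454 - spec$eps_454 / 1000 * D_ox * pathlength
  f_ox <- (A_enz - A454_fully_red) / (A454_fully_ox - A454_fully_red)
  f_ox <- pmin(pmax(f_ox, 0), 1)
  tibble(E_ox = f_ox, E_red = 1 - f_ox)
}

#' Log-log Nernst analysis of a dye-referenced titration
#'
#' Reduces a series of (A454, A521) pairs recorded during a slow
#' equilibrium reduction to an enzyme midpoint potential. At equilibrium
#' both couples see the same solution potential, so
#' log10(E_red/E_ox) = (n_e/n_d) log10(D_red/D_ox)
#'                     + n_e (E0_e - E0_d) / 0.0592,
#' a line whose slope checks Nernstian behaviour (1 for two 2-electron
#' couples) and whose intercept yields
#' `E0_e = E0_d + intercept * 0.0592 / n_e`.
#'
#' Points where either couple is essentially fully oxidized or fully
#' reduced carry no log-ratio information and blow up numerically; only
#' points with both fractions inside `window` are fitted.
#'
#' @param series Data frame with columns `A454` and `A521`.
#' @param spec A [dye_spec()].
#' @param A454_fully_ox,A454_fully_red Dye-corrected enzyme endpoint
#'   absorbances, AU.
#' @param n_e Electrons taken up by the enzyme couple.
#' @param pathlength Optical pathlength, cm.
#' @param window Interior window of usable fractions, default 2-98%.
#' @return An object of class `nernst_fit` with `slope`, `intercept`,
#'   `E0_e`, `r_squared`, `n_used`, `n_excluded`.
#' @export
#' @examples
#' s <- gen_titration_series(E0_e = -0.190, noise = 0, seed = 1)
#' nernst_fit(s, A454_fully_ox = attr(s, "A454_fully_ox"),
#'            A454_fully_red = attr(s, "A454_fully_red"))
nernst_fit <- function(series, spec = dye_spec(),
                       A454_fully_ox, A454_fully_red,
                       n_e = 2L, pathlength = 1,
                       window = c(0.02, 0.98)) {
  series <- as_tibble(series)
  if (!all(c("A454", "A521") %in% names(series))) {
    abort("`series` needs columns A454 and A521.")
  }
  n_e <- as.integer(n_e)
  if (n_e < 1L) abort("`n_e` must be >= 1.")
  dye <- dye_fractions(series$A521, spec, pathlength)
  enz <- enzyme_fractions(series$A454, dye$D_ox, A454_fully_ox,
                          A454_fully_red, spec, pathlength)
  f_d <- dye$D_ox / spec$total_conc
  ok <- f_d > window[1] & f_d < window[2] &
    enz$E_ox > window[1] & enz$E_ox < window[2]
  d <- tibble(
    x = log10(dye$D_red[ok] / dye$D_ox[ok]),
    y = log10(enz$E_red[ok] / enz$E_ox[ok])
  )
  if (nrow(d) < 3) {
    abort(sprintf(
      "Only %d usable interior points (need >= 3); titration does not bracket both midpoints.",
      nrow(d)))
  }
  fit <- lm(y ~ x, data = d)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  E0_e <- spec$E0_d + intercept * NERNST_V / n_e
  structure(
    list(slope = slope, intercept = intercept, E0_e = E0_e, n_e = n_e,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         n_used = nrow(d), n_excluded = sum(!ok),
         spec = spec, fit = fit, data = d),
    class = "nernst_fit"
  )
}

#' @export
print.nernst_fit <- function(x, ...) {
  cat("<nernst_fit>  log(Ered/Eox) vs log(Dred/Dox)\n")
  cat(sprintf("  slope = %.3f (expect n_e/n_d), intercept = %.3f, R^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  E0(enzyme) = %.3f V vs NHE  (dye %s at %.3f V, n_e = %d)\n",
              x$E0_e, x$spec$name, x$spec$E0_d, x$n_e))
  cat(sprintf("  %d points fitted, %d endpoint points excluded\n",
              x$n_used, x$n_excluded))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nernst_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept", "E0_e"),
         estimate = c(x$slope, x$intercept, x$E0_e))
}

#' @exportS3Method generics::glance
glance.nernst_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, E0_e = x$E0_e, nobs = x$n_used,
         n_excluded = x$n_excluded)
}

#' @exportS3Method ggplot2::autoplot
autoplot.nernst_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(
      x = expression(log[10](D[red] / D[ox])),
      y = expression(log[10](E[red] / E[ox])),
      title = sprintf("Nernst titration: E0 = %.0f mV", 1000 * object$E0_e))
}
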