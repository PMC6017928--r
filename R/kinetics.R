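#' Initial velocity from an absorbance-vs-time trace
#'
#' Estimates the initial enzymatic rate from a spectrophotometric trace by
#' linear fit over an early window, corrects for the uncoupled background
#' slope measured before substrate addition, and converts absorbance change
#' to concentration change with Beer-Lambert. For NADH consumption assays
#' the canonical wavelength is 370 nm with epsilon = 2660 M^-1 cm^-1.
#'
#' The fitted window defaults to the first 10% of points (at least 4). A
#' curvature guard fits a quadratic over the candidate window and shrinks it
#' while the quadratic term contributes more than `curvature_tol` of the
#' linear change across the window, so that only the quasi-linear initial
#' phase is used.
#'
#' @param trace Data frame with columns `time_s` and `A` (absorbance, AU).
#' @param epsilon Molar extinction coefficient, M^-1 cm^-1.
#' @param enzyme_conc Total enzyme concentration, M.
#' @param pathlength Optical pathlength, cm.
#' @param baseline_slope Background (uncoupled) slope, AU/s.
#' @param window_frac Initial fraction of points to fit.
#' @param curvature_tol Maximum tolerated relative quadratic contribution.
#' @return A one-row tibble: `velocity` (M/s), `substrate_conc` (NA, to be
#'   filled by the caller), `enzyme_conc`, plus the fitted `slope` and the
#'   number of points used.
#' @export
#' @examples
#' tr <- tibble::tibble(time_s = 0:60, A = 1 - 2.66e-3 * (0:60))
#' initial_velocity(tr, epsilon = 2660, enzyme_conc = 1e-7)
initial_velocity <- function(trace, epsilon, enzyme_conc,
                             pathlength = 1, baseline_slope = 0,
                             window_frac = 0.1, curvature_tol = 0.05) {
  trace <- as_tibble(trace)
  if (!all(c("time_s", "A") %in% names(trace))) {
    abort("`trace` needs columns time_s and A.")
  }
  if (epsilon <= 0) abort("`epsilon` must be positive.")
  if (enzyme_conc <= 0) abort("`enzyme_conc` must be positive.")
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    abort("`time_s` must be strictly increasing.")
  }
  n <- nrow(trace)
  w <- max(4L, ceiling(window_frac * n))
  if (n < w) abort(sprintf("Trace has %d points; at least %d needed.", n, w))
  # shrink window until the quadratic term is negligible
  while (w > 4L) {
    win <- trace[seq_len(w), ]
    t0 <- win$time_s - win$time_s[1]
    qfit <- lm(win$A ~ t0 + I(t0^2))
    a1 <- coef(qfit)[2]; a2 <- coef(qfit)[3]
    span <- max(t0)
    if (!is.finite(a2) || abs(a1) < .Machine$double.eps) break
    if (abs(a2) * span <= curvature_tol * abs(a1)) break
    w <- max(4L, floor(w * 0.75))
    if (w == 4L) break
  }
  win <- trace[seq_len(w), ]
  slope <- unname(coef(lm(A ~ time_s, data = win))[2])
  v <- (abs(slope) - abs(baseline_slope)) / (epsilon * pathlength)
  v <- max(v, 0)
  tibble(velocity = v, substrate_conc = NA_real_,
         enzyme_conc = enzyme_conc, slope = slope, n_points = w)
}

#' Fit the Michaelis-Menten equation to initial-rate data
#'
#' Nonlinear least squares of v = kcat [E]0 [S] / (KM + [S]), fitted on the
#' normalised rate v/[E]0 so that kcat has units of s^-1 regardless of
#' enzyme concentration. Starting values come from a Hanes-Woolf
#' linearisation (S/v vs S); the Levenberg-Marquardt fit enforces
#' positivity bounds on both parameters.
#'
#' @param data Data frame with columns `substrate_conc` (M), `velocity`
#'   (M/s) and `enzyme_conc` (M). Any consistent concentration unit works:
#'   kcat is unit-free in time^-1 and KM is returned in the unit of
#'   `substrate_conc`.
#' @param weights Either `"none"` (default) or `"1/v"` for relative
#'   weighting.
#' @return An object of class `mm_fit`.
#' @export
#' @examples
#' d <- gen_mm_rates(kcat = 10, KM = 1e-4, noise = 0, seed = 1)
#' fit_michaelis_menten(d)
fit_michaelis_menten <- function(data, weights = c("none", "1/v")) {
  weights <- match.arg(weights)
  data <- as_tibble(data)
  req <- c("substrate_conc", "velocity", "enzyme_conc")
  if (!all(req %in% names(data))) {
    abort("`data` needs columns substrate_conc, velocity, enzyme_conc.")
  }
  if (any(data$substrate_conc < 0) || any(data$velocity < 0)) {
    abort("Concentrations and velocities must be nonnegative.")
  }
  if (any(data$enzyme_conc <= 0)) abort("enzyme_conc must be positive.")
  if (length(unique(data$substrate_conc)) < 2) {
    abort("Need at least 2 distinct substrate concentrations.")
  }
  d <- tibble(S = data$substrate_conc, y = data$velocity / data$enzyme_conc)
  # Hanes-Woolf start: S/v = KM/Vmax + S/Vmax
  pos <- d$y > 0 & d$S > 0
  if (sum(pos) >= 2) {
    hw <- lm(I(S / y) ~ S, data = d[pos, ])
    kcat0 <- 1 / coef(hw)[2]
    KM0 <- coef(hw)[1] * kcat0
  } else {
    kcat0 <- NA_real_; KM0 <- NA_real_
  }
  if (!is.finite(kcat0) || kcat0 <= 0) kcat0 <- max(d$y)
  if (!is.finite(KM0) || KM0 <= 0) KM0 <- median(d$S)
  args <- list(
    y ~ kcat * S / (KM + S), data = d,
    start = list(kcat = unname(kcat0), KM = unname(KM0)),
    lower = c(kcat = .Machine$double.eps, KM = .Machine$double.eps),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (weights == "1/v") args$weights <- 1 / pmax(d$y, .Machine$double.eps)
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e) abort(paste0(
      "Michaelis-Menten fit failed to converge: ", conditionMessage(e),
      sprintf(" [start kcat=%.3g, KM=%.3g, n=%d]", kcat0, KM0, nrow(d))))
  )
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kcat = NA_real_, KM = NA_real_))
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((d$y - mean(d$y))^2)
  kck <- unname(est["kcat"] / est["KM"])
  se_kck <- kck * sqrt(sum((se / est)^2, na.rm = FALSE))
  structure(
    list(kcat = unname(est["kcat"]), KM = unname(est["KM"]),
         kcat_over_KM = kck,
         se_kcat = unname(se["kcat"]), se_KM = unname(se["KM"]),
         se_kcat_over_KM = unname(se_kck),
         r_squared = 1 - ss_res / ss_tot,
         fit = fit, data = data),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit>  v = kcat [E]0 [S] / (KM + [S])\n")
  cat(sprintf("  kcat = %.4g +/- %.2g s^-1\n", x$kcat, x$se_kcat))
  cat(sprintf("  KM   = %.4g +/- %.2g (substrate conc. units)\n",
              x$KM, x$se_KM))
  cat(sprintf("  kcat/KM = %.4g, R^2 = %.4f\n", x$kcat_over_KM, x$r_squared))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("kcat", "KM", "kcat_over_KM"),
         estimate = c(x$kcat, x$KM, x$kcat_over_KM),
         std.error = c(x$se_kcat, x$se_KM, x$se_kcat_over_KM))
}

#' @exportS3Method generics::glance
glance.mm_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = nrow(x$data))
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(kcat = object$kcat, KM = object$KM)
}

#' @exportS3Method ggplot2::autoplot
autoplot.mm_fit <- function(object, ...) {
  d <- object$data
  Sgrid <- seq(0, max(d$substrate_conc), length.out = 200)
  curve <- tibble(
    substrate_conc = Sgrid,
    velocity = object$kcat * mean(d$enzyme_conc) * Sgrid / (object$KM + Sgrid)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$substrate_conc,
                                  y = .data$velocity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::labs(x = "[S]", y = "v", title = "Michaelis-Menten fit")
}

#' Hammett substituent-effect regression
#'
#' Regresses log10 of a rate quantity on the Hammett substituent constant
#' sigma. In `"normalized"` mode each Y is first divided by the parent
#' (sigma = 0) compound's Y0 and the line is constrained through the
#' origin, the form log10(Y/Y0) = rho * sigma. In `"free_intercept"` mode
#' log10(Y) is regressed on sigma with an intercept.
#'
#' @param points Data frame with columns `sigma` and the rate quantity
#'   named by `quantity`; a `compound_id` column is carried through if
#'   present.
#' @param quantity Name of the column holding the rate quantity
#'   (e.g. `"kcat_over_KM"`, `"kcat"`, or `"Y"`).
#' @param mode `"normalized"` (through-origin on Y/Y0) or
#'   `"free_intercept"`.
#' @return An object of class `hammett_fit` with `rho`, `intercept`,
#'   `se_rho`, `r_squared` and `mode`.
#' @export
#' @examples
#' pts <- gen_hammett_series(rho = 3.1, noise = 0, seed = 1)
#' hammett_regression(pts)
hammett_regression <- function(points, quantity = "Y",
                               mode = c("normalized", "free_intercept")) {
  mode <- match.arg(mode)
  points <- as_tibble(points)
  if (!all(c("sigma", quantity) %in% names(points))) {
    abort(sprintf("`points` needs columns sigma and %s.", quantity))
  }
  Y <- points[[quantity]]
  if (any(Y <= 0)) abort("All rate quantities must be positive (log taken).")
  sigma <- points$sigma
  if (mode == "normalized") {
    parent <- which(sigma == 0)
    if (length(parent) == 0) {
      abort("Normalized mode needs a parent point with sigma = 0.")
    }
    if (length(parent) > 1) {
      abort("Exactly one parent (sigma = 0) point expected.")
    }
    ylog <- log10(Y / Y[parent])
    fit <- lm(ylog ~ 0 + sigma)
    rho <- unname(coef(fit)[1])
    intercept <- 0
    se_rho <- suppressWarnings(summary(fit))$coefficients["sigma", "Std. Error"]
    r2 <- suppressWarnings(summary(fit)$r.squared)
  } else {
    ylog <- log10(Y)
    fit <- lm(ylog ~ sigma)
    rho <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    se_rho <- suppressWarnings(summary(fit))$coefficients["sigma", "Std. Error"]
    r2 <- suppressWarnings(summary(fit)$r.squared)
  }
  structure(
    list(rho = rho, intercept = intercept, se_rho = se_rho,
         r_squared = r2,
         mode = if (mode == "normalized") "normalized_through_origin"
                else "free_intercept",
         fit = fit,
         data = tibble(compound_id = if ("compound_id" %in% names(points))
                         points$compound_id else
                         as.character(seq_along(sigma)),
                       sigma = sigma, log_y = ylog)),
    class = "hammett_fit"
  )
}

#' @export
print.hammett_fit <- function(x, ...) {
  cat("<hammett_fit> ", x$mode, "\n")
  cat(sprintf("  rho = %.3g +/- %.2g, intercept = %.3g, R^2 = %.4f\n",
              x$rho, x$se_rho, x$intercept, x$r_squared))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hammett_fit <- function(x, ...) {
  tibble(term = c("rho", "intercept"),
         estimate = c(x$rho, x$intercept),
         std.error = c(x$se_rho, NA_real_))
}

#' @exportS3Method generics::glance
glance.hammett_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, mode = x$mode, nobs = nrow(x$data))
}

#' @exportS3Method ggplot2::autoplot
autoplot.hammett_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$sigma,
                                            y = .data$log_y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$rho, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(x = expression(sigma[para]),
                  y = if (object$mode == "normalized_through_origin")
                    expression(log[10](Y / Y[0])) else expression(log[10](Y)),
                  title = sprintf("Hammett plot (rho = %.2f)", object$rho))
}

#' Reference table of Hammett para substituent constants
#'
#' Standard literature sigma_para values for common substituents, shipped
#' as a convenience for labelling substituted-nitrobenzene series. These
#' are textbook physical-organic values (Hansch-Leo-Taft compilation), not
#' measurements made by this package.
#'
#' @return A tibble with columns `substituent` and `sigma_para`.
#' @export
#' @examples
#' sigma_para_table()
sigma_para_table <- function() {
  tibble::tribble(
    ~substituent, ~sigma_para,
    "H",       0.00,
    "CH3",    -0.17,
    "OCH3",   -0.27,
    "NH2",    -0.66,
    "OH",     -0.37,
    "F",       0.06,
    "Cl",      0.23,
    "Br",      0.23,
    "I",       0.18,
    "CF3",     0.54,
    "CN",      0.66,
    "CHO",     0.42,
    "COCH3",   0.50,
    "COOH",    0.45,
    "CONH2",   0.36,
    "SO2NH2",  0.60,
    "NO2",     0.78
  )
}
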