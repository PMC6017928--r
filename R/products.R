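# Element mass tables. Nominal = integer mass of the most abundant
# isotope; monoisotopic = its exact mass (u).
ELEMENT_MASSES <- list(
  C  = c(nominal = 12,  mono = 12.0),
  H  = c(nominal = 1,   mono = 1.00782503207),
  N  = c(nominal = 14,  mono = 14.0030740048),
  O  = c(nominal = 16,  mono = 15.9949146196),
  S  = c(nominal = 32,  mono = 31.97207100),
  F  = c(nominal = 19,  mono = 18.99840322),
  P  = c(nominal = 31,  mono = 30.97376163),
  Cl = c(nominal = 35,  mono = 34.96885268),
  Br = c(nominal = 79,  mono = 78.9183371),
  I  = c(nominal = 127, mono = 126.904473)
)

#' Parse a molecular formula string
#'
#' Accepts Hill-notation-like strings such as `"C6H6N4O4"`. Element symbols
#' must be among C, H, N, O, S, F, P, Cl, Br, I; counts default to 1 when
#' omitted. Repeated symbols are summed.
#'
#' @param text Formula string.
#' @return A named integer vector of element counts, class `mol_formula`.
#' @export
#' @examples
#' parse_formula("C6H6N4O4")
#' parse_formula("H2O")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) abort("Empty formula string.")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    abort(sprintf("Malformed formula string: '%s'", text))
  }
  counts <- integer(0)
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(ELEMENT_MASSES)) {
      abort(sprintf("Unknown element symbol '%s' in '%s'.", el, text))
    }
    prev <- if (el %in% names(counts)) counts[[el]] else 0L
    counts[el] <- prev + n
  }
  counts <- counts[counts > 0]
  if (sum(counts) < 1) abort("Formula must contain at least one atom.")
  structure(as.integer(counts), names = names(counts), class = "mol_formula")
}

#' Format a molecular formula in Hill order
#'
#' @param x A `mol_formula`.
#' @param ... Unused.
#' @return A formula string (C first, then H, then other elements
#'   alphabetically; count 1 omitted).
#' @export
format.mol_formula <- function(x, ...) {
  els <- names(x)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(el) {
    n <- x[[el]]
    if (n == 1L) el else paste0(el, n)
  }, character(1)), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula>", format(x), "\n")
  invisible(x)
}

#' Nominal and monoisotopic mass of a formula
#'
#' @param formula A `mol_formula` or formula string.
#' @return A one-row tibble with `nominal_mass` (integer Da) and
#'   `monoisotopic_mass` (Da).
#' @export
#' @examples
#' formula_mass("C6H6N4O4")  # nitrofurazone: 198 Da nominal
formula_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "mol_formula"))
  nom <- sum(vapply(names(formula),
                    function(el) ELEMENT_MASSES[[el]]["nominal"],
                    numeric(1)) * as.integer(formula))
  mono <- sum(vapply(names(formula),
                     function(el) ELEMENT_MASSES[[el]]["mono"],
                     numeric(1)) * as.integer(formula))
  tibble(nominal_mass = as.integer(nom), monoisotopic_mass = mono)
}

# apply an element-count delta, erroring if any count would go negative
apply_delta <- function(formula, delta) {
  out <- as.integer(formula)
  names(out) <- names(formula)
  for (el in names(delta)) {
    out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + delta[[el]]
    if (out[[el]] < 0L) abort("Element count would become negative.")
  }
  out <- out[out > 0L]
  structure(as.integer(out), names = names(out), class = "mol_formula")
}

#' Predict nitro-reduction product formulas and m/z
#'
#' Aromatic nitro groups are reduced enzymatically in sequential
#' two-electron steps: nitro -> nitroso -> hydroxylamine -> amine. On the
#' molecular formula this is pure atom bookkeeping for one nitro group:
#' nitroso = parent - O (nominal -16), hydroxylamine = parent - O + 2H
#' (-14), amine = parent - 2O + 2H (-30). The protonated and deprotonated
#' ion m/z for LC-MS identification are reported as nominal mass +/- 1
#' (nearest-integer convention).
#'
#' Exactly one nitro group is reduced per call; regioselectivity on
#' polynitro parents is outside the mass arithmetic.
#'
#' @param parent Parent formula (`mol_formula` or string); must contain a
#'   nitro group (at least 1 N and 2 O).
#' @param stage Product stage(s): any of `"nitroso"`, `"hydroxylamine"`,
#'   `"amine"`; defaults to all three.
#' @return A tibble with one row per stage: `stage`, `formula`,
#'   `nominal_mass`, `monoisotopic_mass`, `mz_plus1`, `mz_minus1`.
#' @export
#' @examples
#' reduce_nitro("C6H6N4O4", "amine")       # nitrofurazone -> M+1 = 169
#' reduce_nitro("C12H5NO5")                # all three stages
reduce_nitro <- function(parent,
                         stage = c("nitroso", "hydroxylamine", "amine")) {
  stage <- match.arg(stage, several.ok = TRUE)
  if (is.character(parent)) parent <- parse_formula(parent)
  stopifnot(inherits(parent, "mol_formula"))
  n_N <- if ("N" %in% names(parent)) parent[["N"]] else 0L
  n_O <- if ("O" %in% names(parent)) parent[["O"]] else 0L
  if (n_N < 1L || n_O < 2L) {
    abort("Parent formula has no nitro group (needs N >= 1 and O >= 2).")
  }
  deltas <- list(
    nitroso      = c(O = -1L),
    hydroxylamine = c(O = -1L, H = 2L),
    amine        = c(O = -2L, H = 2L)
  )
  purrr::map_dfr(stage, function(st) {
    f <- apply_delta(parent, deltas[[st]])
    m <- formula_mass(f)
    tibble(stage = st, formula = format(f),
           nominal_mass = m$nominal_mass,
           monoisotopic_mass = m$monoisotopic_mass,
           mz_plus1 = m$nominal_mass + 1L,
           mz_minus1 = m$nominal_mass - 1L)
  })
}

#' LC-MS amine detection policy
#'
#' Yield bookkeeping for product detection: the LC-MS method detects the
#' amine whenever it forms at more than `detect_threshold` (default 1%) of
#' substrate, and a failure to detect bounds the yield below
#' `absence_bound` (default 0.5%).
#'
#' @param detect_threshold Yield fraction above which the amine is always
#'   detected.
#' @param absence_bound Yield fraction below which non-detection places the
#'   true yield.
#' @return A list of class `detection_policy`.
#' @export
detection_policy <- function(detect_threshold = 0.01, absence_bound = 0.005) {
  if (absence_bound >= detect_threshold) {
    abort("`absence_bound` must be below `detect_threshold`.")
  }
  structure(list(detect_threshold = detect_threshold,
                 absence_bound = absence_bound),
            class = "detection_policy")
}

#' Classify an amine yield under a detection policy
#'
#' @param amine_yield Yield fraction(s) in [0, 1]; vectorised.
#' @param policy A [detection_policy()].
#' @return Character vector: `"detected"`, `"below_bound"` or
#'   `"indeterminate"`.
#' @export
#' @examples
#' detection_call(c(0.02, 0.001, 0.0075))
detection_call <- function(amine_yield, policy = detection_policy()) {
  if (any(amine_yield < 0 | amine_yield > 1)) {
    abort("Yields must lie in [0, 1].")
  }
  dplyr::case_when(
    amine_yield > policy$detect_threshold ~ "detected",
    amine_yield < policy$absence_bound ~ "below_bound",
    TRUE ~ "indeterminate"
  )
}
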