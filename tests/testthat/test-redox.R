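energies_fixture <- function() {
  tibble::tribble(
    ~compound_id, ~state, ~G_hartree,
    "ArNO2",        "ox",  -436.000,
    "ArNO2",        "red", -436.100,
    "nitrobenzene", "ox",  -436.500,
    "nitrobenzene", "red", -436.580
  )
}

test_that("reaction free energy implements the isodesmic cycle", {
  en <- energies_fixture()
  # direct arithmetic: (-436.100 + -436.500) - (-436.000 + -436.580)
  expect_equal(reaction_free_energy(en, "ArNO2"), -0.020)
  # self-exchange of the reference is exactly zero
  expect_equal(reaction_free_energy(en, "nitrobenzene"), 0)
  # missing record errors, naming the absent pair
  expect_error(reaction_free_energy(en[-2, ], "ArNO2"),
               "ArNO2.*reduced_anion")
  expect_error(reaction_free_energy(en, "ArNO2",
                                    reference_couple("absent")),
               "absent")
})

test_that("conformer duplicates resolve to the lowest-energy record", {
  en <- energies_fixture()
  extra <- tibble::tibble(compound_id = "ArNO2", state = "red",
                          G_hartree = -436.050)  # higher-energy conformer
  expect_equal(reaction_free_energy(dplyr::bind_rows(en, extra), "ArNO2"),
               -0.020)
})

test_that("potential conversion is the anchored affine map", {
  expect_equal(potential_from_dg(0), -0.486)
  expect_equal(potential_from_dg(-0.020), -0.486 + 0.020 * 27.2114)
  expect_equal(potential_from_dg(0.010), -0.486 - 0.010 * 27.2114)
  # affine, strictly decreasing, slope exactly -27.2114 V/hartree
  dg <- seq(-0.05, 0.05, by = 0.01)
  E <- potential_from_dg(dg)
  expect_true(all(diff(E) < 0))
  expect_equal(diff(E) / diff(dg), rep(-27.2114, length(dg) - 1))
})

test_that("compute_potentials maps every non-reference compound", {
  out <- compute_potentials(energies_fixture())
  expect_equal(nrow(out), 1)
  expect_equal(out$E_comp, -0.486 + 0.020 * 27.2114)
})

test_that("calibration fit recovers exact and hand-solved lines", {
  # noise-free generating constants come back exactly
  pr <- gen_calibration_pairs(n = 12, slope = 4.67, offset = 0.379,
                              noise = 0, seed = 3)
  m <- fit_calibration(pr)
  expect_equal(m$slope, 4.67, tolerance = 1e-10)
  expect_equal(m$offset, 0.379, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_equal(m$mad_after, 0, tolerance = 1e-12)
  # two points, hand-solved: slope 5, offset 0.38
  m2 <- fit_calibration(tibble::tibble(E_exp = c(-0.3, -0.5),
                                       E_comp = c(0.4, -0.6)))
  expect_equal(m2$slope, 5)
  expect_equal(m2$offset, 0.38)
  # degenerate inputs
  expect_error(fit_calibration(tibble::tibble(E_exp = -0.3, E_comp = 0.4)),
               "at least 2")
  expect_error(fit_calibration(tibble::tibble(E_exp = c(-0.3, -0.3),
                                              E_comp = c(0.4, 0.5))),
               "Degenerate")
})

test_that("noisy calibration recovers the generating slope", {
  pr <- gen_calibration_pairs(n = 12, noise = 0.02, seed = 7)
  m <- fit_calibration(pr)
  expect_lt(abs(m$slope - 4.67), 0.5)
})

test_that("mad_after matches a brute-force residual computation", {
  pr <- gen_calibration_pairs(n = 25, noise = 0.03, seed = 11)
  m <- fit_calibration(pr)
  brute <- mean(abs(residuals(m$fit))) / abs(m$slope)
  expect_equal(m$mad_after, brute, tolerance = 1e-12)
})

test_that("apply_calibration is the inverse map", {
  m <- calibration_model(4.67, 0.379)
  expect_equal(apply_calibration(0, m), -0.379)
  expect_equal(apply_calibration(-0.4997, m), -0.486, tolerance = 1e-3)
  # round trip identity for arbitrary x
  x <- seq(-1, 1, by = 0.1)
  expect_equal(apply_calibration((x + 0.379) * 4.67, m), x)
  # data-frame method appends E_cal
  out <- apply_calibration(tibble::tibble(E_comp = c(0, -0.4997)), m)
  expect_equal(out$E_cal[1], -0.379)
})

test_that("calibration recovery improves with sample size", {
  err <- sapply(c(10, 100, 1000), function(n) {
    mean(sapply(1:20, function(s) {
      m <- fit_calibration(gen_calibration_pairs(n = n, noise = 0.03,
                                                 seed = 1000 + s))
      abs(m$slope - 4.67)
    }))
  })
  expect_true(all(diff(err) < 0))
})

test_that("tidy and glance expose the calibration parameters", {
  m <- fit_calibration(gen_calibration_pairs(seed = 5))
  td <- tidy(m)
  expect_equal(td$estimate[td$term == "slope"], m$slope)
  gl <- glance(m)
  expect_equal(gl$nobs, 12L)
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("compound table is tidy, complete and unique-keyed", {
  empty <- assemble_compound_table(NULL)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("compound_id", "E0_c", "pi_system_size", "volume",
                    "logP", "amine_observed") %in% names(empty)))
  one <- assemble_compound_table(tibble::tibble(
    compound_id = "nitrobenzene", pi_system_size = 9,
    E0_c = -0.486, amine_observed = "no"))
  expect_equal(nrow(one), 1)
  expect_true(is.na(one$volume))
  expect_error(assemble_compound_table(tibble::tibble(
    compound_id = c("a", "a"))), "Duplicate")
})
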