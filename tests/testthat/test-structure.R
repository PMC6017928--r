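test_that("an isolated sphere has its closed-form accessible area", {
  a <- tibble::tibble(x = 0, y = 0, z = 0, radius = 1.7)
  out <- sasa(a, probe = 1.4, n_points = 960)
  expect_equal(sum(out$asa), 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)
})

test_that("non-overlapping spheres do not occlude each other", {
  R <- 1.7 + 1.4
  a <- tibble::tibble(x = c(0, 3 * R), y = 0, z = 0, radius = 1.7)
  out <- sasa(a)
  expect_equal(sum(out$asa), 2 * 4 * pi * R^2, tolerance = 1e-9)
})

test_that("overlapping spheres match the spherical-cap closed form", {
  r <- 1.7; p <- 1.4; R <- r + p
  for (d in c(2.0, 3.5, 5.0)) {
    a <- tibble::tibble(x = c(0, d), y = 0, z = 0, radius = r)
    got <- sum(sasa(a, probe = p, n_points = 4000)$asa)
    # each sphere loses a cap of height R - d/2
    exact <- 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
    expect_equal(got, exact, tolerance = 0.005)
  }
})

test_that("sasa converges as the point count grows", {
  dimer <- gen_toy_dimer(n_atoms_per_chain = 20, separation = 6, seed = 8)
  a60 <- sum(sasa(dimer, n_points = 60)$asa)
  a240 <- sum(sasa(dimer, n_points = 240)$asa)
  a960 <- sum(sasa(dimer, n_points = 960)$asa)
  expect_lt(abs(a960 - a240) / a240, abs(a240 - a60) / a60 + 1e-9)
  expect_lt(abs(a960 - a240) / a240, 0.01)
})

test_that("total sasa is invariant under rigid motion", {
  dimer <- gen_toy_dimer(n_atoms_per_chain = 15, seed = 2)
  base <- sum(sasa(dimer, n_points = 2000)$asa)
  th <- 0.7
  rot <- dplyr::mutate(dimer,
    xn = cos(th) * x - sin(th) * y + 5,
    yn = sin(th) * x + cos(th) * y - 2,
    x = xn, y = yn, z = z + 3)
  moved <- sum(sasa(rot, n_points = 2000)$asa)
  # the deterministic lattice is not rotation-symmetric, so agreement is
  # to sampling tolerance, not bitwise
  expect_equal(moved, base, tolerance = 0.01)
})

test_that("sasa agrees with an independent implementation within 2%", {
  dimer <- gen_toy_dimer(n_atoms_per_chain = 25, separation = 7, seed = 5)
  ours <- sum(sasa(dimer, probe = 1.4, n_points = 960)$asa)
  pdb <- tempfile(fileext = ".pdb")
  write_pdb(dimer, pdb)
  oracle <- biotite_sasa(pdb, radii = dimer$radius, probe = 1.4,
                         n_points = 960)
  expect_false(is.na(oracle))
  expect_equal(ours, oracle, tolerance = 0.02)
})

test_that("buried interface is zero for separated chains and symmetric", {
  far <- gen_toy_dimer(n_atoms_per_chain = 10, separation = 40, seed = 3)
  rep_far <- buried_interface(far)
  expect_equal(rep_far$buried, 0, tolerance = 1e-9)
  near <- gen_toy_dimer(n_atoms_per_chain = 15, separation = 5, seed = 3)
  ab <- buried_interface(near, "A", "B")
  ba <- buried_interface(near, "B", "A")
  expect_gt(ab$buried, 0)
  expect_equal(ab$buried, ba$buried, tolerance = 1e-9)
  expect_equal(ab$asa_A, ba$asa_B)
  expect_error(buried_interface(near, "A", "Z"), "not present")
})

test_that("buried area decreases monotonically with separation", {
  buried <- sapply(c(3, 6, 9, 12, 30), function(sep) {
    d <- gen_toy_dimer(n_atoms_per_chain = 12, separation = sep, seed = 6)
    buried_interface(d, n_points = 480)$buried
  })
  expect_true(all(diff(buried) <= 1e-6))
})

test_that("buried-area arithmetic matches the defining formula", {
  expect_equal(buried_area(13200, 13200, 17200), 4600)
  expect_equal(buried_fraction(4600, 13200), 100 * 4600 / 13200)
})

test_that("cpk volume matches sphere and lens closed forms", {
  one <- tibble::tibble(x = 0, y = 0, z = 0, radius = 1.7)
  expect_equal(cpk_volume(one, spacing = 0.15), 4 / 3 * pi * 1.7^3,
               tolerance = 0.01)
  two_far <- tibble::tibble(x = c(0, 10), y = 0, z = 0, radius = 1.7)
  expect_equal(cpk_volume(two_far, spacing = 0.15),
               2 * 4 / 3 * pi * 1.7^3, tolerance = 0.01)
  # overlapping equal spheres: union = 2V - lens,
  # lens = pi (4r + d)(2r - d)^2 / 12
  r <- 1.7; d <- 1.5
  two <- tibble::tibble(x = c(0, d), y = 0, z = 0, radius = r)
  lens <- pi * (4 * r + d) * (2 * r - d)^2 / 12
  expect_equal(cpk_volume(two, spacing = 0.15),
               2 * 4 / 3 * pi * r^3 - lens, tolerance = 0.01)
  expect_error(cpk_volume(one, spacing = 0), "positive")
})

test_that("pdb round trip preserves atoms, chains and coordinates", {
  dimer <- gen_toy_dimer(n_atoms_per_chain = 8, seed = 7)
  path <- tempfile(fileext = ".pdb")
  write_pdb(dimer, path)
  back <- read_structure(path)
  expect_equal(nrow(back), nrow(dimer))
  expect_setequal(unique(back$chain), c("A", "B"))
  expect_equal(sort(back$x), sort(dimer$x), tolerance = 1e-3)
  expect_equal(back$radius, rep(vdw_radius("C"), nrow(dimer)))
})

test_that("structure reading validates degenerate files", {
  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure(empty), "atom|Atom|ATOM|records")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("unknown elements fall back to 1.8 A with a warning", {
  expect_warning(r <- vdw_radius("Xx"), "Unknown")
  expect_equal(r, 1.8)
})
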