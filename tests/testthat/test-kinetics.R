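test_that("initial velocity follows Beer-Lambert on a linear trace", {
  tr <- tibble::tibble(time_s = 0:60, A = 1 - 2.660e-3 * (0:60))
  out <- initial_velocity(tr, epsilon = 2660, enzyme_conc = 1e-7)
  expect_equal(out$velocity, 1.0e-6, tolerance = 1e-9)
  # flat trace gives zero
  flat <- tibble::tibble(time_s = 0:60, A = rep(0.5, 61))
  expect_equal(initial_velocity(flat, 2660, 1e-7)$velocity, 0)
  # fully uncoupled: baseline slope equals the trace slope
  out2 <- initial_velocity(tr, 2660, 1e-7, baseline_slope = -2.660e-3)
  expect_equal(out2$velocity, 0)
  expect_error(initial_velocity(tr, epsilon = 0, enzyme_conc = 1e-7),
               "positive")
  expect_error(initial_velocity(tr[1:3, ], 2660, 1e-7), "points")
})

test_that("curvature guard shrinks the window on a bending trace", {
  t <- 0:99
  tr <- tibble::tibble(time_s = t, A = 1 - 0.01 * t + 4e-4 * t^2)
  out <- initial_velocity(tr, 2660, 1e-7)
  expect_lt(out$n_points, 10)
})

test_that("Michaelis-Menten fit is exact on noise-free data", {
  d <- gen_mm_rates(kcat = 10, KM = 1e-4, E0 = 1e-7, noise = 0, seed = 1)
  f <- fit_michaelis_menten(d)
  expect_equal(f$kcat, 10, tolerance = 1e-6)
  expect_equal(f$KM, 1e-4, tolerance = 1e-6)
  expect_equal(f$kcat_over_KM, f$kcat / f$KM)
  # half-saturation identity on the fitted curve
  v_at_KM <- f$kcat * 1e-7 * f$KM / (f$KM + f$KM)
  expect_equal(v_at_KM, f$kcat * 1e-7 / 2)
})

test_that("MM fit is invariant to row order and unit rescaling", {
  d <- gen_mm_rates(noise = 0.05, seed = 21)
  f1 <- fit_michaelis_menten(d)
  f2 <- fit_michaelis_menten(d[sample(nrow(d)), ])
  expect_equal(f1$kcat, f2$kcat, tolerance = 1e-8)
  expect_equal(f1$KM, f2$KM, tolerance = 1e-8)
  # [S] in mM instead of M: kcat unchanged, KM scales by 1000
  d_mM <- dplyr::mutate(d, substrate_conc = substrate_conc * 1000)
  f3 <- fit_michaelis_menten(d_mM)
  expect_equal(f3$kcat, f1$kcat, tolerance = 1e-6)
  expect_equal(f3$KM, f1$KM * 1000, tolerance = 1e-3)
})

test_that("scaling all velocities scales kcat and leaves KM fixed", {
  d <- gen_mm_rates(noise = 0.05, seed = 22)
  f1 <- fit_michaelis_menten(d)
  f2 <- fit_michaelis_menten(dplyr::mutate(d, velocity = velocity * 3))
  expect_equal(f2$kcat, 3 * f1$kcat, tolerance = 1e-6)
  expect_equal(f2$KM, f1$KM, tolerance = 1e-6)
})

test_that("MM fit recovers kcat within 10% at 5% noise", {
  d <- gen_mm_rates(kcat = 10, KM = 1e-4, noise = 0.05, seed = 42)
  f <- fit_michaelis_menten(d)
  expect_lt(abs(f$kcat - 10) / 10, 0.10)
})

test_that("MM fit rejects degenerate designs", {
  bad <- tibble::tibble(substrate_conc = rep(1e-4, 5),
                        velocity = rep(5e-7, 5), enzyme_conc = 1e-7)
  expect_error(fit_michaelis_menten(bad), "distinct")
})

test_that("Hammett regression returns the generating rho exactly", {
  pts <- gen_hammett_series(rho = 3.1, noise = 0, seed = 1)
  f <- hammett_regression(pts)
  expect_equal(f$rho, 3.1, tolerance = 1e-10)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$mode, "normalized_through_origin")
  # the parent point lies on any through-origin line
  parent <- f$data[f$data$sigma == 0, ]
  expect_equal(parent$log_y, 0)
})

test_that("free-intercept mode recovers slope and intercept", {
  sig <- c(-0.27, 0, 0.23, 0.54, 0.78)
  pts <- tibble::tibble(sigma = sig, Y = 10^(0.5 + 1.0 * sig))
  f <- hammett_regression(pts, mode = "free_intercept")
  expect_equal(f$rho, 1.0, tolerance = 1e-10)
  expect_equal(f$intercept, 0.5, tolerance = 1e-10)
})

test_that("Hammett regression validates its inputs", {
  pts <- gen_hammett_series(noise = 0, seed = 1)
  expect_error(hammett_regression(dplyr::mutate(pts, Y = Y - max(Y))),
               "positive")
  no_parent <- pts[pts$sigma != 0, ]
  expect_error(hammett_regression(no_parent), "parent")
})

test_that("rho recovery at 10% noise is unbiased over 50 replicates", {
  rhos <- sapply(1:50, function(s) {
    hammett_regression(gen_hammett_series(rho = 3.1, noise = 0.1,
                                          seed = 2000 + s))$rho
  })
  expect_lt(abs(mean(rhos) - 3.1), 0.1)
  # spread comparable to an experimental +/- 0.2 report
  expect_lt(stats::sd(rhos), 0.3)
})

test_that("kinetics accessors behave like broom", {
  f <- fit_michaelis_menten(gen_mm_rates(seed = 4))
  expect_equal(tidy(f)$term, c("kcat", "KM", "kcat_over_KM"))
  expect_s3_class(autoplot(f), "ggplot")
  h <- hammett_regression(gen_hammett_series(seed = 4))
  expect_equal(glance(h)$mode, "normalized_through_origin")
  expect_s3_class(autoplot(h), "ggplot")
})

test_that("the shipped sigma table is well-formed", {
  tb <- sigma_para_table()
  expect_true(all(c("substituent", "sigma_para") %in% names(tb)))
  expect_equal(tb$sigma_para[tb$substituent == "H"], 0)
  expect_false(anyDuplicated(tb$substituent) > 0)
})
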