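# Gel quantification, K_D fitting, ATPase turnover.

test_that("fraction product subtracts background and clips", {
  expect_equal(fraction_product(c(substrate = 70, product = 30)), 0.30)
  expect_equal(fraction_product(c(substrate = 80, product = 40), 10), 0.30)
  expect_equal(fraction_product(c(substrate = 50, product = 0)), 0)
  # per-band background, clipped at zero
  expect_equal(fraction_product(c(substrate = 20, p1 = 30, p2 = 2),
                                background = c(0, 10, 5)), 20 / 40)
  expect_error(fraction_product(c(substrate = 5, product = 5), 10),
               "all bands zero")
  expect_error(fraction_product(c(a = 1, b = 2)), "substrate")
  expect_error(fraction_product(c(substrate = 1)), "one product")
})

test_that("fraction product is gain invariant", {
  set.seed(11)
  for (rep in 1:10) {
    bands <- setNames(runif(4, 1, 100), c("substrate", "p1", "p2", "p3"))
    g <- runif(1, 0.1, 50)
    expect_equal(fraction_product(bands), fraction_product(bands * g),
                 tolerance = 1e-12)
  }
})

test_that("Hill fit identifies exact curves and flags bad data", {
  conc <- c(0.5, 1, 2, 5, 10, 20, 50, 100)
  f <- conc / (conc + 10)
  est <- fit_kd(conc, f)
  expect_equal(est$kd_nM, 10, tolerance = 1e-3)
  expect_equal(est$hill_n, 1, tolerance = 1e-3)
  expect_true(est$converged)

  # interpolation mode reads the 50% crossing directly
  est_i <- fit_kd(conc, f, method = "interpolation")
  expect_equal(est_i$kd_nM, 10, tolerance = 0.35)
  expect_true(is.na(est_i$hill_n))

  expect_warning(fit_kd(conc, 0.3 * conc / (conc + 10)), "never cross")
  expect_error(fit_kd(conc[1:3], f[1:3]), ">= 4")
  expect_error(fit_kd(conc, f + 2), "\\[0, 1\\]")
})

test_that("Hill fit recovers K and n from seeded noisy curves", {
  conc <- c(0.25, 0.5, 1, 2.5, 5, 10, 25, 50, 100, 250)
  for (seed in 1:5) {
    curve <- simulate_binding_assay(10, 1, conc, noise_sd = 0.03,
                                    seed = seed)
    est <- fit_kd(curve$concentration_nM, curve$fraction)
    expect_lt(abs(est$kd_nM - 10) / 10, 0.10)
    expect_lt(abs(est$hill_n - 1) / 1, 0.20)
  }
})

test_that("ATPase turnover reproduces the closed-form arithmetic", {
  t <- 0:59
  a <- 0.9 - 6.22e-3 * t
  res <- atpase_kcat(t, a, enzyme_M = 1e-9)
  expect_equal(res$slope_abs_per_s, -6.22e-3, tolerance = 1e-12)
  expect_equal(res$nadh_rate_M_per_s, 1e-6, tolerance = 1e-12)
  expect_equal(res$kcat_per_s, 1000, tolerance = 1e-9)

  # zero slope -> zero kcat; doubling [E] at fixed slope halves kcat
  flat <- atpase_kcat(t, rep(0.9, 60), enzyme_M = 1e-9)
  expect_equal(flat$kcat_per_s, 0)
  res2 <- atpase_kcat(t, a, enzyme_M = 2e-9)
  expect_equal(res2$kcat_per_s, res$kcat_per_s / 2, tolerance = 1e-12)

  expect_warning(atpase_kcat(t, 0.1 + 6.22e-3 * t, enzyme_M = 1e-9),
                 "rising")
  expect_error(atpase_kcat(t, a, enzyme_M = 0), "> 0")
  expect_error(atpase_kcat(t[1:5], a[1:5], enzyme_M = 1e-9), ">= 10")
  # window selection restricts the fitted range
  bent <- c(0.9 - 6.22e-3 * (0:29), rep(0.9 - 6.22e-3 * 29, 30))
  win <- atpase_kcat(t, bent, enzyme_M = 1e-9, window = c(0, 29))
  expect_equal(win$slope_abs_per_s, -6.22e-3, tolerance = 1e-9)
})

test_that("simulated time courses round trip through the estimator", {
  sim <- simulate_atpase_timecourse(500, 1e-9, duration_s = 200, seed = 3,
                                    noise_sd = 0.001)
  res <- atpase_kcat(sim$time_s, sim$absorbance, enzyme_M = 1e-9)
  expect_lt(abs(res$kcat_per_s - 500) / 500, 0.05)
  flat <- simulate_atpase_timecourse(0, 1e-9, duration_s = 50, seed = 3,
                                     noise_sd = 0)
  expect_true(all(flat$absorbance == flat$absorbance[1]))
  a <- simulate_atpase_timecourse(100, 1e-9, seed = 4)
  b <- simulate_atpase_timecourse(100, 1e-9, seed = 4)
  expect_identical(a$absorbance, b$absorbance)
})

test_that("binding simulation hits its anchors", {
  conc <- c(0, 1, 10, 100)
  curve <- simulate_binding_assay(10, 2, conc, noise_sd = 0, seed = 1)
  expect_equal(curve$fraction[conc == 10], 0.5)
  expect_equal(curve$fraction[conc == 0], 0)
  expect_true(all(curve$fraction >= 0 & curve$fraction <= 1))
})
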