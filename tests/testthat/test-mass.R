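# Mass photometry: calibration, mixture fitting, species assignment.

test_that("contrast calibration recovers exact and noisy lines", {
  cal <- calibrate_contrast(c(1, 2, 4), c(100, 200, 400))
  expect_equal(cal$slope_kDa_per_contrast, 100, tolerance = 1e-10)
  expect_equal(cal$intercept_kDa, 0, tolerance = 1e-8)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)

  expect_error(calibrate_contrast(c(1, 1.1), c(100, 100)), "2 distinct")

  # noisy landings around 3 standards: slope within 5% of generating slope
  sim <- simulate_mass_events(
    data.frame(mass = 300, weight = 1, sd = 30), n = 50, seed = 5,
    slope_kDa_per_contrast = 1200, intercept_kDa = 10,
    standard_masses_kDa = c(66, 146, 480), n_per_standard = 60,
    standard_noise_kDa = 8)
  cal2 <- calibrate_contrast(sim$standards$contrast,
                             sim$standards$standard_mass_kDa)
  expect_lt(abs(cal2$slope_kDa_per_contrast - 1200) / 1200, 0.05)
})

test_that("contrast/mass conversion is an exact affine round trip", {
  ev <- mass_event_set(c(0, 0.1, 0.25))
  ident <- structure(list(slope_kDa_per_contrast = 1, intercept_kDa = 0),
                     class = "mass_calibration")
  expect_equal(contrasts_to_masses(ev, ident)$masses_kDa, ev$contrasts)

  cal <- calibrate_contrast(c(1, 2, 4), c(130, 230, 430))
  masses <- contrasts_to_masses(ev, cal)$masses_kDa
  back <- (masses - cal$intercept_kDa) / cal$slope_kDa_per_contrast
  expect_equal(back, ev$contrasts, tolerance = 1e-12)
  expect_equal(contrasts_to_masses(mass_event_set(0), cal)$masses_kDa,
               cal$intercept_kDa)
})

test_that("the mixture fit recovers single and double Gaussians", {
  set.seed(41)
  x1 <- rnorm(400, 150, 20)
  p1 <- fit_mass_peaks(x1, k = 1)
  expect_equal(p1$mean_kDa, mean(x1), tolerance = 1e-6)
  expect_equal(p1$sd_kDa, sd(x1) * sqrt(399 / 400), tolerance = 1e-4)
  expect_equal(p1$weight, 1)

  # auto-k prefers one component for single-Gaussian data
  auto <- fit_mass_peaks(x1, k = "auto", k_max = 3)
  expect_identical(attr(auto, "k"), 1L)

  # EM diagnostics: weights sum to one, log-likelihood non-decreasing
  x2 <- c(rnorm(600, 115, 27), rnorm(600, 302, 67))
  p2 <- fit_mass_peaks(x2, k = 2)
  expect_equal(sum(p2$weight), 1, tolerance = 1e-6)
  expect_true(all(diff(attr(p2, "ll_trace")) > -1e-8))
  expect_equal(p2$mean_kDa, c(115, 302), tolerance = 0.05)

  expect_error(fit_mass_peaks(rnorm(80), k = 2), ">= 50 events")
})

test_that("species assignment is exhaustive subset-sum with tie-breaking", {
  comp <- c(RPA = 114, Dna2 = 172, DNA = 25)
  peaks <- data.frame(mean_kDa = c(302, 115, 999), sd_kDa = c(67, 27, 10))

  asg <- assign_species(peaks, comp, tolerance_kDa = c(20, 10, 10))
  expect_setequal(asg[[1]]$components, c("RPA", "Dna2", "DNA"))
  expect_equal(asg[[1]]$theoretical_sum_kDa, 311)
  expect_equal(asg[[1]]$deviation_kDa, 9)
  expect_identical(asg[[2]]$components, "RPA")
  expect_false(asg[[3]]$assigned)
  expect_identical(asg[[3]]$components, character(0))

  # ties go to fewer components: 114 = A exactly = B + C exactly
  tie <- assign_species(data.frame(mean_kDa = 114, sd_kDa = 5),
                        c(A = 114, B = 60, C = 54))
  expect_identical(tie[[1]]$components, "A")

  # brute-force property: best subset truly minimizes |mean - sum|
  set.seed(8)
  for (rep in 1:5) {
    m <- sample(2:8, 1)
    comp_r <- setNames(runif(m, 10, 200), paste0("c", 1:m))
    target <- runif(1, 10, sum(comp_r))
    a <- assign_species(data.frame(mean_kDa = target, sd_kDa = 1e6),
                        comp_r)[[1]]
    subsets <- as.matrix(expand.grid(rep(list(0:1), m)))[-1, , drop = FALSE]
    best_dev <- min(abs(target - as.numeric(subsets %*% comp_r)))
    expect_equal(a$deviation_kDa, best_dev, tolerance = 1e-9)
  }

  expect_error(assign_species(peaks, numeric(0)), "non-empty")
  expect_error(assign_species(peaks, c(1, 2)), "named")
})

test_that("mass event simulation is deterministic and well mixed", {
  comp <- data.frame(mass = c(115, 302), weight = c(0.5, 0.5),
                     sd = c(27, 67))
  a <- simulate_mass_events(comp, n = 2000, seed = 13)
  b <- simulate_mass_events(comp, n = 2000, seed = 13)
  expect_identical(a$events$contrasts, b$events$contrasts)

  # mixture fraction recovered within binomial error at n = 2000
  frac <- mean(a$truth$component == 1)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))

  # degenerate single component collapses to a point mass
  pt <- simulate_mass_events(data.frame(mass = 200, weight = 1, sd = 0),
                             n = 50, seed = 2)
  expect_true(all(pt$events$contrasts == pt$events$contrasts[1]))

  expect_error(simulate_mass_events(
    data.frame(mass = 1, weight = 0.7, sd = 1), n = 10, seed = 1),
    "sum to 1")
})
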