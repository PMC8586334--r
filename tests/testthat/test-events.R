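# Event detection, survival curves, force calibration, condition pooling.

test_that("event detection finds staircase rises", {
  # one monotone rise of 2300 bp
  tr <- make_phase_trace(list(list(duration = 52, velocity = 2300 / 52)))
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$processivity_bp, 2300, tolerance = 1)

  # two rises (500 then 1000 bp) separated by a plateau and a drop
  tr2 <- make_phase_trace(list(
    list(duration = 12, velocity = 500 / 12),
    list(duration = 15, velocity = 0),
    list(duration = 3, velocity = -50),
    list(duration = 25, velocity = 1000 / 25),
    list(duration = 10, velocity = 0)))
  ev2 <- detect_events(tr2)
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$processivity_bp, c(500, 1000), tolerance = 2)
  # time-ordered, non-overlapping
  expect_true(all(diff(ev2$t_start_s) > 0))
  expect_lt(ev2$t_end_s[1], ev2$t_start_s[2])

  # flat trace: nothing
  flat <- unwinding_trace((1:300) / 30, rep(3, 300))
  expect_equal(nrow(detect_events(flat)), 0L)

  expect_error(detect_events(tr, min_processivity_bp = 0), "> 0")
})

test_that("event detection tolerates realistic bead noise", {
  set.seed(99)
  tr <- make_phase_trace(list(
    list(duration = 30, velocity = 44),
    list(duration = 60, velocity = 0),
    list(duration = 50, velocity = 44),
    list(duration = 20, velocity = 0)))
  noisy <- unwinding_trace(tr$time_s, tr$unwound_bp + rnorm(nrow(tr), 0, 32))
  ev <- detect_events(noisy)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$processivity_bp, c(30 * 44, 50 * 44), tolerance = 0.12)
})

test_that("survival curves are exceedance fractions", {
  s1 <- survival_probability(5)
  expect_equal(s1$fn(4.9), 1)
  expect_equal(s1$fn(5), 0)

  s2 <- survival_probability(c(1, 2, 3, 4))
  expect_equal(s2$fn(2.5), 0.5)
  expect_equal(s2$p, c(0.75, 0.5, 0.25, 0))

  expect_error(survival_probability(numeric(0)), "at least one")
  expect_error(survival_probability(c(1, NA)), "finite")
})

test_that("survival is non-increasing and integrates to the mean", {
  set.seed(3)
  for (rep in 1:10) {
    vals <- rexp(sample(3:50, 1), 1 / 2000)
    s <- survival_probability(vals)
    expect_true(all(diff(s$p) <= 0))
    expect_equal(s$fn(min(vals) - 1e-9), 1)
    expect_equal(s$fn(max(vals)), 0)
    # integral of S over [0, max] = sample mean for non-negative values
    auc <- s$x[1] * 1 + sum(diff(s$x) * s$p[-length(s$p)])
    expect_equal(auc, mean(vals), tolerance = 1e-9)
  }
})

test_that("equipartition force calibration matches the closed form", {
  # construct a series whose unbiased variance is exactly 1645.6 nm^2
  x <- c(-1, 1) * sqrt(1645.6 / 2)
  series <- rep(x, 50)  # n = 100, mean 0, var = 1645.6 * 100/99
  v <- var(series)
  expect_equal(calibrate_force_variance(series, 2000, 4.114),
               4.114 * 2000 / v, tolerance = 1e-12)
  expect_equal(4.114 * 2000 / 1645.6, 5.0, tolerance = 1e-3)

  # doubling the variance halves the force
  expect_equal(calibrate_force_variance(series * sqrt(2), 2000, 4.114),
               calibrate_force_variance(series, 2000, 4.114) / 2,
               tolerance = 1e-12)

  expect_error(calibrate_force_variance(rnorm(50), 2000), ">= 100")
  expect_error(calibrate_force_variance(rep(1, 200), 2000), "zero variance")
  expect_error(calibrate_force_variance(rnorm(200), -5), "> 0")
})

test_that("force calibration recovers a simulated force within 5%", {
  x <- simulate_transverse_fluctuations(5, 2000, n = 1e4, seed = 17,
                                        kBT_pN_nm = 4.114)
  f <- calibrate_force_variance(x, 2000, 4.114)
  expect_lt(abs(f - 5) / 5, 0.05)
})

test_that("condition pooling summarizes fragments and events", {
  t <- (1:200) / 30
  tr <- unwinding_trace(t, 44 * t)
  sm <- analyze_condition(list(tr), penalty = 10)
  expect_identical(sm$n_fragments, 1L)
  expect_true(is.na(sm$sem_velocity))
  expect_equal(sm$mean_velocity_bp_per_s, 44, tolerance = 1e-9)
  expect_error(analyze_condition(list()), "at least one")
})
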