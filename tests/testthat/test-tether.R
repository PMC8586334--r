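# Polymer elasticity models and extension <-> bp conversion.

test_that("polymer_params validates and derives kBT", {
  p <- polymer_params()
  expect_equal(p$kBT_pN_nm, 0.0138064852 * 298, tolerance = 1e-12)
  expect_error(polymer_params(ds_persistence_nm = -1), "must be > 0")
  expect_error(polymer_params(kBT_pN_nm = 5), "inconsistent")
  # consistent explicit kBT is accepted
  expect_silent(polymer_params(kBT_pN_nm = 4.114))
})

test_that("ds relative extension solves the Marko-Siggia interpolation", {
  p <- polymer_params(kBT_pN_nm = 4.114)
  expect_identical(ds_relative_extension(0, p), 0)
  # closed form: at F*P/kBT = 1.25 the forward formula gives r = 0.5 exactly
  f_half <- 1.25 * p$kBT_pN_nm / p$ds_persistence_nm
  expect_equal(ds_relative_extension(f_half, p), 0.5, tolerance = 1e-10)
  # at 10 pN, r ~ 0.952; verify by substituting the root back
  r10 <- ds_relative_extension(10, p)
  expect_equal(r10, 0.952, tolerance = 1e-3)
  forward <- p$kBT_pN_nm / p$ds_persistence_nm *
    (1 / (4 * (1 - r10)^2) - 0.25 + r10)
  expect_equal(forward, 10, tolerance = 1e-8)
  expect_error(ds_relative_extension(-1, p), ">= 0")
  expect_error(ds_relative_extension(NaN, p), "finite")
})

test_that("ss relative extension is the Langevin function", {
  p <- polymer_params(kBT_pN_nm = 4.114)
  expect_identical(ss_relative_extension(0, p), 0)
  f1 <- p$kBT_pN_nm / p$ss_kuhn_nm  # Fb/kBT = 1
  expect_equal(ss_relative_extension(f1, p), 1 / tanh(1) - 1,
               tolerance = 1e-12)
  # high-force asymptote: r(100 kBT/b) = 0.99 exactly, then climbs past it
  expect_gte(ss_relative_extension(100 * f1, p), 0.99 - 1e-12)
  expect_gt(ss_relative_extension(200 * f1, p), 0.99)
  expect_error(ss_relative_extension(-0.1, p), ">= 0")
})

test_that("both extension models increase strictly on a 0-60 pN grid", {
  p <- polymer_params()
  grid <- seq(0, 60, by = 0.5)
  expect_true(all(diff(ds_relative_extension(grid, p)) > 0))
  expect_true(all(diff(ss_relative_extension(grid, p)) > 0))
})

test_that("bp step signal has the expected limits and a sign crossover", {
  p <- polymer_params()
  expect_identical(bp_step_signal_nm(0, p), 0)
  # low force: collapsed ssDNA shorter than duplex; high force: longer
  expect_lt(bp_step_signal_nm(0.5, p), 0)
  expect_gt(bp_step_signal_nm(20, p), 0)
  root <- uniroot(function(f) bp_step_signal_nm(f, p), c(0.01, 20))$root
  expect_gt(root, 0)
  expect_lt(root, 20)
  # degenerate geometry: no nucleotides gained per bp
  p0 <- polymer_params(nt_gained_per_bp = 1e-12)
  expect_equal(bp_step_signal_nm(10, p0),
               -p$ds_rise_nm_per_bp * ds_relative_extension(10, p),
               tolerance = 1e-9)
})

test_that("extension to bp conversion inverts the forward model", {
  p <- polymer_params()
  f <- 20
  delta <- bp_step_signal_nm(f, p)
  baseline <- 2000
  n_true <- c(0, cumsum(abs(rnorm(199, 1, 0.3))))
  t <- (0:199) / 30
  traj <- bead_trajectory(t + 1 / 30, baseline + delta * n_true,
                          force_pN = f)
  tr <- extension_to_unwound_bp(traj, p, baseline_nm = baseline)
  expect_equal(tr$unwound_bp, n_true, tolerance = 1e-9)
  expect_equal(tr$time_s, traj$time_s)

  # flat trace at baseline -> identically zero
  traj0 <- bead_trajectory(t + 1 / 30, rep(baseline, 200), force_pN = f)
  expect_true(all(extension_to_unwound_bp(traj0, p, baseline)$unwound_bp == 0))

  # below the crossover delta < 0: decreasing extension = increasing bp
  f_low <- 0.5
  d_low <- bp_step_signal_nm(f_low, p)
  expect_lt(d_low, 0)
  traj_low <- bead_trajectory(t + 1 / 30, baseline + d_low * n_true,
                              force_pN = f_low)
  tr_low <- extension_to_unwound_bp(traj_low, p, baseline)
  expect_true(all(diff(tr_low$unwound_bp) >= -1e-9))

  # near the crossover the conversion is degenerate
  root <- uniroot(function(ff) bp_step_signal_nm(ff, p), c(0.01, 20))$root
  traj_deg <- bead_trajectory(t + 1 / 30, rep(baseline, 200),
                              force_pN = root)
  expect_error(extension_to_unwound_bp(traj_deg, p, baseline), "degenerate")
  expect_error(extension_to_unwound_bp(traj0, p, baseline,
                                       delta_tol_nm = 1), "degenerate")
})

test_that("baseline extension combines duplex, flap and handle terms", {
  p <- polymer_params()
  g <- tether_geometry(ds_bp_total = 6600, flap_nt = 40,
                       handle_contribution_nm = 100)
  b <- baseline_extension_nm(20, p, g)
  expect_equal(b, 100 +
                 6600 * p$ds_rise_nm_per_bp * ds_relative_extension(20, p) +
                 40 * p$ss_contour_nm_per_nt * ss_relative_extension(20, p),
               tolerance = 1e-12)
})
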