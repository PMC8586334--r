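# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth, so all stages are testable without
# raw recordings. All generators are pure functions of (config, seed): the
# top-level seed drives a single RNG stream that is saved and restored.

#' Simulation configuration for unwinding experiments
#'
#' Defaults mirror the experimental conditions the analyses assume: a
#' 6.6-kbp nicked-flap tether sampled at 30 Hz, stochastic single-enzyme
#' unwinding at 44 bp/s with mean processivity 2300 bp (the helicase-mimic
#' scenario; simulation defaults, not ground truth of any real recording),
#' sparse long pauses, detachment with geometric per-step probability, and
#' Poisson re-initiation.
#'
#' @param seed integer seed (mandatory).
#' @param n_traces number of traces for condition-level simulations.
#' @param frame_rate_hz camera frame rate in Hz (default 30).
#' @param duration_s trace duration in seconds (default 300, long relative
#'   to the ~52 s mean event duration so completed events are not
#'   length-biased).
#' @param force_pN applied stretching force in pN (default 20).
#' @param velocity_bp_per_s stepping rate in bp/s (default 44).
#' @param mean_processivity_bp mean bp unwound per event (default 2300);
#'   per-step detachment probability is `1/mean_processivity_bp`.
#' @param pause_entry_per_s pause entry rate during active unwinding
#'   (default 0.005 /s).
#' @param pause_exit_per_s pause exit rate (default 0.5 /s, mean pause 2 s).
#' @param reinitiation_per_s re-initiation rate after detachment
#'   (default 0.01 /s, mean idle 100 s: new loading events are rare at
#'   nanomolar enzyme).
#' @param noise_sd_nm Gaussian bead noise per frame in nm (default 5).
#' @param drift_nm_per_s linear drift in nm/s (default 0).
#' @param polymer a [polymer_params()] object.
#' @param geometry a [tether_geometry()] object.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed, n_traces = 25L, frame_rate_hz = 30,
                       duration_s = 300, force_pN = 20,
                       velocity_bp_per_s = 44, mean_processivity_bp = 2300,
                       pause_entry_per_s = 0.005, pause_exit_per_s = 0.5,
                       reinitiation_per_s = 0.01, noise_sd_nm = 5,
                       drift_nm_per_s = 0, polymer = polymer_params(),
                       geometry = tether_geometry()) {
  if (missing(seed)) stop_input("seed is mandatory")
  check_scalar(seed, "seed")
  check_scalar(n_traces, "n_traces", positive = TRUE)
  check_scalar(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(force_pN, "force_pN", nonneg = TRUE)
  check_scalar(velocity_bp_per_s, "velocity_bp_per_s", positive = TRUE)
  check_scalar(mean_processivity_bp, "mean_processivity_bp", positive = TRUE)
  check_scalar(pause_entry_per_s, "pause_entry_per_s", nonneg = TRUE)
  check_scalar(pause_exit_per_s, "pause_exit_per_s", nonneg = TRUE)
  check_scalar(reinitiation_per_s, "reinitiation_per_s", nonneg = TRUE)
  check_scalar(noise_sd_nm, "noise_sd_nm", nonneg = TRUE)
  check_scalar(drift_nm_per_s, "drift_nm_per_s")
  stopifnot(inherits(polymer, "polymer_params"),
            inherits(geometry, "tether_geometry"))
  structure(as.list(environment()), class = "sim_config")
}

# one trace, consuming the active RNG stream (no seeding here)
.sim_one_trace <- function(cfg, label = "sim") {
  v <- cfg$velocity_bp_per_s
  q <- 1 / cfg$mean_processivity_bp
  duration <- cfg$duration_s
  total_bp <- cfg$geometry$ds_bp_total

  step_times <- numeric(0)
  events <- list()
  pauses <- list()
  t_cursor <- 0
  n_total <- 0

  repeat {
    if (n_total >= total_bp || t_cursor >= duration) break
    remaining <- total_bp - n_total
    L_drawn <- stats::rgeom(1, q) + 1L
    capped <- L_drawn > remaining
    L <- min(L_drawn, remaining)

    dts <- stats::rexp(L, rate = v)
    active_cum <- cumsum(dts)
    T_act <- active_cum[L]

    # pauses thinned onto active time (processivity independent of pausing)
    n_pause <- if (cfg$pause_entry_per_s > 0 && cfg$pause_exit_per_s > 0) {
      stats::rpois(1, cfg$pause_entry_per_s * T_act)
    } else 0L
    if (n_pause > 0L) {
      pause_at <- sort(stats::runif(n_pause, 0, T_act))
      pause_dur <- stats::rexp(n_pause, rate = cfg$pause_exit_per_s)
      offset <- c(0, cumsum(pause_dur))[findInterval(active_cum, pause_at) + 1L]
      pause_abs <- t_cursor + pause_at +
        c(0, cumsum(pause_dur))[seq_len(n_pause)]
      pauses[[length(pauses) + 1L]] <-
        data.frame(t_start_s = pause_abs, duration_s = pause_dur)
    } else {
      offset <- rep(0, L)
    }
    st <- t_cursor + active_cum + offset

    emitted <- sum(st <= duration)
    censored <- emitted < L
    st <- st[seq_len(emitted)]
    step_times <- c(step_times, st)
    n_total <- n_total + emitted
    t_end <- if (emitted > 0L) st[emitted] else t_cursor
    events[[length(events) + 1L]] <- data.frame(
      t_start_s = t_cursor,
      t_end_s = if (censored) duration else t_end,
      processivity_bp = emitted,
      completed = !censored && !capped,
      capped = capped
    )
    if (censored) break
    t_cursor <- t_end
    if (capped) break
    if (cfg$reinitiation_per_s <= 0) break
    t_cursor <- t_cursor + stats::rexp(1, rate = cfg$reinitiation_per_s)
  }

  events <- if (length(events)) do.call(rbind, events) else
    data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
               processivity_bp = numeric(0), completed = logical(0),
               capped = logical(0))
  pauses <- if (length(pauses)) do.call(rbind, pauses) else
    data.frame(t_start_s = numeric(0), duration_s = numeric(0))

  # camera frames: boxcar (within-frame) average of the step staircase
  dt <- 1 / cfg$frame_rate_hz
  n_frames <- floor(duration / dt)
  edges <- (0:n_frames) * dt
  st_sorted <- sort(step_times)
  cum_st <- c(0, cumsum(st_sorted))
  area_at <- function(e) {
    cnt <- findInterval(e, st_sorted)
    cnt * e - cum_st[cnt + 1L]
  }
  A <- area_at(edges)
  n_avg <- diff(A) / dt
  t_frame <- edges[-1] - dt / 2  # frame midpoints

  delta <- bp_step_signal_nm(cfg$force_pN, cfg$polymer)
  baseline <- baseline_extension_nm(cfg$force_pN, cfg$polymer, cfg$geometry)
  ext <- baseline + delta * n_avg + cfg$drift_nm_per_s * t_frame +
    stats::rnorm(n_frames, 0, cfg$noise_sd_nm)

  traj <- bead_trajectory(
    time_s = t_frame, extension_nm = ext,
    force_pN = cfg$force_pN, label = label)
  truth <- list(
    n_frame = n_avg,
    step_times_s = st_sorted,
    events = events,
    pauses = pauses,
    force_pN = cfg$force_pN,
    baseline_nm = baseline,
    delta_nm_per_bp = delta,
    velocity_bp_per_s = v,
    mean_processivity_bp = cfg$mean_processivity_bp
  )
  list(trajectory = traj, truth = truth)
}

#' Simulate one unwinding trajectory
#'
#' Continuous-time simulation of a single enzyme on the nicked-flap tether:
#' 1-bp steps at the stepping rate, geometric per-step detachment
#' (processivity approximately exponential and independent of pausing),
#' Poisson pause entry/exit during active unwinding, re-initiation after
#' detachment capped at the remaining duplex. The cumulative unwound count
#' (non-decreasing; unwound DNA does not re-anneal) is mapped to extension
#' through the tether model, box-car averaged per camera frame, and Gaussian
#' noise plus linear drift are added.
#'
#' @param cfg a [sim_config()]; `cfg$seed` seeds the draw.
#' @return a list with `trajectory` (a [bead_trajectory()]) and `truth`
#'   (frame-averaged true unwound bp, step times, event table with
#'   `completed`/`capped` flags, pause intervals, and the generating
#'   parameters).
#' @export
simulate_unwinding_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, .sim_one_trace(cfg))
}

#' Simulate a full condition (multiple traces, one seed)
#'
#' Draws `cfg$n_traces` trajectories from a single RNG stream seeded once
#' with `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a list of `cfg$n_traces` elements, each as returned by
#'   [simulate_unwinding_trajectory()].
#' @export
simulate_unwinding_condition <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, lapply(seq_len(cfg$n_traces), function(i) {
    .sim_one_trace(cfg, label = sprintf("sim_%03d", i))
  }))
}

#' Simulate transverse bead fluctuations
#'
#' Equipartition fluctuations of the transverse bead coordinate: i.i.d.
#' Gaussian with variance `kBT * L / F`, or an Ornstein-Uhlenbeck process
#' with the same stationary variance and a specified corner frequency.
#'
#' @param force_pN applied force in pN (> 0).
#' @param tether_length_nm tether extension in nm.
#' @param n number of samples.
#' @param seed integer seed.
#' @param kBT_pN_nm thermal energy in pN nm (default 4.114).
#' @param model `"iid"` (default) or `"ou"`.
#' @param corner_hz OU corner frequency in Hz (for `model = "ou"`).
#' @param frame_rate_hz sampling rate for the OU model (default 30).
#' @return numeric vector of transverse positions in nm.
#' @export
simulate_transverse_fluctuations <- function(force_pN, tether_length_nm, n,
                                             seed, kBT_pN_nm = 4.114,
                                             model = c("iid", "ou"),
                                             corner_hz = 3,
                                             frame_rate_hz = 30) {
  model <- match.arg(model)
  check_scalar(force_pN, "force_pN", positive = TRUE)
  check_scalar(tether_length_nm, "tether_length_nm", positive = TRUE)
  s2 <- kBT_pN_nm * tether_length_nm / force_pN
  with_seed(seed, {
    if (model == "iid") {
      stats::rnorm(n, 0, sqrt(s2))
    } else {
      phi <- exp(-2 * pi * corner_hz / frame_rate_hz)
      x <- numeric(n)
      x[1] <- stats::rnorm(1, 0, sqrt(s2))
      innov <- stats::rnorm(n - 1, 0, sqrt(s2 * (1 - phi^2)))
      for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i - 1]
      x
    }
  })
}

#' Simulate mass-photometry landings and calibration standards
#'
#' Draws event masses from a Gaussian mixture, converts them to contrasts by
#' the inverse of the supplied calibration line, and also emits synthetic
#' standard landings for [calibrate_contrast()].
#'
#' @param components data.frame with columns `mass`, `weight`, `sd` (weights
#'   must sum to 1).
#' @param n number of sample landings.
#' @param seed integer seed.
#' @param slope_kDa_per_contrast,intercept_kDa the generating calibration
#'   line (defaults 1000 and 0).
#' @param standard_masses_kDa masses of the size-marker standards in kDa
#'   (default: NativeMark-like 66, 146, 480, 1048).
#' @param n_per_standard landings per standard (default 100).
#' @param standard_noise_kDa Gaussian mass spread of each standard peak
#'   (default 0: noiseless standards).
#' @return a list with `events` (a [mass_event_set()] of contrasts),
#'   `standards` (data.frame `contrast`, `standard_mass_kDa`), and `truth`.
#' @export
simulate_mass_events <- function(components, n, seed,
                                 slope_kDa_per_contrast = 1000,
                                 intercept_kDa = 0,
                                 standard_masses_kDa = c(66, 146, 480, 1048),
                                 n_per_standard = 100L,
                                 standard_noise_kDa = 0) {
  stopifnot(is.data.frame(components),
            all(c("mass", "weight", "sd") %in% names(components)))
  if (abs(sum(components$weight) - 1) > 1e-9) {
    stop_input("component weights must sum to 1")
  }
  check_scalar(slope_kDa_per_contrast, "slope_kDa_per_contrast")
  if (slope_kDa_per_contrast == 0) stop_input("slope must be nonzero")
  to_contrast <- function(mass) (mass - intercept_kDa) / slope_kDa_per_contrast
  with_seed(seed, {
    comp <- sample.int(nrow(components), n, replace = TRUE,
                       prob = components$weight)
    masses <- stats::rnorm(n, components$mass[comp], components$sd[comp])
    std <- data.frame(
      contrast = to_contrast(
        rep(standard_masses_kDa, each = n_per_standard) +
          stats::rnorm(length(standard_masses_kDa) * n_per_standard, 0,
                       standard_noise_kDa)),
      standard_mass_kDa = rep(standard_masses_kDa, each = n_per_standard)
    )
    list(
      events = mass_event_set(to_contrast(masses), condition = "sim"),
      standards = std,
      truth = list(component = comp, masses_kDa = masses,
                   slope_kDa_per_contrast = slope_kDa_per_contrast,
                   intercept_kDa = intercept_kDa)
    )
  })
}

#' Simulate a binding titration
#'
#' Hill curve `f = c^n / (c^n + K^n)` with truncated Gaussian noise, clipped
#' to `[0, 1]`.
#'
#' @param K_nM generating K_D in nM (> 0).
#' @param hill_n generating Hill coefficient.
#' @param concentrations_nM titration concentrations in nM.
#' @param noise_sd Gaussian noise sd on the fraction (default 0.03).
#' @param seed integer seed.
#' @return a data.frame `concentration_nM`, `fraction` with attribute
#'   `truth`.
#' @export
simulate_binding_assay <- function(K_nM, hill_n, concentrations_nM,
                                   noise_sd = 0.03, seed = 1L) {
  check_scalar(K_nM, "K_nM", positive = TRUE)
  check_scalar(hill_n, "hill_n", positive = TRUE)
  f0 <- ifelse(concentrations_nM == 0, 0,
               concentrations_nM^hill_n /
                 (concentrations_nM^hill_n + K_nM^hill_n))
  with_seed(seed, {
    f <- pmin(pmax(f0 + stats::rnorm(length(f0), 0, noise_sd), 0), 1)
    structure(
      data.frame(concentration_nM = concentrations_nM, fraction = f),
      truth = list(K_nM = K_nM, hill_n = hill_n, fraction_true = f0))
  })
}

#' Simulate a coupled-ATPase absorbance time course
#'
#' Linear NADH decay `A(t) = A0 - kcat * [E] * epsilon * path * t` plus
#' Gaussian noise, floored at 0.
#'
#' @param kcat_per_s apparent turnover in 1/s.
#' @param enzyme_M enzyme concentration in M.
#' @param duration_s duration in seconds (default 300).
#' @param dt_s sampling interval in seconds (default 1).
#' @param seed integer seed.
#' @param epsilon_M_cm extinction coefficient (default 6220).
#' @param path_cm path length in cm (default 1).
#' @param A0 initial absorbance (default 0.9).
#' @param noise_sd absorbance noise sd (default 0.002).
#' @return a data.frame `time_s`, `absorbance` with attribute `truth`.
#' @export
simulate_atpase_timecourse <- function(kcat_per_s, enzyme_M,
                                       duration_s = 300, dt_s = 1, seed = 1L,
                                       epsilon_M_cm = 6220, path_cm = 1,
                                       A0 = 0.9, noise_sd = 0.002) {
  check_scalar(kcat_per_s, "kcat_per_s", nonneg = TRUE)
  check_scalar(enzyme_M, "enzyme_M", positive = TRUE)
  t <- seq(0, duration_s, by = dt_s)
  slope <- -kcat_per_s * enzyme_M * epsilon_M_cm * path_cm
  with_seed(seed, {
    a <- pmax(A0 + slope * t + stats::rnorm(length(t), 0, noise_sd), 0)
    structure(data.frame(time_s = t, absorbance = a),
              truth = list(slope_abs_per_s = slope, kcat_per_s = kcat_per_s))
  })
}
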