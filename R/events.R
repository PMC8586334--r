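# Unwinding event detection, processivity survival curves, and
# fluctuation-based force calibration.

#' Detect unwinding events in a trace
#'
#' Events are maximal rises of the median-smoothed trace: runs where the
#' local slope (lag difference over `slope_lag_s`) exceeds the
#' moving/stationary threshold, merged across gaps shorter than
#' `merge_gap_s` so pauses inside an event do not split it, and kept when
#' the total rise reaches `min_processivity_bp`. On a noiseless staircase
#' this is exactly the maximal run from a local minimum to the next local
#' maximum; under bead noise the threshold is raised to
#' `max(pause_threshold, 4 * sigma_slope)` where `sigma_slope` is the noise
#' floor of the slope estimate, propagated from the robust per-frame noise
#' (`mad(diff)/sqrt(2)`) through the median filter and the lag difference —
#' otherwise stationary noise constantly crosses a few-bp/s threshold.
#'
#' @param trace an [unwinding_trace()].
#' @param min_processivity_bp minimum rise to count as an event (default 100,
#'   must be > 0).
#' @param smoothing_window running-median window in samples (default 15,
#'   i.e. 0.5 s at 30 Hz); rounded up to odd.
#' @param pause_threshold_bp_per_s slope below which the enzyme is considered
#'   stationary (default 5 bp/s); floor of the adaptive threshold.
#' @param slope_lag_s lag over which the local slope is measured
#'   (default 3 s).
#' @param merge_gap_s moving runs separated by less than this are merged;
#'   choose it above typical pause durations and below typical idle times
#'   between events (default 8 s).
#' @return a `data.frame` of class `unwinding_events` with columns
#'   `t_start_s`, `t_end_s`, `processivity_bp`, `i_start`, `i_end` (0-based,
#'   half-open), time-ordered and non-overlapping. Zero rows when no event
#'   qualifies.
#' @export
detect_events <- function(trace, min_processivity_bp = 100,
                          smoothing_window = 15,
                          pause_threshold_bp_per_s = 5,
                          slope_lag_s = 3,
                          merge_gap_s = 8) {
  check_scalar(min_processivity_bp, "min_processivity_bp", positive = TRUE)
  y <- trace$unwound_bp
  t <- trace$time_s
  n <- length(y)
  if (n == 0L) stop_input("empty trace")
  empty <- structure(
    data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
               processivity_bp = numeric(0), i_start = integer(0),
               i_end = integer(0)),
    class = c("unwinding_events", "data.frame"))
  if (n < 3L) return(empty)

  k <- as.integer(smoothing_window)
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  s <- if (k >= 3L) stats::runmed(y, k) else y

  dt <- stats::median(diff(t))
  lag <- max(1L, as.integer(round(slope_lag_s / dt)))
  lag <- min(lag, n - 1L)
  # local slope over the lag window; v[i] covers samples [i, i + lag]
  v <- (s[(1L + lag):n] - s[1:(n - lag)]) / (lag * dt)
  # adaptive threshold: 4x the noise floor of the slope estimate
  sigma_frame <- stats::mad(diff(y)) / sqrt(2)
  sigma_sm <- if (k >= 3L) 1.25 * sigma_frame / sqrt(k) else sigma_frame
  sigma_slope <- sqrt(2) * sigma_sm / (lag * dt)
  thr <- max(pause_threshold_bp_per_s, 4 * sigma_slope)
  moving <- v > thr

  # merge moving runs separated by short gaps (pauses within an event)
  gap <- max(0L, as.integer(round(merge_gap_s / dt)))
  r <- rle(moving)
  if (length(r$lengths) > 2L) {
    interior <- 2:(length(r$lengths) - 1L)
    fill <- interior[!r$values[interior] & r$lengths[interior] < gap]
    r$values[fill] <- TRUE
  }
  moving <- inverse.rle(r)

  r <- rle(moving)
  ends_r <- cumsum(r$lengths)
  starts_r <- ends_r - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(empty)

  out <- lapply(runs, function(q) {
    i0 <- starts_r[q]                 # index into v; sample index = i0
    i1 <- min(ends_r[q] + lag, n)     # slope window extends lag samples
    # anchor at the extrema of the smoothed trace within the run
    seg <- s[i0:i1]
    lo <- i0 + which.min(seg) - 1L
    hi <- i0 + which.max(seg) - 1L
    if (hi <= lo) return(NULL)
    rise <- s[hi] - s[lo]
    if (rise < min_processivity_bp) return(NULL)
    data.frame(t_start_s = t[lo], t_end_s = t[hi], processivity_bp = rise,
               i_start = lo - 1L, i_end = hi)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) return(empty)
  structure(out[order(out$t_start_s), , drop = FALSE],
            class = c("unwinding_events", "data.frame"))
}

#' Survival probability of processivities
#'
#' Right-continuous empirical survival function `S(x) = #(values > x) / n`,
#' evaluated on the sorted unique values: `S` steps from 1 just below the
#' minimum to 0 at the maximum, and its integral over `[0, max]` equals the
#' sample mean for non-negative values.
#'
#' @param values processivities (n >= 1, finite).
#' @return a list of class `survival_curve` with `x` (sorted unique values),
#'   `p` (`S(x)` at each x), `n`, and `fn`, a function evaluating `S` at
#'   arbitrary points.
#' @export
survival_probability <- function(values) {
  if (!length(values)) stop_input("need at least one value")
  if (any(!is.finite(values))) stop_input("values must be finite")
  n <- length(values)
  x <- sort(unique(values))
  p <- vapply(x, function(q) sum(values > q), numeric(1)) / n
  sorted <- sort(values)
  fn <- function(q) {
    vapply(q, function(z) sum(sorted > z), numeric(1)) / n
  }
  structure(list(x = x, p = p, n = n, fn = fn), class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve: n = %d, range [%g, %g]\n",
              x$n, min(x$x), max(x$x)))
  invisible(x)
}

#' Force from transverse bead fluctuations
#'
#' Equipartition estimator `F = kBT * L / var(x)` with the unbiased sample
#' variance of the transverse coordinate. No camera-blur or aliasing
#' correction is applied.
#'
#' @param transverse_nm transverse bead positions in nm (>= 100 samples).
#' @param tether_length_nm tether extension in nm (> 0).
#' @param kBT_pN_nm thermal energy in pN nm (default 4.114, 298 K).
#' @return force in pN.
#' @export
calibrate_force_variance <- function(transverse_nm, tether_length_nm,
                                     kBT_pN_nm = 4.114) {
  if (length(transverse_nm) < 100L) {
    stop_input("need >= 100 samples for force calibration")
  }
  check_scalar(tether_length_nm, "tether_length_nm", positive = TRUE)
  check_scalar(kBT_pN_nm, "kBT_pN_nm", positive = TRUE)
  v <- stats::var(transverse_nm)
  if (v == 0) stop_input("zero variance: cannot calibrate force")
  kBT_pN_nm * tether_length_nm / v
}

#' Pooled analysis of one experimental condition
#'
#' Segments every trace, pools fragments and events across traces, and
#' returns the condition summary: mean velocity +/- SEM over non-pause
#' fragments, mean processivity +/- SEM over completed events, and the
#' processivity survival curve.
#'
#' Events still rising within `censor_guard_s` of the end of their trace are
#' right-censored (the enzyme had not detached) and are excluded from the
#' processivity statistics.
#'
#' @param traces a non-empty list of [unwinding_trace()] objects.
#' @param penalty segmentation penalty (`NULL` for the per-trace default).
#' @param pause_threshold_bp_per_s pause exclusion threshold for the velocity
#'   mean and for event detection (default 5 bp/s).
#' @param min_processivity_bp minimum event size in bp (default 100).
#' @param smoothing_window event-detection median window in samples.
#' @param censor_guard_s exclusion window at the trace end in seconds
#'   (default 1).
#' @param merge_gap_s event-detection gap merging, see [detect_events()].
#' @return a list of class `trace_summary` with fields
#'   `mean_velocity_bp_per_s`, `sem_velocity`, `n_fragments`,
#'   `mean_processivity_bp`, `sem_processivity`, `n_events`,
#'   `survival_x_bp`, `survival_p`, plus `fragments` and `events` tables.
#' @export
analyze_condition <- function(traces, penalty = NULL,
                              pause_threshold_bp_per_s = 5,
                              min_processivity_bp = 100,
                              smoothing_window = 15,
                              censor_guard_s = 1,
                              merge_gap_s = 8) {
  if (!is.list(traces) || !length(traces)) {
    stop_input("need at least one trace")
  }
  frag_list <- vector("list", length(traces))
  ev_list <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    fr <- segment_constant_velocity(tr, penalty = penalty)
    fr$trace <- i
    frag_list[[i]] <- fr
    ev <- detect_events(tr, min_processivity_bp = min_processivity_bp,
                        smoothing_window = smoothing_window,
                        pause_threshold_bp_per_s = pause_threshold_bp_per_s,
                        merge_gap_s = merge_gap_s)
    if (nrow(ev)) {
      ev$trace <- i
      ev$censored <- ev$t_end_s > tr$time_s[nrow(tr)] - censor_guard_s
    } else {
      ev$trace <- integer(0)
      ev$censored <- logical(0)
    }
    ev_list[[i]] <- ev
  }
  fragments <- do.call(rbind, frag_list)
  events <- do.call(rbind, ev_list)

  vel <- summarize_velocity(fragments, pause_threshold_bp_per_s)
  proc <- events$processivity_bp[!events$censored]
  n_ev <- length(proc)
  if (n_ev > 0L) {
    surv <- survival_probability(proc)
    mean_proc <- mean(proc)
    sem_proc <- if (n_ev > 1L) stats::sd(proc) / sqrt(n_ev) else NA_real_
  } else {
    surv <- list(x = numeric(0), p = numeric(0))
    mean_proc <- NA_real_
    sem_proc <- NA_real_
  }
  structure(list(
    mean_velocity_bp_per_s = vel$mean_velocity_bp_per_s,
    sem_velocity = vel$sem_velocity,
    n_fragments = vel$n,
    mean_processivity_bp = mean_proc,
    sem_processivity = sem_proc,
    n_events = n_ev,
    survival_x_bp = surv$x,
    survival_p = surv$p,
    fragments = fragments,
    events = events
  ), class = "trace_summary")
}

#' @export
print.trace_summary <- function(x, ...) {
  cat("Condition summary\n")
  cat(sprintf("  velocity: %.2f +/- %.2f bp/s (n = %d fragments)\n",
              x$mean_velocity_bp_per_s, x$sem_velocity, x$n_fragments))
  cat(sprintf("  processivity: %.0f +/- %.0f bp (n = %d events)\n",
              x$mean_processivity_bp, x$sem_processivity, x$n_events))
  invisible(x)
}
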