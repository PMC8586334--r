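# Constant-velocity segmentation of unwinding traces.
#
# Exact penalized least-squares change-point detection: minimize
#   sum_fragments RSS(independent linear fit) + penalty * (#breakpoints)
# over all partitions into fragments of >= min_size samples, by O(n^2)
# dynamic programming with O(1) fragment costs from cumulative sums.
# Fragments are independent lines: no continuity across breakpoints, since
# pauses and slips make continuity physically wrong.

# Cumulative sums of centered time/value; centering keeps the O(1) RSS
# formula well conditioned on long traces.
.seg_cumsums <- function(t, y) {
  tc <- t - mean(t)
  yc <- y - mean(y)
  list(
    cx = c(0, cumsum(tc)),
    cy = c(0, cumsum(yc)),
    cxx = c(0, cumsum(tc * tc)),
    cyy = c(0, cumsum(yc * yc)),
    cxy = c(0, cumsum(tc * yc))
  )
}

# RSS of an OLS line on samples [i, j) (0-based half-open); i may be a vector.
.seg_rss <- function(cs, i, j) {
  m <- j - i
  sx <- cs$cx[j + 1] - cs$cx[i + 1]
  sy <- cs$cy[j + 1] - cs$cy[i + 1]
  sxx <- cs$cxx[j + 1] - cs$cxx[i + 1]
  syy <- cs$cyy[j + 1] - cs$cyy[i + 1]
  sxy <- cs$cxy[j + 1] - cs$cxy[i + 1]
  vx <- sxx - sx * sx / m
  vy <- syy - sy * sy / m
  cxy <- sxy - sx * sy / m
  pmax(0, vy - cxy * cxy / vx)
}

#' Default segmentation penalty
#'
#' BIC-like penalty `3 * sigma^2 * log(n)`, charging three parameters per
#' extra breakpoint (slope, intercept, breakpoint location), with the noise
#' scale estimated robustly from the median absolute deviation of first
#' differences (`sigma = mad(diff(y)) / sqrt(2)`) so slopes and rare jumps
#' do not inflate it. With only one sigma^2 log(n) per breakpoint the
#' optimizer isolates short coherent noise excursions as spurious steep
#' fragments on 30 Hz traces; charging all three parameters suppresses them.
#'
#' @param unwound_bp the trace values.
#' @return a non-negative scalar penalty.
#' @export
default_segment_penalty <- function(unwound_bp) {
  n <- length(unwound_bp)
  sigma <- stats::mad(diff(unwound_bp)) / sqrt(2)
  max(3 * sigma^2 * log(n), .Machine$double.eps)
}

#' Segment an unwinding trace into constant-velocity fragments
#'
#' Exact dynamic-programming minimization of total within-fragment RSS plus
#' `penalty` per breakpoint, with a minimum fragment length of `min_size`
#' samples. Returns ordered, disjoint fragments that jointly cover all
#' samples, each carrying its OLS velocity, intercept and RSS.
#'
#' @param trace an [unwinding_trace()] (or any data.frame with `time_s` and
#'   `unwound_bp`), at least 4 samples.
#' @param penalty non-negative cost per breakpoint; defaults to
#'   [default_segment_penalty()]. A penalty of 0 warns (it overfits to
#'   minimum-length fragments).
#' @param min_size minimum fragment length in samples (default 3).
#' @return a `data.frame` of class `velocity_fragments` with columns
#'   `i_start`, `i_end` (0-based, half-open), `t_start_s`, `t_end_s`,
#'   `velocity_bp_per_s`, `intercept_bp`, `rss`, plus attributes `penalty`
#'   and `total_cost`.
#' @export
segment_constant_velocity <- function(trace, penalty = NULL, min_size = 3L) {
  t <- trace$time_s
  y <- trace$unwound_bp
  n <- length(y)
  if (n < 4L) stop_input("need at least 4 samples to segment")
  min_size <- as.integer(min_size)
  if (min_size < 2L) stop_input("min_size must be >= 2")
  if (is.null(penalty)) penalty <- default_segment_penalty(y)
  check_scalar(penalty, "penalty", nonneg = TRUE)
  if (penalty == 0) {
    warning("penalty = 0 overfits to minimum-length fragments", call. = FALSE)
  }

  cs <- .seg_cumsums(t, y)
  # F[j+1]: optimal cost of samples [0, j) plus one penalty per fragment;
  # subtract one penalty at the end so breakpoints, not fragments, are
  # charged. Inner loop in C (src/dp_segment.cpp).
  dp <- .dp_segment_cpp(cs$cx, cs$cy, cs$cxx, cs$cyy, cs$cxy,
                        n, penalty, min_size)
  F <- dp$F
  prev <- dp$prev
  if (!is.finite(F[n + 1L])) stop_input("no feasible segmentation")

  # backtrack
  bounds <- integer(0)
  j <- n
  while (j > 0L) {
    bounds <- c(prev[j + 1L], bounds)
    j <- prev[j + 1L]
  }
  starts <- bounds
  ends <- c(bounds[-1], n)

  fits <- lapply(seq_along(starts), function(k) {
    fragment_velocity_fit(trace, starts[k], ends[k])
  })
  out <- data.frame(
    i_start = starts,
    i_end = ends,
    t_start_s = t[starts + 1L],
    t_end_s = t[ends],
    velocity_bp_per_s = vapply(fits, `[[`, numeric(1), "velocity_bp_per_s"),
    intercept_bp = vapply(fits, `[[`, numeric(1), "intercept_bp"),
    rss = vapply(fits, `[[`, numeric(1), "rss")
  )
  structure(out,
            penalty = penalty,
            total_cost = F[n + 1L] - penalty,
            class = c("velocity_fragments", "data.frame"))
}

#' Ordinary least-squares line over a fragment
#'
#' Slope, intercept and residual sum of squares of the OLS fit over the
#' 0-based half-open sample range `[i_start, i_end)`.
#'
#' @param trace an [unwinding_trace()] or compatible data.frame.
#' @param i_start,i_end 0-based half-open index range, `i_end - i_start >= 2`.
#' @return a list with `velocity_bp_per_s`, `intercept_bp`, `rss`.
#' @export
fragment_velocity_fit <- function(trace, i_start, i_end) {
  n <- nrow(trace)
  if (i_start < 0 || i_end > n || i_end - i_start < 2) {
    stop_input("need a valid range with at least 2 samples")
  }
  idx <- (i_start + 1L):i_end
  x <- trace$time_s[idx]
  y <- trace$unwound_bp[idx]
  vx <- sum((x - mean(x))^2)
  if (vx == 0) stop_input("degenerate fragment: identical times")
  slope <- sum((x - mean(x)) * (y - mean(y))) / vx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  list(velocity_bp_per_s = slope, intercept_bp = intercept, rss = rss)
}

#' Pooled velocity statistics over fragments
#'
#' Mean and standard error of fragment velocities, after excluding pause
#' fragments (|velocity| below `pause_threshold_bp_per_s`; threshold 0
#' disables the exclusion so every fragment contributes).
#'
#' @param fragments output of [segment_constant_velocity()] (rows may be
#'   pooled across traces).
#' @param pause_threshold_bp_per_s pause exclusion threshold in bp/s.
#' @return a list with `mean_velocity_bp_per_s`, `sem_velocity` (`NA` when
#'   n = 1), and `n`. When no fragment survives filtering the mean is `NA`,
#'   `n` is 0 and a warning is raised.
#' @export
summarize_velocity <- function(fragments, pause_threshold_bp_per_s = 0) {
  check_scalar(pause_threshold_bp_per_s, "pause_threshold_bp_per_s",
               nonneg = TRUE)
  v <- fragments$velocity_bp_per_s
  if (!length(v)) stop_input("need at least one fragment")
  v <- v[abs(v) >= pause_threshold_bp_per_s]
  n <- length(v)
  if (n == 0L) {
    warning("no fragments survive pause filtering", call. = FALSE)
    return(list(mean_velocity_bp_per_s = NA_real_, sem_velocity = NA_real_,
                n = 0L))
  }
  list(
    mean_velocity_bp_per_s = mean(v),
    sem_velocity = if (n > 1L) stats::sd(v) / sqrt(n) else NA_real_,
    n = n
  )
}
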