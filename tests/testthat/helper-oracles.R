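# Independent oracles and fixture builders shared across tests.

# OLS residual sum of squares of samples (i, j] (0-based half-open [i, j)),
# computed from var/cor -- deliberately independent of the package's
# cumulative-sum path.
oracle_seg_rss <- function(t, y, i, j) {
  idx <- (i + 1):j
  m <- length(idx)
  vy <- stats::var(y[idx]) * (m - 1)
  if (!is.finite(vy) || vy == 0) return(0)
  r <- suppressWarnings(stats::cor(t[idx], y[idx]))
  if (is.na(r)) r <- 0
  vy * (1 - r^2)
}

# Exhaustive-enumeration minimum of sum(RSS) + penalty * breakpoints over
# ALL partitions with fragments >= min_size. Enumerates k = 0, 1, 2, ...
# breakpoints and stops once best <= (k + 1) * penalty: any segmentation
# with more breakpoints costs at least that much, so the restriction is
# provably sufficient. Returns the proven optimum.
oracle_segment_cost <- function(t, y, penalty, min_size = 3L, k_cap = 6L) {
  n <- length(y)
  # cost lookup for every feasible fragment
  C <- matrix(Inf, n + 1L, n + 1L)
  for (i in 0:(n - min_size)) {
    for (j in seq(i + min_size, n)) {
      C[i + 1L, j + 1L] <- oracle_seg_rss(t, y, i, j)
    }
  }
  best <- C[1L, n + 1L]  # k = 0
  k <- 0L
  while (best > (k + 1L) * penalty + 1e-9) {
    k <- k + 1L
    if (k > k_cap) stop("oracle k_cap exceeded: enumeration not proven complete")
    pos <- seq(min_size, n - min_size)
    combos <- if (k == 1L) matrix(pos, nrow = 1) else utils::combn(pos, k)
    if (k >= 2L) {
      ok <- colSums(diff(combos) >= min_size) == (k - 1L)
      combos <- combos[, ok, drop = FALSE]
    }
    if (!ncol(combos)) next
    starts <- rbind(0L, combos) + 1L
    ends <- rbind(combos, n) + 1L
    costs <- matrix(C[cbind(as.vector(starts), as.vector(ends))],
                    nrow = k + 1L)
    best <- min(best, min(colSums(costs)) + k * penalty)
  }
  best
}

# Random piecewise-linear trace with <= max_bp breakpoints (consumes the
# active RNG stream).
make_piecewise_trace <- function(n = sample(30:60, 1),
                                 max_bp = 3L, noise_sd = 1,
                                 min_gap = 5L, frame_rate = 30) {
  nbp <- sample(0:max_bp, 1)
  repeat {
    bps <- sort(sample(seq(min_gap, n - min_gap), nbp))
    if (nbp < 2L || all(diff(bps) >= min_gap)) break
  }
  bounds <- c(0L, bps, n)
  slopes <- stats::runif(nbp + 1, -15, 15)
  t <- (1:n) / frame_rate
  y <- numeric(n)
  lev <- 0
  for (k in seq_len(nbp + 1)) {
    idx <- (bounds[k] + 1):bounds[k + 1]
    y[idx] <- lev + slopes[k] * (t[idx] - t[idx[1]])
    lev <- y[bounds[k + 1]]
  }
  y <- y + stats::rnorm(n, 0, noise_sd)
  list(trace = unwinding_trace(t, y), n_breakpoints = nbp,
       breakpoints = bps, slopes = slopes)
}

# Noiseless staircase trace from (duration, velocity) phases.
make_phase_trace <- function(phases, frame_rate = 30) {
  t <- numeric(0)
  y <- numeric(0)
  t0 <- 0
  lev <- 0
  for (ph in phases) {
    nf <- round(ph$duration * frame_rate)
    tt <- t0 + (1:nf) / frame_rate
    y <- c(y, lev + ph$velocity * (tt - t0))
    lev <- lev + ph$velocity * ph$duration
    t <- c(t, tt)
    t0 <- t0 + ph$duration
  }
  unwinding_trace(t, y)
}
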