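# Mass photometry: contrast-to-mass calibration, Gaussian-mixture fitting of
# mass spectra, and assignment of peaks to complex compositions.
#
# The vendor peak caller is proprietary; the transparent equivalent here is
# 1-D Gaussian-mixture EM with BIC model selection and a deterministic
# quantile-based initialization, so fits are reproducible without tuning.

#' Calibrate contrast against protein standards
#'
#' Least-squares line `mass = slope * contrast + intercept` through the
#' per-standard median contrasts (median, not mean, for robustness against
#' outlier landings) and the known standard masses.
#'
#' @param contrasts per-landing contrasts of the standards.
#' @param standard_mass_kDa known mass of the standard each landing belongs
#'   to, in kDa (same length; >= 2 distinct masses required).
#' @return a list of class `mass_calibration` with `slope_kDa_per_contrast`,
#'   `intercept_kDa`, `r_squared`, and the per-standard medians.
#' @export
calibrate_contrast <- function(contrasts, standard_mass_kDa) {
  if (length(contrasts) != length(standard_mass_kDa)) {
    stop_input("contrasts and standard_mass_kDa must have equal length")
  }
  masses <- sort(unique(standard_mass_kDa))
  if (length(masses) < 2L) {
    stop_input("need at least 2 distinct standard masses")
  }
  med <- vapply(masses, function(m) {
    stats::median(contrasts[standard_mass_kDa == m])
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, med), masses)
  coefs <- fit$coefficients
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((masses - mean(masses))^2)
  structure(list(
    slope_kDa_per_contrast = unname(coefs[2]),
    intercept_kDa = unname(coefs[1]),
    r_squared = 1 - ss_res / ss_tot,
    standard_mass_kDa = masses,
    median_contrast = med
  ), class = "mass_calibration")
}

#' @export
print.mass_calibration <- function(x, ...) {
  cat(sprintf(
    "Mass calibration: mass = %.4g * contrast + %.4g kDa (R^2 = %.4f, %d standards)\n",
    x$slope_kDa_per_contrast, x$intercept_kDa, x$r_squared,
    length(x$standard_mass_kDa)))
  invisible(x)
}

#' Apply a mass calibration to landing contrasts
#'
#' @param events a [mass_event_set()].
#' @param cal a [calibrate_contrast()] result.
#' @return the event set with `masses_kDa` filled in.
#' @export
contrasts_to_masses <- function(events, cal) {
  stopifnot(inherits(events, "mass_event_set"),
            inherits(cal, "mass_calibration"))
  if (cal$slope_kDa_per_contrast == 0) stop_input("calibration slope is zero")
  events$masses_kDa <- cal$slope_kDa_per_contrast * events$contrasts +
    cal$intercept_kDa
  events
}

# one EM run at fixed k with deterministic quantile init
.gmm_em <- function(x, k, max_iter, tol) {
  n <- length(x)
  mu <- as.numeric(stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                                   type = 7))
  sd0 <- stats::sd(x)
  sigma <- rep(max(sd0 / k, 1e-8), k)
  w <- rep(1 / k, k)
  sd_floor <- max(1e-6 * (max(x) - min(x)), .Machine$double.eps)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) {
      w[j] * stats::dnorm(x, mu[j], sigma[j])
    }, numeric(n))
    dens <- matrix(dens, nrow = n)
    rs <- rowSums(dens)
    rs[rs == 0] <- .Machine$double.xmin
    ll <- sum(log(rs))
    ll_trace <- c(ll_trace, ll)
    resp <- dens / rs
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(pmax(
      colSums(resp * (outer(x, mu, "-"))^2) / nk, sd_floor^2))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      return(list(mu = mu, sigma = sigma, w = w, n_k = nk, loglik = ll,
                  ll_trace = ll_trace, iter = iter, converged = TRUE))
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, w = w, n_k = nk, loglik = ll_old,
       ll_trace = ll_trace, iter = max_iter, converged = FALSE)
}

#' Fit a mass spectrum as a Gaussian mixture
#'
#' Expectation-maximization fit of `k` Gaussian components to calibrated
#' masses. With `k = "auto"` the component count is chosen by minimum BIC
#' over `1..k_max`. Initialization is deterministic (component means at
#' evenly spaced sample quantiles), so the fit is reproducible.
#'
#' @param masses_kDa calibrated event masses (>= 50 events per requested
#'   component).
#' @param k number of components, or `"auto"`.
#' @param k_max maximum components tried when `k = "auto"` (default 5).
#' @param max_iter EM iteration cap (default 2000; overfit k converges slowly).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @return a `data.frame` of class `mass_peaks`, one row per component
#'   sorted by mean, with `mean_kDa`, `sd_kDa`, `weight`, `n_events`
#'   (responsibility-weighted counts), and attributes `loglik`, `bic`, `k`,
#'   `ll_trace`.
#' @export
fit_mass_peaks <- function(masses_kDa, k = "auto", k_max = 5L,
                           max_iter = 2000L, tol = 1e-8) {
  x <- as.numeric(masses_kDa)
  if (any(!is.finite(x))) stop_input("masses must be finite")
  auto <- identical(k, "auto")
  ks <- if (auto) seq_len(k_max) else as.integer(k)
  if (!auto && (ks < 1L)) stop_input("k must be >= 1")
  if (length(x) < 50L * max(ks)) {
    stop_input("need >= 50 events per requested component")
  }
  fits <- lapply(ks, function(kk) {
    fit <- .gmm_em(x, kk, max_iter = max_iter, tol = tol)
    if (!fit$converged) {
      stop_input(sprintf(
        "EM did not converge for k = %d after %d iterations (loglik %.6g)",
        kk, max_iter, fit$loglik))
    }
    n_par <- 3 * kk - 1
    fit$bic <- -2 * fit$loglik + n_par * log(length(x))
    fit
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
  ord <- order(best$mu)
  out <- data.frame(
    mean_kDa = best$mu[ord],
    sd_kDa = best$sigma[ord],
    weight = best$w[ord],
    n_events = best$n_k[ord]
  )
  structure(out,
            loglik = best$loglik, bic = best$bic, k = nrow(out),
            ll_trace = best$ll_trace,
            class = c("mass_peaks", "data.frame"))
}

#' Assign mass peaks to complex compositions
#'
#' Exhaustive search over all non-empty subsets of the named component
#' masses: each peak is assigned the subset whose theoretical mass sum is
#' closest to the peak mean, reported only when within `tolerance_kDa`
#' (default: one fitted sd of the peak). Ties go to the subset with fewer
#' components.
#'
#' @param peaks a [fit_mass_peaks()] result (or data.frame with `mean_kDa`
#'   and `sd_kDa`).
#' @param components named numeric vector of candidate component masses in
#'   kDa (e.g. `c(RPA = 114, Dna2 = 172, DNA = 25)`). Masses are
#'   user-supplied inputs, never hard-coded.
#' @param tolerance_kDa maximum accepted deviation; scalar or per-peak
#'   vector; `NULL` uses each peak's fitted sd.
#' @return a list of class `species_assignment`, one element per peak with
#'   `mean_kDa`, `components` (character(0) when unassigned),
#'   `theoretical_sum_kDa`, `deviation_kDa`, `assigned`.
#' @export
assign_species <- function(peaks, components, tolerance_kDa = NULL) {
  if (!length(components)) stop_input("components must be non-empty")
  if (is.null(names(components)) || any(!nzchar(names(components)))) {
    stop_input("components must be named")
  }
  m <- length(components)
  if (m > 16L) stop_input("too many components for exhaustive search")
  tol <- if (is.null(tolerance_kDa)) peaks$sd_kDa else tolerance_kDa
  tol <- rep_len(tol, nrow(peaks))
  if (any(tol <= 0)) stop_input("tolerance must be > 0")

  # all 2^m - 1 non-empty subsets as a logical matrix
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))[-1, ,
                                                                  drop = FALSE]
  sums <- as.numeric(subsets %*% components)
  sizes <- rowSums(subsets)

  out <- lapply(seq_len(nrow(peaks)), function(i) {
    dev <- abs(peaks$mean_kDa[i] - sums)
    # best deviation, ties broken toward fewer components
    ord <- order(dev, sizes)
    best <- ord[1]
    assigned <- dev[best] <= tol[i]
    list(
      mean_kDa = peaks$mean_kDa[i],
      components = if (assigned) names(components)[subsets[best, ]]
                   else character(0),
      theoretical_sum_kDa = if (assigned) sums[best] else NA_real_,
      deviation_kDa = if (assigned) dev[best] else NA_real_,
      assigned = assigned
    )
  })
  structure(out, class = "species_assignment")
}

#' @export
print.species_assignment <- function(x, ...) {
  for (a in x) {
    if (a$assigned) {
      cat(sprintf("  %.1f kDa -> %s (sum %.1f, off by %.1f kDa)\n",
                  a$mean_kDa, paste(a$components, collapse = "+"),
                  a$theoretical_sum_kDa, a$deviation_kDa))
    } else {
      cat(sprintf("  %.1f kDa -> unassigned\n", a$mean_kDa))
    }
  }
  invisible(x)
}
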