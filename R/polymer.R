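# Tether elasticity: worm-like chain (dsDNA) and freely-jointed chain (ssDNA)
# models, and the conversion between apparent tether extension and base pairs
# unwound. Unwinding one bp removes one bp of duplex from the tether and adds
# `nt_gained_per_bp` nucleotides of single strand, so the extension change per
# unwound bp at force F is
#   delta(F) = nt_gained_per_bp * L_ss * r_ss(F) - L_ds * r_ds(F)
# with r_* the relative extensions of the two polymer models.

#' Polymer elasticity parameters
#'
#' Container for the double-stranded (worm-like chain) and single-stranded
#' (freely-jointed chain) DNA elasticity parameters used to convert tether
#' extension into base pairs unwound.
#'
#' @param ds_persistence_nm dsDNA persistence length in nm (default 45).
#' @param ds_rise_nm_per_bp dsDNA contour rise per base pair in nm
#'   (default 0.338).
#' @param ss_kuhn_nm ssDNA Kuhn length in nm (default 1.5).
#' @param ss_contour_nm_per_nt ssDNA contour length per nucleotide in nm
#'   (default 0.56).
#' @param temperature_K absolute temperature in K (default 298).
#' @param kBT_pN_nm thermal energy in pN nm. Derived from `temperature_K`
#'   when `NULL`; if supplied it must agree with the temperature within 0.1%.
#' @param nt_gained_per_bp nucleotides added to the tether per base pair
#'   unwound (default 1: the displaced strand exits at the nick).
#' @return an object of class `polymer_params`.
#' @examples
#' p <- polymer_params()
#' p$kBT_pN_nm  # ~4.114 at 298 K
#' @export
polymer_params <- function(ds_persistence_nm = 45,
                           ds_rise_nm_per_bp = 0.338,
                           ss_kuhn_nm = 1.5,
                           ss_contour_nm_per_nt = 0.56,
                           temperature_K = 298,
                           kBT_pN_nm = NULL,
                           nt_gained_per_bp = 1) {
  check_scalar(ds_persistence_nm, "ds_persistence_nm", positive = TRUE)
  check_scalar(ds_rise_nm_per_bp, "ds_rise_nm_per_bp", positive = TRUE)
  check_scalar(ss_kuhn_nm, "ss_kuhn_nm", positive = TRUE)
  check_scalar(ss_contour_nm_per_nt, "ss_contour_nm_per_nt", positive = TRUE)
  check_scalar(temperature_K, "temperature_K", positive = TRUE)
  check_scalar(nt_gained_per_bp, "nt_gained_per_bp", positive = TRUE)
  kBT_derived <- .kB_pN_nm_per_K * temperature_K
  if (is.null(kBT_pN_nm)) {
    kBT_pN_nm <- kBT_derived
  } else {
    check_scalar(kBT_pN_nm, "kBT_pN_nm", positive = TRUE)
    if (abs(kBT_pN_nm - kBT_derived) / kBT_derived > 1e-3) {
      stop_input("kBT_pN_nm inconsistent with temperature_K (>0.1% off)")
    }
  }
  structure(
    list(
      ds_persistence_nm = ds_persistence_nm,
      ds_rise_nm_per_bp = ds_rise_nm_per_bp,
      ss_kuhn_nm = ss_kuhn_nm,
      ss_contour_nm_per_nt = ss_contour_nm_per_nt,
      temperature_K = temperature_K,
      kBT_pN_nm = kBT_pN_nm,
      nt_gained_per_bp = nt_gained_per_bp
    ),
    class = "polymer_params"
  )
}

#' @export
print.polymer_params <- function(x, ...) {
  cat("Polymer parameters (WLC ds / FJC ss)\n")
  cat(sprintf("  dsDNA: P = %g nm, rise = %g nm/bp\n",
              x$ds_persistence_nm, x$ds_rise_nm_per_bp))
  cat(sprintf("  ssDNA: b = %g nm, contour = %g nm/nt\n",
              x$ss_kuhn_nm, x$ss_contour_nm_per_nt))
  cat(sprintf("  kBT = %.4f pN nm (%g K); nt gained per bp = %g\n",
              x$kBT_pN_nm, x$temperature_K, x$nt_gained_per_bp))
  invisible(x)
}

#' Tether geometry
#'
#' Geometry of the nicked-flap DNA construct: total duplex length, the
#' single-stranded flap, and a constant handle offset.
#'
#' @param ds_bp_total total duplex length in bp (default 6600).
#' @param flap_nt length of the 5' single-stranded flap in nt (default 40).
#' @param handle_contribution_nm constant extension offset of the attachment
#'   handles in nm (default 0).
#' @return an object of class `tether_geometry`.
#' @export
tether_geometry <- function(ds_bp_total = 6600, flap_nt = 40,
                            handle_contribution_nm = 0) {
  check_scalar(ds_bp_total, "ds_bp_total", positive = TRUE)
  check_scalar(flap_nt, "flap_nt", nonneg = TRUE)
  check_scalar(handle_contribution_nm, "handle_contribution_nm")
  structure(
    list(
      ds_bp_total = ds_bp_total,
      flap_nt = flap_nt,
      handle_contribution_nm = handle_contribution_nm
    ),
    class = "tether_geometry"
  )
}

# Marko-Siggia interpolation, forward direction: F(r) for the WLC.
.wlc_force <- function(r, P, kBT) {
  kBT / P * (1 / (4 * (1 - r)^2) - 0.25 + r)
}

#' Relative extension of dsDNA (worm-like chain)
#'
#' Solves the Marko-Siggia interpolation formula
#' `F = kBT/P * (1/(4(1-r)^2) - 1/4 + r)` for the relative extension
#' `r = x/L` by bracketed root finding. No enthalpic stretch term is used.
#'
#' @param force_pN applied force in pN (vectorized, >= 0).
#' @param params a [polymer_params()] object.
#' @return relative extension in `[0, 1)`, strictly increasing in force.
#' @examples
#' p <- polymer_params()
#' ds_relative_extension(1.25 * p$kBT_pN_nm / p$ds_persistence_nm, p)  # 0.5
#' @export
ds_relative_extension <- function(force_pN, params = polymer_params()) {
  stopifnot(inherits(params, "polymer_params"))
  if (!is.numeric(force_pN) || any(!is.finite(force_pN))) {
    stop_input("force_pN must be finite numeric")
  }
  if (any(force_pN < 0)) stop_input("force_pN must be >= 0")
  P <- params$ds_persistence_nm
  kBT <- params$kBT_pN_nm
  vapply(force_pN, function(f) {
    if (f == 0) return(0)
    g <- function(r) .wlc_force(r, P, kBT) - f
    stats::uniroot(g, lower = 0, upper = 1 - 1e-9, tol = 1e-12,
                   maxiter = 1000L)$root
  }, numeric(1))
}

#' Relative extension of ssDNA (freely-jointed chain)
#'
#' Langevin-function extension `r = coth(Fb/kBT) - kBT/(Fb)` with Kuhn length
#' `b`, continuously extended to `r(0) = 0`.
#'
#' @inheritParams ds_relative_extension
#' @return relative extension in `[0, 1)`, strictly increasing in force.
#' @export
ss_relative_extension <- function(force_pN, params = polymer_params()) {
  stopifnot(inherits(params, "polymer_params"))
  if (!is.numeric(force_pN) || any(!is.finite(force_pN))) {
    stop_input("force_pN must be finite numeric")
  }
  if (any(force_pN < 0)) stop_input("force_pN must be >= 0")
  x <- force_pN * params$ss_kuhn_nm / params$kBT_pN_nm
  r <- numeric(length(x))
  small <- x < 1e-4
  # series expansion avoids 0/0 at small argument: L(x) = x/3 - x^3/45 + ...
  r[small] <- x[small] / 3 - x[small]^3 / 45
  xs <- x[!small]
  r[!small] <- 1 / tanh(xs) - 1 / xs
  r
}

#' Extension change per unwound base pair
#'
#' Signed tether length change per base pair unwound at force `F`:
#' `delta(F) = nt_gained_per_bp * L_ss * r_ss(F) - rise_ds * r_ds(F)`.
#' Negative at low force where collapsed ssDNA is shorter than the duplex it
#' replaces; a sign crossover exists within (0, 20] pN for the defaults.
#'
#' @inheritParams ds_relative_extension
#' @return signed extension change in nm per bp (vectorized).
#' @export
bp_step_signal_nm <- function(force_pN, params = polymer_params()) {
  ss <- params$nt_gained_per_bp * params$ss_contour_nm_per_nt *
    ss_relative_extension(force_pN, params)
  ds <- params$ds_rise_nm_per_bp * ds_relative_extension(force_pN, params)
  ss - ds
}

#' Convert an extension trajectory into base pairs unwound
#'
#' Inverts the tether model at the trajectory's (constant) force:
#' `n(t) = (z(t) - baseline_nm) / delta(F)` sample for sample.
#'
#' @param traj a [bead_trajectory()] with `force_pN` recorded.
#' @param params a [polymer_params()] object.
#' @param baseline_nm extension corresponding to zero unwinding, in nm.
#' @param delta_tol_nm smallest usable `|delta(F)|`; below this the force is
#'   degenerate (unwinding produces no length change) and an error is raised.
#' @return an [unwinding_trace()] on the same time axis.
#' @export
extension_to_unwound_bp <- function(traj, params = polymer_params(),
                                    baseline_nm = 0, delta_tol_nm = 1e-3) {
  stopifnot(inherits(traj, "bead_trajectory"))
  check_scalar(baseline_nm, "baseline_nm")
  f <- attr(traj, "force_pN")
  if (!is.finite(f)) stop_input("trajectory has no recorded force_pN")
  delta <- bp_step_signal_nm(f, params)
  if (abs(delta) < delta_tol_nm) {
    stop_input(sprintf(
      "degenerate force: |delta(F)| = %.3g nm/bp < %g nm/bp, unwinding unobservable",
      abs(delta), delta_tol_nm))
  }
  unwinding_trace(
    time_s = traj$time_s,
    unwound_bp = (traj$extension_nm - baseline_nm) / delta,
    force_pN = f,
    label = attr(traj, "label")
  )
}

#' Baseline tether extension before unwinding
#'
#' Expected extension of the intact construct at force `F`: fully duplex
#' tether plus the single-stranded flap plus the handle offset.
#'
#' @inheritParams ds_relative_extension
#' @param geometry a [tether_geometry()] object.
#' @return extension in nm.
#' @export
baseline_extension_nm <- function(force_pN, params = polymer_params(),
                                  geometry = tether_geometry()) {
  stopifnot(inherits(geometry, "tether_geometry"))
  geometry$handle_contribution_nm +
    geometry$ds_bp_total * params$ds_rise_nm_per_bp *
      ds_relative_extension(force_pN, params) +
    geometry$flap_nt * params$ss_contour_nm_per_nt *
      ss_relative_extension(force_pN, params)
}
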