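# Data containers. Both trajectory classes are data.frames with metadata
# attributes, so they print, subset and write like ordinary tables.

#' Bead trajectory
#'
#' Raw magnetic-tweezers recording for one bead: time, tether extension and
#' (optionally) the transverse bead coordinate, sampled on a uniform grid.
#'
#' @param time_s time in seconds, strictly increasing on a uniform grid
#'   (spacing uniform within 1e-6 relative).
#' @param extension_nm tether extension in nm.
#' @param transverse_nm optional transverse bead coordinate in nm (used for
#'   fluctuation-based force calibration).
#' @param force_pN applied force in pN (scalar metadata, may be `NA`).
#' @param frame_rate_hz camera frame rate; derived from the time grid when
#'   `NULL`, checked for consistency when supplied.
#' @param label free-text label for the bead / condition.
#' @return a `data.frame` of class `bead_trajectory` with attributes
#'   `force_pN`, `frame_rate_hz`, `label`.
#' @export
bead_trajectory <- function(time_s, extension_nm, transverse_nm = NULL,
                            force_pN = NA_real_, frame_rate_hz = NULL,
                            label = "") {
  if (length(time_s) < 2L) stop_input("need at least 2 samples")
  if (length(extension_nm) != length(time_s)) {
    stop_input("time_s and extension_nm must have equal length")
  }
  if (any(!is.finite(time_s)) || any(!is.finite(extension_nm))) {
    stop_input("time_s and extension_nm must be finite")
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) stop_input("time_s must be strictly increasing")
  dt_med <- stats::median(dt)
  if (any(abs(dt - dt_med) > 1e-6 * dt_med)) {
    stop_input("time grid not uniform (spacing varies by > 1e-6 relative)")
  }
  rate <- 1 / dt_med
  if (is.null(frame_rate_hz)) {
    frame_rate_hz <- rate
  } else if (abs(frame_rate_hz - rate) > 1e-3 * rate) {
    stop_input("frame_rate_hz inconsistent with time spacing")
  }
  df <- data.frame(time_s = time_s, extension_nm = extension_nm)
  if (!is.null(transverse_nm)) {
    if (length(transverse_nm) != length(time_s)) {
      stop_input("transverse_nm must match time_s length")
    }
    if (any(!is.finite(transverse_nm))) stop_input("transverse_nm must be finite")
    df$transverse_nm <- transverse_nm
  }
  structure(df,
            force_pN = as.numeric(force_pN),
            frame_rate_hz = frame_rate_hz,
            label = label,
            class = c("bead_trajectory", "data.frame"))
}

#' @export
print.bead_trajectory <- function(x, ...) {
  cat(sprintf(
    "Bead trajectory '%s': %d frames at %.3g Hz, %.1f s, force %s pN\n",
    attr(x, "label"), nrow(x), attr(x, "frame_rate_hz"),
    x$time_s[nrow(x)] - x$time_s[1],
    format(attr(x, "force_pN"))))
  invisible(x)
}

#' Unwinding trace
#'
#' Time versus base pairs unwound, after tether-model conversion.
#'
#' @param time_s time in seconds.
#' @param unwound_bp base pairs unwound (real-valued).
#' @param force_pN applied force in pN.
#' @param label free-text label.
#' @return a `data.frame` of class `unwinding_trace`.
#' @export
unwinding_trace <- function(time_s, unwound_bp, force_pN = NA_real_,
                            label = "") {
  if (length(time_s) != length(unwound_bp)) {
    stop_input("time_s and unwound_bp must have equal length")
  }
  if (any(!is.finite(time_s)) || any(!is.finite(unwound_bp))) {
    stop_input("values must be finite")
  }
  structure(data.frame(time_s = time_s, unwound_bp = unwound_bp),
            force_pN = as.numeric(force_pN),
            label = label,
            class = c("unwinding_trace", "data.frame"))
}

#' @export
print.unwinding_trace <- function(x, ...) {
  cat(sprintf("Unwinding trace '%s': %d samples, %.0f bp net\n",
              attr(x, "label"), nrow(x),
              x$unwound_bp[nrow(x)] - x$unwound_bp[1]))
  invisible(x)
}

#' Mass-photometry event set
#'
#' Per-landing interferometric contrasts, with calibrated masses when
#' available.
#'
#' @param contrasts dimensionless per-landing contrast values.
#' @param masses_kDa optional calibrated masses in kDa (same length).
#' @param condition free-text condition label.
#' @return a list of class `mass_event_set`.
#' @export
mass_event_set <- function(contrasts, masses_kDa = NULL, condition = "") {
  if (!is.numeric(contrasts) || any(!is.finite(contrasts))) {
    stop_input("contrasts must be finite numeric")
  }
  if (!is.null(masses_kDa) && length(masses_kDa) != length(contrasts)) {
    stop_input("masses_kDa must match contrasts length")
  }
  structure(list(contrasts = as.numeric(contrasts),
                 masses_kDa = masses_kDa,
                 condition = condition),
            class = "mass_event_set")
}

#' @export
print.mass_event_set <- function(x, ...) {
  cat(sprintf("Mass event set '%s': %d landings%s\n", x$condition,
              length(x$contrasts),
              if (is.null(x$masses_kDa)) " (uncalibrated)" else ""))
  invisible(x)
}
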