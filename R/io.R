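# File I/O: TSV/CSV dialects for trajectories, mass events, binding and
# ATPase tables; deterministic JSON output; run configuration.

.fmt_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

#' Read a bead trajectory file
#'
#' Tab- or comma-separated file with header columns `time_s`,
#' `extension_nm`, and optionally `transverse_nm`; one file per bead.
#'
#' @param path file path.
#' @param force_pN applied force metadata in pN.
#' @param label trajectory label (default: file name).
#' @return a [bead_trajectory()].
#' @export
read_trajectory <- function(path, force_pN = NA_real_,
                            label = basename(path)) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("time_s", "extension_nm")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop_input("malformed header in ", path, ": missing column(s) ",
               paste(missing_cols, collapse = ", "))
  }
  for (col in intersect(c(need, "transverse_nm"), names(dt))) {
    if (!is.numeric(dt[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(dt[[col]]))))[1]
      stop_input(sprintf("non-numeric value in column '%s' of %s (line %d)",
                         col, path, bad + 1L))
    }
  }
  bead_trajectory(
    time_s = dt$time_s, extension_nm = dt$extension_nm,
    transverse_nm = if ("transverse_nm" %in% names(dt)) dt$transverse_nm,
    force_pN = force_pN, label = label)
}

#' Write a bead trajectory file
#'
#' Writes tab-separated with 17 significant digits so that
#' `read_trajectory(write_trajectory(x))` is a lossless round trip.
#'
#' @param traj a [bead_trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "bead_trajectory"))
  out <- as.data.frame(lapply(as.data.frame(traj), .fmt_full))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Deterministic JSON output
#'
#' Writes JSON with numbers formatted to 12 significant digits, so identical
#' inputs give byte-identical files.
#'
#' @param x an R object (lists/data.frames of numbers and strings).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(12),
                       pretty = TRUE, na = "null", always_decimal = FALSE)
  invisible(path)
}

# documented schema for run_config(): key -> required type
.config_schema <- list(
  seed = "numeric",
  n_traces = "numeric", frame_rate_hz = "numeric", duration_s = "numeric",
  force_pN = "numeric", velocity_bp_per_s = "numeric",
  mean_processivity_bp = "numeric", pause_entry_per_s = "numeric",
  pause_exit_per_s = "numeric", reinitiation_per_s = "numeric",
  noise_sd_nm = "numeric", drift_nm_per_s = "numeric",
  ds_persistence_nm = "numeric", ds_rise_nm_per_bp = "numeric",
  ss_kuhn_nm = "numeric", ss_contour_nm_per_nt = "numeric",
  temperature_K = "numeric", nt_gained_per_bp = "numeric",
  ds_bp_total = "numeric", flap_nt = "numeric",
  handle_contribution_nm = "numeric",
  penalty = "numeric", pause_threshold_bp_per_s = "numeric",
  min_processivity_bp = "numeric", smoothing_window = "numeric",
  censor_guard_s = "numeric", merge_gap_s = "numeric",
  baseline_nm = "numeric",
  tether_length_nm = "numeric", kBT_pN_nm = "numeric",
  k_components = "numeric", tolerance_kDa = "numeric",
  epsilon_M_cm = "numeric", path_cm = "numeric", enzyme_M = "numeric",
  output_dir = "character", log_level = "character"
)

#' Run configuration
#'
#' Reads a JSON run-configuration file and validates it against the
#' documented schema before any computation: unknown keys are rejected and
#' every value must have the declared type.
#'
#' @param path path to a JSON config file, or `NULL` for an empty config.
#' @param overrides named list merged over the file contents.
#' @return a validated named list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) {
    if (!file.exists(path)) stop_input("config file not found: ", path)
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    list()
  }
  cfg[names(overrides)] <- overrides
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown)) {
    stop_input("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in names(cfg)) {
    want <- .config_schema[[key]]
    ok <- switch(want,
                 numeric = is.numeric(cfg[[key]]),
                 character = is.character(cfg[[key]]))
    if (!ok) stop_input(sprintf("config key '%s' must be %s", key, want))
  }
  structure(cfg, class = c("run_config", "list"))
}

# build sim_config from a run_config, using sim_config defaults elsewhere
.sim_config_from_run <- function(cfg, seed) {
  pick <- function(key, default) {
    if (!is.null(cfg[[key]])) cfg[[key]] else default
  }
  polymer <- polymer_params(
    ds_persistence_nm = pick("ds_persistence_nm", 45),
    ds_rise_nm_per_bp = pick("ds_rise_nm_per_bp", 0.338),
    ss_kuhn_nm = pick("ss_kuhn_nm", 1.5),
    ss_contour_nm_per_nt = pick("ss_contour_nm_per_nt", 0.56),
    temperature_K = pick("temperature_K", 298),
    nt_gained_per_bp = pick("nt_gained_per_bp", 1))
  geometry <- tether_geometry(
    ds_bp_total = pick("ds_bp_total", 6600),
    flap_nt = pick("flap_nt", 40),
    handle_contribution_nm = pick("handle_contribution_nm", 0))
  sim_config(
    seed = seed,
    n_traces = pick("n_traces", 25L),
    frame_rate_hz = pick("frame_rate_hz", 30),
    duration_s = pick("duration_s", 300),
    force_pN = pick("force_pN", 20),
    velocity_bp_per_s = pick("velocity_bp_per_s", 44),
    mean_processivity_bp = pick("mean_processivity_bp", 2300),
    pause_entry_per_s = pick("pause_entry_per_s", 0.005),
    pause_exit_per_s = pick("pause_exit_per_s", 0.5),
    reinitiation_per_s = pick("reinitiation_per_s", 0.01),
    noise_sd_nm = pick("noise_sd_nm", 5),
    drift_nm_per_s = pick("drift_nm_per_s", 0),
    polymer = polymer, geometry = geometry)
}
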