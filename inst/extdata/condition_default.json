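{
  "n_traces": 25,
  "duration_s": 300,
  "frame_rate_hz": 30,
  "force_pN": 20,
  "velocity_bp_per_s": 44,
  "mean_processivity_bp": 2300,
  "pause_entry_per_s": 0.005,
  "pause_exit_per_s": 0.5,
  "reinitiation_per_s": 0.01,
  "noise_sd_nm": 5,
  "drift_nm_per_s": 0,
  "ds_bp_total": 6600,
  "flap_nt": 40
}
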