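# Example pipeline configuration. Any key omitted here keeps its default
# (see default_config()). WLC keys: persistence_length_nm, rise_nm_per_bp,
# kT_pN_nm.
conditions:
  - "DPK+LINP1_0.6kbp"
  - "DPK+PAXX_0.6kbp"
protocol:
  low_force: 0.01        # pN
  high_force: 1.4        # pN
  low_duration: 120      # s
  high_duration: 120     # s
  sampling_rate: 10      # Hz
noise:
  extension_noise_sd_high: 15   # nm per sample at high force
  extension_noise_sd_low: 60    # nm per sample at low force
  drift_rate: 0                 # nm/s
fitting:
  k_detect: 5            # detection threshold, noise-sd units
  dwell_min: 3           # samples of hysteresis for a durable recovery
  smooth_window_s: 0.5   # moving-median window
  min_fit_n: 50          # below this, arithmetic averages replace fits
wlc:
  persistence_length_nm: 50
  rise_nm_per_bp: 0.34
  kT_pN_nm: 4.11
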