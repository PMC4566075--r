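# Experimental condition table: simulation_config overrides per condition.
# participation_p encodes the reported mean fraction of responsive ROIs
# per wave for each group; reported_mean_pct / reported_sd_pct carry the
# published mean +/- SD (in %) the recovery studies are scored against.
# Calcium-sensor recordings run at 0.74 Hz (150 frames, ~203 s);
# glutamate-sensor recordings run at 1.7 Hz with the frame count raised
# to keep a comparable recording duration (~200 s).
P7_control:
  participation_p: 0.42
  sensor: calcium
  frame_rate_hz: 0.74
  n_frames: 150
  reported_mean_pct: 42.0
  reported_sd_pct: 10.2
P9_control:
  participation_p: 0.48
  sensor: calcium
  frame_rate_hz: 0.74
  n_frames: 150
  reported_mean_pct: 48.0
  reported_sd_pct: 4.6
P11_control:
  participation_p: 0.13
  sensor: calcium
  frame_rate_hz: 0.74
  n_frames: 150
  reported_mean_pct: 13.0
  reported_sd_pct: 2.2
P11_TBOA:
  participation_p: 0.61
  sensor: calcium
  frame_rate_hz: 0.74
  n_frames: 150
  reported_mean_pct: 61.0
  reported_sd_pct: 4.3
P9_iGluSnFR:
  participation_p: 0.38
  sensor: glutamate
  frame_rate_hz: 1.7
  n_frames: 340
  reported_mean_pct: 38.0
  reported_sd_pct: 4.0
P11_iGluSnFR:
  participation_p: 0.06
  sensor: glutamate
  frame_rate_hz: 1.7
  n_frames: 340
  reported_mean_pct: 6.0
  reported_sd_pct: 2.0
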